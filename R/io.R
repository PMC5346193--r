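participant_columns <- c("participant_id", "centre", "age", "age_group",
                         "stage", "excision", "bmi", "smoking", "ehp30_pain",
                         "accepted_arms", "scheme_id", "allocated_arm")

#' Write participants to delimited text
#'
#' Columns: participant_id, centre, age, age_group, stage, excision, bmi,
#' smoking, ehp30_pain, accepted_arms (arm ids joined by `+`), scheme_id,
#' allocated_arm.
#'
#' @param participants Participant data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(participants, path) {
  stopifnot(all(participant_columns %in% names(participants)))
  utils::write.csv(participants[, participant_columns], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Read participants from delimited text
#'
#' Validates the documented header, types each column, and checks every
#' accepted-arm set against the design's class constraint and arm ids;
#' malformed rows are reported with their line numbers.
#'
#' @param path CSV path (header as written by [write_participants()]).
#' @param design A [trial_design()] used for validation.
#' @return Participant data frame (zero rows for a header-only file).
#' @export
read_participants <- function(path, design = preempt_design()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = "")
  missing_cols <- setdiff(participant_columns, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, participant_columns]
  for (col in c("age", "bmi", "ehp30_pain")) df[[col]] <- as.numeric(df[[col]])
  if (nrow(df) == 0) return(empty_participants())
  bad <- character(0)
  for (i in seq_len(nrow(df))) {
    arms <- strsplit(df$accepted_arms[i], "+", fixed = TRUE)[[1]]
    line <- i + 1L  # header is line 1
    unknown <- setdiff(arms, design_arm_ids(design))
    if (length(unknown)) {
      bad <- c(bad, sprintf("line %d: unknown arm id(s) %s", line,
                            paste(unknown, collapse = ", ")))
      next
    }
    ok <- tryCatch({validate_scheme(design, arms); TRUE},
                   error = function(e) FALSE)
    if (!ok) {
      bad <- c(bad, sprintf("line %d: accepted arms '%s' violate the class constraint",
                            line, df$accepted_arms[i]))
    } else if (!is.na(df$allocated_arm[i]) &&
               !df$allocated_arm[i] %in% arms) {
      bad <- c(bad, sprintf("line %d: allocated arm '%s' not in accepted set",
                            line, df$allocated_arm[i]))
    }
  }
  if (length(bad)) {
    stop("invalid participant record(s):\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  df$scheme_id <- vapply(strsplit(df$accepted_arms, "+", fixed = TRUE),
                         scheme_id, character(1))
  df
}

#' Run the complete pilot-design workflow
#'
#' Chains the toolkit end to end: obtain a pilot cohort (the reconstruction
#' fixture by default, or a fresh accrual simulation), summarise scheme
#' uptake, evaluate and rank every candidate design under the feasibility
#' rule, adapt the design, and compute the adapted design's sample-size
#' block. Returns one bundle; identical seed and inputs give a
#' byte-identical JSON serialisation.
#'
#' @param design A [trial_design()].
#' @param seed Integer seed.
#' @param cohort `"fixture"` (default) or `"simulate"`.
#' @param comparator Comparator arm id used if adaptation is needed
#'   (default `"COCP"`).
#' @param n_screened Screened count when `cohort = "simulate"`.
#' @param out_dir Optional directory; when given, writes `bundle.json`,
#'   `participants.csv` and a human-readable `report.txt`.
#' @return The report bundle (list).
#' @export
run_pilot_workflow <- function(design = preempt_design(), seed = 1L,
                               cohort = c("fixture", "simulate"),
                               comparator = "COCP", n_screened = 504L,
                               out_dir = NULL) {
  cohort <- match.arg(cohort)
  sim <- if (cohort == "fixture") pilot_fixture(seed, design) else
    simulate_accrual(design, n_screened = n_screened, seed = seed)
  participants <- sim$participants
  uptake <- summarise_uptake(participants, design)
  rule <- design$feasibility %||% feasibility_rule()
  ranked <- rank_candidates(participants, design, rule)
  adapted <- adapt_design(ranked, design, comparator = comparator)
  ss <- samplesize_block(adapted$samplesize)
  bundle <- list(
    seed = seed, cohort = cohort,
    flow = sim$summary,
    uptake = unclass(uptake),
    feasibility = lapply(ranked, unclass),
    adapted_design = unclass(adapted)[c("adapted", "arms", "main_comparison",
                                        "strata", "sub_randomisation")],
    samplesize = ss)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(bundle, file.path(out_dir, "bundle.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    write_participants(participants, file.path(out_dir, "participants.csv"))
    writeLines(utils::capture.output({
      print(uptake); for (c in ranked) print(c); print(adapted)
    }), file.path(out_dir, "report.txt"))
  }
  bundle
}
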