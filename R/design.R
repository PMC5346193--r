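#' Define a treatment arm
#'
#' An arm belongs to exactly one treatment class; the class structure drives
#' the admissibility rule for randomisation schemes (every scheme must
#' contain at least one arm from every class).
#'
#' @param arm_id Short unique token identifying the arm (e.g. `"LNG-IUS"`).
#' @param class_id Token naming the treatment class the arm belongs to.
#' @param label Free-text label; defaults to `arm_id`.
#' @return An object of class `flex_arm`.
#' @export
arm <- function(arm_id, class_id, label = arm_id) {
  stopifnot(is.character(arm_id), length(arm_id) == 1L, nzchar(arm_id),
            is.character(class_id), length(class_id) == 1L, nzchar(class_id))
  structure(list(arm_id = arm_id, class_id = class_id, label = label),
            class = "flex_arm")
}

#' Define a stratification (minimisation) factor
#'
#' @param factor_id Token identifying the factor.
#' @param levels Character vector of at least two unique level tokens.
#' @return An object of class `flex_factor`.
#' @export
trial_factor <- function(factor_id, levels) {
  stopifnot(is.character(factor_id), length(factor_id) == 1L)
  levels <- as.character(levels)
  if (length(levels) < 2L) {
    stop("factor '", factor_id, "' needs at least 2 levels", call. = FALSE)
  }
  if (anyDuplicated(levels)) {
    stop("factor '", factor_id, "' has duplicate levels", call. = FALSE)
  }
  structure(list(factor_id = factor_id, levels = levels),
            class = "flex_factor")
}

#' Assemble a trial design
#'
#' A design is a set of arms partitioned into treatment classes, together
#' with the stratification factors used by the minimisation algorithm, the
#' pilot feasibility rule, and the sample-size specification. Admissible
#' randomisation schemes are the subsets of arms containing at least one arm
#' from every class.
#'
#' @param arms List of [arm()] objects (at least two).
#' @param factors List of [trial_factor()] objects (may be empty).
#' @param feasibility A [feasibility_rule()], or `NULL`.
#' @param samplesize A [samplesize_spec()], or `NULL`.
#' @return An object of class `flex_design`.
#' @seealso [preempt_design()] for the shipped reference configuration.
#' @export
trial_design <- function(arms, factors = list(), feasibility = NULL,
                         samplesize = NULL) {
  if (length(arms) < 2L) stop("a design needs at least 2 arms", call. = FALSE)
  ids <- vapply(arms, function(a) a$arm_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate arm_id in design", call. = FALSE)
  classes <- unique(vapply(arms, function(a) a$class_id, character(1)))
  for (cl in classes) {
    if (!any(vapply(arms, function(a) a$class_id == cl, logical(1)))) {
      stop("class '", cl, "' has no arms", call. = FALSE)
    }
  }
  fids <- vapply(factors, function(f) f$factor_id, character(1))
  if (anyDuplicated(fids)) stop("duplicate factor_id in design", call. = FALSE)
  names(arms) <- ids
  names(factors) <- fids
  structure(list(arms = arms, classes = classes, factors = factors,
                 feasibility = feasibility, samplesize = samplesize),
            class = "flex_design")
}

#' @export
print.flex_design <- function(x, ...) {
  cat("Flexible-entry trial design\n")
  for (cl in x$classes) {
    in_cl <- vapply(x$arms, function(a) a$class_id == cl, logical(1))
    cat("  class ", cl, ": ",
        paste(names(x$arms)[in_cl], collapse = ", "), "\n", sep = "")
  }
  if (length(x$factors)) {
    cat("  factors: ",
        paste(vapply(x$factors, function(f)
          paste0(f$factor_id, " {", paste(f$levels, collapse = ","), "}"),
          character(1)), collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

design_arm_ids <- function(design) names(design$arms)

design_arm_classes <- function(design) {
  vapply(design$arms, function(a) a$class_id, character(1))
}

#' Canonical scheme identifier
#'
#' A scheme's identity is its arm set; the identifier is the lexicographically
#' sorted arm ids joined by `"+"`, so permuting the input never changes it.
#'
#' @param arm_ids Character vector of arm ids.
#' @return A single string.
#' @export
scheme_id <- function(arm_ids) {
  paste(sort(unique(as.character(arm_ids))), collapse = "+")
}

new_scheme <- function(arm_ids) {
  arm_ids <- sort(unique(as.character(arm_ids)))
  structure(list(scheme_id = scheme_id(arm_ids), arm_ids = arm_ids),
            class = "flex_scheme")
}

#' @export
print.flex_scheme <- function(x, ...) {
  cat("Scheme ", x$scheme_id, " (", length(x$arm_ids), " arms)\n", sep = "")
  invisible(x)
}

#' Validate an arm set as an admissible randomisation scheme
#'
#' A scheme is admissible when it has at least two arms and contains at
#' least one arm from every treatment class of the design ("one LARC and one
#' non-LARC" in the reference configuration).
#'
#' @param design A [trial_design()].
#' @param arm_ids Character vector (or set) of arm ids.
#' @return A canonical `flex_scheme`; errors if inadmissible.
#' @export
validate_scheme <- function(design, arm_ids) {
  arm_ids <- unique(as.character(arm_ids))
  unknown <- setdiff(arm_ids, design_arm_ids(design))
  if (length(unknown)) {
    stop("unknown arm id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(arm_ids) < 2L) {
    stop("a scheme needs at least 2 arms", call. = FALSE)
  }
  cls <- design_arm_classes(design)[arm_ids]
  missing_cl <- setdiff(design$classes, cls)
  if (length(missing_cl)) {
    stop("scheme violates class constraint: no arm from class ",
         paste(missing_cl, collapse = ", "), call. = FALSE)
  }
  new_scheme(arm_ids)
}

#' Enumerate all admissible randomisation schemes of a design
#'
#' Every subset of arms containing at least one arm from each class, in
#' canonical (lexicographic scheme-id) order. For two classes of sizes a and
#' b the count is (2^a - 1)(2^b - 1); the reference 2x2 design has nine.
#'
#' @param design A [trial_design()].
#' @return A named list of `flex_scheme` objects, named by scheme id.
#' @export
enumerate_schemes <- function(design) {
  ids <- design_arm_ids(design)
  cls <- design_arm_classes(design)
  n <- length(ids)
  schemes <- list()
  for (mask in seq_len(2^n - 1L)) {
    take <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    sub <- ids[take]
    if (length(sub) < 2L) next
    if (all(design$classes %in% cls[sub])) {
      s <- new_scheme(sub)
      schemes[[s$scheme_id]] <- s
    }
  }
  schemes[order(names(schemes))]
}

#' Does a scheme cover a candidate design?
#'
#' `TRUE` when the participant holding this scheme accepted every arm of the
#' candidate design, i.e. the candidate arm set is a subset of the scheme's.
#'
#' @param scheme A `flex_scheme` (or character vector of accepted arm ids).
#' @param candidate_arms Character vector of candidate arm ids.
#' @return Logical scalar.
#' @export
scheme_compatible_with_design <- function(scheme, candidate_arms) {
  accepted <- if (inherits(scheme, "flex_scheme")) scheme$arm_ids else
    as.character(scheme)
  all(candidate_arms %in% accepted)
}

#' Reference four-arm contraceptive trial design
#'
#' The shipped configuration: class `"LARC"` holding the levonorgestrel
#' intrauterine system (`LNG-IUS`) and depot medroxyprogesterone acetate
#' (`DMPA`), class `"non-LARC"` holding the combined oral contraceptive pill
#' (`COCP`) and no treatment (`NONE`); minimisation factors are disease
#' stage (I-IV), extent of excision, age group (<35 / >=35) and recruiting
#' centre; the pilot feasibility threshold is 10% and the sample-size block
#' targets an EHP-30 pain difference of 10 points (SD 25) at Bonferroni
#' alpha 0.01 and 80% power across four groups.
#'
#' @param centres Character vector of recruiting-centre labels.
#' @return A [trial_design()].
#' @export
preempt_design <- function(centres = paste0("C", 1:6)) {
  trial_design(
    arms = list(
      arm("LNG-IUS", "LARC", "levonorgestrel intrauterine system"),
      arm("DMPA", "LARC", "depot medroxyprogesterone acetate"),
      arm("COCP", "non-LARC", "combined oral contraceptive pill"),
      arm("NONE", "non-LARC", "no treatment")
    ),
    factors = list(
      trial_factor("stage", c("I", "II", "III", "IV")),
      trial_factor("excision", c("complete", "incomplete")),
      trial_factor("age_group", c("<35", ">=35")),
      trial_factor("centre", centres)
    ),
    feasibility = feasibility_rule(threshold = 0.10),
    samplesize = samplesize_spec(delta = 10, sd = 25, alpha = 0.05,
                                 power = 0.80, n_comparisons = 6,
                                 attrition = 0.20, round_to = 50,
                                 n_groups = 4)
  )
}

#' Read a trial design from a YAML or JSON configuration file
#'
#' The schema mirrors [trial_design()]: a `classes` map of class id to a
#' vector of arm ids (or arm id to label maps), a `factors` map of factor id
#' to level vector, and optional `feasibility` and `samplesize` blocks.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [trial_design()].
#' @export
read_design_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$classes)) stop("config lacks a 'classes' block", call. = FALSE)
  arms <- list()
  for (cl in names(cfg$classes)) {
    entry <- cfg$classes[[cl]]
    if (is.list(entry) && !is.null(names(entry))) {
      for (aid in names(entry)) arms[[length(arms) + 1L]] <-
          arm(aid, cl, as.character(entry[[aid]]))
    } else {
      for (aid in as.character(unlist(entry))) arms[[length(arms) + 1L]] <-
          arm(aid, cl)
    }
  }
  factors <- list()
  for (fid in names(cfg$factors)) {
    factors[[length(factors) + 1L]] <-
      trial_factor(fid, as.character(unlist(cfg$factors[[fid]])))
  }
  feas <- NULL
  if (!is.null(cfg$feasibility)) {
    feas <- feasibility_rule(
      threshold = cfg$feasibility$threshold %||% 0.10,
      metric = cfg$feasibility$metric %||% "compatible_uptake")
  }
  ss <- NULL
  if (!is.null(cfg$samplesize)) {
    s <- cfg$samplesize
    ss <- samplesize_spec(delta = s$delta, sd = s$sd, alpha = s$alpha,
                          power = s$power,
                          n_comparisons = s$n_comparisons %||% 1L,
                          attrition = s$attrition %||% 0,
                          round_to = s$round_to %||% 1L,
                          n_groups = s$n_groups %||% 2L)
  }
  trial_design(arms, factors, feasibility = feas, samplesize = ss)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
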