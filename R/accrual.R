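#' Screening-outcome (eligibility) model
#'
#' Categorical probabilities over the outcome of screening one individual.
#' Defaults are the pilot's empirical rates out of 504 screened: 77
#' randomised; 42 planning to conceive; 35 with contraindications; 33 with
#' no endometriosis found at laparoscopy; 94 declining because of a
#' treatment preference; the remaining 223 pooled as other exclusions.
#'
#' @param probs Named numeric vector over the outcomes `randomised`,
#'   `plan_to_conceive`, `contraindication`, `no_endometriosis`,
#'   `declined_preference`, `other_exclusion`; must sum to 1.
#' @return An object of class `flex_eligibility`.
#' @export
eligibility_model <- function(probs = c(randomised = 77, plan_to_conceive = 42,
                                        contraindication = 35,
                                        no_endometriosis = 33,
                                        declined_preference = 94,
                                        other_exclusion = 223) / 504) {
  required <- c("randomised", "plan_to_conceive", "contraindication",
                "no_endometriosis", "declined_preference", "other_exclusion")
  if (!setequal(names(probs), required)) {
    stop("eligibility probs must be named over: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  probs <- probs[required]
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    stop("eligibility probabilities must be >= 0 and sum to 1", call. = FALSE)
  }
  structure(list(probs = probs), class = "flex_eligibility")
}

#' Preference model for scheme selection
#'
#' Either a categorical distribution over the design's enumerated schemes
#' (`mode = "per-scheme"`) or independent per-arm acceptance probabilities
#' conditioned on the class constraint by rejection (`mode = "per-arm"`).
#' The default per-scheme distribution is the pilot's empirical scheme
#' frequencies (see [pilot_fixture()]).
#'
#' @param mode `"per-scheme"` or `"per-arm"`.
#' @param scheme_probs Named numeric vector over scheme ids, summing to 1
#'   (per-scheme mode). `NULL` selects the pilot empirical distribution for
#'   the reference design.
#' @param arm_probs Named numeric vector of acceptance probabilities in
#'   [0, 1] per arm (per-arm mode).
#' @return An object of class `flex_preference`.
#' @export
preference_model <- function(mode = c("per-scheme", "per-arm"),
                             scheme_probs = NULL, arm_probs = NULL) {
  mode <- match.arg(mode)
  if (mode == "per-scheme" && !is.null(scheme_probs)) {
    if (any(scheme_probs < 0) || abs(sum(scheme_probs) - 1) > 1e-8) {
      stop("scheme probabilities must be >= 0 and sum to 1", call. = FALSE)
    }
  }
  if (mode == "per-arm") {
    if (is.null(arm_probs) || any(arm_probs < 0) || any(arm_probs > 1)) {
      stop("per-arm mode needs acceptance probabilities in [0, 1]",
           call. = FALSE)
    }
  }
  structure(list(mode = mode, scheme_probs = scheme_probs,
                 arm_probs = arm_probs), class = "flex_preference")
}

#' Covariate model for simulated participants
#'
#' Defaults emulate the pilot cohort: age from a normal(31, 7.5) truncated
#' to [16, 45]; disease stage I-IV with probabilities (0.47, 0.26, 0.14,
#' 0.13); complete excision with probability 0.92; EHP-30 pain from a
#' normal(58, 18.5) truncated to [0, 100]; ever-smoked probability 0.48;
#' BMI normal(27, 5.7) with missingness probability 17/77 (missing
#' completely at random); centre uniform over the design's centres.
#'
#' @param age_mean,age_sd,age_bounds Age distribution parameters.
#' @param stage_probs Probabilities for stages I-IV.
#' @param p_complete_excision Probability of complete excision.
#' @param pain_mean,pain_sd Pain-score normal parameters (truncated [0,100]).
#' @param p_smoking Ever-smoked probability.
#' @param bmi_mean,bmi_sd,p_bmi_missing BMI parameters and missingness.
#' @param age_cut Age-group cut point (years).
#' @return An object of class `flex_covariates`.
#' @export
covariate_model <- function(age_mean = 31, age_sd = 7.5,
                            age_bounds = c(16, 45),
                            stage_probs = c(I = 0.47, II = 0.26, III = 0.14,
                                            IV = 0.13),
                            p_complete_excision = 0.92,
                            pain_mean = 58, pain_sd = 18.5,
                            p_smoking = 0.48,
                            bmi_mean = 27, bmi_sd = 5.7,
                            p_bmi_missing = 17 / 77,
                            age_cut = 35) {
  if (abs(sum(stage_probs) - 1) > 1e-8) {
    stop("stage probabilities must sum to 1", call. = FALSE)
  }
  structure(list(age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds,
                 stage_probs = stage_probs,
                 p_complete_excision = p_complete_excision,
                 pain_mean = pain_mean, pain_sd = pain_sd,
                 p_smoking = p_smoking, bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 p_bmi_missing = p_bmi_missing, age_cut = age_cut),
            class = "flex_covariates")
}

# Truncated-normal draws by rejection; bounds are always a few SDs wide here
# so acceptance is high.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

draw_covariates <- function(n, model, centres, age_groups = NULL) {
  age <- if (is.null(age_groups)) {
    rtruncnorm(n, model$age_mean, model$age_sd,
               model$age_bounds[1], model$age_bounds[2])
  } else {
    # condition age on a preassigned age group (used by the pilot fixture)
    a <- numeric(n)
    lo <- age_groups == paste0("<", model$age_cut)
    a[lo] <- rtruncnorm(sum(lo), model$age_mean, model$age_sd,
                        model$age_bounds[1], model$age_cut - 1e-9)
    a[!lo] <- rtruncnorm(sum(!lo), model$age_mean, model$age_sd,
                         model$age_cut, model$age_bounds[2])
    a
  }
  bmi <- stats::rnorm(n, model$bmi_mean, model$bmi_sd)
  bmi[stats::runif(n) < model$p_bmi_missing] <- NA_real_
  data.frame(
    centre = sample(centres, n, replace = TRUE),
    age = round(age, 1),
    age_group = ifelse(age < model$age_cut, paste0("<", model$age_cut),
                       paste0(">=", model$age_cut)),
    stage = sample(names(model$stage_probs), n, replace = TRUE,
                   prob = model$stage_probs),
    excision = ifelse(stats::runif(n) < model$p_complete_excision,
                      "complete", "incomplete"),
    bmi = round(bmi, 1),
    smoking = ifelse(stats::runif(n) < model$p_smoking, "yes", "no"),
    ehp30_pain = round(rtruncnorm(n, model$pain_mean, model$pain_sd, 0, 100),
                       1),
    stringsAsFactors = FALSE)
}

draw_scheme_ids <- function(n, design, preference) {
  schemes <- enumerate_schemes(design)
  if (preference$mode == "per-scheme") {
    probs <- preference$scheme_probs
    if (is.null(probs)) probs <- pilot_scheme_probs(design)
    unknown <- setdiff(names(probs), names(schemes))
    if (length(unknown)) {
      stop("scheme probabilities name unknown schemes: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    sample(names(probs), n, replace = TRUE, prob = probs)
  } else {
    arm_ids <- design_arm_ids(design)
    p <- preference$arm_probs[arm_ids]
    if (anyNA(p)) stop("per-arm probabilities must cover every arm",
                       call. = FALSE)
    out <- character(n)
    need <- seq_len(n)
    while (length(need)) {  # condition on the class constraint by rejection
      acc <- matrix(stats::runif(length(need) * length(arm_ids)) <
                      rep(p, each = length(need)), nrow = length(need))
      ok <- vapply(seq_len(nrow(acc)), function(i) {
        ids <- arm_ids[acc[i, ]]
        length(ids) >= 2 &&
          all(design$classes %in% design_arm_classes(design)[ids])
      }, logical(1))
      out[need[ok]] <- vapply(which(ok), function(i)
        scheme_id(arm_ids[acc[i, ]]), character(1))
      need <- need[!ok]
    }
    out
  }
}

#' Pilot empirical per-scheme preference distribution
#'
#' The nine-scheme selection frequencies of the 77-participant pilot
#' fixture, as probabilities (see [pilot_fixture()] for how the
#' under-determined cells are filled).
#'
#' @param design The reference [preempt_design()] (or compatible 2x2 design).
#' @return Named probability vector over scheme ids.
#' @export
pilot_scheme_probs <- function(design = preempt_design()) {
  counts <- pilot_scheme_counts(design)
  counts / sum(counts)
}

#' Simulate screening and preference-driven accrual
#'
#' Each screened individual draws a screening outcome from the eligibility
#' model; randomised individuals draw a scheme from the preference model and
#' covariates from the covariate model. Fully reproducible from the seed.
#'
#' @param design A [trial_design()].
#' @param eligibility An [eligibility_model()].
#' @param preference A [preference_model()].
#' @param covariates A [covariate_model()].
#' @param n_screened Number of individuals screened (>= 0).
#' @param seed Integer seed.
#' @return List with `participants` (data frame of randomised participants;
#'   see [write_participants()] for the column layout) and `summary` (a
#'   trial-flow summary list satisfying screened = randomised + exclusions).
#' @export
simulate_accrual <- function(design, eligibility = eligibility_model(),
                             preference = preference_model(),
                             covariates = covariate_model(),
                             n_screened = 504L, seed = 1L) {
  stopifnot(n_screened >= 0)
  set.seed(seed)
  outcomes <- if (n_screened > 0) {
    sample(names(eligibility$probs), n_screened, replace = TRUE,
           prob = eligibility$probs)
  } else character(0)
  n_rand <- sum(outcomes == "randomised")
  centres <- design$factors[["centre"]]$levels %||% "C1"
  if (n_rand > 0) {
    cov <- draw_covariates(n_rand, covariates, centres)
    sid <- draw_scheme_ids(n_rand, design, preference)
    participants <- cbind(
      data.frame(participant_id = sprintf("P%04d", seq_len(n_rand)),
                 stringsAsFactors = FALSE),
      cov,
      data.frame(accepted_arms = sid, scheme_id = sid,
                 allocated_arm = NA_character_, stringsAsFactors = FALSE))
  } else {
    participants <- empty_participants()
  }
  list(participants = participants,
       summary = flow_summary(outcomes, participants))
}

empty_participants <- function() {
  data.frame(participant_id = character(), centre = character(),
             age = numeric(), age_group = character(), stage = character(),
             excision = character(), bmi = numeric(), smoking = character(),
             ehp30_pain = numeric(), accepted_arms = character(),
             scheme_id = character(), allocated_arm = character(),
             stringsAsFactors = FALSE)
}

flow_summary <- function(outcomes, participants) {
  reasons <- c("plan_to_conceive", "contraindication", "no_endometriosis",
               "declined_preference", "other_exclusion")
  excl <- vapply(reasons, function(r) sum(outcomes == r), integer(1))
  per_scheme <- if (nrow(participants)) {
    tab <- table(participants$scheme_id)
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  per_arm <- if (nrow(participants) && any(!is.na(participants$allocated_arm))) {
    tab <- table(participants$allocated_arm)
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  list(screened = length(outcomes),
       randomised = sum(outcomes == "randomised"),
       exclusions = as.list(excl),
       per_scheme = as.list(per_scheme),
       per_arm_allocated = as.list(per_arm))
}

#' Summarise randomisation-scheme uptake
#'
#' Per-scheme selection counts, per-arm willingness (how many participants
#' accepted each arm), and the preference aggregates used by the pilot
#' report: acceptance of all arms, single-arm preference within each class,
#' and two-way selections (exactly one arm per class). Percentages are
#' reported against the number randomised, both integer-rounded and to one
#' decimal place.
#'
#' @param participants Participant data frame (all randomised).
#' @param design A [trial_design()]; default reference design.
#' @return An object of class `flex_uptake` (a list of tables).
#' @export
summarise_uptake <- function(participants, design = preempt_design()) {
  n <- nrow(participants)
  if (n == 0) stop("no randomised participants", call. = FALSE)
  accepted <- strsplit(participants$accepted_arms, "+", fixed = TRUE)
  cls <- design_arm_classes(design)
  all_arms <- design_arm_ids(design)

  per_scheme <- sort(table(vapply(accepted, scheme_id, character(1))),
                     decreasing = TRUE)
  per_arm <- vapply(all_arms, function(a)
    sum(vapply(accepted, function(s) a %in% s, logical(1))), integer(1))

  n_per_class <- function(s) vapply(design$classes, function(cl)
    sum(cls[s] == cl), integer(1))
  counts_mat <- vapply(accepted, n_per_class,
                       integer(length(design$classes)))
  if (is.null(dim(counts_mat))) counts_mat <- matrix(counts_mat, nrow = 1)

  all_four <- sum(vapply(accepted, function(s) setequal(s, all_arms),
                         logical(1)))
  single_pref <- vapply(seq_along(design$classes), function(i)
    sum(counts_mat[i, ] == 1L), integer(1))
  names(single_pref) <- design$classes
  two_way <- sum(apply(counts_mat == 1L, 2, all))

  pct <- function(k) list(count = as.integer(k),
                          pct = as.integer(round(100 * k / n)),
                          pct_1dp = round(100 * k / n, 1))
  structure(list(
    n_randomised = n,
    per_scheme = lapply(stats::setNames(as.integer(per_scheme),
                                        names(per_scheme)), pct),
    per_arm_willingness = lapply(per_arm, pct),
    all_arms = pct(all_four),
    single_class_preference = lapply(single_pref, pct),
    two_way = pct(two_way)
  ), class = "flex_uptake")
}

#' @export
print.flex_uptake <- function(x, ...) {
  cat("Uptake summary (n =", x$n_randomised, "randomised)\n")
  cat("  all arms accepted:", x$all_arms$count,
      paste0("(", x$all_arms$pct, "%)\n"))
  for (cl in names(x$single_class_preference)) {
    e <- x$single_class_preference[[cl]]
    cat("  single-", cl, " preference: ", e$count, " (", e$pct, "%)\n",
        sep = "")
  }
  cat("  two-way selections:", x$two_way$count,
      paste0("(", x$two_way$pct, "%)\n"))
  cat("  per scheme:\n")
  for (s in names(x$per_scheme)) {
    e <- x$per_scheme[[s]]
    cat(sprintf("    %-28s %3d (%d%%)\n", s, e$count, e$pct))
  }
  invisible(x)
}
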