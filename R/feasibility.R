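#' Pilot feasibility decision rule
#'
#' A candidate design is infeasible when its uptake metric falls below the
#' threshold (10% of randomisations in the reference design). Two readings
#' of "a group attracting less than 10%" are supported: `compatible_uptake`
#' (fraction of participants whose accepted-arm set contains every candidate
#' arm — the reading under which the pilot ruled out the four-way design at
#' 6%) and `allocation_share` (the smallest per-arm share of actual
#' allocations among the candidate's arms). Both metrics are always
#' reported; the configured one decides the verdict.
#'
#' @param threshold Proportion in (0, 1); default 0.10. A threshold of 0
#'   makes every candidate feasible.
#' @param metric `"compatible_uptake"` (default) or `"allocation_share"`.
#' @return An object of class `flex_feasibility_rule`.
#' @export
feasibility_rule <- function(threshold = 0.10,
                             metric = c("compatible_uptake",
                                        "allocation_share")) {
  metric <- match.arg(metric)
  stopifnot(threshold >= 0, threshold < 1)
  structure(list(threshold = threshold, metric = metric),
            class = "flex_feasibility_rule")
}

#' Evaluate one candidate design against pilot uptake
#'
#' Computes, for a candidate arm subset, the compatible uptake (fraction of
#' participants who accepted every candidate arm), the exact-selection share
#' (fraction whose accepted set is exactly the candidate — the framing under
#' which a sole DMPA-versus-COCP trial attracted 18%), and, when
#' allocations are present, the minimum per-arm allocation share. The
#' verdict compares the rule's configured metric with its threshold.
#'
#' @param candidate_arms Character vector of arm ids (must satisfy the
#'   design's class constraint).
#' @param participants Randomised participant data frame.
#' @param rule A [feasibility_rule()].
#' @param design A [trial_design()].
#' @return An object of class `flex_candidate`: arm ids, metric values,
#'   `feasible` verdict.
#' @export
evaluate_candidate <- function(candidate_arms, participants,
                               rule = feasibility_rule(),
                               design = preempt_design()) {
  if (nrow(participants) == 0) stop("no randomised participants",
                                    call. = FALSE)
  scheme <- validate_scheme(design, candidate_arms)
  n <- nrow(participants)
  accepted <- strsplit(participants$accepted_arms, "+", fixed = TRUE)
  compat <- vapply(accepted, scheme_compatible_with_design,
                   logical(1), candidate_arms = scheme$arm_ids)
  compatible_uptake <- sum(compat) / n
  exact_selection <- sum(vapply(accepted, setequal, logical(1),
                                y = scheme$arm_ids)) / n
  allocation_share <- NA_real_
  if (any(!is.na(participants$allocated_arm))) {
    alloc <- participants$allocated_arm
    shares <- vapply(scheme$arm_ids, function(a) sum(alloc == a, na.rm = TRUE),
                     numeric(1)) / n
    allocation_share <- min(shares)
  }
  metric_value <- switch(rule$metric,
                         compatible_uptake = compatible_uptake,
                         allocation_share = allocation_share)
  structure(list(
    scheme_id = scheme$scheme_id, arm_ids = scheme$arm_ids,
    n = n,
    compatible_uptake = compatible_uptake,
    exact_selection = exact_selection,
    allocation_share = allocation_share,
    metric = rule$metric, metric_value = metric_value,
    threshold = rule$threshold,
    feasible = !is.na(metric_value) && metric_value >= rule$threshold
  ), class = "flex_candidate")
}

#' @export
print.flex_candidate <- function(x, ...) {
  cat(sprintf(
    "Candidate %s: compatible uptake %.1f%%, exact selection %.1f%%%s -> %s\n",
    x$scheme_id, 100 * x$compatible_uptake, 100 * x$exact_selection,
    if (!is.na(x$allocation_share))
      sprintf(", min allocation share %.1f%%", 100 * x$allocation_share)
    else "",
    if (x$feasible) "feasible" else
      sprintf("infeasible (%s %.1f%% < %.0f%%)", x$metric,
              100 * x$metric_value, 100 * x$threshold)))
  invisible(x)
}

#' Evaluate and rank every admissible candidate design
#'
#' Sweeps all admissible arm subsets of the design (every enumerated
#' scheme), evaluates each with [evaluate_candidate()], and sorts by the
#' rule's metric descending, breaking ties by arm count descending then
#' scheme id.
#'
#' @inheritParams evaluate_candidate
#' @return List of `flex_candidate`, best first.
#' @export
rank_candidates <- function(participants, design = preempt_design(),
                            rule = feasibility_rule()) {
  schemes <- enumerate_schemes(design)
  cands <- lapply(schemes, function(s)
    evaluate_candidate(s$arm_ids, participants, rule, design))
  metric <- vapply(cands, function(c) c$metric_value, numeric(1))
  metric[is.na(metric)] <- -Inf
  n_arms <- vapply(cands, function(c) length(c$arm_ids), integer(1))
  ids <- vapply(cands, function(c) c$scheme_id, character(1))
  cands[order(-metric, -n_arms, ids)]
}

#' Adapt the trial design after the pilot
#'
#' Applies the prespecified decision process: if the full multi-arm design
#' is feasible it is retained unchanged; otherwise the design collapses to a
#' class-versus-comparator comparison in which the preferred class member is
#' chosen by the participant before randomisation (strata: one per class
#' member, plus a no-preference stratum offered sub-randomisation between
#' the class members), with a revised sample-size specification attached.
#'
#' @param ranked Output of [rank_candidates()] (or a list of evaluated
#'   candidates including the full design).
#' @param design The pilot [trial_design()].
#' @param comparator Arm id of the designated comparator (reference: COCP,
#'   chosen on external evidence, supplied as an input). Required when the
#'   full design is infeasible.
#' @param preferred_class Class whose members are preselected (reference:
#'   "LARC").
#' @param revised_spec [samplesize_spec()] for the adapted design; the
#'   default is the reference revision (8-point difference, SD 22, 90%
#'   power, two-sided alpha 0.05, 20% attrition).
#' @return An object of class `flex_adapted_design`.
#' @export
adapt_design <- function(ranked, design = preempt_design(),
                         comparator = NULL, preferred_class = NULL,
                         revised_spec = samplesize_spec(
                           delta = 8, sd = 22, alpha = 0.05, power = 0.90,
                           attrition = 0.20, round_to = 1L, n_groups = 2L)) {
  full_id <- scheme_id(design_arm_ids(design))
  ids <- vapply(ranked, function(c) c$scheme_id, character(1))
  idx <- match(full_id, ids)
  if (is.na(idx)) stop("ranked candidates must include the full design",
                       call. = FALSE)
  full <- ranked[[idx]]
  if (full$feasible) {
    return(structure(list(
      adapted = FALSE, arms = design_arm_ids(design),
      main_comparison = NULL, strata = NULL, sub_randomisation = NULL,
      samplesize = design$samplesize), class = "flex_adapted_design"))
  }
  if (is.null(comparator)) {
    stop("pilot inconclusive: full design infeasible and no comparator ",
         "designated for adaptation", call. = FALSE)
  }
  cls <- design_arm_classes(design)
  if (!comparator %in% names(cls)) {
    stop("unknown comparator arm: ", comparator, call. = FALSE)
  }
  if (is.null(preferred_class)) {
    preferred_class <- setdiff(design$classes, cls[[comparator]])[1]
  }
  members <- names(cls)[cls == preferred_class]
  structure(list(
    adapted = TRUE,
    arms = c(members, comparator),
    main_comparison = list(class_id = preferred_class,
                           comparator = comparator),
    strata = c(members, "no-preference"),
    sub_randomisation = list(stratum = "no-preference", arms = members),
    samplesize = revised_spec), class = "flex_adapted_design")
}

#' @export
print.flex_adapted_design <- function(x, ...) {
  if (!x$adapted) {
    cat("Design retained unchanged:", paste(x$arms, collapse = ", "), "\n")
  } else {
    cat("Adapted design:", x$main_comparison$class_id, "(as a class) vs",
        x$main_comparison$comparator, "\n")
    cat("  prerandomisation strata:", paste(x$strata, collapse = ", "), "\n")
    cat("  sub-randomisation in '", x$sub_randomisation$stratum, "': ",
        paste(x$sub_randomisation$arms, collapse = " vs "), "\n", sep = "")
  }
  if (!is.null(x$samplesize)) {
    b <- samplesize_block(x$samplesize)
    cat(sprintf("  sample size: %d per group, %d total, recruit %d\n",
                b$n_per_group, b$n_total, b$recruitment_target))
  }
  invisible(x)
}

#' Stratified analysis sets of an adapted design
#'
#' Participants enter the subgroup comparison of the class member they
#' preselected: only those selecting a given member before randomisation
#' are included in that member's versus-comparator analysis.
#'
#' @param adapted A `flex_adapted_design` with `adapted = TRUE`.
#' @param preselected Character vector of each participant's prerandomised
#'   class-member choice (or `"no-preference"`).
#' @return Named list mapping each class member to the indices of
#'   participants in its analysis set.
#' @export
stratified_analysis_sets <- function(adapted, preselected) {
  stopifnot(inherits(adapted, "flex_adapted_design"), adapted$adapted)
  members <- adapted$sub_randomisation$arms
  stats::setNames(lapply(members, function(m) which(preselected == m)),
                  members)
}
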