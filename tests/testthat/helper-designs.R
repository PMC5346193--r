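# Small designs used across tests.

two_arm_design <- function() {
  trial_design(
    arms = list(arm("A", "left"), arm("B", "right")),
    factors = list(trial_factor("sex", c("f", "m"))))
}

# a arms in class X, b arms in class Y, one binary factor
ab_design <- function(a, b) {
  arms <- c(lapply(seq_len(a), function(i) arm(paste0("X", i), "X")),
            lapply(seq_len(b), function(i) arm(paste0("Y", i), "Y")))
  trial_design(arms = arms,
               factors = list(trial_factor("g", c("lo", "hi"))))
}

# Independent brute-force scheme enumerator: loop over every arm subset and
# keep those with >= 2 arms covering all classes.
brute_force_schemes <- function(design) {
  ids <- names(design$arms)
  cls <- vapply(design$arms, function(x) x$class_id, character(1))
  keep <- list()
  for (k in 2:length(ids)) {
    combos <- utils::combn(ids, k, simplify = FALSE)
    for (s in combos) {
      if (all(unique(cls) %in% cls[s])) keep[[length(keep) + 1L]] <- sort(s)
    }
  }
  keep
}

# Participant data frame with given accepted-arm sets and minimal covariates.
cohort_of <- function(accepted_sets, design = preempt_design()) {
  n <- length(accepted_sets)
  if (n == 0) return(flexrand:::empty_participants())
  ids <- vapply(accepted_sets, function(s) paste(sort(s), collapse = "+"),
                character(1))
  data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    centre = "C1", age = 30, age_group = "<35", stage = "I",
    excision = "complete", bmi = 25, smoking = "no", ehp30_pain = 50,
    accepted_arms = ids, scheme_id = ids, allocated_arm = NA_character_,
    stringsAsFactors = FALSE)
}
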