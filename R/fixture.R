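# Feasibility of a transportation problem restricted to the free-cell
# pattern (Gale-Hoffman): with equal total supply and demand, an integral
# fill exists iff every subset of rows can ship all its supply into the
# columns it reaches. Row counts here are tiny, so subsets are enumerated.
transport_feasible <- function(rr, cc, free) {
  if (any(rr < 0) || any(cc < 0)) return(FALSE)
  if (sum(rr) != sum(cc)) return(FALSE)
  nr <- length(rr)
  for (mask in seq_len(2^nr - 1L)) {
    rows <- which(as.logical(bitwAnd(mask, 2^(seq_len(nr) - 1L))))
    reach <- apply(free[rows, , drop = FALSE], 2, any)
    if (sum(rr[rows]) > sum(cc[reach])) return(FALSE)
  }
  TRUE
}

#' Deterministic greedy fill of a partially fixed contingency grid
#'
#' Completes a non-negative integer grid with given row and column totals
#' and some cells fixed, iterating the free cells in row-major order and
#' assigning each the maximum value that still leaves the remaining grid
#' completable (checked by a transportation-feasibility test). Used to
#' resolve the interior of the pilot's scheme-selection grid, which the
#' printed marginals under-determine.
#'
#' @param row_tot,col_tot Integer marginal totals (must agree in sum).
#' @param fixed Numeric matrix of the grid's dimensions; `NA` marks a free
#'   cell, any other value is fixed.
#' @return Completed integer matrix with the requested marginals.
#' @export
fill_grid <- function(row_tot, col_tot, fixed) {
  stopifnot(nrow(fixed) == length(row_tot), ncol(fixed) == length(col_tot))
  if (sum(row_tot) != sum(col_tot)) {
    stop("grid marginals and fixed cells are inconsistent", call. = FALSE)
  }
  grid <- fixed
  rr <- row_tot - rowSums(fixed, na.rm = TRUE)
  cc <- col_tot - colSums(fixed, na.rm = TRUE)
  free <- is.na(fixed)
  if (!transport_feasible(rr, cc, free)) {
    stop("grid marginals and fixed cells are inconsistent", call. = FALSE)
  }
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(ncol(grid))) {
      if (!free[i, j]) next
      for (v in seq(min(rr[i], cc[j]), 0)) {
        rr2 <- rr; cc2 <- cc; free2 <- free
        rr2[i] <- rr2[i] - v; cc2[j] <- cc2[j] - v; free2[i, j] <- FALSE
        if (transport_feasible(rr2, cc2, free2)) {
          grid[i, j] <- v; rr <- rr2; cc <- cc2; free <- free2
          break
        }
      }
    }
  }
  storage.mode(grid) <- "integer"
  grid
}

# Pilot scheme-selection grid: rows are the LARC acceptance pattern
# (LNG-IUS only / DMPA only / both), columns the comparator pattern
# (COCP only / no-treatment only / both). Printed marginals: LARC
# preference 63 split 27/36, comparator preference 55 split 28/27, all-four
# 5, DMPA-vs-COCP two-way 14; the interior is completed by fill_grid().
pilot_grid <- function() {
  fixed <- matrix(NA_real_, 3, 3,
                  dimnames = list(c("LNG-IUS", "DMPA", "both"),
                                  c("COCP", "NONE", "both")))
  fixed["DMPA", "COCP"] <- 14
  fixed["both", "both"] <- 5
  g <- fill_grid(row_tot = c(27, 36, 14), col_tot = c(28, 27, 22), fixed)
  stopifnot(sum(g[1:2, 1:2]) == 46)  # printed two-way total must re-derive
  g
}

pilot_scheme_counts <- function(design = preempt_design()) {
  g <- pilot_grid()
  larc <- list("LNG-IUS", "DMPA", c("LNG-IUS", "DMPA"))
  comp <- list("COCP", "NONE", c("COCP", "NONE"))
  out <- integer(0)
  for (i in 1:3) for (j in 1:3) {
    out[scheme_id(c(larc[[i]], comp[[j]]))] <- g[i, j]
  }
  schemes <- names(enumerate_schemes(design))
  out <- out[schemes]
  names(out) <- schemes
  out
}

# A vector holding exactly `counts[k]` copies of names(counts)[k], shuffled.
shuffled_counts <- function(counts, n) {
  stopifnot(sum(counts) == n)
  sample(rep(names(counts), times = counts))
}

#' The 77-participant pilot cohort fixture
#'
#' Reconstructs a cohort reproducing every printed marginal of the pilot:
#' scheme-selection counts (all-four 5, two-way total 46 including
#' DMPA-vs-COCP 14, LARC preference 63 split 27/36, comparator preference
#' 55 split 28/27, the interior completed by the deterministic [fill_grid()]
#' rule) and the reported covariate counts (stage 36/20/11/10, complete
#' excision 71, age under 35 53, ever-smoked 34 with 6 missing, BMI missing
#' 17, pain score missing 2). Continuous values are drawn from the reported
#' distributions conditioned on those counts; covariates are shuffled
#' independently of scheme. Arms are allocated by per-scheme minimisation.
#' Bit-identical across runs for a fixed seed.
#'
#' @param seed Integer seed.
#' @param design The reference [preempt_design()] (or compatible design).
#' @param allocate_arms Run minimisation to fill `allocated_arm`?
#' @return List with `participants` (77-row data frame) and `summary`
#'   (trial-flow summary including the screening funnel of 504).
#' @export
pilot_fixture <- function(seed = 1L, design = preempt_design(),
                          allocate_arms = TRUE) {
  set.seed(seed)
  n <- 77L
  counts <- pilot_scheme_counts(design)
  sid <- shuffled_counts(counts, n)
  model <- covariate_model()
  centres <- design$factors[["centre"]]$levels
  age_group <- shuffled_counts(c("<35" = 53L, ">=35" = 24L), n)
  smoking <- shuffled_counts(c(yes = 34L, no = 37L, missing = 6L), n)
  smoking[smoking == "missing"] <- NA_character_
  stage <- shuffled_counts(c(I = 36L, II = 20L, III = 11L, IV = 10L), n)
  excision <- shuffled_counts(c(complete = 71L, incomplete = 6L), n)
  bmi <- round(stats::rnorm(n, model$bmi_mean, model$bmi_sd), 1)
  bmi[sample.int(n, 17L)] <- NA_real_
  pain <- round(rtruncnorm(n, model$pain_mean, model$pain_sd, 0, 100), 1)
  pain[sample.int(n, 2L)] <- NA_real_
  age <- numeric(n)
  lo <- age_group == "<35"
  age[lo] <- round(rtruncnorm(sum(lo), model$age_mean, model$age_sd,
                              model$age_bounds[1], model$age_cut - 0.1), 1)
  age[!lo] <- round(rtruncnorm(sum(!lo), model$age_mean, model$age_sd,
                               model$age_cut, model$age_bounds[2]), 1)
  participants <- data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    centre = sample(rep_len(centres, n)),
    age = age, age_group = age_group, stage = stage, excision = excision,
    bmi = bmi, smoking = smoking, ehp30_pain = pain,
    accepted_arms = sid, scheme_id = sid,
    allocated_arm = NA_character_,
    stringsAsFactors = FALSE)
  if (allocate_arms) {
    schemes <- enumerate_schemes(design)
    st <- minimisation_state(design)
    cfg <- minimisation_config(p = 0.8)
    for (i in seq_len(n)) {
      lv <- list(stage = participants$stage[i],
                 excision = participants$excision[i],
                 age_group = participants$age_group[i],
                 centre = participants$centre[i])
      res <- allocate(st, lv, schemes[[participants$scheme_id[i]]], cfg,
                      participants$participant_id[i])
      participants$allocated_arm[i] <- res$arm_id
      st <- res$state
    }
  }
  outcomes <- c(rep("randomised", n),
                rep("plan_to_conceive", 42), rep("contraindication", 35),
                rep("no_endometriosis", 33), rep("declined_preference", 94),
                rep("other_exclusion", 223))
  list(participants = participants,
       summary = flow_summary(outcomes, participants))
}
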