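#' Minimisation configuration
#'
#' Marginal-totals (Pocock-Simon) minimisation: each candidate arm is scored
#' by the weighted sum, over stratification factors, of the arm's running
#' count at the participant's factor level; the lowest-scoring arm is
#' allocated with probability `p`, otherwise one of the remaining arms is
#' chosen uniformly. Exact ties among minimal arms are broken uniformly.
#'
#' @param p Probability of allocating to the imbalance-minimising arm, in
#'   (0.5, 1]. Default 0.8; `p = 1` gives deterministic minimisation.
#' @param weights Named numeric vector of factor weights, or `NULL` for
#'   equal weights 1.
#' @return An object of class `flex_min_config`.
#' @export
minimisation_config <- function(p = 0.8, weights = NULL) {
  stopifnot(p > 0.5, p <= 1)
  if (!is.null(weights) && any(weights < 0)) {
    stop("weights must be >= 0", call. = FALSE)
  }
  structure(list(p = p, weights = weights), class = "flex_min_config")
}

#' Create an empty minimisation state
#'
#' One independent state per scheme: schemes never share counts unless
#' `shared = TRUE`, which collapses all schemes onto a single shared table
#' over the full design (off by default, matching the usual one-algorithm-
#' per-entry-option practice).
#'
#' @param design A [trial_design()].
#' @param shared Logical; share one state across all schemes.
#' @return An object of class `flex_min_state`.
#' @export
minimisation_state <- function(design, shared = FALSE) {
  structure(list(design = design, shared = shared, schemes = list(),
                 audit = list(), draw_index = 0L),
            class = "flex_min_state")
}

empty_scheme_tables <- function(design, arm_ids) {
  counts <- lapply(design$factors, function(f) {
    m <- matrix(0L, nrow = length(f$levels), ncol = length(arm_ids),
                dimnames = list(f$levels, arm_ids))
    m
  })
  names(counts) <- names(design$factors)
  total <- stats::setNames(integer(length(arm_ids)), arm_ids)
  list(counts = counts, total = total)
}

state_key <- function(state, scheme) {
  if (state$shared) "__shared__" else scheme$scheme_id
}

# Marginal-totals score for every candidate arm: weighted sum over factors of
# the arm's current count at the participant's level.
minimisation_scores <- function(tables, levels, weights) {
  arm_ids <- names(tables$total)
  scores <- stats::setNames(numeric(length(arm_ids)), arm_ids)
  for (fid in names(tables$counts)) {
    w <- if (is.null(weights)) 1 else weights[[fid]]
    if (is.null(w) || is.na(w)) w <- 1
    scores <- scores + w * tables$counts[[fid]][levels[[fid]], ]
  }
  scores
}

#' Allocate a participant by minimisation
#'
#' Scores every arm of the participant's scheme by the marginal-totals
#' method, allocates the minimal-score arm with probability `p` (ties among
#' minimal arms split uniformly) and otherwise one of the remaining arms
#' uniformly, then updates the per-scheme state. Exactly one uniform draw is
#' consumed per allocation, so a sequence is replayable from its seed.
#'
#' @param state A [minimisation_state()].
#' @param levels Named list/vector giving the participant's level for every
#'   design factor.
#' @param scheme A `flex_scheme` ([validate_scheme()]) the participant
#'   accepted.
#' @param config A [minimisation_config()].
#' @param participant_id Optional identifier recorded in the audit log.
#' @return List with `arm_id` (the allocation) and `state` (updated).
#' @export
allocate <- function(state, levels, scheme, config = minimisation_config(),
                     participant_id = NA_character_) {
  stopifnot(inherits(state, "flex_min_state"),
            inherits(scheme, "flex_scheme"))
  design <- state$design
  levels <- as.list(levels)
  for (fid in names(design$factors)) {
    lev <- levels[[fid]]
    if (is.null(lev) || !lev %in% design$factors[[fid]]$levels) {
      stop("missing or unknown level for factor '", fid, "'", call. = FALSE)
    }
  }
  key <- state_key(state, scheme)
  if (is.null(state$schemes[[key]])) {
    tab_arms <- if (state$shared) design_arm_ids(design) else scheme$arm_ids
    state$schemes[[key]] <- empty_scheme_tables(design, tab_arms)
  }
  tables <- state$schemes[[key]]
  scores <- minimisation_scores(tables, levels, config$weights)
  scores <- scores[scheme$arm_ids]

  u <- stats::runif(1)
  state$draw_index <- state$draw_index + 1L
  chosen <- pick_arm(scores, config$p, u)

  for (fid in names(tables$counts)) {
    tables$counts[[fid]][levels[[fid]], chosen] <-
      tables$counts[[fid]][levels[[fid]], chosen] + 1L
  }
  tables$total[chosen] <- tables$total[chosen] + 1L
  state$schemes[[key]] <- tables
  state$audit[[length(state$audit) + 1L]] <- list(
    participant_id = participant_id, scheme_id = scheme$scheme_id,
    levels = levels, scores = scores, arm_id = chosen,
    draw_index = state$draw_index)
  list(arm_id = chosen, state = state)
}

# Map one uniform draw to an arm: the first p of probability mass is split
# equally among minimal-score arms, the rest equally among the others.
pick_arm <- function(scores, p, u) {
  arms <- names(scores)
  minimal <- arms[scores == min(scores)]
  others <- setdiff(arms, minimal)
  if (!length(others)) {
    return(minimal[pmin(length(minimal), 1L + floor(u * length(minimal)))])
  }
  if (u < p) {
    v <- u / p
    minimal[pmin(length(minimal), 1L + floor(v * length(minimal)))]
  } else {
    v <- (u - p) / (1 - p)
    others[pmin(length(others), 1L + floor(v * length(others)))]
  }
}

#' Per-factor marginal imbalance of a scheme's state
#'
#' For every factor level, the range (max minus min) of arm counts at that
#' level; all zeros for an empty state.
#'
#' @param state A [minimisation_state()].
#' @param scheme The scheme to report on.
#' @return Named list per factor of named integer vectors per level.
#' @export
imbalance_report <- function(state, scheme) {
  design <- state$design
  key <- state_key(state, scheme)
  tables <- state$schemes[[key]]
  out <- list()
  for (fid in names(design$factors)) {
    levs <- design$factors[[fid]]$levels
    if (is.null(tables)) {
      out[[fid]] <- stats::setNames(integer(length(levs)), levs)
    } else {
      m <- tables$counts[[fid]]
      out[[fid]] <- stats::setNames(
        as.integer(apply(m, 1, max) - apply(m, 1, min)), levs)
    }
  }
  out
}

#' Maximum marginal imbalance across all factors and levels
#'
#' @inheritParams imbalance_report
#' @return Single non-negative integer.
#' @export
max_marginal_imbalance <- function(state, scheme) {
  imb <- imbalance_report(state, scheme)
  if (!length(imb)) return(0L)
  max(vapply(imb, function(v) if (length(v)) max(v) else 0L, integer(1)))
}

#' Allocation audit log as a data frame
#'
#' One row per allocation: participant id, scheme, factor levels, candidate
#' scores, chosen arm and RNG draw index.
#'
#' @param state A [minimisation_state()] after allocations.
#' @return A data frame (zero rows for a fresh state).
#' @export
audit_log <- function(state) {
  if (!length(state$audit)) {
    return(data.frame(participant_id = character(), scheme_id = character(),
                      levels = character(), scores = character(),
                      arm_id = character(), draw_index = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(state$audit, function(e) {
    data.frame(
      participant_id = e$participant_id, scheme_id = e$scheme_id,
      levels = paste(names(e$levels), unlist(e$levels), sep = "=",
                     collapse = ";"),
      scores = paste(names(e$scores), e$scores, sep = "=", collapse = ";"),
      arm_id = e$arm_id, draw_index = e$draw_index,
      stringsAsFactors = FALSE)
  }))
}
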