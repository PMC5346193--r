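#' Sample-size specification
#'
#' Numeric parameters of a two-group mean-difference sample-size
#' calculation: minimum important difference on the outcome scale (EHP-30
#' pain points in the reference design), outcome standard deviation,
#' two-sided type-I error, target power, the number of pairwise comparisons
#' used for Bonferroni adjustment, the anticipated attrition proportion, and
#' the multiple the recruitment target is rounded up to.
#'
#' @param delta Minimum important difference (> 0).
#' @param sd Outcome standard deviation (> 0).
#' @param alpha Two-sided type-I error in (0, 1).
#' @param power Target power in (0, 1).
#' @param n_comparisons Comparisons in the Bonferroni family (>= 1).
#' @param attrition Anticipated loss to follow-up in [0, 1).
#' @param round_to Recruitment target is rounded up to this multiple.
#' @param n_groups Number of randomised groups the total is scaled over.
#' @return An object of class `flex_samplesize_spec`.
#' @export
samplesize_spec <- function(delta, sd, alpha, power, n_comparisons = 1L,
                            attrition = 0, round_to = 1L, n_groups = 2L) {
  stopifnot(delta > 0, sd > 0, alpha > 0, alpha < 1, power > 0, power < 1,
            n_comparisons >= 1, attrition >= 0, attrition < 1, round_to >= 1,
            n_groups >= 2)
  structure(list(delta = delta, sd = sd, alpha = alpha, power = power,
                 n_comparisons = as.integer(n_comparisons),
                 attrition = attrition, round_to = as.integer(round_to),
                 n_groups = as.integer(n_groups)),
            class = "flex_samplesize_spec")
}

round_half_up <- function(x, dp) {
  # round() is banker's rounding; alpha adjustment needs half-up (0.0083 -> 0.01)
  floor(x * 10^dp + 0.5) / 10^dp
}

#' Bonferroni-adjusted significance level
#'
#' Divides the family-wise alpha by the number of comparisons, optionally
#' rounding half-up to a number of decimal places (0.05/6 = 0.00833 becomes
#' 0.01 at two decimal places, the level used by the reference design).
#'
#' @param family_alpha Family-wise two-sided alpha.
#' @param k Number of comparisons (>= 1).
#' @param round_dp Decimal places to round to, or `NULL` for full precision.
#' @return Adjusted alpha.
#' @export
bonferroni_alpha <- function(family_alpha, k, round_dp = NULL) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  a <- family_alpha / k
  if (!is.null(round_dp)) a <- round_half_up(a, round_dp)
  a
}

#' Number of pairwise comparisons among groups
#'
#' @param n_groups Number of groups (>= 2).
#' @return `n_groups * (n_groups - 1) / 2` (6 for four groups).
#' @export
pairwise_comparisons <- function(n_groups) {
  if (n_groups < 2) stop("n_groups must be >= 2", call. = FALSE)
  as.integer(n_groups * (n_groups - 1) / 2)
}

#' Power of a two-sided two-sample comparison of means
#'
#' Noncentral-t formulation: with n per group the test statistic under the
#' alternative is noncentral t with 2n - 2 degrees of freedom and
#' noncentrality (delta / sd) * sqrt(n / 2); power is the probability of
#' exceeding the two-sided critical value. A normal-approximation variant is
#' available via `method`.
#'
#' @param n_per_group Participants per group (>= 2).
#' @param delta True mean difference.
#' @param sd Common standard deviation.
#' @param alpha Two-sided significance level.
#' @param method `"nct"` (noncentral t, default) or `"normal"`.
#' @return Power in (0, 1).
#' @export
power_two_group <- function(n_per_group, delta, sd, alpha,
                            method = c("nct", "normal")) {
  method <- match.arg(method)
  stopifnot(n_per_group >= 2, sd > 0, alpha > 0, alpha < 1)
  ncp <- (delta / sd) * sqrt(n_per_group / 2)
  if (method == "normal") {
    z <- stats::qnorm(1 - alpha / 2)
    return(stats::pnorm(-z - ncp) + stats::pnorm(ncp - z))
  }
  df <- 2 * n_per_group - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp) + stats::pt(tcrit, df, ncp, lower.tail = FALSE)
}

#' Per-group sample size for a two-sample comparison of means
#'
#' Smallest integer n per group for which [power_two_group()] reaches the
#' target. Iterates from the normal-approximation starting value
#' n0 = 2 ((z_{1-alpha/2} + z_{power}) sd / delta)^2, stepping down while the
#' target is still met and up while it is not.
#'
#' @inheritParams power_two_group
#' @param power Target power in (0, 1).
#' @return Integer n per group.
#' @export
n_per_group <- function(delta, sd, alpha, power, method = c("nct", "normal")) {
  method <- match.arg(method)
  if (delta == 0) stop("effect size zero", call. = FALSE)
  stopifnot(sd > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  delta <- abs(delta)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n <- max(2L, ceiling(2 * (z * sd / delta)^2))
  while (n > 2L &&
         power_two_group(n - 1L, delta, sd, alpha, method) >= power) {
    n <- n - 1L
  }
  while (power_two_group(n, delta, sd, alpha, method) < power) {
    n <- n + 1L
  }
  as.integer(n)
}

#' Inflate an analysable sample size for attrition
#'
#' Divides by (1 - attrition) and rounds up to the nearest multiple of
#' `round_to` (592 at 20% attrition rounded to a multiple of 50 gives 750).
#'
#' @param n_total Analysable sample size.
#' @param attrition Anticipated loss proportion in [0, 1).
#' @param round_to Round the target up to this multiple (default 1).
#' @return Integer recruitment target.
#' @export
inflate_for_attrition <- function(n_total, attrition, round_to = 1L) {
  if (attrition < 0 || attrition >= 1) {
    stop("attrition must be in [0, 1)", call. = FALSE)
  }
  if (round_to < 1) stop("round_to must be >= 1", call. = FALSE)
  n <- ceiling(n_total / (1 - attrition))
  as.integer(ceiling(n / round_to) * round_to)
}

#' Standardised effect size
#'
#' @param delta Mean difference.
#' @param sd Standard deviation (> 0).
#' @return List with `value` (full precision) and `display` (2 dp).
#' @export
effect_size_sd <- function(delta, sd) {
  if (sd <= 0) stop("sd must be > 0", call. = FALSE)
  v <- delta / sd
  list(value = v, display = round_half_up(v, 2))
}

#' Power of stratified two-group comparisons
#'
#' Splits a total sample size across strata by the given proportions,
#' assumes 1:1 allocation within each stratum (floor of half the stratum
#' size per arm), and evaluates [power_two_group()] per stratum. Strata with
#' fewer than two participants per arm are reported as `NA` (not estimable).
#'
#' @param n_total Total participants across strata.
#' @param split Numeric vector of stratum proportions summing to 1.
#' @param delta,sd,alpha As in [power_two_group()].
#' @param method Power method, see [power_two_group()].
#' @return Named numeric vector of per-stratum power (`NA` if not estimable).
#' @export
stratified_power <- function(n_total, split, delta, sd, alpha,
                             method = c("nct", "normal")) {
  method <- match.arg(method)
  if (abs(sum(split) - 1) > 1e-8) {
    stop("split proportions must sum to 1", call. = FALSE)
  }
  n_arm <- floor(n_total * split / 2)
  out <- vapply(n_arm, function(n) {
    if (n < 2) return(NA_real_)
    power_two_group(n, delta, sd, alpha, method)
  }, numeric(1))
  names(out) <- names(split) %||% paste0("stratum", seq_along(split))
  out
}

#' Monte-Carlo check of the analytic power
#'
#' Simulates independent normal outcomes with the stated difference and SD,
#' applies the equal-variance two-sample t-test, and reports the rejection
#' fraction. Agrees with [power_two_group()] to within binomial error.
#'
#' @inheritParams power_two_group
#' @param n_reps Number of simulated trials (>= 100).
#' @param seed Integer seed.
#' @return List: `power` (empirical), `se` (binomial SE), `n_reps`.
#' @export
simulate_power_check <- function(n_per_group, delta, sd, alpha, n_reps = 2000L,
                                 seed = 1L) {
  if (n_reps < 100) stop("n_reps must be >= 100", call. = FALSE)
  set.seed(seed)
  n <- n_per_group
  df <- 2 * n - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  rej <- logical(n_reps)
  block <- max(1L, min(n_reps, floor(5e6 / n)))
  done <- 0L
  while (done < n_reps) {
    b <- min(block, n_reps - done)
    x <- matrix(stats::rnorm(n * b, 0, sd), nrow = n)
    y <- matrix(stats::rnorm(n * b, delta, sd), nrow = n)
    mx <- colMeans(x); my <- colMeans(y)
    vx <- colSums((x - rep(mx, each = n))^2)
    vy <- colSums((y - rep(my, each = n))^2)
    sp <- sqrt((vx + vy) / df)
    tstat <- (my - mx) / (sp * sqrt(2 / n))
    rej[done + seq_len(b)] <- abs(tstat) > tcrit
    done <- done + b
  }
  p <- mean(rej)
  list(power = p, se = sqrt(p * (1 - p) / n_reps), n_reps = n_reps)
}

#' Full sample-size block for a specification
#'
#' Runs the complete arithmetic of a [samplesize_spec()]: Bonferroni-adjusted
#' alpha (when `n_comparisons > 1`, rounded half-up to 2 dp as in the
#' reference design), per-group and total analysable n, attrition-inflated
#' recruitment target, and standardised effect size.
#'
#' @param spec A [samplesize_spec()].
#' @param alpha_round_dp Decimal places for the adjusted alpha (default 2).
#' @return List with the computed quantities.
#' @export
samplesize_block <- function(spec, alpha_round_dp = 2L) {
  stopifnot(inherits(spec, "flex_samplesize_spec"))
  a <- if (spec$n_comparisons > 1L) {
    bonferroni_alpha(spec$alpha, spec$n_comparisons, alpha_round_dp)
  } else spec$alpha
  npg <- n_per_group(spec$delta, spec$sd, a, spec$power)
  total <- npg * spec$n_groups
  target <- inflate_for_attrition(total, spec$attrition, spec$round_to)
  list(alpha_adjusted = a, n_per_group = npg, n_total = total,
       recruitment_target = target,
       effect_size = effect_size_sd(spec$delta, spec$sd),
       power_at_n = power_two_group(npg, spec$delta, spec$sd, a))
}
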