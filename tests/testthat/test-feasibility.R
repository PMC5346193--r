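test_that("the four-way candidate fails the 10% rule on the pilot cohort", {
  fx <- pilot_fixture(seed = 1)
  cand <- evaluate_candidate(c("LNG-IUS", "DMPA", "COCP", "NONE"),
                             fx$participants)
  expect_false(cand$feasible)
  expect_equal(cand$compatible_uptake, 5 / 77)
  expect_lt(cand$compatible_uptake, 0.10)
})

test_that("a sole DMPA-vs-COCP design attracts 14 of 77 exact selections", {
  fx <- pilot_fixture(seed = 1)
  cand <- evaluate_candidate(c("DMPA", "COCP"), fx$participants)
  expect_equal(cand$exact_selection, 14 / 77)
  expect_equal(round(100 * cand$exact_selection), 18)
  # compatible uptake counts everyone whose set contains both arms
  expect_equal(cand$compatible_uptake, (14 + 17 + 5) / 77)
})

test_that("a zero threshold makes every candidate feasible", {
  fx <- pilot_fixture(seed = 1)
  rule0 <- feasibility_rule(threshold = 0)
  ranked <- rank_candidates(fx$participants, rule = rule0)
  expect_true(all(vapply(ranked, function(c) c$feasible, logical(1))))
})

test_that("raising the threshold never rescues an infeasible candidate", {
  fx <- pilot_fixture(seed = 1)
  thresholds <- c(0, 0.02, 0.05, 0.10, 0.20, 0.40, 0.80)
  verdicts <- sapply(thresholds, function(th) {
    ranked <- rank_candidates(fx$participants,
                              rule = feasibility_rule(threshold = th))
    vapply(ranked, function(c) c$feasible, logical(1))
  })
  # along each row (candidate), feasibility is monotone non-increasing
  for (i in seq_len(nrow(verdicts))) {
    expect_true(all(diff(as.integer(verdicts[i, ])) <= 0))
  }
})

test_that("compatible uptake is non-increasing as arms are added", {
  fx <- pilot_fixture(seed = 1)
  chains <- list(
    list(c("LNG-IUS", "COCP"), c("LNG-IUS", "COCP", "NONE"),
         c("LNG-IUS", "DMPA", "COCP", "NONE")),
    list(c("DMPA", "NONE"), c("DMPA", "COCP", "NONE"),
         c("LNG-IUS", "DMPA", "COCP", "NONE")))
  for (chain in chains) {
    vals <- vapply(chain, function(arms)
      evaluate_candidate(arms, fx$participants)$compatible_uptake, numeric(1))
    expect_true(all(diff(vals) <= 0))
  }
})

test_that("ranking puts the four-way design below every two-way candidate", {
  fx <- pilot_fixture(seed = 1)
  ranked <- rank_candidates(fx$participants)
  ids <- vapply(ranked, function(c) c$scheme_id, character(1))
  n_arms <- vapply(ranked, function(c) length(c$arm_ids), integer(1))
  pos_four <- which(ids == scheme_id(c("LNG-IUS", "DMPA", "COCP", "NONE")))
  expect_true(all(which(n_arms == 2) < pos_four))
  # metric values are sorted descending
  vals <- vapply(ranked, function(c) c$metric_value, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("a universally accepting cohort ranks the full design first", {
  all_four <- cohort_of(rep(list(c("LNG-IUS", "DMPA", "COCP", "NONE")), 10))
  ranked <- rank_candidates(all_four)
  expect_equal(ranked[[1]]$scheme_id,
               scheme_id(c("LNG-IUS", "DMPA", "COCP", "NONE")))
  expect_equal(ranked[[1]]$metric_value, 1)
  # every candidate has uptake 1: ties broken by arm count then id
  expect_true(all(vapply(ranked, function(c) c$metric_value, numeric(1)) == 1))
})

test_that("disjoint two-way schemes under a high threshold leave nothing", {
  two <- cohort_of(list(c("LNG-IUS", "COCP"), c("DMPA", "NONE")))
  ranked <- rank_candidates(two, rule = feasibility_rule(threshold = 0.6))
  expect_true(all(!vapply(ranked, function(c) c$feasible, logical(1))))
})

test_that("four-way pass probability matches a binomial-tail oracle", {
  d <- preempt_design()
  probs <- pilot_scheme_probs(d)
  four <- scheme_id(c("LNG-IUS", "DMPA", "COCP", "NONE"))
  n_pilot <- 30L
  threshold <- 0.10
  # oracle: the four-way design passes iff the all-four count is >= 3 of 30
  k_min <- ceiling(threshold * n_pilot)
  p_pass_oracle <- stats::pbinom(k_min - 1, n_pilot, probs[[four]],
                                 lower.tail = FALSE)
  set.seed(2718)
  n_sims <- 600
  pass <- logical(n_sims)
  rule <- feasibility_rule(threshold)
  for (i in seq_len(n_sims)) {
    sid <- sample(names(probs), n_pilot, replace = TRUE, prob = probs)
    cohort <- cohort_of(strsplit(sid, "+", fixed = TRUE))
    pass[i] <- evaluate_candidate(strsplit(four, "+", fixed = TRUE)[[1]],
                                  cohort, rule, d)$feasible
  }
  se <- sqrt(p_pass_oracle * (1 - p_pass_oracle) / n_sims)
  expect_lt(abs(mean(pass) - p_pass_oracle), 3 * se + 0.01)
})

test_that("the pilot result adapts to a class-versus-comparator design", {
  fx <- pilot_fixture(seed = 1)
  ranked <- rank_candidates(fx$participants)
  ad <- adapt_design(ranked, comparator = "COCP")
  expect_true(ad$adapted)
  expect_equal(ad$main_comparison$class_id, "LARC")
  expect_equal(ad$main_comparison$comparator, "COCP")
  expect_setequal(ad$strata, c("LNG-IUS", "DMPA", "no-preference"))
  expect_setequal(ad$sub_randomisation$arms, c("LNG-IUS", "DMPA"))
  b <- samplesize_block(ad$samplesize)
  expect_identical(b$n_per_group, 160L)
  expect_identical(b$recruitment_target, 400L)
})

test_that("a feasible full design is retained unchanged", {
  all_four <- cohort_of(rep(list(c("LNG-IUS", "DMPA", "COCP", "NONE")), 20))
  ranked <- rank_candidates(all_four)
  ad <- adapt_design(ranked)
  expect_false(ad$adapted)
  expect_setequal(ad$arms, c("LNG-IUS", "DMPA", "COCP", "NONE"))
  expect_identical(samplesize_block(ad$samplesize)$recruitment_target, 750L)
})

test_that("an infeasible pilot without a comparator is inconclusive", {
  fx <- pilot_fixture(seed = 1)
  ranked <- rank_candidates(fx$participants)
  expect_error(adapt_design(ranked, comparator = NULL), "inconclusive")
})

test_that("stratified analysis sets keep only the matching preselection", {
  fx <- pilot_fixture(seed = 1)
  ranked <- rank_candidates(fx$participants)
  ad <- adapt_design(ranked, comparator = "COCP")
  presel <- c("LNG-IUS", "DMPA", "LNG-IUS", "no-preference", "DMPA")
  sets <- stratified_analysis_sets(ad, presel)
  expect_equal(sets$`LNG-IUS`, c(1L, 3L))
  expect_equal(sets$DMPA, c(2L, 5L))
  expect_false(4L %in% unlist(sets))
})
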