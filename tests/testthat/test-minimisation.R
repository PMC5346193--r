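# Independent brute-force oracle: recompute every arm's marginal-totals
# score directly from the audit-free count tables and return the minimal set.
oracle_minimal_arms <- function(tables, levels) {
  arms <- names(tables$total)
  scores <- sapply(arms, function(a) {
    s <- 0
    for (fid in names(tables$counts)) s <- s + tables$counts[[fid]][levels[[fid]], a]
    s
  })
  arms[scores == min(scores)]
}

ref_levels <- function(stage = "I", excision = "complete",
                       age_group = "<35", centre = "C1") {
  list(stage = stage, excision = excision, age_group = age_group,
       centre = centre)
}

preload_state <- function(design, scheme, fill) {
  # fill: list of (factor, level, arm, count)
  st <- minimisation_state(design)
  tb <- flexrand:::empty_scheme_tables(design, scheme$arm_ids)
  for (f in fill) tb$counts[[f[[1]]]][f[[2]], f[[3]]] <- as.integer(f[[4]])
  for (a in scheme$arm_ids) {
    tb$total[a] <- max(vapply(tb$counts, function(m)
      max(colSums(m[, a, drop = FALSE])), numeric(1)))
  }
  st$schemes[[scheme$scheme_id]] <- tb
  st
}

test_that("the worked two-arm state allocates to the less-loaded arm at p = 1", {
  d <- preempt_design()
  sch <- validate_scheme(d, c("LNG-IUS", "COCP"))
  st <- preload_state(d, sch, list(
    list("age_group", "<35", "LNG-IUS", 3), list("stage", "I", "LNG-IUS", 2),
    list("age_group", "<35", "COCP", 1), list("stage", "I", "COCP", 1)))
  set.seed(1)
  res <- allocate(st, ref_levels(), sch, minimisation_config(p = 1))
  expect_identical(res$arm_id, "COCP")  # score 2 beats 5
  entry <- res$state$audit[[1]]
  expect_equal(unname(entry$scores[c("LNG-IUS", "COCP")]), c(5, 2))
})

test_that("allocation agrees with the brute-force score oracle on random states", {
  d <- preempt_design()
  schemes <- enumerate_schemes(d)
  set.seed(99)
  for (rep in 1:120) {
    sch <- schemes[[sample(length(schemes), 1)]]
    fill <- list()
    for (fid in names(d$factors)) {
      for (a in sch$arm_ids) {
        for (lv in d$factors[[fid]]$levels) {
          fill[[length(fill) + 1L]] <- list(fid, lv, a, sample(0:4, 1))
        }
      }
    }
    st <- preload_state(d, sch, fill)
    lv <- ref_levels(sample(c("I", "II", "III", "IV"), 1),
                     sample(c("complete", "incomplete"), 1),
                     sample(c("<35", ">=35"), 1),
                     sample(paste0("C", 1:6), 1))
    res <- allocate(st, lv, sch, minimisation_config(p = 1))
    minimal <- oracle_minimal_arms(st$schemes[[sch$scheme_id]], lv)
    expect_true(res$arm_id %in% minimal,
                info = sprintf("rep %d scheme %s", rep, sch$scheme_id))
  }
})

test_that("an empty state allocates every arm with equal probability", {
  d <- preempt_design()
  sch <- validate_scheme(d, c("LNG-IUS", "DMPA", "COCP", "NONE"))
  cfg <- minimisation_config(p = 0.8)
  set.seed(7)
  draws <- vapply(seq_len(10000), function(i) {
    allocate(minimisation_state(d), ref_levels(), sch, cfg)$arm_id
  }, character(1))
  tab <- table(factor(draws, levels = sch$arm_ids))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("a symmetric state allocates 50/50 within Monte-Carlo error", {
  d <- preempt_design()
  sch <- validate_scheme(d, c("DMPA", "NONE"))
  cfg <- minimisation_config(p = 0.8)
  set.seed(11)
  n <- 4000
  picks <- vapply(seq_len(n), function(i) {
    st <- preload_state(d, sch, list(
      list("stage", "I", "DMPA", 2), list("stage", "I", "NONE", 2)))
    allocate(st, ref_levels(), sch, cfg)$arm_id
  }, character(1))
  p_hat <- mean(picks == "DMPA")
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / n))
})

test_that("allocation sequences replay bit-exactly from the seed", {
  d <- preempt_design()
  sch <- validate_scheme(d, c("LNG-IUS", "NONE"))
  run_once <- function() {
    set.seed(123)
    st <- minimisation_state(d)
    out <- character(20)
    for (i in 1:20) {
      res <- allocate(st, ref_levels(stage = sample(c("I", "II"), 1)), sch,
                      minimisation_config(p = 0.8))
      out[i] <- res$arm_id
      st <- res$state
    }
    list(out, audit_log(st))
  }
  a <- run_once(); b <- run_once()
  expect_identical(a[[1]], b[[1]])
  expect_identical(a[[2]], b[[2]])
  expect_identical(a[[2]]$draw_index, 1:20)
})

test_that("counts are conserved after n allocations", {
  d <- preempt_design()
  sch <- validate_scheme(d, c("DMPA", "COCP", "NONE"))
  set.seed(5)
  st <- minimisation_state(d)
  n <- 60
  for (i in seq_len(n)) {
    lv <- ref_levels(sample(c("I", "II", "III", "IV"), 1),
                     sample(c("complete", "incomplete"), 1),
                     sample(c("<35", ">=35"), 1), sample(paste0("C", 1:6), 1))
    st <- allocate(st, lv, sch, minimisation_config())$state
  }
  tb <- st$schemes[[sch$scheme_id]]
  expect_equal(sum(tb$total), n)
  for (fid in names(tb$counts)) expect_equal(sum(tb$counts[[fid]]), n)
})

test_that("single-factor two-arm imbalance never exceeds 1 at p = 1", {
  d <- two_arm_design()
  sch <- validate_scheme(d, c("A", "B"))
  set.seed(21)
  st <- minimisation_state(d)
  for (i in 1:200) {
    lv <- list(sex = sample(c("f", "m"), 1))
    res <- allocate(st, lv, sch, minimisation_config(p = 1))
    st <- res$state
    expect_lte(max_marginal_imbalance(st, sch), 1L)
  }
})

test_that("schemes keep independent states by default", {
  d <- preempt_design()
  s1 <- validate_scheme(d, c("LNG-IUS", "COCP"))
  s2 <- validate_scheme(d, c("DMPA", "NONE"))
  set.seed(3)
  st <- minimisation_state(d)
  for (i in 1:10) st <- allocate(st, ref_levels(), s1,
                                 minimisation_config())$state
  expect_null(st$schemes[[s2$scheme_id]])
  expect_equal(sum(st$schemes[[s1$scheme_id]]$total), 10)
  imb2 <- imbalance_report(st, s2)
  expect_true(all(unlist(imb2) == 0L))
})

test_that("allocation refuses missing factor levels and unknown levels", {
  d <- preempt_design()
  sch <- validate_scheme(d, c("LNG-IUS", "COCP"))
  st <- minimisation_state(d)
  expect_error(allocate(st, list(stage = "I"), sch), "factor")
  expect_error(allocate(st, ref_levels(stage = "V"), sch), "factor 'stage'")
})

test_that("minimisation balances markedly better than simple randomisation", {
  d <- preempt_design()
  sch <- validate_scheme(d, c("LNG-IUS", "COCP"))
  n_reps <- 200
  n_part <- 500
  set.seed(2024)
  imb_min <- numeric(n_reps)
  imb_srs <- numeric(n_reps)
  cfg <- minimisation_config(p = 0.8)
  for (r in seq_len(n_reps)) {
    lv_mat <- data.frame(
      stage = sample(c("I", "II", "III", "IV"), n_part, TRUE,
                     prob = c(0.47, 0.26, 0.14, 0.13)),
      excision = sample(c("complete", "incomplete"), n_part, TRUE,
                        prob = c(0.92, 0.08)),
      age_group = sample(c("<35", ">=35"), n_part, TRUE, prob = c(0.69, 0.31)),
      centre = sample(paste0("C", 1:6), n_part, TRUE),
      stringsAsFactors = FALSE)
    st <- minimisation_state(d)
    for (i in seq_len(n_part)) {
      st <- allocate(st, as.list(lv_mat[i, ]), sch, cfg)$state
    }
    imb_min[r] <- max_marginal_imbalance(st, sch)
    # paired simple randomisation on the same covariates
    arms <- sample(sch$arm_ids, n_part, replace = TRUE)
    worst <- 0L
    for (fid in names(d$factors)) {
      tab <- table(lv_mat[[fid]], factor(arms, levels = sch$arm_ids))
      worst <- max(worst, max(abs(tab[, 1] - tab[, 2])))
    }
    imb_srs[r] <- worst
  }
  expect_lt(mean(imb_min), mean(imb_srs))
})
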