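test_that("clone area is 2 VAF B, clamped at the biopsy", {
  expect_equal(clone_area(0.5, 1), 1)
  expect_equal(clone_area(0.005, 3.14), 0.0314)
  expect_equal(clone_area(0, 2), 0)
  expect_equal(clone_area(0.9, 1), 1) # noise-driven VAF > 0.5 clamps
  expect_error(clone_area(-0.1, 1), "0, 1")
  expect_error(clone_area(0.1, 0), "positive")
})

test_that("neutral-drift clone pmf evaluates the printed expression", {
  # r*t = e makes the log factor 1: P_1 = exp(-1/e)
  r <- 0.51
  t_e <- exp(1) / r
  expect_equal(neutral_clone_pmf(1, r, t_e), exp(-1 / exp(1)))
  # independent evaluation at the patient-scale age (58 years)
  t58 <- 58 * 365.25 / 7
  rt <- r * t58
  expect_equal(neutral_clone_pmf(1, r, t58), exp(-1 / rt) / log(rt))
  # decreasing in n
  p <- neutral_clone_pmf(1:50, r, t58)
  expect_true(all(diff(p) < 0))
  expect_error(neutral_clone_pmf(1, 0.51, 1), "exceed 1")
  expect_error(neutral_clone_pmf(0, 0.51, 100), ">= 1")
})

test_that("the first incomplete moment starts at 1 and never increases", {
  set.seed(1)
  x <- rexp(500, rate = 0.2)
  mu <- first_incomplete_moment(x)
  expect_equal(mu$mu1[1], 1)
  expect_true(all(diff(mu$mu1) <= 0))
  expect_true(all(mu$mu1 >= 0))
  # repeated single size: full mass then none
  mu2 <- first_incomplete_moment(rep(7, 10), n_grid = c(7, 8))
  expect_equal(mu2$mu1, c(1, 0))
  expect_error(first_incomplete_moment(numeric(0)), "empty")
})

test_that("exponential clone sizes give the closed-form incomplete moment", {
  beta <- 0.05
  set.seed(4)
  x <- rexp(1e4, rate = beta)
  grid <- seq(5, 100, by = 5)
  mu <- first_incomplete_moment(x, n_grid = grid)
  closed <- exp(-beta * grid) * (1 + beta * grid)
  expect_lt(max(abs(mu$mu1 - closed)), 0.02)
  # brute-force check of the estimator itself on a small fixture
  small <- c(2, 3, 5, 8, 13)
  mu_small <- first_incomplete_moment(small, n_grid = 5)
  expect_equal(mu_small$mu1, (5 + 8 + 13) / sum(small))
  # log-linear tail with slope approaching -beta (the exact slope is
  # -beta + beta/(1 + beta n), so a ~15% curvature correction remains
  # over this grid)
  tail_grid <- c(4, 8) / beta
  mu_tail <- first_incomplete_moment(x, n_grid = tail_grid)
  slope <- diff(log(mu_tail$mu1)) / diff(tail_grid)
  expect_lt(abs(-slope - beta) / beta, 0.25)
})

test_that("the KS decision matches a brute-force ECDF scan and is symmetric", {
  a <- c(1, 2, 2, 4, 7, 9, 12, 15, 15, 20)
  b <- c(2, 3, 5, 5, 8, 10, 11, 18, 22, 25)
  res <- ks_compare(a, b)
  # independent oracle
  expect_equal(res$d_stat, unname(stats::ks.test(a, b)$statistic))
  m <- length(a); n <- length(b)
  expect_equal(res$d_crit / sqrt((m + n) / (m * n)), 1.3581015,
               tolerance = 1e-6)
  sym <- ks_compare(b, a)
  expect_equal(res$d_stat, sym$d_stat)
  expect_equal(res$reject, sym$reject)
  expect_equal(res$excess, res$d_stat - res$d_crit)

  ident <- ks_compare(a, a)
  expect_equal(ident$d_stat, 0)
  expect_false(ident$reject)

  set.seed(2)
  far <- ks_compare(runif(1000), runif(1000, 0.5, 1.5))
  expect_true(far$reject)
  expect_error(ks_compare(numeric(0), a), "nonempty")
})

test_that("neutral replicates almost never reject each other", {
  p <- hot_panel()
  cfg <- tiny_config()
  sims <- lapply(1:40, function(s)
    neutral_clone_sample(1000 + s, p, cfg, days = 300)$sizes)
  ns <- vapply(sims, function(s) length(s$cells), numeric(1))
  expect_true(all(ns >= 20))
  rejects <- vapply(1:20, function(i)
    ks_compare(sims[[2 * i - 1]], sims[[2 * i]], alpha = 0.05)$reject,
    logical(1))
  expect_gte(mean(!rejects), 0.9)
})

test_that("clone ages and clone sizes are positively rank-correlated", {
  p <- hot_panel()
  cfg <- tiny_config()
  pooled <- do.call(rbind, lapply(1:5, function(s) {
    res <- neutral_clone_sample(300 + s, p, cfg, days = 300)
    res$calls
  }))
  age <- max(pooled$birth_day) + 1 - pooled$birth_day
  ct <- suppressWarnings(
    stats::cor.test(age, pooled$n_cells, method = "spearman",
                    alternative = "greater"))
  expect_gt(unname(ct$estimate), 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("age-size summaries bin by mutation age and driver class", {
  m <- data.frame(birth_day = c(10, 10, 400, 400, 3000),
                  driver_class = c("passenger", "passenger", "NOTCH1-like",
                                   "passenger", "passenger"),
                  area_mm2 = c(0.01, 0.02, 0.5, 0.03, 0.2))
  out <- age_size_summary(m, end_day = 3650,
                          age_breaks_years = c(0, 2, 5, 15))
  expect_equal(sum(out$n), 5)
  expect_true("NOTCH1-like" %in% out$driver_class)
  expect_false("TP53-like" %in% out$driver_class) # absent class, no rows
  one_bin <- age_size_summary(m[1:2, ], end_day = 3650,
                              age_breaks_years = c(0, 20))
  expect_equal(nrow(one_bin), 1)
  expect_equal(one_bin$median_area_mm2, 0.015)
  empty <- age_size_summary(m[0, ], end_day = 100)
  expect_equal(nrow(empty), 0)
})

test_that("clone-size distributions discretise areas in cell footprints", {
  calls <- data.frame(vaf_sim = c(0.005, 0.1, 0.7))
  cs <- clone_size_distribution(calls, B = 1, cell_size_um = 15)
  expect_equal(cs$areas_mm2, c(0.01, 0.2, 1)) # last clamped at B
  expect_equal(cs$cells, pmax(1L, as.integer(round(cs$areas_mm2 / 0.000225))))
  expect_error(clone_size_distribution(data.frame(vaf_sim = numeric(0)), 1),
               "no clones")
})
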