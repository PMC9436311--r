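test_that("lattice geometry follows biopsy area and cell size", {
  cfg <- sim_config(biopsy_area_mm2 = 1, cell_size_um = 15)
  expect_equal(cfg$Lx, 66L)
  expect_equal(cfg$Ly, 66L)
  p <- tiny_panel()
  st <- init_tissue(cfg, p)
  expect_equal(sum(st$occ[, , 1] > 0), 66L^2)
  expect_equal(sum(st$occ > 0), 66L^2) # only the basal layer is seeded
  expect_error(sim_config(biopsy_area_mm2 = -1), "positive")
})

test_that("initialisation is deterministic under a fixed seed", {
  cfg <- tiny_config()
  p <- tiny_panel()
  a <- init_tissue(cfg, p, seed = 3)
  b <- init_tissue(cfg, p, seed = 3)
  expect_identical(a$occ, b$occ)
  expect_identical(a$gf, b$gf)
})

test_that("growth-factor field matches the 1D diffusion-decay closed form", {
  # empty lattice, pure decay: u'' = (lambda/D) u, u(0)=s0, absorbing top.
  # A tight solver tolerance isolates the discretisation error.
  cfg <- sim_config(biopsy_area_mm2 = 0.01, Lz = 40, gf_lambda = 6.25e-4,
                    gf_consumption = 0, gf_tol = 1e-7, gf_max_sweeps = 2e5)
  st <- init_tissue(cfg, tiny_panel())
  st$occ[] <- 0L
  st <- solve_gf(st, cfg)
  prof <- apply(st$gf, 3, mean)
  z <- 0:(cfg$Lz - 1)
  kap <- sqrt(cfg$gf_lambda)
  ana <- sinh(kap * (cfg$Lz - z)) / sinh(kap * cfg$Lz)
  expect_lt(max(abs(prof - ana) / ana), 0.01)
  # and essentially exact against the discrete boundary-value closed form
  rr <- (2 + cfg$gf_lambda + sqrt((2 + cfg$gf_lambda)^2 - 4)) / 2
  disc <- (rr^(cfg$Lz - z) - rr^(-(cfg$Lz - z))) / (rr^cfg$Lz - rr^(-cfg$Lz))
  expect_lt(max(abs(prof - disc)), 1e-4)
})

test_that("with no decay and no sinks the field is the linear Laplace profile", {
  cfg <- sim_config(biopsy_area_mm2 = 0.01, Lz = 10,
                    gf_lambda = 0, gf_consumption = 0)
  st <- init_tissue(cfg, tiny_panel())
  st$occ[] <- 0L
  st <- solve_gf(st, cfg)
  prof <- apply(st$gf, 3, mean)
  # Dirichlet s0 at z=0 and absorbing lid: linear decay to the ghost layer
  expect_equal(prof, 1 - (0:9) / 10, tolerance = 1e-3)
})

test_that("doubling consumption lowers the mean field monotonically", {
  p <- tiny_panel()
  base <- sim_config(biopsy_area_mm2 = 0.01)
  st <- init_tissue(base, p)
  st$occ[, , 1:10] <- 1L
  means <- sapply(c(0.012, 0.024, 0.048), function(cons) {
    cfg <- sim_config(biopsy_area_mm2 = 0.01, gf_consumption = cons)
    mean(solve_gf(st, cfg)$gf)
  })
  expect_true(all(diff(means) < 0))
})

test_that("growth factor decreases with height in a running tissue", {
  cfg <- tiny_config()
  set.seed(2)
  st <- run_epidermis(init_tissue(cfg, tiny_panel()), cfg, 200)
  prof <- apply(st$gf, 3, mean)
  expect_true(all(diff(prof) < 0))
})

test_that("null responses freeze the tissue and certain death empties it", {
  p <- tiny_panel()
  frozen <- sim_config(biopsy_area_mm2 = 0.01, p_max = 0, d_max = 0)
  set.seed(1)
  st <- init_tissue(frozen, p)
  occ0 <- st$occ
  st <- run_epidermis(st, frozen, 5)
  expect_identical(st$occ, occ0)
  expect_equal(st$clock_days, 5)

  lethal <- sim_config(biopsy_area_mm2 = 0.01, p_max = 0,
                       d_max = 1, K_die = 1e9, h_die = 1)
  set.seed(1)
  st <- run_epidermis(init_tissue(lethal, p), lethal, 1)
  expect_equal(sum(st$occ > 0), 0)
})

test_that("births - deaths - sheds equals the population change every step", {
  cfg <- tiny_config()
  set.seed(8)
  st <- run_epidermis(init_tissue(cfg, tiny_panel()), cfg, 400)
  s <- st$series
  dN <- diff(c(cfg$Lx * cfg$Ly, s$total))
  expect_identical(dN, s$births - s$deaths - s$sheds)
  expect_true(all(s$uv_deaths == 0))
})

test_that("trajectories are reproducible under a shared seed", {
  cfg <- tiny_config()
  p <- tiny_panel()
  set.seed(5); a <- run_epidermis(init_tissue(cfg, p), cfg, 60)
  set.seed(5); b <- run_epidermis(init_tissue(cfg, p), cfg, 60)
  expect_identical(a$occ, b$occ)
  expect_identical(a$series, b$series)
  expect_identical(a$mutations, b$mutations)
})

test_that("knock-on displacement shifts the whole column and sheds at the lid", {
  p <- tiny_panel()
  cfg <- sim_config(biopsy_area_mm2 = 0.0025, Lz = 5,
                    place_w = c(1, 0, 0, 0, 0)) # +x only
  set.seed(2)
  st <- init_tissue(cfg, p)
  st$occ[] <- 0L
  st$occ[2, 2, 1:5] <- 1L # column full to the lid
  st$occ[1, 2, 1] <- 1L   # divider
  st$birth[2, 2, 1:5] <- 101:105
  res <- place_daughter(st, cfg, 1, 2, 1)
  expect_equal(res$outcome, "placed")
  expect_equal(res$sheds, 1)         # top cell pushed past the lid
  expect_equal(res$basal_losses, 1)  # basal occupant displaced upward
  expect_equal(res$state$birth[2, 2, ], c(0, 101, 102, 103, 104))
})

test_that("an empty column above means placement without displacement", {
  p <- tiny_panel()
  cfg <- sim_config(biopsy_area_mm2 = 0.0025, Lz = 5,
                    place_w = c(0, 0, 0, 0, 1)) # above only
  set.seed(2)
  st <- init_tissue(cfg, p)
  n0 <- sum(st$occ > 0)
  res <- place_daughter(st, cfg, 2, 2, 1)
  expect_equal(res$outcome, "placed")
  expect_equal(res$sheds, 0)
  expect_equal(sum(res$state$occ > 0), n0 + 1)
  expect_gt(res$state$occ[2, 2, 2], 0)
})

test_that("lateral targets wrap around the periodic boundary", {
  p <- tiny_panel()
  cfg <- sim_config(biopsy_area_mm2 = 0.0025, Lz = 5,
                    place_w = c(0, 1, 0, 0, 0)) # -x only
  set.seed(2)
  st <- init_tissue(cfg, p)
  st$occ[] <- 0L
  st$occ[1, 2, 1] <- 1L
  res <- place_daughter(st, cfg, 1, 2, 1)
  expect_equal(res$outcome, "placed")
  expect_gt(res$state$occ[cfg$Lx, 2, 1], 0) # wrapped to the opposite face
})

test_that("neutral tissue is stationary over a simulated year", {
  cfg <- sim_config(biopsy_area_mm2 = 0.0225) # 10x10 columns
  p <- tiny_panel()
  slopes <- sapply(1:5, function(seed) {
    set.seed(seed)
    st <- run_epidermis(init_tissue(cfg, p), cfg, 565)
    s <- tail(st$series, 365)
    wk <- (seq_len(nrow(s)) - 1) %/% 7
    weekly <- tapply(s$total, wk, mean)
    fit <- summary(lm(weekly ~ seq_along(weekly)))$coefficients
    # t statistic of the weekly trend
    fit[2, "t value"]
  })
  # no significant trend: |t| < 2 for most seeds, never extreme
  expect_gt(mean(abs(slopes) < 2), 0.5)
  expect_true(all(abs(slopes) < 4))
})

test_that("wounds regrow to the pre-wound population", {
  cfg <- tiny_config()
  p <- tiny_panel()
  recovered <- sapply(1:3, function(seed) {
    set.seed(seed)
    st <- run_epidermis(init_tissue(cfg, p), cfg, 320)
    pre <- mean(tail(st$series$total, 60))
    st <- wound(st, 1:4, 1:4) # ~1/3 of the columns, full height
    st <- run_epidermis(st, cfg, 200)
    post <- mean(tail(st$series$total, 30))
    abs(post - pre) / pre
  })
  expect_true(all(recovered < 0.05))
})

test_that("an empty wound leaves the trajectory untouched", {
  cfg <- tiny_config()
  p <- tiny_panel()
  set.seed(4)
  st0 <- run_epidermis(init_tissue(cfg, p), cfg, 30)
  set.seed(10); a <- run_epidermis(wound(st0, integer(0), integer(0)), cfg, 50)
  set.seed(10); b <- run_epidermis(st0, cfg, 50)
  expect_identical(a$occ, b$occ)
})

test_that("immortal non-dividing cells keep every lineage alive", {
  cfg <- sim_config(biopsy_area_mm2 = 0.01, p_max = 0, d_max = 0)
  set.seed(1)
  st <- label_basal_lineages(init_tissue(cfg, tiny_panel()))
  st <- run_epidermis(st, cfg, 28)
  surv <- lineage_survival(st)
  expect_true(all(surv$frac == 1))
  expect_error(fit_lineage_halflife(surv), "does not decay")
})

test_that("a pure death process recovers its Markov half-life", {
  d <- 0.05 # per day, flat response
  cfg <- sim_config(biopsy_area_mm2 = 0.09, p_max = 0,
                    d_max = d, K_die = 1e9, h_die = 1)
  set.seed(2)
  st <- label_basal_lineages(init_tissue(cfg, tiny_panel()))
  st <- run_epidermis(st, cfg, 7 * 6)
  fit <- fit_lineage_halflife(lineage_survival(st))
  expected <- log(2) / (-7 * log(1 - d)) # weeks
  expect_lt(abs(fit$half_life_weeks - expected) / expected, 0.2)
})

test_that("basal lineage half-life is invariant to domain size", {
  p <- tiny_panel()
  fits <- lapply(c(0.25, 1), function(area) {
    cfg <- sim_config(biopsy_area_mm2 = area)
    set.seed(31)
    st <- run_epidermis(init_tissue(cfg, p), cfg, 120)
    tr <- track_lineages(st, cfg, weeks = 16)
    tr$fit
  })
  lo <- sapply(fits, function(f) f$ci[1])
  hi <- sapply(fits, function(f) f$ci[2])
  expect_gt(min(hi), max(lo)) # confidence intervals overlap
})
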