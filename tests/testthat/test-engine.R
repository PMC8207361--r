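test_that("realized suitability implements the basin-model rule", {
  expect_equal(realized_suitability(H = 0.5, Z = 0.5, N = 0, K = 40), 1)
  expect_equal(realized_suitability(H = 0.3, Z = 0.5, N = 20, K = 40), 0.3)
  expect_equal(realized_suitability(H = 0.7, Z = 0.7, N = 40, K = 40), 0)
  expect_error(realized_suitability(0.5, 0.5, 0, K = 0), "positive")
})

test_that("initialisation places 100 fish per age class with in-niche preferences", {
  cfg <- sim_config(preference = "strong", seed = 3)
  g <- make_gradient_landscape(cfg$K)
  m <- niche_model(cfg$preference)
  set.seed(cfg$seed)
  st <- initialize_population(cfg, m, g)
  expect_equal(length(st$age), 900L)
  expect_equal(unname(table(st$age)), rep(100L, 9L), ignore_attr = TRUE)
  expect_true(all(st$cell >= 1L & st$cell <= 121L))
  iv <- niche_interval(m, st$age)
  expect_true(all(st$Z >= iv[, "lo"] & st$Z <= iv[, "hi"]))
  set.seed(cfg$seed)
  st2 <- initialize_population(cfg, m, g)
  expect_identical(st, st2)
})

test_that("movement conserves fish and moves at most one cell", {
  cfg <- sim_config(seed = 8)
  g <- make_gradient_landscape(cfg$K)
  m <- niche_model("strong")
  set.seed(cfg$seed)
  st <- initialize_population(cfg, m, g)
  grid_rc <- function(cell) cbind((cell - 1L) %/% 11L, (cell - 1L) %% 11L)
  co0 <- grid_rc(st$cell)
  st1 <- movement_step(st, g)
  expect_equal(length(st1$age), length(st$age))
  expect_identical(st1$age, st$age)
  expect_identical(st1$Z, st$Z)
  expect_equal(sum(occupancy(st1)), length(st1$age))
  co1 <- grid_rc(st1$cell)
  cheb <- pmax(abs(co1[, 1] - co0[, 1]), abs(co1[, 2] - co0[, 2]))
  expect_true(all(cheb <= 1))
})

test_that("a fish moves iff the candidate cell is strictly better", {
  # 1x2 world, one fish preferring H = 1 sitting on H = 0: forced move
  w <- make_fixture_world(width = 2, height = 1, H = c(0, 1), K = 1e6,
                          age = 5L, Z = 1.0, row = 0L, col = 0L)
  st <- movement_step(w$state, w$grid)
  expect_equal(st$cell, 2L)
  # strictly worse candidate: the fish stays despite the empty neighbour
  w2 <- make_fixture_world(width = 2, height = 1, H = c(0, 1), K = 10,
                           age = 5L, Z = 0.0, row = 0L, col = 0L)
  for (i in 1:5) expect_equal(movement_step(w2$state, w2$grid)$cell, 1L)
  # exactly equal suitability (equal H, equal snapshot density): both stay
  w3 <- make_fixture_world(width = 2, height = 1, H = c(0.5, 0.5), K = 10,
                           age = c(5L, 5L), Z = c(0.5, 0.5),
                           row = c(0L, 0L), col = c(0L, 1L))
  for (i in 1:5) {
    expect_equal(movement_step(w3$state, w3$grid)$cell, c(1L, 2L))
  }
})

test_that("annual demographic update follows the reproduction-then-survival schedule", {
  m <- niche_model("strong")
  # degenerate rates: no reproduction, no mortality -> only ageing
  w <- make_fixture_world(width = 2, height = 2, H = rep(0.5, 4), K = 100,
                          age = c(1L, 4L, 8L, 9L), Z = rep(0.5, 4),
                          row = c(0L, 0L, 1L, 1L), col = c(0L, 1L, 0L, 1L),
                          R = rep(0, 9), M = c(rep(0, 8), 1))
  set.seed(1)
  nxt <- annual_demographic_update(w$state, w$vr, m)
  expect_equal(sort(nxt$age), c(2L, 5L, 9L))  # age-9 fish died, others aged
  # total mortality: the population empties in one year
  w2 <- make_fixture_world(width = 2, height = 1, H = c(0, 1), K = 10,
                           age = c(3L, 7L), Z = c(0.2, 0.8),
                           row = c(0L, 0L), col = c(0L, 1L),
                           R = rep(0, 9), M = rep(1, 9))
  nxt2 <- annual_demographic_update(w2$state, w2$vr, m)
  expect_equal(length(nxt2$age), 0L)
  # an all-age-9 cohort leaves only its Bernoulli(R9) newborns
  n9 <- 200L
  w3 <- make_fixture_world(width = 2, height = 1, H = c(0, 1), K = 1e6,
                           age = rep(9L, n9), Z = rep(0.8, n9),
                           row = rep(0L, n9), col = rep(0L, n9))
  set.seed(2)
  nxt3 <- annual_demographic_update(w3$state, w3$vr, m)
  expect_true(all(nxt3$age == 1L))
  expect_lte(length(nxt3$age), n9)
})

test_that("expected newborn count matches the binomial expectation", {
  m <- niche_model("weak")
  vr <- make_vital_rates(0)
  n_per <- 60L
  age <- rep(1:9, each = n_per)
  w <- make_fixture_world(width = 11, height = 11,
                          H = make_gradient_landscape(40)$H, K = 40,
                          age = age, Z = rep(0.5, length(age)),
                          row = rep(0L, length(age)),
                          col = rep(0L, length(age)))
  expected <- sum(vr$R * n_per)
  set.seed(99)
  reps <- 400L
  newborn <- vapply(seq_len(reps), function(i) {
    sum(annual_demographic_update(w$state, vr, m)$age == 1L)
  }, numeric(1))
  # Monte-Carlo mean within 3 standard errors of sum_i R_i N_i
  se <- stats::sd(newborn) / sqrt(reps)
  expect_lt(abs(mean(newborn) - expected), 3 * se)
})

test_that("a full run records 15 annual snapshots and is seed-reproducible", {
  cfg <- sim_config(preference = "weak", F = 0.2, landscape = "fragmented",
                    K = 20, seed = 77)
  out <- run_simulation(cfg)
  expect_equal(dim(out$abund), c(121L, 9L, 15L))
  expect_true(all(out$abund >= 0L))
  expect_true(is.na(out$extinct_year))
  out2 <- run_simulation(cfg)
  expect_identical(out$abund, out2$abund)
  # tidy view reconstructs the same totals
  df <- as.data.frame(out)
  expect_equal(sum(df$abundance), sum(out$abund))
  expect_true(all(df$age_class %in% 1:9))
})

test_that("the unfished population is quasi-stationary after the transient", {
  cfg <- sim_config(preference = "strong", F = 0, K = 40, seed = 21)
  out <- run_simulation(cfg)
  tot <- apply(out$abund, 3, sum)
  # after the 5-year transient the trajectory stays near its year-5 level
  expect_true(all(abs(tot[5:15] - tot[5]) / tot[5] < 0.15))
})

test_that("age structure is right-skewed and fishing truncates the old ages", {
  mean_age_structure <- function(Fv, seed) {
    out <- run_simulation(sim_config("strong", F = Fv, K = 40, seed = seed))
    rowMeans(apply(out$abund[, , 5:15], c(2, 3), sum))
  }
  set.seed(0)
  a0 <- (mean_age_structure(0, 31) + mean_age_structure(0, 32) +
           mean_age_structure(0, 33)) / 3
  a5 <- (mean_age_structure(0.5, 41) + mean_age_structure(0.5, 42) +
           mean_age_structure(0.5, 43)) / 3
  expect_true(all(diff(a0) < 0))  # strictly decreasing with age at F = 0
  # fishing depresses the exploited-and-older ages relative to no fishing
  expect_true(all(a5[5:9] < a0[5:9]))
  # and leaves the youngest classes comparatively intact
  expect_gt(sum(a5[1:3]) / sum(a0[1:3]), sum(a5[5:9]) / sum(a0[5:9]))
})

test_that("strong preference segregates age classes in space more than weak", {
  pair_overlap <- function(pref) {
    out <- run_simulation(sim_config(pref, F = 0, K = 160, seed = 55))
    snap <- out$abund[, , 15]
    p <- sweep(snap, 2, pmax(colSums(snap), 1), "/")
    ov <- outer(1:9, 1:9, Vectorize(function(i, j) sum(pmin(p[, i], p[, j]))))
    mean(ov[upper.tri(ov)])
  }
  expect_lt(pair_overlap("strong"), pair_overlap("weak"))
})

test_that("scenario enumeration and seed derivation are deterministic", {
  expect_equal(nrow(scenario_grid()), 144L)
  small <- scenario_grid(F = 0.2, K = 40)
  expect_equal(nrow(small), 4L)  # 2 preferences x 2 landscapes
  s1 <- derive_seed(1, 3, 7)
  expect_identical(s1, derive_seed(1, 3, 7))
  expect_false(s1 == derive_seed(1, 3, 8))
  expect_false(s1 == derive_seed(2, 3, 7))
  seeds <- vapply(1:500, function(r) derive_seed(1, 1, r), integer(1))
  expect_equal(length(unique(seeds)), 500L)
  expect_true(all(seeds >= 1 & seeds < 2^31))
})

test_that("a tiny scenario grid returns one summary row per run", {
  sc <- scenario_grid(preference = "strong", F = c(0, 0.5),
                      landscape = "gradient", K = 40)
  sm <- run_scenario_grid(sc, replicates = 2, master_seed = 5,
                          years = 6, window = 5:6)
  expect_equal(nrow(sm), 4L)
  expect_equal(sort(unique(sm$F)), c(0, 0.5))
  expect_true(all(c("mean_shannon", "mean_cv", "mean_popsize", "seed")
                  %in% names(sm)))
  # rerunning one replicate in isolation reproduces the grid row
  row <- sm[sm$F == 0.5 & sm$replicate == 2, ]
  cfg <- sim_config("strong", 0.5, "gradient", 40, years = 6,
                    seed = row$seed, replicate = 2)
  sm_single <- summarize_replicate(run_simulation(cfg), window = 5:6)
  expect_equal(row$mean_cv, sm_single$mean_cv)
  expect_equal(row$mean_shannon, sm_single$mean_shannon)
})
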