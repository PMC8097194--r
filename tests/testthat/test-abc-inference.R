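# brute-force two-sample KS: exhaustive scan of the CDF difference at every
# step point (independent oracle for the package's ECDF implementation)
ks_brute <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(vapply(pts, function(v) abs(mean(x <= v) - mean(y <= v)), numeric(1)))
}

test_that("the summed KS distance matches brute force and ks.test", {
  obs <- clone_dataset(data.frame(
    mouse_id = rep(c("a", "b"), each = 10),
    time_days = rep(c(3, 84), 10),
    clone_size = sample(1:12, 20, replace = TRUE)))
  set.seed(81)
  sim <- list(sample(1:9, 40, replace = TRUE), sample(1:30, 40, replace = TRUE))
  d <- ks_distance(sim, obs)
  tps <- c(3, 84)
  exp_d <- 0
  for (k in 1:2) {
    o <- obs$clone_size[obs$time_days == tps[k]]
    expect_equal(ks_brute(sim[[k]], o),
                 suppressWarnings(stats::ks.test(sim[[k]], o)$statistic[[1]]))
    exp_d <- exp_d + ks_brute(sim[[k]], o)
  }
  expect_equal(d, exp_d)
})

test_that("KS distance hits its extremes", {
  obs <- clone_dataset(data.frame(
    mouse_id = "m",
    time_days = rep(standard_timepoints_days(), each = 5),
    clone_size = rep(1:5, 7)))
  identical_sim <- lapply(standard_timepoints_days(), function(.) 1:5)
  expect_equal(ks_distance(identical_sim, obs), 0)
  disjoint_sim <- lapply(standard_timepoints_days(), function(.) 100:104)
  expect_equal(ks_distance(disjoint_sim, obs), 7)
})

test_that("KS distance validates timepoint coverage and survival", {
  obs <- clone_dataset(data.frame(mouse_id = "m", time_days = c(3, 10),
                                  clone_size = c(2, 3)))
  expect_error(ks_distance(list(1:3), obs), "one simulated size vector")
  expect_error(ks_distance(list(c(0L, 0L), 1:3), obs), "no surviving")
  # simulated sizes are conditioned on survival before comparison
  expect_equal(ks_distance(list(c(0L, 2L), c(0L, 3L)), obs), 0)
})

test_that("per-mouse averaging differs from pooling when mice differ", {
  obs <- clone_dataset(data.frame(
    mouse_id = rep(c("a", "b"), each = 6),
    time_days = 3,
    clone_size = c(rep(1L, 6), rep(8L, 6))))
  sim <- list(rep(1L, 20))
  pooled <- ks_distance(sim, obs)
  per_mouse <- ks_distance(sim, obs, per_mouse = TRUE)
  expect_equal(pooled, 0.5)
  expect_equal(per_mouse, 0.5)  # mean of 0 and 1
  sim2 <- list(c(rep(1L, 10), rep(8L, 10)))
  expect_false(isTRUE(all.equal(ks_distance(sim2, obs),
                                ks_distance(sim2, obs, per_mouse = TRUE))))
})

test_that("SMC-ABC respects the prior support and shrinks its tolerance", {
  ch <- generate_cohort(cohort_design(
    timepoints_days = c(10, 84), mice_per_timepoint = 2,
    clones_per_mouse = 50, simulated_clones_per_mouse = 500,
    lambda_sd = 0, r_sd = 0, rho_sd = 0), seed = 83)
  post <- smc_abc(ch$observations, 2.9,
                  config = abc_config(n_populations = 4, population_size = 60,
                                      clones_per_particle = 150), seed = 84)
  expect_true(all(post$particles$r > 0 & post$particles$r < 0.5))
  expect_true(all(post$particles$rho > 0 & post$particles$rho < 1))
  expect_true(all(diff(post$history$tolerance) < 0))
  expect_true(all(diff(post$history$mean_distance) <= 0))
  w <- post$particles$weight[post$particles$generation == 4]
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w >= 0))
})

test_that("SMC-ABC is deterministic given a seed", {
  ch <- generate_cohort(cohort_design(
    timepoints_days = c(21, 180), mice_per_timepoint = 1,
    clones_per_mouse = 40, simulated_clones_per_mouse = 400,
    lambda_sd = 0, r_sd = 0, rho_sd = 0), seed = 85)
  cfg <- abc_config(n_populations = 2, population_size = 30,
                    clones_per_particle = 100)
  a <- smc_abc(ch$observations, 2.9, config = cfg, seed = 86)
  b <- smc_abc(ch$observations, 2.9, config = cfg, seed = 86)
  expect_identical(a$particles, b$particles)
  expect_identical(a$history, b$history)
})

test_that("posterior summaries reduce to sample quantiles for uniform weights", {
  particles <- data.frame(r = seq(0.1, 0.3, length.out = 101),
                          rho = seq(0.4, 0.8, length.out = 101),
                          weight = rep(1 / 101, 101), generation = 1L)
  post <- structure(list(particles = particles,
                         history = data.frame(), config = abc_config(),
                         lambda = 2.9, cell_cycle = cc_exponential(),
                         seed = NULL),
                    class = "abc_posterior")
  s <- posterior_summary(post)
  expect_equal(s$r[["median"]], stats::quantile(particles$r, 0.5,
                                                type = 1, names = FALSE))
  expect_equal(s$r[["lower"]], stats::quantile(particles$r, 0.025,
                                               type = 1, names = FALSE))
  expect_equal(s$rho[["upper"]], stats::quantile(particles$rho, 0.975,
                                                 type = 1, names = FALSE))
  # identical particles collapse to zero-width intervals
  pd <- particles; pd$r <- 0.2; pd$rho <- 0.6
  post$particles <- pd
  sd <- posterior_summary(post)
  expect_equal(unname(sd$r[c("lower", "upper")]), c(0.2, 0.2))
  expect_equal(unname(sd$rho[c("lower", "upper")]), c(0.6, 0.6))
})

test_that("posterior summaries warn on tiny effective sample size", {
  particles <- data.frame(r = c(0.1, 0.2), rho = c(0.5, 0.6),
                          weight = c(0.999, 0.001), generation = 1L)
  post <- structure(list(particles = particles, history = data.frame(),
                         config = abc_config(), lambda = 2.9,
                         cell_cycle = cc_exponential(), seed = NULL),
                    class = "abc_posterior")
  expect_warning(posterior_summary(post), "effective sample size")
})

test_that("ABC recovers parameters of a small exponential cohort", {
  ch <- generate_cohort(cohort_design(
    timepoints_days = c(10, 84, 365), mice_per_timepoint = 2,
    clones_per_mouse = 100, simulated_clones_per_mouse = 2000,
    r_mean = 0.09, r_sd = 0, rho_mean = 0.7, rho_sd = 0, lambda_sd = 0),
    seed = 87)
  post <- smc_abc(ch$observations, 2.9,
                  config = abc_config(n_populations = 4, population_size = 100,
                                      clones_per_particle = 300), seed = 88)
  s <- posterior_summary(post)
  expect_lt(s$r[["lower"]], 0.09)
  expect_gt(s$r[["upper"]], 0.09)
  expect_lt(s$rho[["lower"]], 0.7)
  expect_gt(s$rho[["upper"]], 0.7)
})
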