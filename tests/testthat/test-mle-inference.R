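make_pmf <- function(p, t_days, conditioned = TRUE) {
  # hand-built conditioned PMF over n = 1..length(p)
  structure(list(p = p, n = seq_along(p), time_weeks = t_days / 7,
                 conditioned = conditioned, n_max = length(p),
                 tail_mass = max(0, 1 - sum(p)), source = "test",
                 leakage = NA_real_),
            class = "clone_size_pmf")
}

test_that("the log-likelihood is the count-weighted log probability sum", {
  # counts {n=1: 2, n=2: 1}; probabilities {0.5, 0.25}
  dat <- clone_dataset(data.frame(mouse_id = "m", time_days = 3,
                                  clone_size = c(1, 1, 2)))
  pm <- list(d3 = make_pmf(c(0.5, 0.25), 3))
  expect_equal(as.numeric(log_likelihood(dat, pm)),
               2 * log(0.5) + log(0.25))
  expect_equal(as.numeric(log_likelihood(dat, pm)), -2.772589, tolerance = 1e-6)
})

test_that("log-likelihood is linear in counts and zero on empty data", {
  empty <- clone_dataset(data.frame(mouse_id = character(),
                                    time_days = numeric(),
                                    clone_size = integer()))
  expect_equal(as.numeric(log_likelihood(empty, list())), 0)
  dat1 <- clone_dataset(data.frame(mouse_id = "m", time_days = 3,
                                   clone_size = c(1, 2, 2, 5)))
  dat3 <- clone_dataset(dat1[rep(seq_len(4), each = 3), ])
  pm <- list(d3 = make_pmf(c(0.4, 0.3, 0.1, 0.1, 0.1), 3))
  expect_equal(3 * as.numeric(log_likelihood(dat1, pm)),
               as.numeric(log_likelihood(dat3, pm)))
})

test_that("coverage gaps error while zero probabilities hit the sentinel", {
  dat <- clone_dataset(data.frame(mouse_id = "m", time_days = 3,
                                  clone_size = c(1, 4)))
  expect_error(log_likelihood(dat, list(d3 = make_pmf(c(0.6, 0.4), 3))),
               "does not cover")
  ll <- log_likelihood(dat, list(d3 = make_pmf(c(0.6, 0.2, 0.2, 0), 3)))
  expect_equal(as.numeric(ll), log(0.6) + (-1000))
  expect_equal(attr(ll, "n_zero"), 1L)
  # unconditioned PMFs are rejected: observed clones are survivors
  expect_error(
    log_likelihood(dat, list(d3 = empirical_pmf(c(1L, 4L)))),
    "conditioned")
})

test_that("grid axes follow the documented open/closed-bound node formula", {
  g <- grid_spec(49, 49)
  expect_length(g$r, 49)
  expect_equal(max(g$r), 0.5)       # closed upper bound included
  expect_gt(min(g$r), 0)            # open lower bound excluded
  expect_equal(g$rho, (1:49) / 50)  # both endpoints excluded
  g25 <- grid_spec(25, 25)
  expect_true(0.06 %in% g25$r)
  expect_true(0.5 %in% round(g25$rho, 10))
})

test_that("concatenated datasets add their log-likelihood surfaces", {
  set.seed(51)
  p1 <- sp_params(2.9, 0.1, 0.4)
  p2 <- sp_params(2.9, 0.3, 0.6)
  tw <- days_to_weeks(c(10, 84))
  mk <- function(p, id) {
    s <- simulate_clones(p, tw, 400)
    do.call(rbind, lapply(1:2, function(k) {
      sz <- s$size[s$size[, k] >= 1, k]
      data.frame(mouse_id = id, time_days = weeks_to_days(tw[k]),
                 clone_size = sz)
    }))
  }
  d1 <- clone_dataset(mk(p1, "a"))
  d2 <- clone_dataset(mk(p2, "b"))
  d12 <- clone_dataset(rbind(d1, d2))
  g <- grid_spec(5, 5)
  s1 <- mle_grid_analytic(d1, 2.9, grid = g, n_max = 64)
  s2 <- mle_grid_analytic(d2, 2.9, grid = g, n_max = 64)
  s12 <- mle_grid_analytic(d12, 2.9, grid = g, n_max = 64)
  expect_equal(s12$loglik, s1$loglik + s2$loglik, tolerance = 1e-7)
})

test_that("the full surface is the exact sum of per-timepoint surfaces", {
  set.seed(53)
  ch <- generate_cohort(cohort_design(
    timepoints_days = c(10, 42, 180), mice_per_timepoint = 2,
    clones_per_mouse = 200, simulated_clones_per_mouse = 2000), seed = 53)
  res <- per_timepoint_surfaces(ch$observations, 2.9, grid = grid_spec(7, 7),
                                n_max = 64)
  total <- Reduce(`+`, lapply(res$per_timepoint, function(s) s$loglik))
  expect_equal(res$combined$loglik, total, tolerance = 1e-12)
  # single-timepoint surfaces are individually broader than the combined one
  width <- function(s) diff(s$intervals$r) + diff(s$intervals$rho)
  expect_true(all(vapply(res$per_timepoint, width, numeric(1)) >=
                    width(res$combined)))
})

test_that("analytic grid MLE recovers generating parameters on a moderate cohort", {
  ch <- generate_cohort(large_sample_design(total_clones = 2e4), seed = 55)
  g <- grid_spec(25, 25)
  s <- mle_grid_analytic(ch$observations, 2.9, grid = g)
  expect_lte(abs(s$argmax["r"] - 0.06), 0.5 / 25 + 1e-12)
  expect_lte(abs(s$argmax["rho"] - 0.5), 1 / 26 + 1e-12)
  expect_equal(s$settings$n_failed, 0L)
})

test_that("simulation-based MLE agrees with the analytic engine", {
  ch <- generate_cohort(cohort_design(
    timepoints_days = c(3, 42, 365), mice_per_timepoint = 1,
    clones_per_mouse = Inf, simulated_clones_per_mouse = 5000,
    lambda_sd = 0, r_sd = 0, rho_sd = 0, r_mean = 0.09, rho_mean = 0.7),
    seed = 57)
  g <- grid_spec(9, 9)
  sa <- mle_grid_analytic(ch$observations, 2.9, grid = g)
  ss <- mle_grid_simulation(ch$observations, 2.9, grid = g, n_sim = 1e4,
                            seed = 58)
  expect_lte(abs(sa$argmax["r"] - ss$argmax["r"]), 0.5 / 9 + 1e-12)
  expect_lte(abs(sa$argmax["rho"] - ss$argmax["rho"]), 1 / 10 + 1e-12)
})

test_that("starved simulation PMFs give rougher surfaces than rich ones", {
  ch <- generate_cohort(cohort_design(
    timepoints_days = c(10, 84), mice_per_timepoint = 1,
    clones_per_mouse = 100, simulated_clones_per_mouse = 2000,
    lambda_sd = 0, r_sd = 0, rho_sd = 0), seed = 61)
  g <- grid_spec(5, 5)
  surf_sd <- function(n_sim, seeds) {
    m <- vapply(seeds, function(sd) {
      s <- mle_grid_simulation(ch$observations, 2.9, grid = g, n_sim = n_sim,
                               seed = sd)
      v <- as.vector(s$loglik)
      v[!is.finite(v)] <- -1000 * nrow(ch$observations)
      v
    }, numeric(25))
    mean(apply(m, 1, stats::sd))
  }
  # N = 10 clones per grid point: surface varies wildly across seeds;
  # N = 1e4 is far more stable (the sampling-noise failure mode)
  expect_gt(surf_sd(10, 71:73), 5 * surf_sd(1e4, 74:76))
})

test_that("interval construction behaves at its edges", {
  ch <- generate_cohort(cohort_design(
    timepoints_days = c(21, 180), mice_per_timepoint = 1,
    clones_per_mouse = 200, simulated_clones_per_mouse = 2000,
    lambda_sd = 0, r_sd = 0, rho_sd = 0), seed = 63)
  s <- mle_grid_analytic(ch$observations, 2.9, grid = grid_spec(9, 9),
                         n_max = 64)
  full <- interval_from_surface(s, level = 1)
  expect_equal(full$r, range(s$r))
  expect_equal(full$rho, range(s$rho))
  # a degenerate surface collapses to zero width, with a warning
  s2 <- s
  s2$loglik[] <- -1e6
  s2$loglik[3, 4] <- 0
  s2$normalized <- exp(s2$loglik - max(s2$loglik))
  s2$normalized <- s2$normalized / sum(s2$normalized)
  s2$profile_r <- rowSums(s2$normalized)
  s2$profile_rho <- colSums(s2$normalized)
  expect_warning(ci <- interval_from_surface(s2), "degenerate")
  expect_equal(diff(ci$r), 0)
  expect_equal(diff(ci$rho), 0)
})

test_that("sharper data never widens the intervals", {
  des <- cohort_design(timepoints_days = c(10, 84, 365),
                       mice_per_timepoint = 1, clones_per_mouse = Inf,
                       simulated_clones_per_mouse = 800,
                       lambda_sd = 0, r_sd = 0, rho_sd = 0)
  small <- generate_cohort(des, seed = 65)
  des$simulated_clones_per_mouse <- 8000
  big <- generate_cohort(des, seed = 65)
  g <- grid_spec(13, 13)
  si <- mle_grid_analytic(small$observations, 2.9, grid = g)
  bi <- mle_grid_analytic(big$observations, 2.9, grid = g)
  expect_lte(diff(bi$intervals$r), diff(si$intervals$r))
  expect_lte(diff(bi$intervals$rho), diff(si$intervals$rho))
})
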