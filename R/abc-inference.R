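# Sequential Monte Carlo approximate Bayesian computation for (r, rho) at
# fixed lambda, with a summed per-timepoint two-sample Kolmogorov-Smirnov
# distance between simulated and observed basal clone-size samples.
#
# Scheme (Toni et al. style): generation 1 draws particles from independent
# uniform priors r ~ U(0, 0.5), rho ~ U(0, 1); later generations resample
# the previous weighted population, perturb with a Gaussian kernel whose
# covariance is twice the weighted particle covariance, reject proposals
# outside the prior support, and accept when the distance falls below the
# adaptive tolerance (the median of the previous generation's accepted
# distances). Importance weights use the standard kernel correction.

# two-sample KS statistic: sup |ECDF_x - ECDF_y| (tie-safe for discrete data)
ks_stat <- function(x, y) {
  v <- sort(unique(c(x, y)))
  Fx <- cumsum(tabulate(match(x, v), nbins = length(v))) / length(x)
  Fy <- cumsum(tabulate(match(y, v), nbins = length(v))) / length(y)
  max(abs(Fx - Fy))
}

#' Summed Kolmogorov-Smirnov distance between clone-size samples
#'
#' For each timepoint, computes the two-sample KS statistic between the
#' simulated and observed basal clone sizes (both conditioned on survival,
#' n >= 1; observed clones pooled across mice by default) and returns the
#' sum over timepoints.
#'
#' @param sim A `clone_sample` from [simulate_clones()] whose
#'   `timepoints_weeks` match the observed timepoints, or a list of integer
#'   size vectors per timepoint.
#' @param obs A [clone_dataset()].
#' @param per_mouse If `TRUE`, average per-mouse KS statistics within each
#'   timepoint instead of pooling mice.
#' @return Non-negative scalar; at most the number of timepoints.
#' @export
ks_distance <- function(sim, obs, per_mouse = FALSE) {
  obs <- clone_dataset(obs)
  tps <- sort(unique(obs$time_days))
  sim_sizes <- if (inherits(sim, "clone_sample")) {
    if (length(sim$timepoints_weeks) != length(tps) ||
        max(abs(weeks_to_days(sim$timepoints_weeks) - tps)) > 1e-8)
      stop("simulated timepoints do not match observed timepoints",
           call. = FALSE)
    lapply(seq_along(tps), function(k) sim$size[, k])
  } else {
    if (length(sim) != length(tps))
      stop("need one simulated size vector per observed timepoint",
           call. = FALSE)
    sim
  }
  d <- 0
  for (k in seq_along(tps)) {
    s <- sim_sizes[[k]]
    s <- s[s >= 1]  # condition on survival to match observed clones
    if (!length(s))
      stop("no surviving simulated clones at timepoint ", tps[k], " days",
           call. = FALSE)
    o_t <- obs[obs$time_days == tps[k], , drop = FALSE]
    if (!nrow(o_t))
      stop("no observed clones at timepoint ", tps[k], " days",
           call. = FALSE)
    if (per_mouse) {
      per <- vapply(split(o_t$clone_size, o_t$mouse_id),
                    function(o) ks_stat(s, o), numeric(1))
      d <- d + mean(per)
    } else {
      d <- d + ks_stat(s, o_t$clone_size)
    }
  }
  d
}

#' SMC-ABC configuration
#'
#' Defaults follow the published protocol sizes: 10 populations of 500
#' particles, 1000 simulated clones per proposed parameter set.
#'
#' @param n_populations Number of SMC generations.
#' @param population_size Accepted particles per generation.
#' @param clones_per_particle Clones simulated per proposal.
#' @param tolerance_quantile Quantile of the previous generation's accepted
#'   distances used as the next tolerance (default 0.5, the median).
#' @param min_acceptance Acceptance-rate floor: below it the run stops
#'   early with a warning and returns the generations completed (rising
#'   rejection signals the onset of overfitting).
#' @param per_mouse Use the per-mouse-averaged KS variant.
#' @return A list of class `abc_config`.
#' @export
abc_config <- function(n_populations = 10, population_size = 500,
                       clones_per_particle = 1000, tolerance_quantile = 0.5,
                       min_acceptance = 1e-3, per_mouse = FALSE) {
  structure(list(n_populations = n_populations,
                 population_size = population_size,
                 clones_per_particle = clones_per_particle,
                 tolerance_quantile = tolerance_quantile,
                 min_acceptance = min_acceptance, per_mouse = per_mouse),
            class = "abc_config")
}

#' Sequential Monte Carlo ABC inference of (r, rho)
#'
#' Likelihood-free posterior inference at fixed `lambda` with uniform
#' priors r ~ U(0, 0.5), rho ~ U(0, 1). Works with either cell-cycle
#' model; the non-Markovian simulator is the route that accommodates
#' realistic (gamma) division-time distributions.
#'
#' @param data A [clone_dataset()].
#' @param lambda Fixed division rate (per week).
#' @param cell_cycle Cell-cycle model for the simulator.
#' @param config An [abc_config()].
#' @param seed Optional integer seed (full-run determinism).
#' @return An `abc_posterior`: `particles` (data.frame r, rho, weight,
#'   generation for every generation, final generation carrying the
#'   posterior), `history` (per-generation tolerance, acceptance rate, mean
#'   accepted distance), and the configuration.
#' @export
smc_abc <- function(data, lambda, cell_cycle = cc_exponential(),
                    config = abc_config(), seed = NULL) {
  data <- clone_dataset(data, lambda = lambda)
  if (!nrow(data)) stop("empty dataset", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tps <- sort(unique(data$time_days))
  tw <- days_to_weeks(tps)
  npop <- config$population_size
  r_max <- 0.5
  simulate_distance <- function(r, rho) {
    p <- sp_params(lambda, r, rho)
    s <- simulate_clones(p, tw, n_clones = config$clones_per_particle,
                         cell_cycle = cell_cycle)
    # a proposal whose clones are all extinct at some timepoint cannot match
    # survival-conditioned observations: infinite distance, certain rejection
    tryCatch(ks_distance(s, data, per_mouse = config$per_mouse),
             error = function(e) {
               if (grepl("no surviving", conditionMessage(e))) Inf else stop(e)
             })
  }
  all_particles <- list()
  history <- data.frame()
  prev <- NULL
  tol <- Inf
  for (gen in seq_len(config$n_populations)) {
    acc_r <- acc_rho <- acc_d <- numeric(npop)
    new_w <- numeric(npop)
    n_acc <- 0L; n_prop <- 0L
    if (!is.null(prev)) {
      cv <- 2 * stats::cov.wt(cbind(prev$r, prev$rho), wt = prev$w)$cov
      # guard against degenerate covariance
      cv <- cv + diag(1e-10, 2)
      ch <- chol(cv)
    }
    max_prop <- ceiling(npop / config$min_acceptance)
    early <- FALSE
    while (n_acc < npop) {
      if (n_prop >= max_prop) { early <- TRUE; break }
      n_prop <- n_prop + 1L
      if (is.null(prev)) {
        r <- stats::runif(1, 0, r_max); rho <- stats::runif(1, 0, 1)
      } else {
        i <- sample.int(npop, 1, prob = prev$w)
        th <- c(prev$r[i], prev$rho[i]) + drop(stats::rnorm(2) %*% ch)
        r <- th[1]; rho <- th[2]
        if (r <= 0 || r >= r_max || rho <= 0 || rho >= 1) next
      }
      d <- simulate_distance(r, rho)
      if (is.finite(d) && d <= tol) {
        n_acc <- n_acc + 1L
        acc_r[n_acc] <- r; acc_rho[n_acc] <- rho; acc_d[n_acc] <- d
        new_w[n_acc] <- if (is.null(prev)) 1 else {
          dx <- acc_r[n_acc] - prev$r; dy <- acc_rho[n_acc] - prev$rho
          # bivariate normal kernel density at the proposal
          ici <- chol2inv(ch)
          q <- dx * (ici[1, 1] * dx + ici[1, 2] * dy) +
            dy * (ici[2, 1] * dx + ici[2, 2] * dy)
          dens <- sum(prev$w * exp(-0.5 * q)) /
            (2 * pi * prod(diag(ch)))
          1 / max(dens, 1e-300)  # uniform prior: constant numerator
        }
      }
    }
    if (early && n_acc == 0L) {
      warning(sprintf(paste0("SMC-ABC stopped before generation %d: ",
                             "acceptance rate below %.1e (rising rejection ",
                             "suggests overfitting); returning %d completed ",
                             "generation(s)"),
                      gen, config$min_acceptance, gen - 1L), call. = FALSE)
      break
    }
    keep <- seq_len(n_acc)
    w <- new_w[keep] / sum(new_w[keep])
    prev <- list(r = acc_r[keep], rho = acc_rho[keep], w = w)
    all_particles[[gen]] <- data.frame(r = prev$r, rho = prev$rho,
                                       weight = w, generation = gen)
    history <- rbind(history, data.frame(
      generation = gen, tolerance = tol, n_proposals = n_prop,
      acceptance_rate = n_acc / n_prop, mean_distance = mean(acc_d[keep])))
    if (early) {
      warning(sprintf(paste0("SMC-ABC stopped early at generation %d with ",
                             "%d/%d particles (acceptance below %.1e)"),
                      gen, n_acc, npop, config$min_acceptance), call. = FALSE)
      break
    }
    tol_next <- stats::quantile(acc_d[keep], config$tolerance_quantile,
                                names = FALSE)
    if (is.finite(tol) && tol_next >= tol) tol_next <- tol * 0.95
    tol <- tol_next
  }
  structure(list(particles = do.call(rbind, all_particles),
                 history = history, config = config, lambda = lambda,
                 cell_cycle = cell_cycle, seed = seed),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  g <- max(x$particles$generation)
  cat(sprintf("SMC-ABC posterior: %d generation(s), %d particles in final\n",
              g, sum(x$particles$generation == g)))
  s <- posterior_summary(x)
  cat(sprintf("  r  : median %.4g, 95%% CI (%.4g, %.4g)\n",
              s$r["median"], s$r["lower"], s$r["upper"]))
  cat(sprintf("  rho: median %.4g, 95%% CI (%.4g, %.4g)\n",
              s$rho["median"], s$rho["lower"], s$rho["upper"]))
  invisible(x)
}

# weighted quantile (type-1 step interpolation on the weighted ECDF)
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[o][which(cw >= p - 1e-12)[1]], numeric(1))
}

#' Weighted summaries of an ABC posterior
#'
#' Weighted median, mean and equal-tailed 95% credible interval per
#' parameter from the final particle generation, plus a weighted bivariate
#' Gaussian-kernel density estimate on a regular grid for plotting. Warns
#' when the effective sample size drops below 10.
#'
#' @param posterior An `abc_posterior` from [smc_abc()].
#' @param level Credible level (default 0.95).
#' @param kde_n Grid side length of the density estimate.
#' @return A list with `r`, `rho` (named vectors: median, mean, lower,
#'   upper), `ess`, and `kde` (list x, y, z).
#' @export
posterior_summary <- function(posterior, level = 0.95, kde_n = 50) {
  fin <- posterior$particles
  fin <- fin[fin$generation == max(fin$generation), ]
  w <- fin$weight / sum(fin$weight)
  ess <- 1 / sum(w^2)
  if (ess < 10)
    warning(sprintf("effective sample size %.1f < 10; summaries unreliable",
                    ess), call. = FALSE)
  a <- (1 - level) / 2
  summ <- function(x) {
    q <- weighted_quantile(x, w, c(0.5, a, 1 - a))
    c(median = q[1], mean = sum(w * x), lower = q[2], upper = q[3])
  }
  # weighted KDE with per-axis normal-reference bandwidths
  bw <- function(x) {
    sd <- sqrt(max(sum(w * (x - sum(w * x))^2), 1e-12))
    1.06 * sd * ess^(-1 / 5)
  }
  gx <- seq(min(fin$r), max(fin$r), length.out = kde_n)
  gy <- seq(min(fin$rho), max(fin$rho), length.out = kde_n)
  hx <- bw(fin$r); hy <- bw(fin$rho)
  z <- matrix(0, length(gx), length(gy))
  for (i in seq_along(w)) {
    z <- z + w[i] * outer(stats::dnorm(gx, fin$r[i], hx),
                          stats::dnorm(gy, fin$rho[i], hy))
  }
  list(r = summ(fin$r), rho = summ(fin$rho), ess = ess, level = level,
       kde = list(r = gx, rho = gy, density = z))
}
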