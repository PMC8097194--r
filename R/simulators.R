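#' Simulate single-progenitor clones
#'
#' Stochastic simulation of independent clones under the SP model, starting
#' (by default) from a single labelled progenitor cell. With an exponential
#' cell-cycle model this is an exact Gillespie simulation of the
#' continuous-time Markov chain in which each A cell divides at rate
#' \eqn{\lambda} (fates AA, AB, BB with probabilities \eqn{r}, \eqn{1-2r},
#' \eqn{r}) and each B cell stratifies at rate \eqn{\Gamma}. With a gamma
#' cell-cycle model each A cell draws its time-to-division at birth from
#' Gamma(shape, scale = 1/(\eqn{\lambda}·shape)) and events are processed
#' through a scheduled-event queue; B-cell stratification stays exponential.
#'
#' Simulation uses R's random number stream: call `set.seed()` (or pass
#' `seed`) for reproducible samples.
#'
#' @param params An [sp_params()] object.
#' @param timepoints_weeks Strictly increasing non-negative times (weeks) at
#'   which basal clone sizes are recorded (state strictly at that time, no
#'   interpolation).
#' @param n_clones Number of independent clones.
#' @param cell_cycle A [cc_exponential()] or [cc_gamma()] model.
#' @param init Either `"A"` (one progenitor, the default) or `"basal"`
#'   (initial cell is A with probability `rho`, B otherwise).
#' @param components If `TRUE`, also return the progenitor (`nA`) and
#'   differentiating (`nB`) counts.
#' @param seed Optional integer seed applied via `set.seed()`.
#' @return An object of class `clone_sample`: a list with `size` (an
#'   `n_clones` x `length(timepoints_weeks)` integer matrix of basal sizes
#'   \eqn{n = n_A + n_B}), `timepoints_weeks`, and if requested `nA`, `nB`.
#' @examples
#' p <- sp_params(2.9, 0.06, 0.5)
#' s <- simulate_clones(p, days_to_weeks(c(3, 10)), n_clones = 100, seed = 1)
#' dim(s$size)
#' @export
simulate_clones <- function(params, timepoints_weeks, n_clones,
                            cell_cycle = cc_exponential(), init = c("A", "basal"),
                            components = FALSE, seed = NULL) {
  params <- validate_parameters(params)
  timepoints_weeks <- check_time_grid(timepoints_weeks)
  init <- match.arg(init)
  if (!inherits(cell_cycle, "cell_cycle"))
    stop("`cell_cycle` must be built with cc_exponential() or cc_gamma()",
         call. = FALSE)
  if (!is.numeric(n_clones) || n_clones < 1)
    stop("`n_clones` must be a positive integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  init_a <- if (init == "A") 1.0 else params$rho
  res <- if (cell_cycle$kind == "exponential") {
    cpp_simulate_markov(as.integer(n_clones), params$lambda, params$r,
                        params$gamma, timepoints_weeks, init_a)
  } else {
    cpp_simulate_nonmarkov(as.integer(n_clones), params$lambda, params$r,
                           params$gamma, cell_cycle$shape, timepoints_weeks,
                           init_a)
  }
  out <- list(size = res$nA + res$nB, timepoints_weeks = timepoints_weeks,
              params = params, cell_cycle = cell_cycle, init = init)
  if (components) { out$nA <- res$nA; out$nB <- res$nB }
  structure(out, class = "clone_sample")
}

#' @export
print.clone_sample <- function(x, ...) {
  cat(sprintf("SP clone sample: %d clones x %d timepoints (%s cell cycle)\n",
              nrow(x$size), ncol(x$size), x$cell_cycle$kind))
  cat("  surviving fraction per timepoint:",
      paste(sprintf("%.3f", colMeans(x$size > 0)), collapse = " "), "\n")
  invisible(x)
}

#' Sample cell-cycle (division) times
#'
#' Draws times-to-division for a single progenitor under a cell-cycle model;
#' the mean is `1/lambda` for either kind and the coefficient of variation is
#' `shape^(-1/2)` for the gamma model.
#'
#' @param n Number of draws.
#' @param lambda Division rate (per week).
#' @param cell_cycle A [cc_exponential()] or [cc_gamma()] model.
#' @return Numeric vector of times (weeks).
#' @export
r_division_time <- function(n, lambda, cell_cycle = cc_exponential()) {
  if (cell_cycle$kind == "exponential") stats::rexp(n, rate = lambda)
  else stats::rgamma(n, shape = cell_cycle$shape,
                     rate = lambda * cell_cycle$shape)
}

#' Empirical clone-size distribution from a simulated sample
#'
#' Normalized histogram over basal clone size at one timepoint, optionally
#' conditioned on clone survival (size >= 1).
#'
#' @param sample A `clone_sample` from [simulate_clones()], or an integer
#'   vector of sizes for a single timepoint.
#' @param timepoint_index Column of the sample to use (ignored for vectors).
#' @param n_max Largest size carried in the PMF; defaults to the sample
#'   maximum. Sizes above `n_max` are tallied as tail mass, never silently
#'   dropped.
#' @param condition_on_survival If `TRUE`, restrict to sizes >= 1 and
#'   renormalize.
#' @return A `clone_size_pmf` object (see [clone_size_pmf_analytic()]).
#' @export
empirical_pmf <- function(sample, timepoint_index = 1, n_max = NULL,
                          condition_on_survival = FALSE) {
  if (inherits(sample, "clone_sample")) {
    sizes <- sample$size[, timepoint_index]
    t_w <- sample$timepoints_weeks[timepoint_index]
  } else {
    sizes <- as.integer(sample)
    t_w <- NA_real_
  }
  if (!length(sizes)) stop("empty sample", call. = FALSE)
  if (is.null(n_max)) n_max <- max(sizes)
  n_max <- max(1L, as.integer(n_max))
  counts <- tabulate(pmin(sizes, n_max + 1L) + 1L, nbins = n_max + 2L)
  tail_mass <- counts[n_max + 2L] / length(sizes)
  p <- counts[seq_len(n_max + 1L)] / length(sizes)
  pmf <- new_clone_size_pmf(p, t_w, conditioned = FALSE, tail_mass = tail_mass,
                            source = "empirical")
  if (condition_on_survival) pmf <- condition_on_survival(pmf)
  pmf
}
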