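# Exact clone-size probabilities P_n(t) for the Markovian SP model.
#
# Route 1 (clone_size_pmf_analytic): the probability generating function
# F(z, t) = E[z^(nA+nB)] of a clone started from one progenitor solves the
# backward Kolmogorov equation
#     dF/dt = lambda * ( r F^2 + (1-2r) F G + r G^2 - F ),
#     G(t)  = 1 + (z - 1) exp(-Gamma t)
# (G is the closed-form generating function of the pure-death B lineage).
# F is evaluated on a circle of radius sigma < 1 in the complex plane at
# 2*n_max points and the coefficients P_n recovered by discrete Fourier
# transform; the slight deflation (sigma < 1) damps aliasing of mass beyond
# the truncation. This is the exact branching-process solution evaluated by
# high-accuracy quadrature.
#
# Route 2 (clone_size_pmf_master): direct integration of the truncated
# master equation on the (nA, nB) lattice, used as the independent oracle.

new_clone_size_pmf <- function(p, t_weeks, conditioned, tail_mass,
                               source, leakage = NA_real_) {
  structure(list(p = p, n = seq_along(p) - if (conditioned) 0L else 1L,
                 time_weeks = t_weeks, conditioned = conditioned,
                 n_max = length(p) - if (conditioned) 0L else 1L,
                 tail_mass = tail_mass, source = source, leakage = leakage),
            class = "clone_size_pmf")
}

#' @export
print.clone_size_pmf <- function(x, ...) {
  cat(sprintf("Clone-size PMF (%s) at t = %.3g weeks (%.4g days)\n",
              x$source, x$time_weeks, weeks_to_days(x$time_weeks)))
  cat(sprintf("  support n = %d..%d%s, tail mass %.3g\n", min(x$n), max(x$n),
              if (x$conditioned) " (conditioned on survival)" else "",
              x$tail_mass))
  invisible(x)
}

#' Mean of a clone-size PMF
#' @param pmf A `clone_size_pmf`.
#' @return The mean basal clone size (over the carried support).
#' @export
pmf_mean <- function(pmf) sum(pmf$n * pmf$p) / sum(pmf$p)

#' Exact clone-size distribution via the generating function
#'
#' Computes \eqn{P_n(t)}, the probability that a clone founded by a single
#' progenitor contains \eqn{n = n_A + n_B} basal cells at time \eqn{t},
#' under the Markovian (exponential cell-cycle) SP model. The probability
#' generating function is integrated along time with `deSolve::zvode`
#' (non-stiff Adams, functional iteration) at points on a complex circle and
#' inverted by FFT.
#'
#' @param params An [sp_params()] object.
#' @param t_weeks Non-negative times (weeks); may be unsorted.
#' @param n_max Largest clone size returned (support 0..`n_max`).
#' @param rtol,atol Solver tolerances.
#' @param deflation Aliasing suppression factor: the evaluation radius is
#'   `deflation^(1/(2*n_max))`; coefficients beyond the truncation are damped
#'   by `deflation`.
#' @return A list of `clone_size_pmf` objects, one per time (a single object
#'   if `length(t_weeks) == 1`).
#' @examples
#' p <- sp_params(2.9, 0.06, 0.5)
#' pmf <- clone_size_pmf_analytic(p, days_to_weeks(10), n_max = 64)
#' sum(pmf$p)
#' @export
clone_size_pmf_analytic <- function(params, t_weeks, n_max = 128,
                                    rtol = 1e-10, atol = 1e-12,
                                    deflation = 1e-8) {
  params <- validate_parameters(params)
  if (any(t_weeks < 0)) stop("times must be non-negative", call. = FALSE)
  n_max <- as.integer(n_max)
  N <- 2L * n_max
  sig <- deflation^(1 / N)
  z <- sig * exp(2i * pi * (seq_len(N) - 1) / N)
  ord <- order(t_weeks)
  ts <- t_weeks[ord]
  pos <- ts[ts > 0]
  Fmat <- matrix(NA_complex_, nrow = length(ts), ncol = N)
  if (length(pos)) {
    lambda <- params$lambda; r <- params$r; gam <- params$gamma
    rhs <- function(t, Fv, parms) {
      G <- 1 + (z - 1) * exp(-gam * t)
      list(lambda * (r * Fv^2 + (1 - 2 * r) * Fv * G + r * G^2 - Fv))
    }
    sol <- tryCatch(
      deSolve::zvode(y = z, times = c(0, unique(pos)), func = rhs,
                     parms = NULL, rtol = rtol, atol = atol, mf = 10),
      error = function(e) e, warning = function(w) w)
    if (inherits(sol, "condition") ||
        anyNA(Re(unclass(sol)[-1, -1, drop = FALSE])))
      stop(sprintf(paste0("generating-function integration failed for ",
                          "(r = %g, rho = %g, t = %g weeks): %s"),
                   params$r, params$rho, max(pos),
                   if (inherits(sol, "condition")) conditionMessage(sol)
                   else "non-finite solution"), call. = FALSE)
    upos <- unique(pos)
    for (i in seq_along(ts)) {
      if (ts[i] > 0) Fmat[i, ] <- sol[match(ts[i], upos) + 1L, -1]
    }
  }
  damp <- sig^(0:n_max)
  out <- vector("list", length(ts))
  for (i in seq_along(ts)) {
    if (ts[i] == 0) {
      p <- c(0, 1, numeric(n_max - 1L))
    } else {
      coef <- Re(stats::fft(Fmat[i, ])) / N
      p <- coef[seq_len(n_max + 1L)] / damp
      if (min(p) < -1e-6)
        stop(sprintf(paste0("coefficient extraction lost precision for ",
                            "(r = %g, rho = %g, t = %g weeks): min P_n = %g"),
                     params$r, params$rho, ts[i], min(p)), call. = FALSE)
      p <- pmax(p, 0)
    }
    out[[i]] <- new_clone_size_pmf(p, ts[i], conditioned = FALSE,
                                   tail_mass = max(0, 1 - sum(p)),
                                   source = "analytic")
  }
  out <- out[order(ord)]  # restore caller's time order
  if (length(out) == 1L) out[[1L]] else out
}

#' Clone-size distribution by truncated master-equation integration
#'
#' Integrates the linear master equation for the joint law
#' \eqn{P_{n_A,n_B}(t)} on the lattice \eqn{0..A_{max} \times 0..B_{max}}
#' from a single progenitor, then marginalizes to basal size
#' \eqn{n = n_A + n_B}. Probability flux across the truncation boundary is
#' measured as leakage; the call fails if it exceeds `leakage_tol`, with
#' instructions to enlarge the caps. Serves as the independent oracle for
#' [clone_size_pmf_analytic()].
#'
#' @param params An [sp_params()] object.
#' @param t_weeks Strictly increasing non-negative times (weeks).
#' @param caps Integer vector `c(A_max, B_max)` truncating the lattice.
#' @param n_max Largest basal size in the returned PMF (default
#'   `sum(caps)`).
#' @param leakage_tol Maximum tolerated probability loss through the
#'   boundary.
#' @param joint If `TRUE`, attach the joint `(n_A, n_B)` matrix as attribute
#'   `"joint"` of each PMF.
#' @return A list of `clone_size_pmf` objects (single object for one time);
#'   each carries its `leakage`.
#' @export
clone_size_pmf_master <- function(params, t_weeks, caps = c(60, 80),
                                  n_max = NULL, leakage_tol = 1e-8,
                                  joint = FALSE) {
  params <- validate_parameters(params)
  t_weeks <- check_time_grid(t_weeks)
  caps <- as.integer(caps)
  if (length(caps) != 2 || any(caps < 1))
    stop("`caps` must be c(A_max, B_max), both >= 1", call. = FALSE)
  if (is.null(n_max)) n_max <- sum(caps)
  res <- cpp_master_joint(params$lambda, params$r, params$gamma, t_weeks,
                          caps[1], caps[2])
  out <- vector("list", length(t_weeks))
  for (i in seq_along(t_weeks)) {
    J <- res[[i]]
    leak <- 1 - sum(J)
    if (leak > leakage_tol)
      stop(sprintf(paste0("master-equation leakage %.3g exceeds %.3g at ",
                          "t = %g weeks; increase caps above (%d, %d)"),
                   leak, leakage_tol, t_weeks[i], caps[1], caps[2]),
           call. = FALSE)
    # marginalize to n = nA + nB along anti-diagonals
    p <- numeric(n_max + 1L)
    for (a in 0:caps[1]) {
      b_idx <- 0:min(caps[2], n_max - a)
      if (a <= n_max)
        p[a + b_idx + 1L] <- p[a + b_idx + 1L] + J[a + 1L, b_idx + 1L]
    }
    pmf <- new_clone_size_pmf(p, t_weeks[i], conditioned = FALSE,
                              tail_mass = max(0, 1 - sum(p)),
                              source = "master", leakage = leak)
    if (joint) attr(pmf, "joint") <- J
    out[[i]] <- pmf
  }
  if (length(out) == 1L) out[[1L]] else out
}

#' Condition a clone-size PMF on survival
#'
#' Lineage tracing scores persisting clones, so observed clone-size counts
#' are draws from the distribution conditioned on \eqn{n \ge 1}. Removes the
#' extinct class and renormalizes. Idempotent.
#'
#' @param pmf A `clone_size_pmf`.
#' @return The conditioned `clone_size_pmf` (support starts at n = 1).
#' @export
condition_on_survival <- function(pmf) {
  stopifnot(inherits(pmf, "clone_size_pmf"))
  if (pmf$conditioned) return(pmf)
  surv <- sum(pmf$p[-1]) + pmf$tail_mass
  if (surv <= 0)
    stop("cannot condition on survival: all probability mass is on n = 0",
         call. = FALSE)
  new_clone_size_pmf(pmf$p[-1] / surv, pmf$time_weeks, conditioned = TRUE,
                     tail_mass = pmf$tail_mass / surv, source = pmf$source,
                     leakage = pmf$leakage)
}

#' Write / read clone-size PMFs as CSV
#'
#' Columns: `time_days`, `n`, `probability`, `conditioned`.
#'
#' @param pmfs A `clone_size_pmf` or list of them.
#' @param path Output CSV path.
#' @return `write_pmf_csv` returns `path` invisibly; `read_pmf_csv` returns
#'   a data.frame.
#' @export
write_pmf_csv <- function(pmfs, path) {
  if (inherits(pmfs, "clone_size_pmf")) pmfs <- list(pmfs)
  rows <- do.call(rbind, lapply(pmfs, function(x)
    data.frame(time_days = weeks_to_days(x$time_weeks), n = x$n,
               probability = x$p, conditioned = x$conditioned)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pmf_csv
#' @export
read_pmf_csv <- function(path) utils::read.csv(path)
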