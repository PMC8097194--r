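#' Stratification rate under homeostasis
#'
#' In the single-progenitor (SP) model the basal layer contains a fraction
#' \eqn{\rho} of progenitor (A) cells dividing at rate \eqn{\lambda} and a
#' fraction \eqn{1-\rho} of differentiating (B) cells leaving the basal layer
#' at rate \eqn{\Gamma}. Homeostasis (constant basal cell number) fixes
#' \deqn{\Gamma = \frac{\rho}{1-\rho}\,\lambda.}
#'
#' @param rho Progenitor fraction, in (0, 1).
#' @param lambda Division rate (per week), positive.
#' @return The stratification rate \eqn{\Gamma} (per week).
#' @examples
#' stratification_rate(0.5, 2.0)  # 2.0
#' @export
stratification_rate <- function(rho, lambda) {
  if (!is.numeric(rho) || anyNA(rho) || any(rho <= 0) || any(rho >= 1))
    stop("`rho` must lie strictly in (0, 1); Gamma diverges as rho -> 1",
         call. = FALSE)
  if (!is.numeric(lambda) || anyNA(lambda) || any(lambda <= 0))
    stop("`lambda` must be a positive division rate", call. = FALSE)
  rho / (1 - rho) * lambda
}

#' Single-progenitor model parameters
#'
#' Bundles the SP model parameters: division rate \eqn{\lambda} (per week),
#' symmetric-division probability \eqn{r} (division fates AA/AB/BB with
#' probabilities \eqn{r}, \eqn{1-2r}, \eqn{r}), progenitor fraction
#' \eqn{\rho}, and the derived stratification rate
#' \eqn{\Gamma = \rho\lambda/(1-\rho)}. The suprabasal shedding rate
#' \eqn{\mu} is carried for completeness but plays no role in basal clone
#' sizes and defaults to unset.
#'
#' @param lambda Division rate, per week; positive.
#' @param r Symmetric-division probability, in (0, 0.5].
#' @param rho Progenitor fraction, in (0, 1).
#' @param mu Optional suprabasal shedding rate (per week), non-negative.
#' @return An object of class `sp_params` with elements `lambda`, `r`,
#'   `rho`, `gamma` (the stratification rate) and `mu`.
#' @examples
#' sp_params(lambda = 2.9, r = 0.06, rho = 0.5)
#' @export
sp_params <- function(lambda, r, rho, mu = NA_real_) {
  p <- structure(
    list(lambda = as.numeric(lambda), r = as.numeric(r),
         rho = as.numeric(rho), gamma = NA_real_, mu = as.numeric(mu)),
    class = "sp_params")
  validate_parameters(p)
}

#' Validate SP parameters and derive the stratification rate
#'
#' Checks every bound individually (\eqn{\lambda > 0}, \eqn{0 < r \le 0.5},
#' \eqn{0 < \rho < 1}, \eqn{\mu \ge 0} if set) and recomputes
#' \eqn{\Gamma = \rho\lambda/(1-\rho)} when absent.
#'
#' @param p An `sp_params` object (or a bare list with the same fields).
#' @return The validated `sp_params` with `gamma` filled in.
#' @export
validate_parameters <- function(p) {
  problems <- character()
  if (!is.numeric(p$lambda) || is.na(p$lambda) || p$lambda <= 0)
    problems <- c(problems, "lambda must be > 0 (per week)")
  if (!is.numeric(p$r) || is.na(p$r) || p$r <= 0 || p$r > 0.5)
    problems <- c(problems, "r must lie in (0, 0.5]")
  if (!is.numeric(p$rho) || is.na(p$rho) || p$rho <= 0 || p$rho >= 1)
    problems <- c(problems, "rho must lie in (0, 1)")
  if (!is.na(p$mu) && p$mu < 0)
    problems <- c(problems, "mu must be >= 0")
  if (length(problems))
    stop("invalid SP parameters: ", paste(problems, collapse = "; "),
         call. = FALSE)
  if (is.null(p$gamma) || is.na(p$gamma))
    p$gamma <- stratification_rate(p$rho, p$lambda)
  class(p) <- "sp_params"
  p
}

#' @export
print.sp_params <- function(x, ...) {
  cat("Single-progenitor model parameters\n")
  cat(sprintf("  lambda (division rate)      : %.4g /week\n", x$lambda))
  cat(sprintf("  r (symmetric division prob) : %.4g\n", x$r))
  cat(sprintf("  rho (progenitor fraction)   : %.4g\n", x$rho))
  cat(sprintf("  Gamma (stratification rate) : %.4g /week [derived]\n",
              x$gamma))
  if (!is.na(x$mu)) cat(sprintf("  mu (shedding rate)          : %.4g /week\n", x$mu))
  invisible(x)
}

#' Cell-cycle time models
#'
#' The Markovian SP model assumes exponentially distributed cell-cycle
#' (division) times. Live-imaging and histone-dilution data show a
#' refractory period after division, captured by a gamma-distributed cycle
#' time. `cc_gamma(shape)` fixes the scale to `1/(lambda*shape)` at
#' simulation time so the mean cycle time is always `1/lambda`.
#'
#' @param shape Gamma shape parameter, positive. Larger values give more
#'   regular (lower-CV) cycle times; `shape = 1` recovers the exponential.
#' @return An object of class `cell_cycle`.
#' @examples
#' cc_exponential()
#' cc_gamma(shape = 8)
#' @export
cc_exponential <- function() {
  structure(list(kind = "exponential", shape = 1), class = "cell_cycle")
}

#' @rdname cc_exponential
#' @export
cc_gamma <- function(shape) {
  if (!is.numeric(shape) || length(shape) != 1 || is.na(shape) || shape <= 0)
    stop("gamma cell-cycle model requires a positive `shape`", call. = FALSE)
  structure(list(kind = "gamma", shape = as.numeric(shape)),
            class = "cell_cycle")
}

#' @export
print.cell_cycle <- function(x, ...) {
  if (x$kind == "exponential") cat("Cell cycle: exponential (Markovian)\n")
  else cat(sprintf("Cell cycle: gamma, shape = %.4g (CV = %.3f)\n",
                   x$shape, 1 / sqrt(x$shape)))
  invisible(x)
}

#' Time-unit conversion
#'
#' Rates are quoted per week throughout; experimental timepoints are quoted
#' in days. Conversion happens once at ingest.
#'
#' @param days,weeks Numeric vectors of times.
#' @return The converted times.
#' @export
days_to_weeks <- function(days) {
  if (any(days < 0, na.rm = TRUE)) stop("times must be non-negative", call. = FALSE)
  days / 7
}

#' @rdname days_to_weeks
#' @export
weeks_to_days <- function(weeks) weeks * 7

#' Standard lineage-tracing timepoints
#'
#' The sacrifice timepoints used throughout: 3, 10, 21, 42, 84, 180 and
#' 365 days post induction.
#' @return Numeric vector of days.
#' @export
standard_timepoints_days <- function() c(3, 10, 21, 42, 84, 180, 365)

# internal: strictly increasing non-negative time grid (weeks)
check_time_grid <- function(t_weeks) {
  if (!length(t_weeks)) stop("empty time grid", call. = FALSE)
  if (any(t_weeks < 0)) stop("times must be non-negative", call. = FALSE)
  if (is.unsorted(t_weeks, strictly = TRUE))
    stop("timepoints must be strictly increasing", call. = FALSE)
  as.numeric(t_weeks)
}
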