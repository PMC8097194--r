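# Synthetic lineage-tracing cohort generator.
#
# Emulates a sacrifice design: each synthetic mouse is assigned one
# timepoint, receives its own (lambda, r, rho) drawn from normal
# distributions truncated (by rejection) to the valid domain, and
# contributes the surviving clones of an independent simulation run. The
# per-mouse ground truth is kept in a separate ledger that never enters the
# observation table.

#' Cohort design
#'
#' Defaults reproduce the published synthetic-cohort protocol: 7 sacrifice
#' timepoints (3, 10, 21, 42, 84, 180, 365 days), 3 mice per timepoint
#' (21 mice), 10 000 simulated clones per mouse of which 100 surviving
#' clones are observed, and per-mouse parameters drawn from normal
#' distributions with means \eqn{\lambda = 2.9}/week, \eqn{r = 0.09},
#' \eqn{\rho = 0.7} and s.d. 0.1, 0.01, 0.05.
#'
#' @param timepoints_days Sacrifice timepoints in days.
#' @param mice_per_timepoint Mice sacrificed at each timepoint.
#' @param clones_per_mouse Surviving clones recorded per mouse
#'   (`Inf` keeps all survivors).
#' @param simulated_clones_per_mouse Clones simulated per mouse.
#' @param lambda_mean,lambda_sd,r_mean,r_sd,rho_mean,rho_sd Normal
#'   parameter distributions; zero s.d. gives every mouse the mean exactly.
#' @param cell_cycle A [cc_exponential()] or [cc_gamma()] model.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(timepoints_days = standard_timepoints_days(),
                          mice_per_timepoint = 3, clones_per_mouse = 100,
                          simulated_clones_per_mouse = 10000,
                          lambda_mean = 2.9, lambda_sd = 0.1,
                          r_mean = 0.09, r_sd = 0.01,
                          rho_mean = 0.7, rho_sd = 0.05,
                          cell_cycle = cc_exponential()) {
  if (is.unsorted(timepoints_days, strictly = TRUE) || any(timepoints_days < 0))
    stop("timepoints_days must be strictly increasing and non-negative",
         call. = FALSE)
  # means must themselves be valid SP parameters
  validate_parameters(list(lambda = lambda_mean, r = r_mean, rho = rho_mean,
                           mu = NA_real_))
  structure(list(timepoints_days = timepoints_days,
                 mice_per_timepoint = mice_per_timepoint,
                 clones_per_mouse = clones_per_mouse,
                 simulated_clones_per_mouse = simulated_clones_per_mouse,
                 lambda_mean = lambda_mean, lambda_sd = lambda_sd,
                 r_mean = r_mean, r_sd = r_sd,
                 rho_mean = rho_mean, rho_sd = rho_sd,
                 cell_cycle = cell_cycle),
            class = "cohort_design")
}

#' Draw per-mouse SP parameters
#'
#' Independent normal draws for \eqn{\lambda}, \eqn{r}, \eqn{\rho},
#' rejection-resampled until all fall in the valid domain
#' (\eqn{\lambda > 0}, \eqn{0 < r \le 0.5}, \eqn{0 < \rho < 1}); the
#' stratification rate is derived. Errors out if fewer than 1% of draws are
#' valid.
#'
#' @param design A [cohort_design()].
#' @return An [sp_params()] object.
#' @export
draw_mouse_parameters <- function(design) {
  for (attempt in seq_len(100)) {
    lambda <- stats::rnorm(1, design$lambda_mean, design$lambda_sd)
    r <- stats::rnorm(1, design$r_mean, design$r_sd)
    rho <- stats::rnorm(1, design$rho_mean, design$rho_sd)
    if (lambda > 0 && r > 0 && r <= 0.5 && rho > 0 && rho < 1)
      return(sp_params(lambda, r, rho))
  }
  stop(paste0("parameter rejection rate above 99%: the normal s.d.s are ",
              "too large for the valid SP domain"), call. = FALSE)
}

#' Generate a synthetic lineage-tracing cohort
#'
#' For each (timepoint, mouse) slot: draws that mouse's parameters,
#' simulates `simulated_clones_per_mouse` clones to the mouse's sacrifice
#' time, keeps the surviving clones (basal size >= 1), and subsamples
#' `clones_per_mouse` of them without replacement into the observation
#' table (all survivors if fewer, with a warning). Ground truth (drawn
#' parameters per mouse) is recorded separately.
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed; identical design + seed reproduce the cohort.
#' @return A `synthetic_cohort`: list with `observations` (a
#'   [clone_dataset()]), `truth` (data.frame mouse_id, time_days, lambda,
#'   r, rho, n_simulated, n_surviving, n_observed), `design`, `seed`.
#' @export
generate_cohort <- function(design, seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  if (!is.null(seed)) set.seed(seed)
  obs <- list(); truth <- list(); m <- 0L
  for (td in design$timepoints_days) {
    for (k in seq_len(design$mice_per_timepoint)) {
      m <- m + 1L
      id <- sprintf("m%02d_d%g", m, td)
      p <- draw_mouse_parameters(design)
      s <- simulate_clones(p, days_to_weeks(td),
                           n_clones = design$simulated_clones_per_mouse,
                           cell_cycle = design$cell_cycle)
      sizes <- s$size[s$size[, 1] >= 1, 1]
      n_surv <- length(sizes)
      n_keep <- min(design$clones_per_mouse, n_surv)
      if (n_surv < design$clones_per_mouse && is.finite(design$clones_per_mouse))
        warning(sprintf("mouse %s: only %d surviving clones (< %g requested)",
                        id, n_surv, design$clones_per_mouse), call. = FALSE)
      if (n_keep < n_surv) sizes <- sample(sizes, n_keep)
      if (n_keep > 0)
        obs[[m]] <- data.frame(mouse_id = id, time_days = td,
                               clone_size = sizes)
      truth[[m]] <- data.frame(mouse_id = id, time_days = td,
                               lambda = p$lambda, r = p$r, rho = p$rho,
                               n_simulated = design$simulated_clones_per_mouse,
                               n_surviving = n_surv, n_observed = n_keep)
    }
  }
  structure(list(observations = clone_dataset(do.call(rbind, obs),
                                              lambda = design$lambda_mean,
                                              cell_cycle = design$cell_cycle),
                 truth = do.call(rbind, truth), design = design, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic lineage-tracing cohort: %d mice, %d ",
                     "timepoints, %d observed clones\n"),
              nrow(x$truth), length(unique(x$truth$time_days)),
              nrow(x$observations)))
  invisible(x)
}

#' Restrict a cohort to a subset of timepoints
#'
#' Without rebalancing, simply drops records outside `keep_days`. With
#' `rebalance = TRUE`, the total mouse budget of the original design is
#' redistributed as evenly as possible across the kept timepoints and the
#' cohort is regenerated from the stored design (fresh mice at the kept
#' timepoints, deterministic given the stored seed), mirroring an
#' experiment that concentrates the same number of animals on fewer
#' sacrifice times.
#'
#' @param cohort A `synthetic_cohort`.
#' @param keep_days Subset of the cohort's timepoints (days).
#' @param rebalance Redistribute the mouse budget over `keep_days`.
#' @return A `synthetic_cohort`.
#' @export
subset_timepoints <- function(cohort, keep_days, rebalance = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!length(keep_days)) stop("empty timepoint subset", call. = FALSE)
  if (!all(keep_days %in% cohort$design$timepoints_days))
    stop("keep_days must be a subset of the cohort's timepoints",
         call. = FALSE)
  keep_days <- sort(keep_days)
  if (!rebalance) {
    obs <- cohort$observations
    obs <- obs[obs$time_days %in% keep_days, , drop = FALSE]
    truth <- cohort$truth[cohort$truth$time_days %in% keep_days, , drop = FALSE]
    out <- cohort
    out$observations <- clone_dataset(obs, lambda = attr(cohort$observations, "lambda"))
    out$truth <- truth
    return(out)
  }
  total_mice <- cohort$design$mice_per_timepoint *
    length(cohort$design$timepoints_days)
  base <- total_mice %/% length(keep_days)
  extra <- total_mice %% length(keep_days)
  counts <- rep(base, length(keep_days)) + c(rep(1, extra),
                                             rep(0, length(keep_days) - extra))
  # regenerate per-timepoint with its own mouse count, deterministic in seed
  sub_seed <- if (is.null(cohort$seed)) NULL else cohort$seed + 1L
  if (!is.null(sub_seed)) set.seed(sub_seed)
  pieces <- lapply(seq_along(keep_days), function(i) {
    d <- cohort$design
    d$timepoints_days <- keep_days[i]
    d$mice_per_timepoint <- counts[i]
    generate_cohort(d, seed = NULL)
  })
  obs <- do.call(rbind, lapply(pieces, function(x) as.data.frame(x$observations)))
  design <- cohort$design
  design$timepoints_days <- keep_days
  structure(list(observations = clone_dataset(obs,
                                              lambda = cohort$design$lambda_mean,
                                              cell_cycle = cohort$design$cell_cycle),
                 truth = do.call(rbind, lapply(pieces, function(x) x$truth)),
                 design = design, seed = sub_seed),
            class = "synthetic_cohort")
}

#' Serialize / read a synthetic cohort
#'
#' Writes two CSVs under `dir`: `observations.csv` (mouse_id, time_days,
#' clone_size) and `truth.csv` (the ground-truth ledger, kept apart from
#' the observation table). `read_cohort` round-trips both.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns a
#'   list with `observations` (a [clone_dataset()]) and `truth`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(cohort$observations),
                   file.path(dir, "observations.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  list(observations = clone_dataset(
         utils::read.csv(file.path(dir, "observations.csv"))),
       truth = utils::read.csv(file.path(dir, "truth.csv")))
}
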