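# Shared fixtures: reference parameter set and small builders used across
# test files. All datasets are generated in code at test time.

ref_params <- function() sp_params(lambda = 2.9, r = 0.06, rho = 0.5)

# gamma cell-cycle shape used throughout the tests (no published value;
# chosen once: a pronounced refractory period, CV ~ 0.35)
test_gamma_shape <- function() 8

# small clone table as a plain data.frame
toy_table <- function() {
  data.frame(mouse_id = c("m1", "m1", "m2"),
             time_days = c(3, 3, 10),
             clone_size = c(1L, 2L, 4L))
}

# large-sample synthetic cohort design: single parameter set (zero s.d.),
# exponential cycles, ~1e5 clones spread over the 7 standard timepoints
large_sample_design <- function(total_clones = 1e5) {
  cohort_design(mice_per_timepoint = 1, clones_per_mouse = Inf,
                simulated_clones_per_mouse = round(total_clones / 7),
                lambda_mean = 2.9, lambda_sd = 0,
                r_mean = 0.06, r_sd = 0,
                rho_mean = 0.5, rho_sd = 0,
                cell_cycle = cc_exponential())
}

# cohort design with gamma cell-cycle times and inter-mouse variation
# (3 mice/timepoint, 100 observed clones/mouse, published normals)
noisy_gamma_design <- function() {
  cohort_design(cell_cycle = cc_gamma(test_gamma_shape()))
}

# master-equation PMF with automatic cap escalation (the package contract
# is an explicit error; tests escalate until leakage passes)
master_pmf_autocaps <- function(params, t_weeks, caps = c(40, 60), ...) {
  for (i in 1:6) {
    out <- tryCatch(clone_size_pmf_master(params, t_weeks, caps = caps, ...),
                    error = function(e) e)
    if (!inherits(out, "error")) return(out)
    if (!grepl("leakage", conditionMessage(out))) stop(out)
    caps <- caps * 2
  }
  stop(out)
}

# total-variation distance between two PMFs on 0..n_max (+ tail classes)
tv_distance <- function(a, b) {
  n <- max(length(a$p), length(b$p))
  pa <- c(a$p, numeric(n - length(a$p)))
  pb <- c(b$p, numeric(n - length(b$p)))
  0.5 * (sum(abs(pa - pb)) + abs(a$tail_mass - b$tail_mass))
}
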