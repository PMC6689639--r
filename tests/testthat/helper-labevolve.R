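# Shared fixtures: all built in code, no files.

# Small, fast parameter set for structural tests.
quick_params <- function(...) {
  defaults <- list(n = 20, d = 4, iterations = 200, record_interval = 20,
                   fdr_window = 100, seed = 1)
  do.call(lab_params, utils::modifyList(defaults, list(...)))
}

# A lab data frame with given trait vectors (defaults zeroed).
make_labs <- function(alpha, funds = 10L, age = 0L, publications = 0L,
                      erroneous = 0L) {
  n <- length(alpha)
  data.frame(id = seq_len(n), alpha = alpha,
             funds = rep_len(as.integer(funds), n),
             age = rep_len(as.integer(age), n),
             publications = rep_len(as.integer(publications), n),
             erroneous_publications = rep_len(as.integer(erroneous), n))
}

# Final recorded community mean false positive rate of one run.
final_alpha <- function(params) {
  rec <- run_simulation(params)$record
  rec$mean_alpha[nrow(rec)]
}

# Equilibrium windowed F of one run.
eq_fdr <- function(params, window = 10000) {
  equilibrium_stats(run_simulation(params), window)$F_eq
}
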