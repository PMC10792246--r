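# shared builders for small simulated worlds

noiseless_config <- function(activities = c(a = 0, b = 50, c = 95),
                             seed = 1, renilla_cv = 0, ...) {
  sim_config(seed = seed,
             constructs = data.frame(name = names(activities),
                                     activity = unname(activities)),
             noise_cv = 0, load_cv = 0, renilla_cv = renilla_cv, ...)
}

noisy_config <- function(activities = c(lof = 20, vus = 65, ben = 95),
                         seed = 1, ...) {
  sim_config(seed = seed,
             constructs = data.frame(name = names(activities),
                                     activity = unname(activities)),
             noise_cv = 0.10, load_cv = 0.15, ...)
}

relative_activities <- function(config, renilla_normalize = FALSE) {
  a <- summarize_activity(process_efflux(simulate_plate(config),
                                         renilla_normalize),
                          vs_wt = FALSE)
  stats::setNames(a$mean_activity, a$construct)
}
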