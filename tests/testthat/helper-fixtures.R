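# shared fixture builders; all deterministic under explicit seeds

sim_events <- function(n, alpha, beta, seed = 1L) {
  withr::with_seed(seed, as_event_times(rgompertz_time(n, alpha, beta),
                                        rep(1L, n)))
}

toy_survival_table <- function() {
  as_survival_table(data.frame(
    genotype = "g", vial = "v1",
    census_day = c(3.5, 7, 10.5),
    deaths = c(1L, 2L, 1L), censored = c(0L, 0L, 1L)))
}

two_genotype_flux <- function(seed = 1L, sigma_well = 2, sigma_batch = 1,
                              sigma_resid = 1, n_wells = 6, n_batches = 2,
                              m_per_phase = 3) {
  simulate_flux_plate(do.call(flux_sim_spec, c(
    default_flux_means(),
    list(sigma_well = sigma_well, sigma_batch = sigma_batch,
         sigma_resid = sigma_resid, n_wells_per_genotype = n_wells,
         n_batches = n_batches, measurements_per_phase = m_per_phase,
         seed = seed))))
}

# brute-force multiple-testing oracles, written from the step-down /
# step-up definitions, independent of stats::p.adjust
holm_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 0
  for (i in seq_len(n)) {
    running <- max(running, (n - i + 1) * p[o[i]])
    adj[o[i]] <- min(running, 1)
  }
  adj
}

bh_brute <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(n)
  running <- Inf
  for (i in seq_len(n)) {
    rank <- n - i + 1
    running <- min(running, n * p[o[i]] / rank)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# hand product-limit estimator on exact (time, status) data
km_brute <- function(time, status) {
  ut <- sort(unique(time[status == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & status == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ut, surv = surv)
}
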