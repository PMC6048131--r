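# Small two-species study used by the inference tests: same structure as
# the default conditions but ~10x smaller populations and mutation rates
# so grids and chain solves stay cheap.
small_study <- function(dfe = gamma_dfe(0.3, 0.01 / 0.3),
                        hs = hs_relationship("additive")) {
  cond <- study_conditions(dfe = dfe, hs = hs)
  out <- cond$species$outcrossing
  out$N_anc <- 2000; out$n_sample <- 12L
  out$theta_syn <- 2000; out$theta_nonsyn <- 4620
  out$L_syn <- out$theta_syn / (4 * out$N_anc * out$mu)
  self <- cond$species$selfing
  self$N_anc <- 1000; self$n_sample <- 8L
  self$theta_syn <- 700; self$theta_nonsyn <- 1617
  self$L_syn <- self$theta_syn / (4 * (self$N_anc / 2) * self$mu)
  cond$species <- list(outcrossing = out, selfing = self)
  cond
}

small_grids <- local({
  g <- NULL
  function() {
    if (is.null(g)) {
      g <<- condition_grids(small_study(), coarse_gamma = 36,
                            coarse_h = 12, fine_gamma = 250, fine_h = 200)
    }
    g
  }
})

small_datasets <- function(seed = 1, dfe = gamma_dfe(0.3, 0.01 / 0.3),
                           hs = hs_relationship("additive"),
                           replicates = 1) {
  cond <- small_study(dfe = dfe, hs = hs)
  sims <- forward_simulate(cond, replicates = replicates, seed = seed)
  lapply(seq_len(replicates), function(r) {
    domdfe:::prepare_replicate_datasets(sims, r, cond, small_grids(),
                                        seed = seed + r)
  })
}
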