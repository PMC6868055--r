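library(kinetoforge)
for (k_on in c(4, 6)) for (mu in c(0.09, 0.19, 1.6)) {
  res <- sapply(c(201, 202, 203), function(s) {
    tr <- run_trajectory(rdna_only_params(mu = mu, k_on = k_on),
                         total_steps = 1250, sample_every = 625,
                         seed = s, burn_in = 3000)
    c(mean(rdna_rg(tr)), 2 * tr$n_active_links / 361)
  })
  cat(sprintf("k_on=%g mu=%.2f: Rg=%s occ=%s\n", k_on, mu,
              paste(round(res[1, ]), collapse = ","),
              paste(round(res[2, ], 2), collapse = ",")))
}
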