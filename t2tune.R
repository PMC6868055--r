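library(kinetoforge)
for (s in c(42, 7)) {
  t0 <- proc.time()
  cfg <- nucleolus_mu_config(images_per_class = 300, seed = s,
                             n_trajectories = 12, burn_in = 4000)
  rep <- run_nucleolus_mu(cfg)
  cat(sprintf("seed %d: val %.3f test %.3f time %.0fs\n", s,
              rep$validation_accuracy, rep$test_accuracy, (proc.time()-t0)[3]))
}
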