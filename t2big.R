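library(kinetoforge)
t0 <- proc.time()
cfg <- nucleolus_mu_config(images_per_class = 600, seed = 42,
                           n_trajectories = 12)
rep <- run_nucleolus_mu(cfg)
cat(sprintf("600/class seed42: val %.3f test %.3f time %.0fs\n",
            rep$validation_accuracy, rep$test_accuracy, (proc.time()-t0)[3]))
print(rep$confusion)
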