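library(kinetoforge)
cfg <- nucleolus_mu_config(images_per_class = 300, seed = 42)
rep <- run_nucleolus_mu(cfg)
cat(sprintf("t2 300/class 16traj seed42: val %.4f test %.4f\n",
            rep$validation_accuracy, rep$test_accuracy))
print(rep$confusion)
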