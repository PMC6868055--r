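library(kinetoforge)
scan <- function(tag, capt, xk) {
  for (mu in c(0.09, 0.19, 1.6)) {
    res <- sapply(c(301, 302, 303, 304), function(s) {
      tr <- run_trajectory(rdna_only_params(mu = mu, capture_radius = capt,
                                            crosslink_spring = xk),
                           total_steps = 1250, sample_every = 625,
                           seed = s, burn_in = 3000)
      round(mean(rdna_rg(tr)))
    })
    cat(sprintf("%s mu=%.2f: Rg=%s\n", tag, mu, paste(res, collapse=" ")))
  }
}
scan("capt200 xk0.1", 200, 0.1)
scan("capt150 xk0.2", 150, 0.2)
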