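# Shared fixtures, all generated in code.

# A [y, x, channel] image with Gaussian spots; spots is a data frame with
# columns row, col (1-based centres), sigma, amp, channel.
make_spot_image <- function(size = 50L, spots, baseline = 0,
                            noise_sd = 0, seed = 1L) {
  withr::with_seed(seed, {
    img <- array(baseline, c(size, size, 3L))
    rr <- matrix(seq_len(size), size, size)
    cc <- t(rr)
    for (i in seq_len(nrow(spots))) {
      s <- spots[i, ]
      img[, , s$channel] <- img[, , s$channel] +
        s$amp * exp(-((rr - s$row)^2 + (cc - s$col)^2) / (2 * s$sigma^2))
    }
    if (noise_sd > 0) img <- img + array(rnorm(length(img), sd = noise_sd),
                                         dim(img))
    img
  })
}

# A standard two-kinetochore / two-SPB test image (red = SPB channel 1,
# green = kinetochore channel 2).
make_kinet_image <- function(size = 50L, noise_sd = 50, seed = 1L,
                             k_sigma = 1.6) {
  spots <- data.frame(
    row = c(25, 25, 25, 25),
    col = c(14, 36, 19, 31),
    sigma = c(1.3, 1.3, k_sigma, k_sigma),
    amp = c(20000, 20000, 15000, 15000),
    channel = c(1L, 1L, 2L, 2L)
  )
  make_spot_image(size, spots, baseline = 500, noise_sd = noise_sd,
                  seed = seed)
}

# Small rendered stack fixture: a few fluorophores in both channels.
make_test_stack <- function(seed = 1L) {
  fl <- fluorophore_set(
    x = c(-400, 400, -700, 700), y = c(0, 0, 50, -50), z = c(0, 0, 0, 0),
    channel = c("green", "green", "red", "red")
  )
  render_stack(fl, optics_params())
}

# Feature table with planted informative columns: features 1 and 2 carry
# the class signal, the rest are standard normal noise.
make_planted_features <- function(n_per_class = 200L, shift = 3,
                                  seed = 1L) {
  withr::with_seed(seed, {
    n <- 2L * n_per_class
    cls <- rep(c("a", "b"), each = n_per_class)
    sgn <- ifelse(cls == "a", -1, 1)
    x <- matrix(rnorm(n * 13L), n, 13L,
                dimnames = list(NULL, paste0("f", 1:13)))
    x[, 1L] <- x[, 1L] + sgn * shift
    x[, 2L] <- x[, 2L] + sgn * shift
    list(x = x, labels = cls)
  })
}

# FWHM of a sampled profile via a Gaussian (log-parabola) fit around the
# peak; less biased than linear interpolation on coarse samples.
measure_fwhm_profile <- function(prof) {
  pk <- which.max(prof)
  ix <- max(1, pk - 2):min(length(prof), pk + 2)
  fit <- lm(log(prof[ix]) ~ poly(ix, 2, raw = TRUE))
  a2 <- coef(fit)[3]
  sigma <- sqrt(-1 / (2 * a2))
  2 * sqrt(2 * log(2)) * sigma
}
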