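test_that("Gaussian PSF widths follow the widefield formulas", {
  op <- optics_params()
  s_g <- psf_sigma(op, "green")
  expect_equal(unname(s_g["sigma_xy"]), 0.21 * 510 / 1.4)
  expect_equal(unname(s_g["sigma_z"]), 0.66 * 510 * 1.515 / 1.4^2)
  s_r <- psf_sigma(op, "red")
  expect_equal(unname(s_r["sigma_xy"] / s_g["sigma_xy"]), 580 / 510)
  op2 <- optics_params(numerical_aperture = 2.8)
  expect_equal(unname(psf_sigma(op2, "green")["sigma_xy"]),
               unname(s_g["sigma_xy"]) / 2)
  expect_error(psf_sigma(op, "blue"), "unknown channel")
  expect_error(optics_params(n_zplanes = 6), "odd")
})

test_that("a centred fluorophore renders a symmetric central focus", {
  fl <- fluorophore_set(32.5, 32.5, 0, "green")  # centre of a pixel
  op <- optics_params()
  st <- render_stack(fl, op)
  expect_equal(dim(st), c(50, 50, 7, 2))
  peak <- which(st == max(st), arr.ind = TRUE)
  expect_equal(unname(peak[1, 1:3]), c(26, 26, 4))
  central <- st[, , 4, "green"]
  expect_equal(central, t(central))
  expect_equal(sum(st[, , , "red"]), 0)
})

test_that("per-plane photon mass matches the analytic Gaussian weight", {
  fl <- fluorophore_set(0, 0, 120, "green")
  op <- optics_params()
  st <- render_stack(fl, op)
  sz <- unname(psf_sigma(op, "green")["sigma_z"])
  zc <- (1:7 - 4) * op$z_step
  expected <- op$photons_per_fluorophore * dnorm(zc, 120, sz) * op$z_step
  got <- apply(st[, , , "green"], 3, sum)
  expect_equal(unname(got), expected, tolerance = 0.01)
})

test_that("rendering is linear and resolves well-separated fluorophores", {
  op <- optics_params()
  a <- fluorophore_set(-500, 0, 0, "green")
  b <- fluorophore_set(500, 0, 0, "green")
  ab <- combine_fluorophores(a, b)
  expect_equal(unclass(render_stack(ab, op)),
               unclass(render_stack(a, op)) + unclass(render_stack(b, op)))
  img <- render_stack(ab, op)[, , 4, "green"]
  top2 <- sort(as.numeric(img), decreasing = TRUE)[1:2]
  expect_lt(abs(diff(top2)) / top2[1], 0.01)
  # empty set renders a valid all-zero stack
  expect_equal(sum(render_stack(fluorophore_set(), op)), 0)
})

test_that("rendered in-focus FWHM matches the PSF width", {
  op <- optics_params()
  fl <- fluorophore_set(32.5, 32.5, 0, "green")
  img <- render_stack(fl, op)[, , 4, "green"]
  fwhm <- measure_fwhm_profile(img[, 26])
  expected <- 2 * sqrt(2 * log(2)) * psf_sigma(op, "green")["sigma_xy"] /
    op$pixel_size
  expect_equal(unname(fwhm), unname(expected), tolerance = 0.05)
})

test_that("translating fluorophores by one pixel translates the image", {
  op <- optics_params()
  f0 <- fluorophore_set(0, 0, 0, "green")
  f1 <- fluorophore_set(op$pixel_size, 0, 0, "green")
  i0 <- render_stack(f0, op)[, , 4, "green"]
  i1 <- render_stack(f1, op)[, , 4, "green"]
  expect_equal(i1[5:45, 5:45], i0[5:45, 4:44], tolerance = 1e-10)
})

test_that("camera noise model behaves as configured", {
  op <- optics_params()
  st <- render_stack(fluorophore_set(0, 0, 0, "green"), op)
  clean <- add_noise(st, noise_params(read_noise_sd = 0, baseline = 100,
                                      apply_shot_noise = FALSE), seed = 1)
  expect_equal(unclass(clean), unclass(st) + 100)

  flat <- st
  flat[] <- 10000
  noisy <- add_noise(flat, noise_params(read_noise_sd = 0, baseline = 0),
                     seed = 2)
  v <- as.numeric(noisy)
  expect_lt(abs(mean(v) - 10000), 3 * sqrt(10000 / length(v)) * 100)
  expect_lt(abs(var(v) / mean(v) - 1), 0.1)

  n1 <- add_noise(st, noise_params(), seed = 7)
  n2 <- add_noise(st, noise_params(), seed = 7)
  expect_identical(n1, n2)
})

test_that("stacks round-trip through TIFF with 16-bit fidelity", {
  st <- add_noise(make_test_stack(), noise_params(), seed = 3)
  path <- file.path(tempdir(), "stack.tiff")
  write_stack(st, path)
  expect_true(file.exists(paste0(path, ".json")))
  pages <- tiff::readTIFF(path, all = TRUE)
  expect_length(pages, 14L)
  back <- read_stack(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  q_orig <- round(as.vector(unclass(st)) / meta$scale)
  q_back <- round(as.vector(unclass(back)) / meta$scale)
  expect_identical(q_orig, q_back)
  expect_equal(dimnames(back)[[4]], c("green", "red"))

  file.remove(paste0(path, ".json"))
  expect_warning(read_stack(path), "sidecar")
})
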