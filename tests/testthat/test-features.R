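test_that("foci detection recovers synthetic spot centres to subpixel", {
  img <- make_kinet_image(noise_sd = 750, seed = 3)  # SNR about 20
  spb <- detect_foci(img[, , 1], 2L)
  expect_false(is_flagged(spb))
  expect_equal(spb$col, c(13, 35))  # 0-based brightest pixels
  expect_lt(max(abs(spb$sub_row - 24)), 0.25)
  expect_lt(max(abs(spb$sub_col - c(13, 35))), 0.25)

  kin <- detect_foci(img[, , 2], 2L)
  expect_equal(kin$col, c(18, 30))
})

test_that("images without the expected foci are flagged, not errored", {
  blank <- array(100, c(50, 50, 3))
  expect_true(is_flagged(detect_foci(blank[, , 1], 2L)))
  one_spot <- make_spot_image(
    spots = data.frame(row = 25, col = 25, sigma = 1.5, amp = 10000,
                       channel = 1L))
  expect_true(is_flagged(detect_foci(one_spot[, , 1], 2L)))
  expect_false(is_flagged(detect_foci(one_spot[, , 1], 1L)))
})

test_that("the spindle axis comes from the two SPB foci", {
  f <- data.frame(row = c(25, 25), col = c(10, 40), sub_row = c(25, 25),
                  sub_col = c(10, 40), peak = c(1, 1))
  ax <- spindle_axis(f)
  expect_equal(ax$length, 30)
  expect_equal(ax$axis, c(0, 1))
  f2 <- data.frame(row = c(10, 13), col = c(10, 14))
  expect_equal(spindle_axis(f2)$length, 5)
  expect_equal(abs(spindle_axis(f2[2:1, ])$axis),
               abs(spindle_axis(f2)$axis))
  expect_error(spindle_axis(f[c(1, 1), ]), "degenerate")
})

test_that("spot height measures the perpendicular FWHM", {
  img <- make_spot_image(
    spots = data.frame(row = 25, col = 25, sigma = 2, amp = 10000,
                       channel = 1L))
  focus <- detect_foci(img[, , 1], 1L)
  h <- spot_height(img[, , 1], focus[1, ], c(0, 1))
  expect_equal(h, 2 * sqrt(2 * log(2)) * 2, tolerance = 0.05)
  # amplitude scaling leaves the width unchanged
  h2 <- spot_height(img[, , 1] * 2, focus[1, ], c(0, 1))
  expect_equal(h, h2)
  expect_true(is_flagged(spot_height(array(5, c(50, 50)), focus[1, ],
                                     c(0, 1))))
})

test_that("line scans and region statistics match direct computation", {
  flat <- matrix(100, 50, 50)
  f <- data.frame(row = 24, col = 24, sub_row = 24, sub_col = 24,
                  peak = 100)
  expect_equal(linescan_std(flat, f[1, ], c(0, 1), "parallel"), 0)
  rs <- region_stats(flat, f[1, ])
  expect_equal(unname(rs), c(100, 0))

  withr::with_seed(8, m <- matrix(rpois(2500, 400), 50, 50))
  block <- m[23:27, 23:27]
  rs2 <- region_stats(m, f[1, ])
  expect_equal(unname(rs2["mean"]), mean(block))
  expect_equal(unname(rs2["std"]), sd(as.numeric(block)))
  # transposing the image swaps the scan directions
  par_t <- linescan_std(t(m), f[1, ], c(0, 1), "parallel")
  perp <- linescan_std(m, f[1, ], c(0, 1), "perpendicular")
  expect_equal(par_t, perp)
  edge <- data.frame(row = 1, col = 1)
  expect_true(is_flagged(region_stats(m, edge[1, ])))
})

test_that("normalized distances follow the pairing geometry", {
  spb <- data.frame(row = c(25, 25), col = c(10, 40))
  ax <- spindle_axis(spb)
  # kinetochore at the spindle midpoint
  k_mid <- data.frame(row = c(25, 25), col = c(25, 25))
  d <- foci_distances(k_mid, spb, ax$axis, ax$length)
  expect_equal(d$distance_to_spb, c(0.5, 0.5))
  # coincident with one SPB
  k_co <- data.frame(row = c(25, 25), col = c(10, 40))
  d2 <- foci_distances(k_co, spb, ax$axis, ax$length)
  expect_equal(d2$distance_to_spb, c(0, 0))
  expect_equal(d2$x_distance, c(0, 0))
  expect_equal(d2$kk_distance, 1)
  # purely perpendicular displacement has zero parallel component
  k_perp <- data.frame(row = c(31, 19), col = c(10, 40))
  d3 <- foci_distances(k_perp, spb, ax$axis, ax$length)
  expect_equal(d3$x_distance, c(0, 0))
  expect_true(all(d3$distance_to_spb > 0))
})

test_that("feature extraction returns all 13 fields on a valid image", {
  img <- make_kinet_image(noise_sd = 300, seed = 5)
  rec <- extract_features(img)
  expect_false(is_flagged(rec))
  expect_named(rec, feature_names)
  expect_true(all(is.finite(rec)))
  # distances match the construction: SPBs 22 px apart, K 5 px inside
  expect_equal(unname(rec["kinetochore_distance_to_spb"]), 5 / 22,
               tolerance = 0.05)
  expect_equal(unname(rec["kk_distance"]), 12 / 22, tolerance = 0.05)
  # deterministic
  expect_identical(rec, extract_features(img))
})

test_that("images missing an SPB focus are flagged and reported", {
  # only one SPB focus (the younger pole lost in processing), two
  # kinetochore foci
  img <- make_spot_image(spots = data.frame(
    row = c(25, 25, 25), col = c(14, 19, 31), sigma = c(1.3, 1.6, 1.6),
    amp = c(20000, 15000, 15000), channel = c(1L, 2L, 2L)),
    baseline = 500, noise_sd = 300, seed = 6)
  res <- extract_features(img)
  expect_true(is_flagged(res))
  expect_match(res$reason, "SPB")

  tab <- feature_table(list(make_kinet_image(seed = 7), img),
                       labels = c("a", "b"))
  expect_equal(nrow(tab), 1L)
  expect_length(attr(tab, "flagged"), 1L)
})

test_that("distance features are invariant under dihedral orientations", {
  img <- make_kinet_image(noise_sd = 300, seed = 9)
  recs <- lapply(augment_orientations(img), extract_features)
  expect_false(any(vapply(recs, is_flagged, logical(1))))
  base <- recs[[1]]
  inv <- c("kinetochore_distance_to_spb", "kinetochore_x_distance",
           "kk_distance", "spb_mean_intensity",
           "kinetochore_mean_intensity", "spb_height",
           "kinetochore_height")
  for (k in 2:8)
    expect_equal(recs[[k]][inv], base[inv], tolerance = 0.02)
})

test_that("kinetochore height separates wide from narrow foci classes", {
  narrow <- vapply(1:25, function(s)
    extract_features(make_kinet_image(seed = s, k_sigma = 1.4,
                                      noise_sd = 300))["kinetochore_height"],
    numeric(1))
  wide <- vapply(1:25, function(s)
    extract_features(make_kinet_image(seed = 100 + s, k_sigma = 2.2,
                                      noise_sd = 300))["kinetochore_height"],
    numeric(1))
  expect_lt(wilcox.test(narrow, wide, alternative = "less")$p.value, 0.01)
})

test_that("radial displacement raises measured kinetochore focus height", {
  cfg0 <- kinet_radial_config(classes = c(0, 100), images_per_class = 50L,
                              seed = 23L)
  heights <- lapply(c(0, 100), function(r) {
    imgs <- kinetoforge:::simulate_kinet_class(cfg0, r, seed = 29L)
    h <- vapply(imgs, function(im) {
      rec <- extract_features(im)
      if (is_flagged(rec)) NA_real_ else rec[["kinetochore_height"]]
    }, numeric(1))
    h[!is.na(h)]
  })
  expect_gt(length(heights[[1]]), 25)
  expect_lt(wilcox.test(heights[[1]], heights[[2]],
                        alternative = "less")$p.value, 0.01)
})
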