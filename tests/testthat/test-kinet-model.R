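test_that("spindle geometry places plus and minus ends as configured", {
  sp <- spindle_params(n_complexes = 1L, stagger_range = 0,
                       spindle_length = 800)
  geo <- build_spindle(sp, seed = 1)
  expect_equal(nrow(geo), 16L)
  expect_equal(geo$px, rep(0, 16))
  expect_equal(geo$mx, rep(800, 16))
  # plus ends evenly spaced on the 250 nm ring
  expect_equal(sqrt(geo$py^2 + geo$pz^2), rep(125, 16))
  ang <- sort(atan2(geo$pz, geo$py) %% (2 * pi))
  expect_equal(diff(ang), rep(2 * pi / 16, 15))
})

test_that("plus-end stagger is uniform within its half-width", {
  sp <- spindle_params(n_complexes = 1L, n_microtubules = 10000L,
                       stagger_range = 100, spindle_length = 500)
  geo <- build_spindle(sp, seed = 99)
  expect_gt(min(geo$px), -100)
  expect_lt(max(geo$px), 100)
  se <- 100 / sqrt(3) / sqrt(10000)
  expect_lt(abs(mean(geo$px)), 3 * se)
  # minus ends track their plus ends
  expect_equal(geo$mx - geo$px, rep(500, 10000))
})

test_that("full spindle mirrors the second complex through the midplane", {
  sp <- spindle_params(n_complexes = 2L, stagger_range = 0,
                       spindle_length = 350, plus_separation = 800)
  geo <- build_spindle(sp, seed = 1)
  expect_equal(nrow(geo), 32L)
  expect_equal(geo$px[geo$complex == 1], rep(400, 16))
  expect_equal(geo$px[geo$complex == 2], rep(-400, 16))
  expect_equal(geo$mx[geo$complex == 2], rep(-750, 16))
})

test_that("invalid spindle configurations error", {
  expect_error(spindle_params(n_complexes = 3L), "n_complexes")
  expect_error(spindle_params(n_microtubules = 0L), "n_microtubules")
  expect_error(spindle_params(complex_diameter = -1), "complex_diameter")
})

test_that("Nuf2 marks lie within the configured range of the plus end", {
  sp <- spindle_params(n_complexes = 1L, stagger_range = 0)
  geo <- build_spindle(sp, seed = 2)
  fl <- place_nuf2(geo, nuf2_params(length = 50, n_per_mt = 700), seed = 3)
  expect_equal(nrow(fl), 16L * 700L)
  # axial offsets from plus ends (at x = 0) toward minus ends in [0, 50]
  expect_gte(min(fl$x_nm), 0)
  expect_lte(max(fl$x_nm), 50)
  # on the MT surface: radial distance from own MT axis = 12.5 nm
  geo_r <- sqrt(geo$py^2 + geo$pz^2)
  expect_equal(unname(geo_r), rep(125, 16))
  fl0 <- place_nuf2(geo, nuf2_params(length = 0, n_per_mt = 3), seed = 3)
  expect_equal(unique(fl0$x_nm), 0)
  expect_equal(nrow(place_nuf2(geo, nuf2_params(n_per_mt = 0), seed = 1)),
               0L)
})

test_that("SPB placement yields 20 fluorophores per minus end by default", {
  sp <- spindle_params(n_complexes = 1L)
  geo <- build_spindle(sp, seed = 4)
  fl <- place_spb(geo, spc29_params(), seed = 5)
  expect_equal(nrow(fl), 320L)
  expect_true(all(fl$channel == "red"))

  # degenerate spread: all fluorophores of a site coincide at its centre
  fl0 <- place_spb(geo, spc29_params(length = 0, tubule_diameter = 0,
                                     n_tubules = 4L,
                                     n_fluor_per_tubule = 5L), seed = 6)
  pos <- unique(round(cbind(fl0$x_nm, fl0$y_nm, fl0$z_nm), 9))
  expect_equal(nrow(pos), 4L)
  ang <- sort(atan2(pos[, 3], pos[, 2]) %% (2 * pi))
  expect_equal(diff(ang), rep(pi / 2, 3))
})

test_that("kinetochore protein geometry honours displacement and marking", {
  sp <- spindle_params(n_complexes = 1L, stagger_range = 0)
  geo <- build_spindle(sp, seed = 7)

  on_axis <- place_kinetochore_protein(
    geo, kinetochore_protein_params(radial_displacement = 0,
                                    point_marked = 1), seed = 8)
  d_axis <- sqrt((on_axis$y_nm - geo$py)^2 + (on_axis$z_nm - geo$pz)^2)
  expect_equal(unname(d_axis), rep(0, 16))

  off <- place_kinetochore_protein(
    geo, kinetochore_protein_params(radial_displacement = 100,
                                    point_marked = 1), seed = 8)
  d_axis <- sqrt((off$y_nm - geo$py)^2 + (off$z_nm - geo$pz)^2)
  expect_equal(unname(d_axis), rep(100, 16))

  at_plus <- place_kinetochore_protein(
    geo, kinetochore_protein_params(radial_displacement = 100,
                                    point_marked = 0), seed = 8)
  expect_equal(at_plus$x_nm, geo$px)
  expect_equal(at_plus$y_nm, geo$py)
  expect_equal(at_plus$z_nm, geo$pz)

  expect_error(place_kinetochore_protein(
    geo, structure(list(n_arms = 1L, n_bound_arms = 2L),
                   class = "kinetochore_protein_params"), seed = 1),
    "n_bound_arms")
})

test_that("all fluorophores stay inside the enclosing cylinder", {
  sp <- spindle_params(n_complexes = 1L)
  geo <- build_spindle(sp, seed = 11)
  spc <- spc29_params()
  kin <- kinetochore_protein_params(radial_displacement = 100,
                                    arm_length = 60)
  fl <- combine_fluorophores(
    place_spb(geo, spc, seed = 12),
    place_kinetochore_protein(geo, kin, seed = 13),
    place_nuf2(geo, nuf2_params(), seed = 14))
  r_max <- 250 / 2 + 60 + spc$structure_diameter / 2
  expect_true(all(sqrt(fl$y_nm^2 + fl$z_nm^2) <= r_max + 1e-9))
  # aligned spindle: axis is exactly the first coordinate axis
  expect_equal(unique(geo$uy), 0)
  expect_equal(unique(geo$uz), 0)
})

test_that("ensembles are reproducible and respond to displacement", {
  sp <- spindle_params(n_complexes = 1L)
  prot <- list(cse4 = kinetochore_protein_params(radial_displacement = 0),
               spb = spc29_params())
  e1 <- generate_kinet_ensemble(sp, prot, n_models = 3, seed = 7)
  e2 <- generate_kinet_ensemble(sp, prot, n_models = 3, seed = 7)
  expect_identical(e1$models, e2$models)
  expect_equal(nrow(e1$manifest), 3L)

  e100 <- generate_kinet_ensemble(
    sp, list(cse4 = kinetochore_protein_params(radial_displacement = 100),
             spb = spc29_params()), n_models = 20, seed = 7)
  e0 <- generate_kinet_ensemble(sp, prot, n_models = 20, seed = 7)
  mean_r <- function(ens) mean(vapply(ens$models, function(m) {
    g <- m$channel == "green"
    mean(sqrt(m$y_nm[g]^2 + m$z_nm[g]^2))
  }, numeric(1)))
  expect_gt(mean_r(e100), mean_r(e0))

  big <- generate_kinet_ensemble(sp, prot, n_models = 100, seed = 1)
  expect_equal(length(unique(big$manifest$seed)), 100L)
})

test_that("radial spread of kinetochore marks increases monotonically", {
  sp <- spindle_params(n_complexes = 1L)
  spread <- vapply(c(0, 25, 50, 100), function(r) {
    ens <- generate_kinet_ensemble(
      sp, list(k = kinetochore_protein_params(radial_displacement = r)),
      n_models = 15, seed = 21)
    mean(vapply(ens$models, function(m)
      sd(m$y_nm) + sd(m$z_nm), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})

test_that("rotation turns the spindle axis away from x", {
  sp <- spindle_params(n_complexes = 1L, easy_align = FALSE,
                       rotation = c(pi / 2, 0, 0), stagger_range = 0)
  geo <- build_spindle(sp, seed = 3)
  # 90 degree rotation about z maps +x onto +y
  expect_equal(unique(round(geo$ux, 12)), 0)
  expect_equal(unique(round(geo$uy, 12)), 1)
})
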