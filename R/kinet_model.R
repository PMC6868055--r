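#' Spindle geometry parameters
#'
#' Parameters of the parametric budding-yeast mitotic-spindle model. The
#' kinetochore microtubule (MT) plus ends are arranged on a ring whose
#' diameter matches electron-tomography measurements of the metaphase
#' spindle (250 nm), each plus end staggered axially by a uniform draw to
#' represent the observed range of MT lengths.
#'
#' Coordinate convention: right-handed nm coordinates with the spindle axis
#' along +x. With one complex (a half spindle) the plus-end ring is centred
#' at the origin and minus ends extend toward +x; with two complexes (a full
#' spindle) the origin is the midpoint between the two plus-end rings, which
#' sit at `+- plus_separation / 2`.
#'
#' @param n_complexes 1 (half spindle) or 2 (full spindle).
#' @param n_microtubules number of kinetochore MTs per complex (default 16).
#' @param mt_diameter MT diameter in nm (default 25).
#' @param complex_diameter diameter of the plus-end ring in nm (default 250).
#' @param stagger_range half-width (nm) of the uniform axial stagger of plus
#'   ends (default 100, i.e. +-100 nm).
#' @param spindle_length plus-end to minus-end distance along the axis in nm.
#' @param plus_separation axial separation of the two plus-end rings of a
#'   full spindle (nm); the metaphase sister-kinetochore separation.
#' @param easy_align if `TRUE`, the model stays aligned to the coordinate
#'   axes regardless of `rotation`.
#' @param rotation `"none"`, `"random"`, or a numeric vector of three Euler
#'   angles (radians, Z-Y-X) applied to the whole model about the origin.
#' @return an object of class `spindle_params`.
#' @export
spindle_params <- function(n_complexes = 2L, n_microtubules = 16L,
                           mt_diameter = 25, complex_diameter = 250,
                           stagger_range = 100, spindle_length = 350,
                           plus_separation = 800,
                           easy_align = TRUE, rotation = "none") {
  if (!n_complexes %in% c(1L, 2L)) stop("n_complexes must be 1 or 2")
  stopifnot_scalar_num(n_microtubules, "n_microtubules", min = 1)
  for (nm in c("mt_diameter", "complex_diameter", "stagger_range",
               "spindle_length", "plus_separation"))
    stopifnot_scalar_num(get(nm), nm, min = 0)
  structure(list(
    n_complexes = as.integer(n_complexes),
    n_microtubules = as.integer(n_microtubules),
    mt_diameter = mt_diameter, complex_diameter = complex_diameter,
    stagger_range = stagger_range, spindle_length = spindle_length,
    plus_separation = plus_separation,
    easy_align = isTRUE(easy_align), rotation = rotation
  ), class = "spindle_params")
}

#' Outer-kinetochore (Nuf2) placement parameters
#'
#' Nuf2 N-termini bind near MT plus ends; fluorophores are distributed
#' uniformly within `length` nm of the plus end, on the MT surface.
#'
#' @param length axial range (nm) over which fluorophores are distributed
#'   from the plus end toward the minus end (default 50).
#' @param n_per_mt fluorophores per microtubule.
#' @param channel colour channel label.
#' @return an object of class `nuf2_params`.
#' @export
nuf2_params <- function(length = 50, n_per_mt = 5L, channel = "green") {
  stopifnot_scalar_num(length, "length", min = 0)
  stopifnot_scalar_num(n_per_mt, "n_per_mt", min = 0)
  structure(list(length = length, n_per_mt = as.integer(n_per_mt),
                 channel = channel), class = "nuf2_params")
}

#' Spindle pole body (Spc29) placement parameters
#'
#' The SPB is approximated by fluorophores surrounding the MT minus ends:
#' `n_tubules` minus-end sites on a ring of diameter `structure_diameter`,
#' each carrying `n_fluor_per_tubule` fluorophores spread within `length`
#' axially and within a disc of diameter `tubule_diameter` radially.
#'
#' @param length axial spread (nm) of fluorophores at each minus end.
#' @param distance_to_plus axial distance (nm) from the plus-end ring to the
#'   minus-end sites (the mean kinetochore-MT length).
#' @param tubule_diameter diameter (nm) of each minus-end site disc.
#' @param structure_diameter diameter (nm) of the ring of minus-end sites.
#' @param n_fluor_per_tubule fluorophores per minus end (default 20).
#' @param n_tubules number of minus ends (default 16).
#' @param channel colour channel label.
#' @return an object of class `spc29_params`.
#' @export
spc29_params <- function(length = 50, distance_to_plus = 350,
                         tubule_diameter = 25, structure_diameter = 250,
                         n_fluor_per_tubule = 20L, n_tubules = 16L,
                         channel = "red") {
  for (nm in c("length", "distance_to_plus", "tubule_diameter",
               "structure_diameter"))
    stopifnot_scalar_num(get(nm), nm, min = 0)
  stopifnot_scalar_num(n_fluor_per_tubule, "n_fluor_per_tubule", min = 0)
  stopifnot_scalar_num(n_tubules, "n_tubules", min = 0)
  structure(list(length = length, distance_to_plus = distance_to_plus,
                 tubule_diameter = tubule_diameter,
                 structure_diameter = structure_diameter,
                 n_fluor_per_tubule = as.integer(n_fluor_per_tubule),
                 n_tubules = as.integer(n_tubules), channel = channel),
            class = "spc29_params")
}

#' Inner-kinetochore protein placement parameters
#'
#' Kinetochore complexes are modeled as straight rods ("arms") running from
#' each MT plus end to a single convergence point — the centromeric (Cse4)
#' nucleosome. The convergence point continues axially past the plus end and
#' can be displaced radially from the MT axis (`radial_displacement`,
#' modelling the experimentally observed perpendicular spread of Cse4).
#' The displacement direction is radially outward from the spindle axis
#' (`azimuth = "outward"`, modelling kinetochores pulled radially from the
#' spindle, which widens the ring of marks and makes foci taller), or a
#' uniformly random azimuth per MT (`azimuth = "random"`). Arms beyond `n_bound_arms` orient
#' randomly within a cone of half-angle `angle_range` about the MT axis.
#' The fluorophore sits at fraction `point_marked` along its arm measured
#' from the plus end (1 = at the convergence point).
#'
#' @param n_arms arms (kinetochore fluorophores) per MT plus end.
#' @param n_bound_arms how many of those arms converge on the single point.
#' @param arm_length rod length in nm.
#' @param point_marked fraction in \[0, 1\] of the arm at which the
#'   fluorophore is placed, from the plus end.
#' @param radial_displacement distance (nm) of the convergence point from
#'   the MT axis.
#' @param angle_range cone half-angle (degrees) for unbound arms.
#' @param azimuth `"outward"` (radially away from the spindle axis) or
#'   `"random"` (uniform per MT).
#' @param channel colour channel label.
#' @return an object of class `kinetochore_protein_params`.
#' @export
kinetochore_protein_params <- function(n_arms = 1L, n_bound_arms = 1L,
                                       arm_length = 50, point_marked = 1,
                                       radial_displacement = 0,
                                       angle_range = 90,
                                       azimuth = c("outward", "random"),
                                       channel = "green") {
  azimuth <- match.arg(azimuth)
  stopifnot_scalar_num(n_arms, "n_arms", min = 0)
  stopifnot_scalar_num(n_bound_arms, "n_bound_arms", min = 0)
  if (n_bound_arms > n_arms) stop("n_bound_arms must be <= n_arms")
  stopifnot_scalar_num(arm_length, "arm_length", min = 0)
  stopifnot_scalar_num(point_marked, "point_marked", min = 0)
  if (point_marked > 1) stop("point_marked must be in [0, 1]")
  stopifnot_scalar_num(radial_displacement, "radial_displacement", min = 0)
  structure(list(n_arms = as.integer(n_arms),
                 n_bound_arms = as.integer(n_bound_arms),
                 arm_length = arm_length, point_marked = point_marked,
                 radial_displacement = radial_displacement,
                 angle_range = angle_range, azimuth = azimuth,
                 channel = channel),
            class = "kinetochore_protein_params")
}

# Rotation matrix encoded by a spindle_params object (identity when aligned).
spindle_rotation <- function(params, seed = NULL) {
  if (params$easy_align || identical(params$rotation, "none"))
    return(diag(3))
  if (identical(params$rotation, "random")) {
    ang <- runif(3, 0, 2 * pi)
    return(euler_matrix(ang[1L], ang[2L], ang[3L]))
  }
  if (is.numeric(params$rotation) && length(params$rotation) == 3L)
    return(euler_matrix(params$rotation[1L], params$rotation[2L],
                        params$rotation[3L]))
  stop("rotation must be \"none\", \"random\", or 3 Euler angles")
}

#' Build the microtubule geometry of a spindle
#'
#' Places `n_microtubules` plus ends evenly on the plus-end ring (in the
#' y–z plane), staggers each axially by `U(-stagger_range, +stagger_range)`
#' along the half-spindle's outward axis, and puts minus ends
#' `spindle_length` further out along that axis. With two complexes the
#' sister half-spindle is mirrored through the spindle midplane with
#' independent stagger draws.
#'
#' @param params a [spindle_params()] object.
#' @param seed integer seed.
#' @return an object of class `mt_geometry`: a data frame with one row per
#'   MT (`mt`, `complex`, plus-end `px, py, pz`, minus-end `mx, my, mz`,
#'   outward axis unit vector `ux, uy, uz`), carrying the parameters and
#'   the model rotation matrix as attributes.
#' @export
build_spindle <- function(params, seed = 1L) {
  stopifnot(inherits(params, "spindle_params"))
  if (params$n_microtubules < 1L)
    stop("n_microtubules must be positive")
  withr::with_seed(as.integer(seed), {
    R <- spindle_rotation(params)
    n <- params$n_microtubules
    theta <- 2 * pi * (seq_len(n) - 1L) / n
    ring_r <- params$complex_diameter / 2
    rows <- vector("list", params$n_complexes)
    for (cx in seq_len(params$n_complexes)) {
      # outward axis: +x for complex 1; -x for the mirrored sister.
      dirx <- if (cx == 1L) 1 else -1
      base_x <- if (params$n_complexes == 1L) 0 else
        dirx * params$plus_separation / 2
      stagger <- if (params$stagger_range > 0)
        runif(n, -params$stagger_range, params$stagger_range) else
        rep(0, n)
      px <- base_x + dirx * stagger
      py <- ring_r * cos(theta)
      pz <- ring_r * sin(theta)
      mx <- px + dirx * params$spindle_length
      rows[[cx]] <- data.frame(
        mt = seq_len(n), complex = cx,
        px = px, py = py, pz = pz,
        mx = mx, my = py, mz = pz,
        ux = dirx, uy = 0, uz = 0
      )
    }
    geo <- do.call(rbind, rows)
    # rotate the whole model about the origin
    P <- t(R %*% t(as.matrix(geo[, c("px", "py", "pz")])))
    M <- t(R %*% t(as.matrix(geo[, c("mx", "my", "mz")])))
    U <- t(R %*% t(as.matrix(geo[, c("ux", "uy", "uz")])))
    geo[, c("px", "py", "pz")] <- P
    geo[, c("mx", "my", "mz")] <- M
    geo[, c("ux", "uy", "uz")] <- U
    structure(geo, class = c("mt_geometry", "data.frame"),
              params = params, rotation = R, seed = as.integer(seed))
  })
}

#' Place outer-kinetochore (Nuf2) fluorophores
#'
#' For each MT, draws `n_per_mt` fluorophores at axial offsets
#' `U(0, length)` from the plus end toward the minus end, sitting on the MT
#' surface (radius `mt_diameter / 2`) at a uniformly random azimuth.
#'
#' @param geometry an `mt_geometry` from [build_spindle()].
#' @param params a [nuf2_params()] object.
#' @param seed integer seed.
#' @return a [fluorophore_set()].
#' @export
place_nuf2 <- function(geometry, params, seed = 1L) {
  stopifnot(inherits(geometry, "mt_geometry"), inherits(params, "nuf2_params"))
  mt_r <- attr(geometry, "params")$mt_diameter / 2
  withr::with_seed(as.integer(seed), {
    pts <- lapply(seq_len(nrow(geometry)), function(i) {
      k <- params$n_per_mt
      if (k == 0L) return(NULL)
      u <- c(geometry$ux[i], geometry$uy[i], geometry$uz[i])
      b <- perp_basis(u)
      d <- if (params$length > 0) runif(k, 0, params$length) else rep(0, k)
      phi <- runif(k, 0, 2 * pi)
      p0 <- c(geometry$px[i], geometry$py[i], geometry$pz[i])
      t(p0 + outer(u, d) +
          mt_r * (outer(b$e1, cos(phi)) + outer(b$e2, sin(phi))))
    })
    xyz <- do.call(rbind, pts)
    if (is.null(xyz)) xyz <- matrix(numeric(), 0L, 3L)
    fluorophore_set(xyz[, 1L], xyz[, 2L], xyz[, 3L],
                    channel = params$channel,
                    provenance = list(protein = "nuf2", params = params,
                                      seed = as.integer(seed)))
  })
}

#' Place spindle pole body (Spc29) fluorophores
#'
#' Arranges `n_tubules` minus-end sites evenly on a ring of diameter
#' `structure_diameter` at axial distance `distance_to_plus` outward of the
#' plus-end ring, then spreads `n_fluor_per_tubule` fluorophores per site:
#' uniform within `length` axially (continuing outward) and uniform within
#' a disc of diameter `tubule_diameter` radially.
#'
#' @param geometry an `mt_geometry` from [build_spindle()].
#' @param params a [spc29_params()] object.
#' @param seed integer seed.
#' @return a [fluorophore_set()].
#' @export
place_spb <- function(geometry, params, seed = 1L) {
  stopifnot(inherits(geometry, "mt_geometry"), inherits(params, "spc29_params"))
  sp <- attr(geometry, "params")
  R <- attr(geometry, "rotation")
  withr::with_seed(as.integer(seed), {
    out <- list()
    for (cx in unique(geometry$complex)) {
      dirx <- if (cx == 1L) 1 else -1
      base_x <- if (sp$n_complexes == 1L) 0 else dirx * sp$plus_separation / 2
      nt <- params$n_tubules
      if (nt == 0L || params$n_fluor_per_tubule == 0L) next
      theta <- 2 * pi * (seq_len(nt) - 1L) / nt
      site <- cbind(
        base_x + dirx * params$distance_to_plus,
        params$structure_diameter / 2 * cos(theta),
        params$structure_diameter / 2 * sin(theta)
      )
      k <- params$n_fluor_per_tubule
      for (s in seq_len(nt)) {
        ax <- if (params$length > 0) runif(k, 0, params$length) else rep(0, k)
        rr <- params$tubule_diameter / 2 * sqrt(runif(k))
        phi <- runif(k, 0, 2 * pi)
        xyz <- cbind(site[s, 1L] + dirx * ax,
                     site[s, 2L] + rr * cos(phi),
                     site[s, 3L] + rr * sin(phi))
        out[[length(out) + 1L]] <- xyz
      }
    }
    xyz <- if (length(out)) do.call(rbind, out) else matrix(numeric(), 0L, 3L)
    if (nrow(xyz)) xyz <- t(R %*% t(xyz))
    fluorophore_set(xyz[, 1L], xyz[, 2L], xyz[, 3L],
                    channel = params$channel,
                    provenance = list(protein = "spc29", params = params,
                                      seed = as.integer(seed)))
  })
}

#' Place inner-kinetochore protein fluorophores
#'
#' Per MT, a convergence point is set on the axial continuation of the plus
#' end (away from the minus end), displaced `radial_displacement` nm from
#' the MT axis at a uniformly random azimuth; the axial continuation
#' distance is `sqrt(max(arm_length^2 - radial_displacement^2, 0))` so that
#' bound arms have length `max(arm_length, radial_displacement)`.
#' `n_bound_arms` arms run from the plus end to that point; the remaining
#' arms orient uniformly within a cone of half-angle `angle_range` about
#' the continuation axis. Each arm's fluorophore sits at fraction
#' `point_marked` along the arm from the plus end.
#'
#' @param geometry an `mt_geometry` from [build_spindle()].
#' @param params a [kinetochore_protein_params()] object.
#' @param seed integer seed.
#' @return a [fluorophore_set()].
#' @export
place_kinetochore_protein <- function(geometry, params, seed = 1L) {
  stopifnot(inherits(geometry, "mt_geometry"),
            inherits(params, "kinetochore_protein_params"))
  if (params$n_bound_arms > params$n_arms)
    stop("n_bound_arms must be <= n_arms")
  withr::with_seed(as.integer(seed), {
    out <- list()
    for (i in seq_len(nrow(geometry))) {
      if (params$n_arms == 0L) next
      u <- c(geometry$ux[i], geometry$uy[i], geometry$uz[i])
      ucont <- -u  # continuation beyond the plus end, away from the minus end
      b <- perp_basis(u)
      p0 <- c(geometry$px[i], geometry$py[i], geometry$pz[i])
      r <- params$radial_displacement
      a <- sqrt(max(params$arm_length^2 - r^2, 0))
      radial <- p0 - sum(p0 * u) * u  # component of the plus end off-axis
      rn2 <- sqrt(sum(radial^2))
      rdir <- if (params$azimuth == "outward" && rn2 > 1e-9) {
        radial / rn2
      } else {
        phi <- runif(1, 0, 2 * pi)
        cos(phi) * b$e1 + sin(phi) * b$e2
      }
      conv <- p0 + a * ucont + r * rdir
      nb <- params$n_bound_arms
      if (nb > 0L) {
        tm <- params$point_marked
        pos <- p0 + tm * (conv - p0)
        out[[length(out) + 1L]] <-
          matrix(rep(pos, nb), ncol = 3L, byrow = TRUE)
      }
      nu <- params$n_arms - nb
      if (nu > 0L) {
        # uniform directions within a cone of half-angle angle_range
        amax <- params$angle_range * pi / 180
        cosang <- runif(nu, cos(amax), 1)
        sinang <- sqrt(pmax(1 - cosang^2, 0))
        aphi <- runif(nu, 0, 2 * pi)
        dirs <- outer(ucont, cosang) +
          outer(b$e1, sinang * cos(aphi)) + outer(b$e2, sinang * sin(aphi))
        ends <- p0 + params$arm_length * dirs
        pos <- p0 + params$point_marked * (ends - p0)
        out[[length(out) + 1L]] <- t(pos)
      }
    }
    xyz <- if (length(out)) do.call(rbind, out) else matrix(numeric(), 0L, 3L)
    fluorophore_set(xyz[, 1L], xyz[, 2L], xyz[, 3L],
                    channel = params$channel,
                    provenance = list(protein = "kinetochore", params = params,
                                      seed = as.integer(seed)))
  })
}

#' Generate an ensemble of kinetochore-model fluorophore sets
#'
#' Builds `n_models` independent spindle models (geometry plus the requested
#' protein placements) from per-model seeds derived from a master seed, and
#' returns them with a manifest for exact reproduction.
#'
#' @param spindle a [spindle_params()] object.
#' @param proteins a named list of placement parameter objects; names are
#'   free, classes decide the placement: [nuf2_params()], [spc29_params()],
#'   [kinetochore_protein_params()].
#' @param n_models number of independent models.
#' @param seed master seed.
#' @return a list with `models` (list of [fluorophore_set()]) and
#'   `manifest` (data frame of model index and seed).
#' @export
generate_kinet_ensemble <- function(spindle, proteins, n_models, seed = 1L) {
  stopifnot(n_models >= 1)
  seeds <- derive_seeds(seed, n_models)
  models <- lapply(seq_len(n_models), function(m) {
    s <- seeds[m]
    sub <- derive_seeds(s, length(proteins) + 1L)
    geo <- build_spindle(spindle, seed = sub[1L])
    sets <- lapply(seq_along(proteins), function(j) {
      p <- proteins[[j]]
      if (inherits(p, "nuf2_params")) place_nuf2(geo, p, seed = sub[j + 1L])
      else if (inherits(p, "spc29_params")) place_spb(geo, p, seed = sub[j + 1L])
      else if (inherits(p, "kinetochore_protein_params"))
        place_kinetochore_protein(geo, p, seed = sub[j + 1L])
      else stop("unknown protein parameter class: ",
                paste(class(p), collapse = "/"))
    })
    do.call(combine_fluorophores, sets)
  })
  list(models = models,
       manifest = data.frame(model = seq_len(n_models), seed = seeds))
}
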