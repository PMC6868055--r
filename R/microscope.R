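#' Widefield optics parameters
#'
#' Describes the simulated microscope: a high-NA oil objective imaging
#' seven z-planes onto a camera with 65 nm effective pixels (6.5 um camera
#' pixels behind a 100x objective). The point-spread function is an
#' anisotropic 3D Gaussian whose widths follow the standard widefield
#' approximations `sigma_xy = 0.21 * lambda / NA` and
#' `sigma_z = 0.66 * lambda * n_refr / NA^2`.
#'
#' @param numerical_aperture objective NA (default 1.4).
#' @param wavelengths named numeric vector of emission wavelengths (nm) per
#'   channel; defaults GFP 510 (green), RFP 580 (red).
#' @param pixel_size nm per pixel (default 65).
#' @param n_zplanes number of z-planes, odd so a central focal plane exists
#'   (default 7).
#' @param z_step plane spacing in nm (default 300).
#' @param image_size field size in pixels (square, default 50).
#' @param photons_per_fluorophore expected photons collected per unit
#'   fluorophore intensity (default 300).
#' @param n_refr immersion refractive index used in the axial width
#'   (default 1.515).
#' @param k_xy,k_z the PSF width prefactors (defaults 0.21 and 0.66).
#' @return an object of class `optics_params`.
#' @export
optics_params <- function(numerical_aperture = 1.4,
                          wavelengths = c(green = 510, red = 580),
                          pixel_size = 65, n_zplanes = 7L, z_step = 300,
                          image_size = 50L, photons_per_fluorophore = 300,
                          n_refr = 1.515, k_xy = 0.21, k_z = 0.66) {
  for (nm in c("numerical_aperture", "pixel_size", "z_step",
               "photons_per_fluorophore"))
    stopifnot_scalar_num(get(nm), nm, min = 0, strict = TRUE)
  if (is.null(names(wavelengths)) || any(!nzchar(names(wavelengths))))
    stop("wavelengths must be a named vector (channel -> nm)")
  if (any(wavelengths <= 0)) stop("wavelengths must be positive")
  n_zplanes <- as.integer(n_zplanes)
  if (n_zplanes < 1L || n_zplanes %% 2L == 0L)
    stop("n_zplanes must be odd so a central focal plane exists")
  structure(list(numerical_aperture = numerical_aperture,
                 wavelengths = wavelengths, pixel_size = pixel_size,
                 n_zplanes = n_zplanes, z_step = z_step,
                 image_size = as.integer(image_size),
                 photons_per_fluorophore = photons_per_fluorophore,
                 n_refr = n_refr, k_xy = k_xy, k_z = k_z),
            class = "optics_params")
}

#' Gaussian PSF widths for a channel
#'
#' @param optics an [optics_params()] object.
#' @param channel channel label present in `optics$wavelengths`.
#' @return named numeric vector `c(sigma_xy = , sigma_z = )` in nm.
#' @export
psf_sigma <- function(optics, channel) {
  stopifnot(inherits(optics, "optics_params"))
  if (!channel %in% names(optics$wavelengths))
    stop("unknown channel: ", channel)
  lambda <- optics$wavelengths[[channel]]
  na <- optics$numerical_aperture
  c(sigma_xy = optics$k_xy * lambda / na,
    sigma_z = optics$k_z * lambda * optics$n_refr / na^2)
}

#' Camera noise parameters
#'
#' @param read_noise_sd Gaussian read noise standard deviation (photons).
#' @param baseline camera offset added to every voxel (counts).
#' @param apply_shot_noise draw Poisson shot noise around the expected
#'   photon count (default `TRUE`).
#' @return an object of class `noise_params`.
#' @export
noise_params <- function(read_noise_sd = 10, baseline = 100,
                         apply_shot_noise = TRUE) {
  stopifnot_scalar_num(read_noise_sd, "read_noise_sd", min = 0)
  structure(list(read_noise_sd = read_noise_sd, baseline = baseline,
                 apply_shot_noise = isTRUE(apply_shot_noise)),
            class = "noise_params")
}

# z coordinate (nm) of each plane centre, focal plane at 0.
plane_z <- function(optics)
  (seq_len(optics$n_zplanes) - (optics$n_zplanes + 1) / 2) * optics$z_step

#' Render fluorophores into a simulated z-stack
#'
#' Each fluorophore contributes an anisotropic 3D Gaussian: integrated over
#' pixel extents in x and y (error-function differences) and point-sampled
#' at plane centres in z (weight `dnorm * z_step`), scaled by
#' `intensity * photons_per_fluorophore`. Contributions sum per channel;
#' rendering is linear in the fluorophore set. The field is centred on the
#' coordinate origin: pixel centres run from
#' `-(image_size - 1)/2 * pixel_size` to `+(image_size - 1)/2 * pixel_size`,
#' columns along +x, rows along +y.
#'
#' @param fluors a [fluorophore_set()]; channels must be a subset of the
#'   optics channel map.
#' @param optics an [optics_params()] object.
#' @return an object of class `image_stack`: a numeric array
#'   `[row(y), col(x), z, channel]` of expected photon counts with the
#'   optics snapshot attached.
#' @export
render_stack <- function(fluors, optics) {
  stopifnot(inherits(optics, "optics_params"))
  npx <- optics$image_size
  chans <- names(optics$wavelengths)
  if (nrow(fluors) && !all(fluors$channel %in% chans))
    stop("fluorophore channels not in optics channel map: ",
         paste(setdiff(unique(fluors$channel), chans), collapse = ", "))
  stack <- array(0, dim = c(npx, npx, optics$n_zplanes, length(chans)),
                 dimnames = list(NULL, NULL, NULL, chans))
  edges <- (seq_len(npx + 1L) - 1L - npx / 2) * optics$pixel_size
  zc <- plane_z(optics)
  for (ci in seq_along(chans)) {
    sel <- fluors$channel == chans[ci]
    if (!any(sel)) next
    sig <- psf_sigma(optics, chans[ci])
    fx <- fluors$x_nm[sel]; fy <- fluors$y_nm[sel]; fz <- fluors$z_nm[sel]
    amp <- fluors$intensity[sel] * optics$photons_per_fluorophore
    nf <- length(fx)
    # per-fluorophore pixel masses along each axis (nf x npx), and z weights
    cdfx <- vapply(seq_len(npx + 1L),
                   function(k) pnorm(edges[k], mean = fx, sd = sig["sigma_xy"]),
                   numeric(nf))
    cdfy <- vapply(seq_len(npx + 1L),
                   function(k) pnorm(edges[k], mean = fy, sd = sig["sigma_xy"]),
                   numeric(nf))
    if (nf == 1L) { cdfx <- matrix(cdfx, 1L); cdfy <- matrix(cdfy, 1L) }
    wx <- cdfx[, -1L, drop = FALSE] - cdfx[, -(npx + 1L), drop = FALSE]
    wy <- cdfy[, -1L, drop = FALSE] - cdfy[, -(npx + 1L), drop = FALSE]
    wy <- wy * amp
    for (k in seq_len(optics$n_zplanes)) {
      wz <- dnorm(zc[k], mean = fz, sd = sig["sigma_z"]) * optics$z_step
      # rows are y, columns are x: image = t(wy * wz) %*% wx
      stack[, , k, ci] <- crossprod(wy * wz, wx)
    }
  }
  structure(stack, class = "image_stack", optics = optics)
}

#' Apply camera noise to a stack
#'
#' Per voxel: a Poisson draw around the expected photon count (if enabled),
#' plus Gaussian read noise, clipped at zero, plus the camera baseline.
#'
#' @param stack an `image_stack` of expected photon counts.
#' @param noise a [noise_params()] object.
#' @param seed integer seed.
#' @return a noisy `image_stack` (counts).
#' @export
add_noise <- function(stack, noise, seed = 1L) {
  stopifnot(inherits(stack, "image_stack"), inherits(noise, "noise_params"))
  d <- dim(stack)
  withr::with_seed(as.integer(seed), {
    v <- as.vector(stack)
    if (noise$apply_shot_noise) v <- rpois(length(v), v)
    if (noise$read_noise_sd > 0)
      v <- v + rnorm(length(v), sd = noise$read_noise_sd)
    v <- pmax(v, 0) + noise$baseline
    out <- array(v, dim = d, dimnames = dimnames(stack))
  })
  attributes(out)[c("class", "optics")] <-
    attributes(stack)[c("class", "optics")]
  dimnames(out) <- dimnames(stack)
  out
}

#' Write / read a stack as multi-page TIFF with a JSON sidecar
#'
#' Voxels are quantised to 16 bits (a per-stack scale factor maps the voxel
#' maximum to 65535) and written as one TIFF page per (channel, z-plane),
#' channel-major. The sidecar `<path>.json` records the optics, channel
#' order and quantisation scale; the quantised 16-bit values round-trip
#' bit-identically. A missing sidecar is tolerated: the stack is read back
#' with default optics and a warning.
#'
#' @param stack an `image_stack`.
#' @param path TIFF file path (sidecar written next to it).
#' @return `read_stack` returns an `image_stack` (quantised counts).
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  optics <- attr(stack, "optics")
  d <- dim(stack)
  mx <- max(stack)
  scale <- if (mx > 0) mx / 65535 else 1
  q <- round(stack / scale)  # 16-bit quantised values
  pages <- list()
  for (ci in seq_len(d[4L])) for (k in seq_len(d[3L]))
    pages[[length(pages) + 1L]] <- q[, , k, ci] / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  op <- unclass(optics)
  op$wavelengths <- as.list(op$wavelengths)  # keep channel names in JSON
  jsonlite::write_json(
    list(optics = op, channels = dimnames(stack)[[4L]],
         n_zplanes = d[3L], scale = scale, page_order = "channel_major"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$channels) || is.null(meta$n_zplanes))
      stop("malformed sidecar: missing field 'channels' or 'n_zplanes'")
    channels <- meta$channels
    nz <- meta$n_zplanes
    scale <- meta$scale
    op <- meta$optics
    wl <- unlist(op$wavelengths)
    optics <- optics_params(op$numerical_aperture, wl, op$pixel_size,
                            op$n_zplanes, op$z_step, op$image_size,
                            op$photons_per_fluorophore, op$n_refr,
                            op$k_xy, op$k_z)
  } else {
    warning("missing sidecar ", sidecar, "; assuming default optics")
    optics <- optics_params()
    nz <- optics$n_zplanes
    if (length(pages) %% nz != 0L)
      stop("cannot infer layout of ", length(pages), " pages without sidecar")
    channels <- names(optics$wavelengths)[seq_len(length(pages) / nz)]
    scale <- 1
  }
  if (length(pages) != nz * length(channels))
    stop(sprintf("expected %d pages (%d channels x %d planes), found %d",
                 nz * length(channels), length(channels), nz, length(pages)))
  npx <- nrow(pages[[1L]])
  stack <- array(0, c(npx, ncol(pages[[1L]]), nz, length(channels)),
                 dimnames = list(NULL, NULL, NULL, channels))
  p <- 0L
  for (ci in seq_along(channels)) for (k in seq_len(nz)) {
    p <- p + 1L
    stack[, , k, ci] <- round(pages[[p]] * 65535) * scale
  }
  structure(stack, class = "image_stack", optics = optics)
}
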