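#' Maximum-intensity projection
#'
#' Per-channel, per-pixel maximum over z, condensing a stack to one plane.
#'
#' @param stack an `image_stack` (`[y, x, z, channel]`).
#' @return numeric array `[y, x, channel]`.
#' @export
max_project <- function(stack) {
  d <- dim(stack)
  stopifnot(length(d) == 4L, d[3L] >= 1L)
  out <- array(-Inf, d[c(1L, 2L, 4L)], dimnames = dimnames(stack)[c(1, 2, 4)])
  for (k in seq_len(d[3L])) out <- pmax(out, stack[, , k, , drop = TRUE])
  if (d[4L] == 1L) dim(out) <- d[c(1L, 2L, 4L)]
  out
}

#' Rescale each channel to the full 16-bit range
#'
#' Linear per-channel rescale of `[min, max]` to `[0, 65535]`, rounded;
#' a constant channel maps to all zeros. Pixel intensity order is
#' preserved within each channel.
#'
#' @param image numeric array `[y, x, channel]`.
#' @return integer-valued array of the same shape in `[0, 65535]`.
#' @export
normalize_16bit <- function(image) {
  d <- dim(image)
  stopifnot(length(d) == 3L)
  out <- image
  for (ci in seq_len(d[3L])) {
    ch <- image[, , ci]
    rng <- range(ch)
    out[, , ci] <- if (rng[2L] > rng[1L])
      round((ch - rng[1L]) / (rng[2L] - rng[1L]) * 65535) else 0
  }
  out
}

# 90-degree CCW rotation of each channel of [y, x, channel].
rot90_image <- function(image) {
  d <- dim(image)
  out <- array(0, c(d[2L], d[1L], d[3L]))
  for (ci in seq_len(d[3L]))
    out[, , ci] <- t(image[, , ci])[d[2L]:1, , drop = FALSE]
  out
}

flip_image <- function(image) image[, dim(image)[2L]:1, , drop = FALSE]

#' The eight dihedral orientations of a square image
#'
#' Returns the D4 group orbit in a fixed order: the identity first, then
#' rotations by 90/180/270 degrees, then the horizontal mirror and its
#' three rotations — one original plus seven additional orientations.
#'
#' @param image numeric array `[y, x, channel]`, square in y/x.
#' @return list of 8 arrays; element 1 is identical to the input.
#' @export
augment_orientations <- function(image) {
  d <- dim(image)
  stopifnot(length(d) == 3L)
  if (d[1L] != d[2L]) stop("augment_orientations requires a square image")
  r1 <- rot90_image(image); r2 <- rot90_image(r1); r3 <- rot90_image(r2)
  f0 <- flip_image(image)
  f1 <- rot90_image(f0); f2 <- rot90_image(f1); f3 <- rot90_image(f2)
  list(image, r1, r2, r3, f0, f1, f2, f3)
}

#' Subtract an estimated background
#'
#' Default estimator is the per-channel median; the result is clipped at
#' zero.
#'
#' @param image numeric array `[y, x, channel]`.
#' @param method `"median"` or a function applied per channel returning a
#'   scalar background level.
#' @return array of the same shape with background removed.
#' @export
subtract_background <- function(image, method = "median") {
  est <- if (is.function(method)) method else
    switch(method, median = stats::median,
           stop("unknown background method: ", method))
  out <- image
  for (ci in seq_len(dim(image)[3L]))
    out[, , ci] <- pmax(image[, , ci] - est(image[, , ci]), 0)
  out
}

# Box-filter local mean with replicate padding (window must be odd).
local_mean <- function(m, win) {
  h <- (win - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(rep(1L, h), seq_len(nr), rep(nr, h)),
           c(rep(1L, h), seq_len(nc), rep(nc, h)), drop = FALSE]
  acc <- matrix(0, nr, nc)
  for (dr in 0:(win - 1L)) for (dc in 0:(win - 1L))
    acc <- acc + pad[dr + seq_len(nr), dc + seq_len(nc)]
  acc / (win * win)
}

#' Local-adaptive (Wiener) low-pass denoising
#'
#' The classic pixelwise adaptive Wiener filter: with local mean `m` and
#' local variance `v` over the window, and noise power `nu` estimated as
#' the mean of the local variances,
#' `out = m + max(v - nu, 0) / max(v, nu) * (x - m)`.
#' Smooth regions collapse to their local mean; structured regions are
#' left nearly untouched. A constant image is unchanged.
#'
#' @param image numeric array `[y, x, channel]`.
#' @param window odd window size (default 3, i.e. 3x3).
#' @return filtered array of the same shape.
#' @export
wiener_denoise <- function(image, window = 3L) {
  d <- dim(image)
  stopifnot(length(d) == 3L)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window > min(d[1:2])) stop("window larger than image")
  out <- image
  for (ci in seq_len(d[3L])) {
    x <- image[, , ci]
    m <- local_mean(x, window)
    v <- pmax(local_mean(x * x, window) - m * m, 0)
    nu <- mean(v)
    gain <- if (nu == 0) 0 else pmax(v - nu, 0) / pmax(v, nu)
    out[, , ci] <- m + gain * (x - m)
  }
  out
}

# Crop a [y, x, channel] array to size x size about its centre.
crop_center <- function(image, size) {
  d <- dim(image)
  if (d[1L] < size || d[2L] < size)
    stop("image smaller than crop size")
  r0 <- floor((d[1L] - size) / 2)
  c0 <- floor((d[2L] - size) / 2)
  image[r0 + seq_len(size), c0 + seq_len(size), , drop = FALSE]
}

#' Run the canonical stack-to-images processing chain
#'
#' The order is: crop a 50x50 field about the image centre, maximum
#' projection over z, per-channel 16-bit normalisation, generation of the
#' eight dihedral orientations, per-channel median background subtraction,
#' and 3x3 adaptive Wiener denoising. The chain is deterministic. Channels
#' are mapped to RGB planes (red -> 1, green -> 2, blue unused) so each
#' output is a 50x50x3 16-bit image.
#'
#' @param stack an `image_stack`.
#' @param size output side length in pixels (default 50).
#' @param window Wiener window (default 3).
#' @param source_id identifier stored in each image's provenance.
#' @return list of 8 objects of class `processed_image`: integer arrays
#'   `[y, x, 3]` with `orientation` (1..8) and `provenance` attributes.
#' @export
process_stack <- function(stack, size = 50L, window = 3L,
                          source_id = NULL) {
  proj <- max_project(stack)
  chans <- dimnames(proj)[[3L]]
  if (is.null(chans))
    chans <- names(attr(stack, "optics")$wavelengths)
  rgb_slot <- c(red = 1L, green = 2L, blue = 3L)
  d <- dim(proj)
  rgb <- array(0, c(d[1L], d[2L], 3L))
  for (ci in seq_along(chans)) {
    slot <- unname(rgb_slot[chans[ci]])
    if (is.na(slot)) stop("unmapped channel: ", chans[ci])
    rgb[, , slot] <- proj[, , ci]
  }
  rgb <- crop_center(rgb, as.integer(size))
  rgb <- normalize_16bit(rgb)
  orients <- augment_orientations(rgb)
  lapply(seq_along(orients), function(k) {
    img <- wiener_denoise(subtract_background(orients[[k]]), window)
    img <- array(as.integer(pmin(pmax(round(img), 0), 65535)), dim(img))
    structure(img, class = "processed_image", orientation = k,
              provenance = list(source = source_id,
                                steps = c("crop", "max_project",
                                          "normalize_16bit",
                                          "augment_orientations",
                                          "subtract_background",
                                          "wiener_denoise")))
  })
}

#' Write / read a processed image as 16-bit RGB TIFF
#'
#' @param image a `processed_image` (or any `[y, x, 3]` array in
#'   `[0, 65535]`).
#' @param path file path.
#' @return `read_processed_image` returns an integer `[y, x, 3]` array of
#'   class `processed_image`.
#' @export
write_processed_image <- function(image, path) {
  tiff::writeTIFF(unclass(image) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_processed_image
#' @export
read_processed_image <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) != 3L || dim(m)[3L] < 3L)
    stop("expected an RGB image: ", path)
  img <- array(as.integer(round(m[, , 1:3] * 65535)), c(dim(m)[1:2], 3L))
  structure(img, class = "processed_image", orientation = NA_integer_,
            provenance = list(source = path))
}
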