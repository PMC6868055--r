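#' The thirteen image features
#'
#' Feature names, in the canonical column order, extracted from two-channel
#' kinetochore/SPB images: normalized distances (kinetochore to proximal
#' SPB, its component parallel to the spindle, kinetochore to kinetochore),
#' foci heights (FWHM perpendicular to the spindle, pixels), line-scan
#' standard deviations parallel/perpendicular to the spindle, and 5x5
#' region mean/standard-deviation intensities, for both the SPB (red) and
#' kinetochore (green) channels.
#'
#' @export
feature_names <- c(
  "kinetochore_distance_to_spb", "kinetochore_x_distance",
  "spb_mean_intensity", "spb_height", "spb_std_y", "spb_std_x", "spb_std",
  "kinetochore_height", "kinetochore_std", "kinetochore_std_y",
  "kk_distance", "kinetochore_mean_intensity", "kinetochore_std_x"
)

flagged <- function(reason)
  structure(list(reason = reason), class = "flagged_image")

#' Test whether a detection or feature result was flagged
#'
#' Images lacking the expected kinetochore or SPB foci are flagged rather
#' than raising an error, mirroring the convention that such images are
#' disregarded by downstream analysis.
#'
#' @param x result of [detect_foci()] or [extract_features()].
#' @return logical.
#' @export
is_flagged <- function(x) inherits(x, "flagged_image")

# Bilinear sampling of matrix m at fractional 1-based (r, c); border
# replicated.
bilinear_sample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# Sub-pixel refinement by a 1D Gaussian (log-parabola) fit on 3 samples.
subpixel_1d <- function(l, c, r) {
  l <- max(l, 1e-9); c <- max(c, 1e-9); r <- max(r, 1e-9)
  den <- log(l) - 2 * log(c) + log(r)
  if (den >= 0) return(0)
  max(min(0.5 * (log(l) - log(r)) / den, 0.5), -0.5)
}

#' Detect bright foci in one channel
#'
#' Candidate foci are 8-neighbourhood local maxima above a robust
#' threshold (median + `k_mad` * MAD); the brightest `n_expected` are
#' kept, refined to sub-pixel centres by a local Gaussian fit, and sorted
#' left-to-right (by column). If fewer than `n_expected` candidates exist
#' the image is flagged rather than erroring.
#'
#' @param channel numeric matrix (one image channel).
#' @param n_expected 1 or 2 foci expected.
#' @param k_mad threshold multiplier (default 5; spurious noise
#'   maxima in a 50x50 field reach about 4 MADs).
#' @param min_separation minimum distance in pixels between accepted foci
#'   (default 4).
#' @return a data frame with 0-based `row`, `col` (brightest pixel),
#'   sub-pixel `sub_row`, `sub_col` and `peak` intensity — or a flagged
#'   object (see [is_flagged()]).
#' @export
detect_foci <- function(channel, n_expected, k_mad = 5, min_separation = 4) {
  stopifnot(n_expected %in% c(1L, 2L))
  nr <- nrow(channel); nc <- ncol(channel)
  thr <- median(channel) + k_mad * mad(channel)
  # interior local maxima
  z <- channel[2:(nr - 1), 2:(nc - 1)]
  ismax <- z > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ismax <- ismax & (z >= channel[2:(nr - 1) + dr, 2:(nc - 1) + dc])
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(flagged("no foci above threshold"))
  rr <- idx[, 1L] + 1L; cc <- idx[, 2L] + 1L
  pk <- channel[cbind(rr, cc)]
  ord <- order(pk, decreasing = TRUE)
  keep <- integer()
  for (i in ord) {
    if (length(keep) == n_expected) break
    if (all(sqrt((rr[keep] - rr[i])^2 + (cc[keep] - cc[i])^2) >=
            min_separation))
      keep <- c(keep, i)
  }
  if (length(keep) < n_expected)
    return(flagged(sprintf("found %d of %d expected foci",
                           length(keep), n_expected)))
  sub <- t(vapply(keep, function(i) {
    r <- rr[i]; c <- cc[i]
    dr <- subpixel_1d(channel[r - 1, c], channel[r, c], channel[r + 1, c])
    dc <- subpixel_1d(channel[r, c - 1], channel[r, c], channel[r, c + 1])
    c(r + dr, c + dc)
  }, numeric(2L)))
  out <- data.frame(row = rr[keep] - 1L, col = cc[keep] - 1L,
                    sub_row = sub[, 1L] - 1, sub_col = sub[, 2L] - 1,
                    peak = pk[keep])
  out[order(out$col), , drop = FALSE]
}

#' Spindle axis from the two SPB foci
#'
#' @param spb_foci data frame of exactly two foci from [detect_foci()].
#' @return list with `axis` (unit vector, `(d_row, d_col)` in pixel space)
#'   and `length` (Euclidean distance in pixels between the brightest
#'   pixels).
#' @export
spindle_axis <- function(spb_foci) {
  stopifnot(nrow(spb_foci) == 2L)
  d <- c(spb_foci$row[2L] - spb_foci$row[1L],
         spb_foci$col[2L] - spb_foci$col[1L])
  len <- sqrt(sum(d^2))
  if (len == 0) stop("degenerate spindle axis: coincident SPB foci")
  list(axis = d / len, length = len)
}

#' Focus height: FWHM perpendicular to the spindle
#'
#' Samples (by bilinear interpolation along the rotated axes) a 7 x 15
#' region about the brightest pixel — 7 samples along the spindle axis, 15
#' perpendicular — maximum-projects along the axis to a 15-sample
#' perpendicular profile, subtracts the profile minimum, and measures the
#' width at half the profile maximum with linear interpolation between
#' samples.
#'
#' @param channel numeric matrix.
#' @param focus one row of a [detect_foci()] result.
#' @param axis unit spindle-axis vector `(d_row, d_col)`.
#' @return FWHM in pixels, or a flagged object for a flat profile.
#' @export
spot_height <- function(channel, focus, axis) {
  perp <- c(-axis[2L], axis[1L])
  r0 <- focus$row + 1; c0 <- focus$col + 1  # back to 1-based
  prof <- vapply(-7:7, function(p) {
    pts_r <- r0 + (-3:3) * axis[1L] + p * perp[1L]
    pts_c <- c0 + (-3:3) * axis[2L] + p * perp[2L]
    max(bilinear_sample(channel, pts_r, pts_c))
  }, numeric(1L))
  prof <- prof - min(prof)
  pk <- which.max(prof)
  half <- prof[pk] / 2
  if (prof[pk] <= 0) return(flagged("flat perpendicular profile"))
  cross <- function(side) {
    ix <- if (side < 0) seq(pk, 1L) else seq(pk, 15L)
    below <- which(prof[ix] < half)
    if (!length(below)) return(if (side < 0) 1 else 15)  # truncated at edge
    b <- ix[below[1L]]; a <- b - side  # last index still above half
    a + side * (prof[a] - half) / (prof[a] - prof[b])
  }
  cross(+1L) - cross(-1L)
}

#' Line-scan intensity standard deviation
#'
#' Sample standard deviation of 15 bilinearly interpolated samples along a
#' line through the brightest pixel, parallel or perpendicular to the
#' spindle axis.
#'
#' @inheritParams spot_height
#' @param direction `"parallel"` or `"perpendicular"` to the spindle axis.
#' @param len scan length in samples (default 15).
#' @return standard deviation in counts.
#' @export
linescan_std <- function(channel, focus, axis,
                         direction = c("parallel", "perpendicular"),
                         len = 15L) {
  direction <- match.arg(direction)
  v <- if (direction == "parallel") axis else c(-axis[2L], axis[1L])
  half <- (len - 1) / 2
  off <- seq(-half, half)
  vals <- bilinear_sample(channel, focus$row + 1 + off * v[1L],
                          focus$col + 1 + off * v[2L])
  sd(vals)
}

#' Mean and standard deviation of a square region about a focus
#'
#' @inheritParams spot_height
#' @param size odd region side (default 5).
#' @return named vector `c(mean = , std = )`, or a flagged object if the
#'   window does not fit in the image.
#' @export
region_stats <- function(channel, focus, size = 5L) {
  h <- (size - 1L) %/% 2L
  r <- focus$row + 1L; c <- focus$col + 1L
  if (r - h < 1L || c - h < 1L || r + h > nrow(channel) ||
      c + h > ncol(channel))
    return(flagged("region window outside image"))
  block <- channel[(r - h):(r + h), (c - h):(c + h)]
  c(mean = mean(block), std = sd(block))
}

#' Normalized inter-foci distances
#'
#' Pairs each kinetochore focus with its nearest SPB focus and returns
#' (all divided by the spindle length): the Euclidean
#' kinetochore-to-SPB distances, their components parallel to the spindle
#' axis, and the kinetochore-kinetochore distance.
#'
#' @param k_foci,spb_foci two-row data frames from [detect_foci()].
#' @param axis unit spindle-axis vector.
#' @param spindle_length spindle length in pixels.
#' @return list with `distance_to_spb` (length 2), `x_distance` (length 2)
#'   and `kk_distance` (scalar).
#' @export
foci_distances <- function(k_foci, spb_foci, axis, spindle_length) {
  stopifnot(nrow(k_foci) == 2L, nrow(spb_foci) == 2L, spindle_length > 0)
  d2spb <- numeric(2L); dx <- numeric(2L)
  for (k in 1:2) {
    d <- cbind(spb_foci$row - k_foci$row[k], spb_foci$col - k_foci$col[k])
    dist <- sqrt(rowSums(d^2))
    nearest <- which.min(dist)
    d2spb[k] <- dist[nearest]
    dx[k] <- abs(sum(d[nearest, ] * axis))
  }
  kk <- sqrt((k_foci$row[2L] - k_foci$row[1L])^2 +
               (k_foci$col[2L] - k_foci$col[1L])^2)
  list(distance_to_spb = d2spb / spindle_length,
       x_distance = dx / spindle_length,
       kk_distance = kk / spindle_length)
}

#' Extract the thirteen features from a processed image
#'
#' Detects two kinetochore foci (green channel) and two SPB foci (red
#' channel), derives the spindle axis from the SPBs, and computes all
#' thirteen features; per-focus quantities are averaged over the two foci
#' of their channel so each image yields one record. Images lacking the
#' expected foci are flagged, not errored.
#'
#' @param image a `processed_image` (`[y, x, 3]`, red = SPB,
#'   green = kinetochore).
#' @return named numeric vector of the 13 features (see [feature_names]),
#'   or a flagged object.
#' @export
extract_features <- function(image) {
  stopifnot(length(dim(image)) == 3L)
  red <- image[, , 1L]; green <- image[, , 2L]
  spb <- detect_foci(red, 2L)
  if (is_flagged(spb)) return(flagged(paste("SPB:", spb$reason)))
  kin <- detect_foci(green, 2L)
  if (is_flagged(kin)) return(flagged(paste("kinetochore:", kin$reason)))
  ax <- spindle_axis(spb)
  per_focus <- function(channel, foci) {
    vals <- lapply(1:2, function(k) {
      f <- foci[k, , drop = FALSE]
      rs <- region_stats(channel, f)
      if (is_flagged(rs)) return(rs)
      h <- spot_height(channel, f, ax$axis)
      if (is_flagged(h)) return(h)
      c(mean = unname(rs["mean"]), std = unname(rs["std"]), height = h,
        std_x = linescan_std(channel, f, ax$axis, "parallel"),
        std_y = linescan_std(channel, f, ax$axis, "perpendicular"))
    })
    fl <- vapply(vals, is_flagged, logical(1L))
    if (any(fl)) return(vals[[which(fl)[1L]]])
    (vals[[1L]] + vals[[2L]]) / 2
  }
  s <- per_focus(red, spb)
  if (is_flagged(s)) return(flagged(paste("SPB:", s$reason)))
  k <- per_focus(green, kin)
  if (is_flagged(k)) return(flagged(paste("kinetochore:", k$reason)))
  dd <- foci_distances(kin, spb, ax$axis, ax$length)
  out <- c(
    kinetochore_distance_to_spb = mean(dd$distance_to_spb),
    kinetochore_x_distance = mean(dd$x_distance),
    spb_mean_intensity = unname(s["mean"]),
    spb_height = unname(s["height"]),
    spb_std_y = unname(s["std_y"]),
    spb_std_x = unname(s["std_x"]),
    spb_std = unname(s["std"]),
    kinetochore_height = unname(k["height"]),
    kinetochore_std = unname(k["std"]),
    kinetochore_std_y = unname(k["std_y"]),
    kk_distance = dd$kk_distance,
    kinetochore_mean_intensity = unname(k["mean"]),
    kinetochore_std_x = unname(k["std_x"])
  )
  out[feature_names]
}

#' Build a feature table from a list of images
#'
#' Applies [extract_features()] to each image, dropping flagged images and
#' recording their reasons.
#'
#' @param images list of processed images.
#' @param labels optional class labels (recycled checked to length).
#' @return data frame with `image`, optional `class`, and the 13 feature
#'   columns; flagged reasons in `attr(, "flagged")`.
#' @export
feature_table <- function(images, labels = NULL) {
  if (!is.null(labels)) stopifnot(length(labels) == length(images))
  recs <- lapply(images, extract_features)
  ok <- !vapply(recs, is_flagged, logical(1L))
  tab <- as.data.frame(do.call(rbind, recs[ok]))
  lead <- data.frame(image = which(ok))
  if (!is.null(labels)) lead$class <- labels[ok]
  out <- cbind(lead, tab)
  attr(out, "flagged") <- setNames(
    vapply(recs[!ok], function(r) r$reason, character(1L)), which(!ok))
  out
}
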