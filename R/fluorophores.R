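#' Labeled 3D point emitters
#'
#' A `fluorophore_set` is the exchange currency between the structural models
#' (kinetochore/spindle geometry, rDNA polymer snapshots) and the microscope
#' renderer: a table of point emitters with nanometre coordinates, a colour
#' channel label and an intensity in relative photon units.
#'
#' @param x,y,z numeric vectors of coordinates in nm.
#' @param channel character vector (recycled) of channel labels, e.g.
#'   `"green"`, `"red"`.
#' @param intensity numeric vector (recycled) of positive relative
#'   intensities; 1 means `photons_per_fluorophore` expected photons when
#'   rendered.
#' @param provenance optional list recording the generating parameters and
#'   seed.
#' @return a data frame of class `fluorophore_set` with columns
#'   `x_nm`, `y_nm`, `z_nm`, `channel`, `intensity`.
#' @export
fluorophore_set <- function(x = numeric(), y = numeric(), z = numeric(),
                            channel = character(), intensity = 1,
                            provenance = NULL) {
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop("x, y, z must have equal length")
  if (n > 0L && (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z))))
    stop("fluorophore coordinates must be finite")
  channel <- if (n == 0L) character() else rep_len(as.character(channel), n)
  intensity <- if (n == 0L) numeric() else rep_len(intensity, n)
  if (n > 0L && any(intensity <= 0))
    stop("fluorophore intensity must be > 0")
  out <- data.frame(
    x_nm = as.numeric(x), y_nm = as.numeric(y), z_nm = as.numeric(z),
    channel = channel, intensity = as.numeric(intensity),
    stringsAsFactors = FALSE
  )
  class(out) <- c("fluorophore_set", "data.frame")
  attr(out, "provenance") <- provenance
  out
}

#' @export
print.fluorophore_set <- function(x, ...) {
  cat(sprintf("<fluorophore_set: %d emitters, channels: %s>\n",
              nrow(x), paste(unique(x$channel), collapse = ", ")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}

#' Combine fluorophore sets
#'
#' @param ... `fluorophore_set` objects.
#' @return a single `fluorophore_set`; provenance entries are concatenated.
#' @export
combine_fluorophores <- function(...) {
  sets <- list(...)
  out <- do.call(rbind, lapply(sets, as.data.frame))
  fluorophore_set(out$x_nm, out$y_nm, out$z_nm, out$channel, out$intensity,
                  provenance = unlist(lapply(sets, attr, "provenance"),
                                      recursive = FALSE))
}

#' Write / read fluorophores as CSV
#'
#' Plain CSV with header `x_nm,y_nm,z_nm,channel,intensity`; round-trips a
#' `fluorophore_set` exactly up to numeric printing precision (15 digits).
#'
#' @param fluors a `fluorophore_set`.
#' @param path file path.
#' @return `read_fluorophores_csv` returns a `fluorophore_set`.
#' @export
write_fluorophores_csv <- function(fluors, path) {
  df <- as.data.frame(fluors)
  old <- options(digits = 15); on.exit(options(old))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fluorophores_csv
#' @export
read_fluorophores_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_nm", "y_nm", "z_nm", "channel", "intensity")
  if (!all(need %in% names(df)))
    stop("fluorophore CSV must have columns: ", paste(need, collapse = ", "))
  fluorophore_set(df$x_nm, df$y_nm, df$z_nm, df$channel, df$intensity)
}

#' Write / read fluorophores as XML
#'
#' One `<Fluorophore>` element per emitter with `x`, `y`, `z` position
#' attributes (nm), a `channel` attribute and an `intensity` attribute,
#' wrapped in a `<FluorophoreModel>` root — the point-fluorophore dialect
#' used by widefield microscope simulators.
#'
#' @inheritParams write_fluorophores_csv
#' @export
write_fluorophores_xml <- function(fluors, path) {
  doc <- xml2::xml_new_root("FluorophoreModel")
  df <- as.data.frame(fluors)
  for (i in seq_len(nrow(df))) {
    xml2::xml_add_child(
      doc, "Fluorophore",
      x = sprintf("%.6f", df$x_nm[i]),
      y = sprintf("%.6f", df$y_nm[i]),
      z = sprintf("%.6f", df$z_nm[i]),
      channel = df$channel[i],
      intensity = sprintf("%.6f", df$intensity[i])
    )
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_fluorophores_xml
#' @export
read_fluorophores_xml <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//Fluorophore")
  num <- function(a) as.numeric(xml2::xml_attr(nodes, a))
  fluorophore_set(num("x"), num("y"), num("z"),
                  xml2::xml_attr(nodes, "channel"), num("intensity"))
}
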