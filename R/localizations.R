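#' Localization table
#'
#' The atomic data structure of the pipeline: one row per single-molecule
#' localization (one fitted blink position), with planar coordinates in nm
#' and the fitted PSF width sigma in nm. Intensity (photons) and
#' localization uncertainty (nm) are optional.
#'
#' @param frame Integer acquisition frame index (>= 1) per localization.
#' @param x,y Planar position, nm (finite).
#' @param sigma Fitted PSF width, nm (> 0).
#' @param intensity Optional photon count.
#' @param uncertainty Optional localization precision, nm.
#' @param source_id Provenance string (file name, nucleus id, ...).
#' @param frame_count Acquisition length in frames; defaults to
#'   `max(frame)` (or 0 for an empty table). Every frame index must be
#'   `<= frame_count`.
#' @param extra Optional data.frame of additional columns carried through
#'   I/O opaquely.
#' @return A data.frame of class `localization_table` with columns
#'   `frame`, `x`, `y`, `sigma` and optionally `intensity`,
#'   `uncertainty`, plus attributes `source_id` and `frame_count`.
#' @export
localization_table <- function(frame = integer(), x = numeric(),
                               y = numeric(), sigma = numeric(),
                               intensity = NULL, uncertainty = NULL,
                               source_id = "", frame_count = NULL,
                               extra = NULL) {
  n <- length(x)
  frame <- as.integer(frame)
  stopifnot(length(frame) == n, length(y) == n, length(sigma) == n)
  if (n > 0) {
    if (any(frame < 1L)) stop("frame indices must be >= 1")
    if (any(!is.finite(x)) || any(!is.finite(y))) {
      stop("x and y must be finite")
    }
    if (any(!is.finite(sigma)) || any(sigma <= 0)) {
      stop("sigma must be positive and finite")
    }
  }
  if (is.null(frame_count)) frame_count <- if (n) max(frame) else 0L
  frame_count <- as.integer(frame_count)
  if (n && any(frame > frame_count)) {
    stop("frame indices exceed frame_count (", frame_count, ")")
  }
  df <- data.frame(frame = frame, x = as.numeric(x), y = as.numeric(y),
                   sigma = as.numeric(sigma))
  if (!is.null(intensity)) df$intensity <- as.numeric(intensity)
  if (!is.null(uncertainty)) df$uncertainty <- as.numeric(uncertainty)
  if (!is.null(extra) && ncol(extra)) df <- cbind(df, extra)
  structure(df, class = c("localization_table", "data.frame"),
            source_id = source_id, frame_count = frame_count)
}

#' @export
print.localization_table <- function(x, ...) {
  cat(sprintf("<localization_table> %d localizations, %d frames, source '%s'\n",
              nrow(x), attr(x, "frame_count"), attr(x, "source_id")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

# Canonical column headers (ThunderSTORM-style export).
.loc_headers <- c(frame = "frame", x = "x [nm]", y = "y [nm]",
                  sigma = "sigma [nm]", intensity = "intensity [photon]",
                  uncertainty = "uncertainty [nm]")

#' Read a localization CSV
#'
#' Parses a comma-separated localization export into a
#' [localization_table()]. The canonical dialect uses header tokens
#' `frame`, `x [nm]`, `y [nm]`, `sigma [nm]` and optionally
#' `intensity [photon]`, `uncertainty [nm]`. Length columns headed with a
#' micrometre unit (`x [um]`) are converted to nm on read; all positions
#' are nm internally. Unknown columns are preserved opaquely.
#'
#' @param path CSV file path.
#' @param dialect Format tag; currently `"thunderstorm"` (the canonical
#'   dialect above).
#' @param frame_count Acquisition length; defaults to the maximum frame
#'   index present.
#' @return A [localization_table()]; row order follows the file.
#' @export
read_localizations <- function(path, dialect = "thunderstorm",
                               frame_count = NULL) {
  dialect <- match.arg(dialect, "thunderstorm")
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", strip.white = TRUE)
  nm <- names(raw)
  find_col <- function(base, required = FALSE) {
    hit <- which(nm == base |
                   grepl(paste0("^", base, " \\[[^]]*\\]$"), nm))
    if (length(hit) == 0L) {
      if (required) {
        stop("format error: required column '", base,
             "' missing in ", path)
      }
      return(NA_integer_)
    }
    hit[1L]
  }
  unit_scale <- function(header) {
    u <- sub("^.*\\[([^]]*)\\]$", "\\1", header)
    if (identical(u, header)) return(1)  # unitless header token
    switch(u,
           "nm" = 1, "photon" = 1, "au" = 1,
           "um" = 1000, "µm" = 1000, "micron" = 1000,
           stop("unsupported unit '[", u, "]' in column '", header, "'"))
  }
  parse_num <- function(i, integer = FALSE) {
    v <- raw[[i]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !(is.na(v) | v == "" | v == "NA"))
    if (length(bad)) {
      stop("parse error: non-numeric value '", v[bad[1L]], "' in column '",
           nm[i], "', row ", bad[1L])
    }
    out * unit_scale(nm[i])
  }
  ic <- vapply(c("frame", "x", "y", "sigma"), find_col, integer(1L),
               required = TRUE)
  oc <- vapply(c("intensity", "uncertainty"), find_col, integer(1L))
  used <- c(ic, oc[!is.na(oc)])
  extra <- raw[, setdiff(seq_along(nm), used), drop = FALSE]
  extra[] <- lapply(extra, utils::type.convert, as.is = TRUE)
  localization_table(
    frame = parse_num(ic[["frame"]]),
    x = parse_num(ic[["x"]]),
    y = parse_num(ic[["y"]]),
    sigma = parse_num(ic[["sigma"]]),
    intensity = if (!is.na(oc[["intensity"]])) parse_num(oc[["intensity"]]),
    uncertainty = if (!is.na(oc[["uncertainty"]])) parse_num(oc[["uncertainty"]]),
    source_id = basename(path), frame_count = frame_count,
    extra = if (ncol(extra)) extra
  )
}

#' Write a localization CSV
#'
#' Inverse of [read_localizations()]: writes the canonical comma-separated
#' dialect with nm units. Numeric fields are written with 17 significant
#' digits so that a read/write round trip is lossless (bit-identical
#' doubles).
#'
#' @param table A [localization_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  stopifnot(inherits(table, "localization_table"))
  cols <- intersect(names(.loc_headers), names(table))
  out <- data.frame(row.names = seq_len(max(nrow(table), 0L)))
  fmt <- function(v) {
    if (is.integer(v)) as.character(v) else sprintf("%.17g", v)
  }
  headers <- character(0)
  for (cn in cols) {
    out[[cn]] <- if (nrow(table)) fmt(table[[cn]]) else character(0)
    headers <- c(headers, .loc_headers[[cn]])
  }
  extra_cols <- setdiff(names(table), names(.loc_headers))
  for (cn in extra_cols) {
    v <- table[[cn]]
    out[[cn]] <- if (is.double(v)) sprintf("%.17g", v) else as.character(v)
    headers <- c(headers, cn)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(headers, collapse = ","), con)
  if (nrow(out)) {
    utils::write.table(out, con, sep = ",", col.names = FALSE,
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read / write a FRAP time-intensity trace CSV
#'
#' Column headers are `t [s]` and `intensity`.
#'
#' @param path CSV path.
#' @return `read_frap_trace()` returns a [frap_trace()].
#' @export
read_frap_trace <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  tc <- which(names(d) %in% c("t [s]", "t"))
  ic <- which(names(d) == "intensity")
  if (!length(tc) || !length(ic)) {
    stop("FRAP trace needs columns 't [s]' and 'intensity'")
  }
  frap_trace(t = d[[tc[1L]]], intensity = d[[ic[1L]]])
}

#' @rdname read_frap_trace
#' @param trace A [frap_trace()].
#' @export
write_frap_trace <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  d <- data.frame(t = sprintf("%.17g", trace$t),
                  intensity = sprintf("%.17g", trace$intensity))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("t [s],intensity", con)
  utils::write.table(d, con, sep = ",", col.names = FALSE,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a single-channel image as TIFF
#'
#' Thin wrappers over the tiff package storing the image as 32-bit float.
#' Matrices are row = y, column = x.
#'
#' @param path TIFF path.
#' @return `read_image_tiff()` returns a numeric matrix.
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' @rdname read_image_tiff
#' @param image Numeric matrix (non-negative).
#' @param scale Divisor mapping intensities into the [0, 1] storage
#'   range of the TIFF writer; default: the image maximum. Absolute
#'   intensities are therefore not preserved on disk, but all ratio
#'   quantities (including N:C ratios) are unaffected. The scale used
#'   is returned invisibly.
#' @export
write_image_tiff <- function(image, path, scale = NULL) {
  if (any(image < 0)) stop("TIFF storage expects non-negative intensities")
  if (is.null(scale)) scale <- max(image, 1e-12)
  tiff::writeTIFF(pmin(image / scale, 1), path, bits.per.sample = 32L)
  invisible(scale)
}
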