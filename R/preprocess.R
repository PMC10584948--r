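#' Reject out-of-focus localizations by PSF width
#'
#' Keeps localizations whose fitted PSF width sigma is at most
#' `sigma_max`; wider fits indicate out-of-focus molecules. The default
#' threshold is 200 nm. Order is preserved and the input is not
#' modified, so the filter is idempotent.
#'
#' @param table A [localization_table()].
#' @param sigma_max Threshold, nm (> 0); records with `sigma > sigma_max`
#'   are rejected.
#' @return A filtered [localization_table()].
#' @export
filter_by_sigma <- function(table, sigma_max = 200) {
  stopifnot(inherits(table, "localization_table"), sigma_max > 0)
  keep <- table$sigma <= sigma_max
  .subset_table(table, keep)
}

.subset_table <- function(table, idx) {
  df <- as.data.frame(table)[idx, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("localization_table", "data.frame"),
            source_id = attr(table, "source_id"),
            frame_count = attr(table, "frame_count"))
}

#' Estimate lateral drift by temporal-bin cross-correlation
#'
#' Splits the acquisition into `n_bins` contiguous equal frame bins,
#' renders each bin as a 2-D localization histogram at `render_px`
#' nm/pixel over a common extent, and measures the displacement of every
#' bin relative to the first as the peak of their FFT cross-correlation,
#' refined to sub-pixel precision with a 3x3 intensity centroid around
#' the peak. Per-frame drift is linear interpolation between bin
#' midpoints with constant extrapolation at the ends.
#'
#' @param table A [localization_table()].
#' @param n_bins Number of temporal bins (>= 2).
#' @param render_px Rendering pixel size, nm.
#' @param min_per_bin Minimum localizations a bin must contain.
#' @return An object of class `drift_track`: list with `bin_mid_frames`,
#'   `shifts` (n_bins x 2, nm, first row 0), and `per_frame`
#'   (frame_count x 2, nm).
#' @export
estimate_drift <- function(table, n_bins = 10L, render_px = 20,
                           min_per_bin = 50L) {
  stopifnot(inherits(table, "localization_table"),
            n_bins >= 2L, render_px > 0)
  fc <- attr(table, "frame_count")
  if (fc < n_bins) stop("frame_count (", fc, ") < n_bins (", n_bins, ")")
  edges <- round(seq(0L, fc, length.out = n_bins + 1L))
  bin_of <- findInterval(table$frame, edges[-1L] + 0.5) + 1L
  counts <- tabulate(bin_of, n_bins)
  if (any(counts < min_per_bin)) {
    stop("temporal bin with only ", min(counts),
         " localizations (< ", min_per_bin, "); use fewer bins")
  }

  pad <- 4 * render_px
  xr <- range(table$x) + c(-pad, pad)
  yr <- range(table$y) + c(-pad, pad)
  nx <- max(8L, ceiling(diff(xr) / render_px))
  ny <- max(8L, ceiling(diff(yr) / render_px))
  render <- function(idx) {
    ix <- pmin(nx, pmax(1L, ceiling((table$x[idx] - xr[1L]) / render_px)))
    iy <- pmin(ny, pmax(1L, ceiling((table$y[idx] - yr[1L]) / render_px)))
    matrix(tabulate(ix + (iy - 1L) * nx, nx * ny), nx, ny)
  }

  ref <- render(which(bin_of == 1L))
  f_ref <- stats::fft(ref)
  shifts <- matrix(0, n_bins, 2L)
  for (b in seq_len(n_bins)[-1L]) {
    img <- render(which(bin_of == b))
    cc <- Re(stats::fft(Conj(f_ref) * stats::fft(img), inverse = TRUE))
    pk <- arrayInd(which.max(cc), dim(cc))
    # 3x3 centroid refinement with wrapped indexing
    wrap <- function(i, n) ((i - 1L) %% n) + 1L
    ii <- wrap(pk[1L] + (-1:1), nx)
    jj <- wrap(pk[2L] + (-1:1), ny)
    w <- cc[ii, jj] - min(cc[ii, jj])
    if (sum(w) > 0) {
      dx_sub <- sum(w %*% rep(1, 3) * (-1:1)) / sum(w)
      dy_sub <- sum(rep(1, 3) %*% w * (-1:1)) / sum(w)
    } else {
      dx_sub <- dy_sub <- 0
    }
    sx <- pk[1L] - 1L
    sy <- pk[2L] - 1L
    if (sx > nx / 2) sx <- sx - nx
    if (sy > ny / 2) sy <- sy - ny
    shifts[b, ] <- c(sx + dx_sub, sy + dy_sub) * render_px
  }

  mids <- (edges[-(n_bins + 1L)] + edges[-1L] + 1) / 2
  per_frame <- cbind(
    stats::approx(mids, shifts[, 1L], xout = seq_len(fc), rule = 2)$y,
    stats::approx(mids, shifts[, 2L], xout = seq_len(fc), rule = 2)$y)
  structure(list(bin_mid_frames = mids, shifts = shifts,
                 per_frame = per_frame),
            class = "drift_track")
}

#' @export
print.drift_track <- function(x, ...) {
  tot <- x$per_frame[nrow(x$per_frame), ] - x$per_frame[1L, ]
  cat(sprintf("<drift_track> %d bins, recovered span (%.1f, %.1f) nm\n",
              nrow(x$shifts), tot[1L], tot[2L]))
  invisible(x)
}

#' Total drift over the acquisition, assuming a linear trend
#'
#' Least-squares slope of the per-bin shifts against bin midpoint
#' frames, extrapolated over the full movie. This extrapolates the
#' bin-midpoint span (which covers ~(1 - 1/n_bins) of the movie) to the
#' full frame range, so a linear stage drift is estimated without the
#' edge truncation of the per-frame track.
#'
#' @param track A `drift_track` from [estimate_drift()].
#' @param frame_count Total frames; defaults to the per-frame track
#'   length.
#' @return Numeric (dx_total, dy_total), nm.
#' @export
drift_total <- function(track, frame_count = nrow(track$per_frame)) {
  stopifnot(inherits(track, "drift_track"), !is.null(track$shifts))
  f <- track$bin_mid_frames
  c(dx = unname(stats::coef(stats::lm(track$shifts[, 1L] ~ f))[2L]),
    dy = unname(stats::coef(stats::lm(track$shifts[, 2L] ~ f))[2L])) *
    (frame_count - 1)
}

#' Apply a drift correction to a localization table
#'
#' Subtracts the estimated per-frame drift from each localization's
#' coordinates; frame indices, sigma and intensity are untouched.
#'
#' @param table A [localization_table()].
#' @param track A `drift_track` from [estimate_drift()] covering every
#'   frame present in `table`.
#' @return The corrected [localization_table()].
#' @export
apply_drift <- function(table, track) {
  stopifnot(inherits(table, "localization_table"),
            inherits(track, "drift_track"))
  if (nrow(table) == 0L) return(table)
  if (max(table$frame) > nrow(track$per_frame)) {
    stop("drift track covers ", nrow(track$per_frame),
         " frames but table has frame ", max(table$frame))
  }
  out <- table
  out$x <- table$x - track$per_frame[table$frame, 1L]
  out$y <- table$y - track$per_frame[table$frame, 2L]
  out
}

#' Read / write a drift track as CSV (frame, dx, dy)
#' @param path CSV path.
#' @return `read_drift_track()` returns a `drift_track` (with per-frame
#'   shifts only; bin structure is not round-tripped).
#' @export
read_drift_track <- function(path) {
  d <- utils::read.csv(path)
  structure(list(bin_mid_frames = NULL, shifts = NULL,
                 per_frame = cbind(d$dx, d$dy)),
            class = "drift_track")
}

#' @rdname read_drift_track
#' @param track A `drift_track`.
#' @export
write_drift_track <- function(track, path) {
  d <- data.frame(frame = seq_len(nrow(track$per_frame)),
                  dx = track$per_frame[, 1L], dy = track$per_frame[, 2L])
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
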