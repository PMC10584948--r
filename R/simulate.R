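#' Parameters of the synthetic NPC localization field
#'
#' Bundles the generator settings for [simulate_npc_field()]. Defaults
#' emulate a STORM acquisition of an isolated nucleus: a disk-like
#' projected nuclear surface of ~78.4 um^2 carrying ~4 nuclear pore
#' complexes (NPCs) per um^2, each an 8-fold ring of dye-labelled corner
#' sites 107 nm across, imaged over 20,000 frames at a localization
#' precision of sigma_loc = 10.6 nm (a 25 nm FWHM resolution figure read
#' as FWHM = 2.355 sigma).
#'
#' @param roi [nucleus_roi()] bounding the field (default: 64-gon disk of
#'   radius 5 um).
#' @param npc_density Expected pores per um^2.
#' @param ring_diameter NPC scaffold ring diameter, nm.
#' @param n_corners Corner sites per ring (8 for the NPC).
#' @param label_prob Probability that a corner site carries >= 1 dye.
#' @param mean_blinks Mean localizations produced per labelled site.
#' @param blink_law `"poisson1"`: blinks ~ 1 + Poisson(mean_blinks - 1);
#'   `"fixed"`: exactly `mean_blinks` blinks (zero variance; requires an
#'   integer), useful for exact-count checks.
#' @param sigma_loc Localization noise standard deviation, nm.
#' @param bg_rate Background localizations per um^2 (spatially uniform).
#' @param frame_count Number of acquisition frames.
#' @param drift Total (dx, dy) stage drift in nm accumulated over the
#'   movie; spread over frames per `drift_mode`.
#' @param drift_mode `"linear"` (default) or `"sine"` (one full period,
#'   amplitude = `drift`), the latter for stress tests.
#' @param min_separation Minimum distance between NPC centres, nm.
#' @param sigma_range Range of fitted PSF widths for in-focus signal
#'   localizations, nm (uniform draw; default passes a 200 nm filter).
#' @param bg_sigma_range PSF width range for background localizations
#'   (broader, so part of the background is filterable).
#' @param seed Integer seed; same seed + params give bit-identical output.
#' @return A list of class `npc_field_params`.
#' @export
npc_field_params <- function(roi = disk_roi(),
                             npc_density = 4.0,
                             ring_diameter = 107,
                             n_corners = 8L,
                             label_prob = 0.6,
                             mean_blinks = 4.0,
                             blink_law = c("poisson1", "fixed"),
                             sigma_loc = 10.6,
                             bg_rate = 40,
                             frame_count = 20000L,
                             drift = c(0, 0),
                             drift_mode = c("linear", "sine"),
                             min_separation = 150,
                             sigma_range = c(100, 180),
                             bg_sigma_range = c(100, 300),
                             seed = 1L) {
  blink_law <- match.arg(blink_law)
  drift_mode <- match.arg(drift_mode)
  stopifnot(inherits(roi, "nucleus_roi"),
            npc_density >= 0, ring_diameter >= 0, n_corners >= 1L,
            label_prob >= 0, label_prob <= 1,
            mean_blinks >= 1, sigma_loc >= 0, bg_rate >= 0,
            frame_count >= 1L, length(drift) == 2L,
            min_separation >= 0)
  if (blink_law == "fixed" && mean_blinks != round(mean_blinks)) {
    stop("blink_law = 'fixed' requires an integer mean_blinks")
  }
  structure(list(roi = roi, npc_density = npc_density,
                 ring_diameter = ring_diameter,
                 n_corners = as.integer(n_corners),
                 label_prob = label_prob, mean_blinks = mean_blinks,
                 blink_law = blink_law, sigma_loc = sigma_loc,
                 bg_rate = bg_rate, frame_count = as.integer(frame_count),
                 drift = as.numeric(drift), drift_mode = drift_mode,
                 min_separation = min_separation,
                 sigma_range = sigma_range,
                 bg_sigma_range = bg_sigma_range,
                 seed = as.integer(seed)),
            class = "npc_field_params")
}

# Uniform points inside a polygon by rejection from the bounding box.
.runif_in_polygon <- function(n, polygon) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2L))
  bb <- apply(polygon, 2L, range)
  out <- matrix(numeric(0), ncol = 2L)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    cand <- cbind(stats::runif(m, bb[1L, 1L], bb[2L, 1L]),
                  stats::runif(m, bb[1L, 2L], bb[2L, 2L]))
    out <- rbind(out, cand[.points_in_polygon(cand, polygon), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# Dart-throwing: n points in polygon, pairwise >= min_sep apart.
# Candidates are drawn in batches; acceptance stays sequential so the
# process matches one-at-a-time dart throwing exactly in distribution.
.sample_npc_centers <- function(n, polygon, min_sep, max_tries = 200L) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2L))
  pts <- matrix(NA_real_, n, 2L)
  k <- 0L
  tries <- 0L
  while (k < n) {
    if (tries >= max_tries * n) {
      stop("could not place ", n, " NPC centers at min_separation ",
           min_sep, " nm; lower npc_density or min_separation")
    }
    cand <- .runif_in_polygon(max(n - k, 16L), polygon)
    for (ci in seq_len(nrow(cand))) {
      tries <- tries + 1L
      ok <- k == 0L ||
        min((pts[seq_len(k), 1L] - cand[ci, 1L])^2 +
              (pts[seq_len(k), 2L] - cand[ci, 2L])^2) >= min_sep^2
      if (ok) {
        k <- k + 1L
        pts[k, ] <- cand[ci, ]
        if (k == n) break
      }
    }
  }
  pts
}

# Per-frame drift offsets, frames 1..F. Linear ramps from 0 to `total`;
# sine runs one full period with amplitude `total`.
.drift_per_frame <- function(frame_count, total, mode) {
  f <- seq_len(frame_count)
  frac <- if (frame_count == 1L) 0 else (f - 1) / (frame_count - 1)
  shape <- switch(mode, linear = frac, sine = sin(2 * pi * frac))
  cbind(dx = total[1L] * shape, dy = total[2L] * shape)
}

#' Simulate an NPC localization field with ground truth
#'
#' Generates a blinking-emitter localization table over a nuclear ROI:
#' NPC centres are placed by dart throwing (Poisson count thinned to a
#' minimum separation), each pore carries `n_corners` sites equally
#' spaced on a ring at a random rotation, each site is labelled with
#' probability `label_prob` and emits a random number of blinks; every
#' blink is displaced by isotropic Gaussian localization noise, assigned
#' a uniform random frame and a fitted PSF width, and shifted by the
#' injected per-frame drift. Background localizations are complete
#' spatial randomness over the ROI.
#'
#' @param params An [npc_field_params()].
#' @return A list with `table` (a [localization_table()]) and `truth`, a
#'   list of class `simulation_truth` holding `npc_centers` (matrix, nm),
#'   `emitter_positions` (per-NPC matrices of labelled corner sites),
#'   `blink_counts` (per-NPC integer vectors, aligned with
#'   `emitter_positions` rows), `injected_drift` (frame x 2 matrix, nm)
#'   and `background_count`.
#' @export
simulate_npc_field <- function(params = npc_field_params()) {
  stopifnot(inherits(params, "npc_field_params"))
  set.seed(params$seed)
  p <- params
  poly <- p$roi$polygon
  area <- p$roi$area

  n_npc <- stats::rpois(1L, p$npc_density * area)
  centers <- .sample_npc_centers(n_npc, poly, p$min_separation)

  emitters <- vector("list", n_npc)
  blink_counts <- vector("list", n_npc)
  xs <- ys <- list()
  r <- p$ring_diameter / 2
  for (i in seq_len(n_npc)) {
    rot <- stats::runif(1L, 0, 2 * pi)
    th <- rot + 2 * pi * (seq_len(p$n_corners) - 1L) / p$n_corners
    sites <- cbind(centers[i, 1L] + r * cos(th),
                   centers[i, 2L] + r * sin(th))
    labelled <- stats::runif(p$n_corners) < p$label_prob
    sites <- sites[labelled, , drop = FALSE]
    nb <- nrow(sites)
    b <- if (nb == 0L) integer(0)
    else if (p$blink_law == "fixed") rep.int(as.integer(p$mean_blinks), nb)
    else 1L + stats::rpois(nb, p$mean_blinks - 1)
    emitters[[i]] <- sites
    blink_counts[[i]] <- b
    if (sum(b) > 0L) {
      xs[[length(xs) + 1L]] <- rep(sites[, 1L], b)
      ys[[length(ys) + 1L]] <- rep(sites[, 2L], b)
    }
  }
  sx <- unlist(xs, use.names = FALSE)
  sy <- unlist(ys, use.names = FALSE)
  n_sig <- length(sx)
  if (n_sig > 0L) {
    sx <- sx + stats::rnorm(n_sig, 0, p$sigma_loc)
    sy <- sy + stats::rnorm(n_sig, 0, p$sigma_loc)
  }

  n_bg <- stats::rpois(1L, p$bg_rate * area)
  bg <- .runif_in_polygon(n_bg, poly)

  x <- c(sx, bg[, 1L])
  y <- c(sy, bg[, 2L])
  n <- length(x)
  frame <- if (n) sample.int(p$frame_count, n, replace = TRUE) else integer(0)
  sigma <- c(stats::runif(n_sig, p$sigma_range[1L], p$sigma_range[2L]),
             stats::runif(n_bg, p$bg_sigma_range[1L], p$bg_sigma_range[2L]))

  dr <- .drift_per_frame(p$frame_count, p$drift, p$drift_mode)
  if (n) {
    x <- x + dr[frame, 1L]
    y <- y + dr[frame, 2L]
  }

  table <- localization_table(frame = frame, x = x, y = y, sigma = sigma,
                              source_id = sprintf("sim-seed%d", p$seed),
                              frame_count = p$frame_count)
  truth <- structure(list(npc_centers = centers,
                          emitter_positions = emitters,
                          blink_counts = blink_counts,
                          injected_drift = dr,
                          background_count = n_bg),
                     class = "simulation_truth")
  list(table = table, truth = truth)
}

#' Simulate a FRAP recovery trace
#'
#' Exponential association recovery sampled on a time grid with additive
#' Gaussian noise: `I(t) = f0 + (plateau - f0) * (1 - exp(-k t)) + e_t`.
#' The default grid matches a post-bleach series acquired every 10 s out
#' to 500 s.
#'
#' @param f0 Normalized post-bleach floor.
#' @param plateau Recovery asymptote (> `f0`).
#' @param k Recovery rate, 1/s (> 0).
#' @param t_grid Sampling times, s.
#' @param noise_sd Additive Gaussian noise s.d.
#' @param seed Integer seed.
#' @return A [frap_trace()].
#' @export
simulate_frap_trace <- function(f0 = 0.2, plateau = 1, k = 0.01,
                                t_grid = seq(0, 500, by = 10),
                                noise_sd = 0, seed = 1L) {
  if (k <= 0) stop("recovery rate k must be positive")
  if (plateau <= f0) stop("plateau must exceed the post-bleach floor f0")
  set.seed(seed)
  mu <- f0 + (plateau - f0) * (1 - exp(-k * t_grid))
  frap_trace(t = t_grid, intensity = mu + stats::rnorm(length(t_grid), 0, noise_sd))
}

#' Simulate an intensity image with nucleus and cell masks
#'
#' Builds a pixel image in which the nucleus and the surrounding
#' cytoplasm have constant mean intensities plus optional Gaussian noise;
#' intended as ground truth for nuclear-to-cytoplasmic ratio
#' quantification. The default geometry is a centred nuclear disk inside
#' a larger cell disk.
#'
#' @param nuc_mean,cyto_mean Mean intensity (a.u.) inside the nucleus and
#'   in the cytoplasm (cell minus nucleus).
#' @param geometry List with `dim` (c(rows, cols)) and either logical
#'   mask matrices `nucleus`/`cell` or radii `nuc_radius`/`cell_radius`
#'   in pixels for centred disks.
#' @param noise_sd Additive Gaussian noise s.d.
#' @param seed Integer seed.
#' @return List with `image`, `nucleus_mask`, `cell_mask` (matrices).
#' @export
simulate_nc_image <- function(nuc_mean = 2, cyto_mean = 1,
                              geometry = list(dim = c(64L, 64L),
                                              nuc_radius = 12,
                                              cell_radius = 28),
                              noise_sd = 0, seed = 1L) {
  d <- geometry$dim
  if (!is.null(geometry$nucleus)) {
    nuc <- geometry$nucleus
    cell <- geometry$cell
  } else {
    cy <- (d[1L] + 1) / 2
    cx <- (d[2L] + 1) / 2
    rr <- outer(seq_len(d[1L]) - cy, seq_len(d[2L]) - cx,
                function(a, b) sqrt(a^2 + b^2))
    nuc <- rr <= geometry$nuc_radius
    cell <- rr <= geometry$cell_radius
  }
  if (!any(nuc)) stop("nucleus mask is empty")
  if (!any(cell)) stop("cell mask is empty")
  if (any(nuc & !cell)) stop("nucleus mask must be contained in cell mask")
  set.seed(seed)
  img <- matrix(0, nrow(nuc), ncol(nuc))
  img[cell & !nuc] <- cyto_mean
  img[nuc] <- nuc_mean
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                                        nrow(img))
  list(image = img, nucleus_mask = nuc, cell_mask = cell)
}
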