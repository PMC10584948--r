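#' Clustering configuration
#'
#' The single tunable of the pore-extraction step is the minimal number
#' of points per cluster; the neighbourhood size used for density
#' estimation (`min_samples`) is tied to it unless overridden.
#'
#' @param min_cluster_size Minimum localizations per cluster (>= 2).
#' @param min_samples Core-distance neighbourhood size; default
#'   `min_cluster_size`.
#' @return A list of class `clustering_config`.
#' @export
clustering_config <- function(min_cluster_size, min_samples = min_cluster_size) {
  min_cluster_size <- as.integer(min_cluster_size)
  min_samples <- as.integer(min_samples)
  stopifnot(min_cluster_size >= 2L, min_samples >= 1L)
  structure(list(min_cluster_size = min_cluster_size,
                 min_samples = min_samples, noise_label = 0L),
            class = "clustering_config")
}

#' Cluster localizations into candidate NPCs
#'
#' Runs HDBSCAN on the (x, y) coordinates of a localization table.
#'
#' @param table A [localization_table()] (non-empty).
#' @param cfg A [clustering_config()].
#' @return Integer labels, one per localization; 0 = noise. If the table
#'   holds fewer points than `min_cluster_size`, everything is noise.
#' @export
cluster_localizations <- function(table, cfg) {
  stopifnot(inherits(table, "localization_table"),
            inherits(cfg, "clustering_config"))
  if (nrow(table) == 0L) stop("cannot cluster an empty localization table")
  hdbscan_labels(cbind(table$x, table$y),
                 min_cluster_size = cfg$min_cluster_size,
                 min_samples = cfg$min_samples)
}

#' Summarize one cluster as an NPC candidate
#'
#' Computes the centroid, the number of member localizations and the
#' cluster diameter, defined as twice the mean Euclidean distance of the
#' members from the centroid. This definition is exact for points evenly
#' spaced on an ideal circle and remains well defined for dot-like
#' clusters; under localization noise it overestimates a ring's diameter
#' by roughly sigma^2 / radius.
#'
#' @param table A [localization_table()].
#' @param member_indices Row indices of the cluster members (>= 2).
#' @return A list of class `npc_cluster`: `member_indices`, `centroid`
#'   (nm), `n_sml`, `diameter` (nm).
#' @export
summarize_cluster <- function(table, member_indices) {
  if (length(member_indices) < 2L) {
    stop("degenerate cluster: need >= 2 members, got ",
         length(member_indices))
  }
  px <- table$x[member_indices]
  py <- table$y[member_indices]
  cx <- mean(px)
  cy <- mean(py)
  d <- 2 * mean(sqrt((px - cx)^2 + (py - cy)^2))
  structure(list(member_indices = member_indices, centroid = c(cx, cy),
                 n_sml = length(member_indices), diameter = d),
            class = "npc_cluster")
}

# All clusters from a label vector, as a data.frame (one row per cluster).
.cluster_table <- function(table, labels) {
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) {
    return(data.frame(cluster_id = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), n_sml = integer(0),
                      diameter_nm = numeric(0)))
  }
  rows <- lapply(ids, function(id) {
    cl <- summarize_cluster(table, which(labels == id))
    data.frame(cluster_id = id, centroid_x = cl$centroid[1L],
               centroid_y = cl$centroid[2L], n_sml = cl$n_sml,
               diameter_nm = cl$diameter)
  })
  do.call(rbind, rows)
}

#' Per-nucleus summary statistics
#'
#' NPC density and localization (SML) density are both computed over the
#' nuclear area: all localization events, clustered or noise, count
#' toward SML density, while per-cluster means are taken over clusters
#' only. When no ROI is supplied the area defaults to the convex hull of
#' the localizations.
#'
#' @param table A [localization_table()].
#' @param clusters Data.frame from clustering (columns `n_sml`,
#'   `diameter_nm`), or a list of `npc_cluster` objects.
#' @param roi Optional [nucleus_roi()].
#' @return A list of class `nucleus_stats`: `n_npc`, `area` (um^2),
#'   `npc_density` (/um^2), `sml_density` (/um^2),
#'   `mean_sml_per_cluster`, `mean_diameter` (nm; the means are `NA`
#'   when there are no clusters).
#' @export
nucleus_stats <- function(table, clusters, roi = NULL) {
  stopifnot(inherits(table, "localization_table"))
  if (is.list(clusters) && !is.data.frame(clusters)) {
    clusters <- data.frame(
      n_sml = vapply(clusters, `[[`, numeric(1L), "n_sml"),
      diameter_nm = vapply(clusters, `[[`, numeric(1L), "diameter"))
  }
  roi <- if (is.null(roi)) hull_roi(table) else roi
  area <- roi$area
  if (area <= 0) stop("nuclear area is zero")
  n_npc <- nrow(clusters)
  structure(list(
    n_npc = n_npc,
    area = area,
    npc_density = n_npc / area,
    sml_density = nrow(table) / area,
    mean_sml_per_cluster = if (n_npc) mean(clusters$n_sml) else NA_real_,
    mean_diameter = if (n_npc) mean(clusters$diameter_nm) else NA_real_),
    class = "nucleus_stats")
}

#' @export
print.nucleus_stats <- function(x, ...) {
  cat(sprintf(paste0("<nucleus_stats> %d NPCs over %.1f um^2 ",
                     "(%.2f /um^2); SML %.1f /um^2; ",
                     "%.1f SML/cluster; diameter %.1f nm\n"),
              x$n_npc, x$area, x$npc_density, x$sml_density,
              x$mean_sml_per_cluster, x$mean_diameter))
  invisible(x)
}

# Greedy nearest-first matching of recovered centroids to true centers
# within match_radius; each side matched at most once.
.match_centers <- function(recovered, truth, match_radius) {
  nr <- nrow(recovered)
  nt <- nrow(truth)
  if (nr == 0L || nt == 0L) return(0L)
  d2 <- outer(recovered[, 1L], truth[, 1L], "-")^2 +
    outer(recovered[, 2L], truth[, 2L], "-")^2
  ok <- which(d2 <= match_radius^2)
  if (!length(ok)) return(0L)
  ord <- ok[order(d2[ok])]
  used_r <- logical(nr)
  used_t <- logical(nt)
  matched <- 0L
  for (idx in ord) {
    i <- ((idx - 1L) %% nr) + 1L
    j <- ((idx - 1L) %/% nr) + 1L
    if (!used_r[i] && !used_t[j]) {
      used_r[i] <- TRUE
      used_t[j] <- TRUE
      matched <- matched + 1L
    }
  }
  matched
}

#' Monte-Carlo tuning of the minimum cluster size
#'
#' Chooses the HDBSCAN `min_cluster_size` by simulation against known
#' ground truth: for each candidate and each replicate field, the
#' standard preprocessing and clustering are run, recovered centroids
#' are greedily matched to true NPC centres within `match_radius`, and
#' the candidate maximizing mean F1 (harmonic mean of precision and
#' recall) wins; ties break toward the smaller candidate.
#'
#' @param sim_params An [npc_field_params()] describing the emitter
#'   statistics to tune against (its `seed` is ignored).
#' @param candidates Integer vector of minimum cluster sizes.
#' @param n_reps Simulated fields per candidate.
#' @param match_radius Matching tolerance, nm.
#' @param seed Integer seed for the replicate fields.
#' @param sigma_max PSF-width filter applied before clustering.
#' @return List of class `mcs_optimization`: `best` (integer), `scores`
#'   (data.frame m / precision / recall / f1), `all_zero` flag.
#' @export
optimize_min_cluster_size <- function(sim_params = npc_field_params(),
                                      candidates = 4:16,
                                      n_reps = 5L, match_radius = 75,
                                      seed = 1L, sigma_max = 200) {
  stopifnot(length(candidates) >= 1L, n_reps >= 1L)
  candidates <- sort(unique(as.integer(candidates)))
  prec <- rec <- f1 <- matrix(NA_real_, n_reps, length(candidates))
  for (r in seq_len(n_reps)) {
    sp <- sim_params
    sp$seed <- as.integer(seed + 1000L * r)
    sim <- simulate_npc_field(sp)
    tab <- filter_by_sigma(sim$table, sigma_max)
    truth <- sim$truth$npc_centers
    for (ci in seq_along(candidates)) {
      labels <- hdbscan_labels(cbind(tab$x, tab$y), candidates[ci])
      cl <- .cluster_table(tab, labels)
      nr <- nrow(cl)
      m <- .match_centers(cbind(cl$centroid_x, cl$centroid_y), truth,
                          match_radius)
      p <- if (nr) m / nr else 0
      re <- if (nrow(truth)) m / nrow(truth) else 0
      prec[r, ci] <- p
      rec[r, ci] <- re
      f1[r, ci] <- if (p + re > 0) 2 * p * re / (p + re) else 0
    }
  }
  scores <- data.frame(m = candidates,
                       precision = colMeans(prec),
                       recall = colMeans(rec),
                       f1 = colMeans(f1))
  all_zero <- all(scores$f1 == 0)
  best <- if (all_zero) {
    warning("all candidate cluster sizes scored F1 = 0; ",
            "returning the smallest candidate")
    candidates[1L]
  } else {
    # ties toward smaller m (within numerical tolerance)
    candidates[which(scores$f1 >= max(scores$f1) - 1e-12)[1L]]
  }
  structure(list(best = best, scores = scores, all_zero = all_zero),
            class = "mcs_optimization")
}

#' @export
print.mcs_optimization <- function(x, ...) {
  cat(sprintf("<mcs_optimization> best min_cluster_size = %d\n", x$best))
  print(x$scores, row.names = FALSE, digits = 3L)
  invisible(x)
}

#' Pipeline configuration
#'
#' One shared configuration for a whole comparison: both groups of a
#' two-group experiment must be processed under identical input
#' parameters.
#'
#' @param min_cluster_size,min_samples See [clustering_config()].
#' @param sigma_max PSF-width rejection threshold, nm.
#' @param drift_correct Estimate and remove drift before filtering.
#' @param n_bins,render_px Drift-estimation settings
#'   (see [estimate_drift()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_cluster_size = 10L,
                            min_samples = min_cluster_size,
                            sigma_max = 200, drift_correct = TRUE,
                            n_bins = 10L, render_px = 20) {
  structure(list(min_cluster_size = as.integer(min_cluster_size),
                 min_samples = as.integer(min_samples),
                 sigma_max = sigma_max,
                 drift_correct = isTRUE(drift_correct),
                 n_bins = as.integer(n_bins), render_px = render_px),
            class = "pipeline_config")
}

#' Run the full per-nucleus NPC quantification pipeline
#'
#' Applies, identically to every nucleus: drift correction (optional) ->
#' PSF-width filtering -> HDBSCAN clustering -> per-cluster and
#' per-nucleus statistics.
#'
#' @param tables A list of [localization_table()] objects, or a
#'   character vector of CSV paths read with [read_localizations()].
#' @param cfg A [pipeline_config()].
#' @param rois Optional list of [nucleus_roi()] (or `NULL` entries),
#'   recycled `NULL` when absent.
#' @param groups Optional character vector of group labels per nucleus.
#' @param ids Optional nucleus identifiers (default: source ids or
#'   sequence numbers).
#' @return List of class `npc_pipeline_result`: `per_nucleus`
#'   (data.frame: nucleus_id, group, n_npc, area_um2, npc_density,
#'   sml_density, mean_sml_per_cluster, mean_diameter_nm), `per_cluster`
#'   (data.frame keyed by nucleus_id), and `manifest` (config + package
#'   version).
#' @export
run_npc_pipeline <- function(tables, cfg = pipeline_config(), rois = NULL,
                             groups = NULL, ids = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.character(tables)) tables <- lapply(tables, read_localizations)
  n <- length(tables)
  if (n < 1L) stop("need at least one nucleus")
  if (is.null(rois)) rois <- vector("list", n)
  if (is.null(groups)) groups <- rep(NA_character_, n)
  if (is.null(ids)) {
    ids <- vapply(seq_len(n), function(i) {
      s <- attr(tables[[i]], "source_id")
      if (is.null(s) || !nzchar(s)) sprintf("nucleus%02d", i) else s
    }, character(1L))
  }
  ids <- make.unique(ids)
  ccfg <- clustering_config(cfg$min_cluster_size, cfg$min_samples)

  per_nucleus <- vector("list", n)
  per_cluster <- vector("list", n)
  for (i in seq_len(n)) {
    tab <- tables[[i]]
    res <- tryCatch({
      if (cfg$drift_correct) {
        tab <- apply_drift(tab, estimate_drift(tab, cfg$n_bins,
                                               cfg$render_px))
      }
      tab <- filter_by_sigma(tab, cfg$sigma_max)
      labels <- cluster_localizations(tab, ccfg)
      cl <- .cluster_table(tab, labels)
      st <- nucleus_stats(tab, cl, rois[[i]])
      list(cl = cl, st = st)
    }, error = function(e) {
      stop("nucleus '", ids[i], "': ", conditionMessage(e), call. = FALSE)
    })
    st <- res$st
    per_nucleus[[i]] <- data.frame(
      nucleus_id = ids[i], group = groups[i], n_npc = st$n_npc,
      area_um2 = st$area, npc_density = st$npc_density,
      sml_density = st$sml_density,
      mean_sml_per_cluster = st$mean_sml_per_cluster,
      mean_diameter_nm = st$mean_diameter)
    if (nrow(res$cl)) {
      per_cluster[[i]] <- cbind(nucleus_id = ids[i], res$cl)
    }
  }
  structure(list(
    per_nucleus = do.call(rbind, per_nucleus),
    per_cluster = if (length(Filter(Negate(is.null), per_cluster)))
      do.call(rbind, Filter(Negate(is.null), per_cluster))
    else NULL,
    manifest = list(config = unclass(cfg),
                    package_version = as.character(utils::packageVersion("npcquant")),
                    timestamp = NA_character_)),
    class = "npc_pipeline_result")
}

#' Write pipeline outputs as tidy CSVs plus a JSON manifest
#'
#' @param result An `npc_pipeline_result`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  stopifnot(inherits(result, "npc_pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$per_nucleus, file.path(dir, "per_nucleus.csv"),
                   row.names = FALSE)
  if (!is.null(result$per_cluster)) {
    utils::write.csv(result$per_cluster, file.path(dir, "per_cluster.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
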