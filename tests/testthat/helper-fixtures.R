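# Shared fixtures and small oracles used across test files.

# A tiny valid localization table.
tiny_table <- function(n = 5L, seed = 1L) {
  set.seed(seed)
  localization_table(
    frame = sample.int(100L, n, replace = TRUE),
    x = runif(n, 0, 5000), y = runif(n, 0, 5000),
    sigma = runif(n, 110, 190),
    intensity = rpois(n, 500), uncertainty = runif(n, 5, 20),
    source_id = "tiny", frame_count = 100L)
}

# Adjusted Rand index between two label vectors (noise treated as its
# own class). Independent of any clustering internals.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n <- length(a)
  expected <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

# Reference HDBSCAN labels from scikit-learn, via the system python.
# Returns NULL if python/sklearn is unavailable.
sklearn_hdbscan <- function(xy, min_cluster_size, min_samples = min_cluster_size) {
  csv <- tempfile(fileext = ".csv")
  on.exit(unlink(csv))
  utils::write.csv(data.frame(x = xy[, 1], y = xy[, 2]), csv,
                   row.names = FALSE)
  code <- sprintf(paste0(
    "import warnings; warnings.filterwarnings('ignore')\n",
    "import pandas as pd\n",
    "from sklearn.cluster import HDBSCAN\n",
    "d = pd.read_csv('%s')\n",
    "h = HDBSCAN(min_cluster_size=%d, min_samples=%d).fit(d[['x','y']].values)\n",
    "print(' '.join(map(str, h.labels_)))"),
    csv, min_cluster_size, min_samples)
  out <- tryCatch(
    suppressWarnings(system2("python", c("-c", shQuote(code)),
                             stdout = TRUE, stderr = FALSE)),
    error = function(e) NULL)
  if (is.null(out) || !length(out)) return(NULL)
  labs <- suppressWarnings(as.integer(strsplit(out[length(out)], " ")[[1]]))
  if (any(is.na(labs))) return(NULL)
  labs
}

# Expected mean radial distance of a ring convolved with isotropic
# Gaussian noise (Rice distribution mean), by numerical integration.
rice_mean <- function(nu, sigma) {
  f <- function(x) {
    z <- x * nu / sigma^2
    x * (x / sigma^2) * exp(-(x^2 + nu^2) / (2 * sigma^2) + z) *
      besselI(z, 0, expon.scaled = TRUE)
  }
  stats::integrate(f, 0, nu + 30 * sigma)$value
}

# Match-score (precision, recall, F1) of recovered centroids against
# true centers, using the package's greedy matcher.
match_f1 <- function(cluster_df, truth, match_radius = 75) {
  m <- npcquant:::.match_centers(
    cbind(cluster_df$centroid_x, cluster_df$centroid_y), truth,
    match_radius)
  p <- if (nrow(cluster_df)) m / nrow(cluster_df) else 0
  r <- if (nrow(truth)) m / nrow(truth) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}
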