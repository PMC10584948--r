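test_that("cluster summaries are exact on analytic configurations", {
  # 8 points equally spaced on a circle of radius 50
  th <- 2 * pi * (0:7) / 8
  tab <- localization_table(frame = rep(1L, 8), x = 300 + 50 * cos(th),
                            y = -200 + 50 * sin(th), sigma = rep(150, 8))
  cl <- summarize_cluster(tab, 1:8)
  expect_equal(cl$centroid, c(300, -200), tolerance = 1e-9)
  expect_equal(cl$diameter, 100, tolerance = 1e-9)
  expect_equal(cl$n_sml, 8L)
  # two points 60 nm apart
  tab2 <- localization_table(frame = c(1L, 1L), x = c(0, 60), y = c(0, 0),
                             sigma = c(150, 150))
  cl2 <- summarize_cluster(tab2, 1:2)
  expect_equal(cl2$centroid, c(30, 0))
  expect_equal(cl2$diameter, 60)
  expect_error(summarize_cluster(tab2, 1L), "degenerate")
})

test_that("mean diameter of noisy rings matches the ring-Gaussian oracle", {
  # isolated, fully labelled rings so the radial statistic is measured
  # free of labeling asymmetry and pore-pore merging
  p <- npc_field_params(npc_density = 1.5, min_separation = 400,
                        label_prob = 1, bg_rate = 0, seed = 11)
  sim <- simulate_npc_field(p)
  tab <- filter_by_sigma(sim$table)
  labels <- cluster_localizations(tab, clustering_config(10L))
  cl <- npcquant:::.cluster_table(tab, labels)
  expect_gte(nrow(cl), 100L)
  expected <- 2 * rice_mean(nu = 107 / 2, sigma = 10.6)
  expect_lt(abs(mean(cl$diameter_nm) - expected), 5)
})

test_that("nucleus statistics follow their defining arithmetic", {
  tab <- tiny_table(1000L, seed = 2)
  roi <- nucleus_roi(cbind(c(0, 1e4, 1e4, 0), c(0, 0, 1e4, 1e4)))  # 100 um^2
  clusters <- data.frame(n_sml = rep(20L, 10), diameter_nm = rep(110, 10))
  st <- nucleus_stats(tab, clusters, roi)
  expect_equal(st$npc_density, 0.10)
  expect_equal(st$sml_density, 10)
  expect_equal(st$mean_sml_per_cluster, 20)
  # zero clusters: densities defined, means marked undefined
  st0 <- nucleus_stats(tab, clusters[0, ], roi)
  expect_equal(st0$n_npc, 0L)
  expect_equal(st0$npc_density, 0)
  expect_true(is.na(st0$mean_sml_per_cluster))
  expect_true(is.na(st0$mean_diameter))
})

test_that("noise localizations count toward SML density but not cluster means", {
  set.seed(5)
  xy <- rbind(cbind(rnorm(30, 0, 12), rnorm(30, 0, 12)),
              cbind(rnorm(30, 1500, 12), rnorm(30, 1500, 12)),
              cbind(runif(40, -500, 2000), runif(40, -500, 2000)))
  tab <- localization_table(frame = rep(1L, 100), x = xy[, 1], y = xy[, 2],
                            sigma = rep(150, 100))
  labels <- cluster_localizations(tab, clustering_config(10L))
  cl <- npcquant:::.cluster_table(tab, labels)
  roi <- nucleus_roi(cbind(c(-500, 2000, 2000, -500),
                           c(-500, -500, 2000, 2000)))
  st <- nucleus_stats(tab, cl, roi)
  expect_equal(st$sml_density * roi$area, 100)  # all events, incl. noise
  # per-cluster mean is computed over clustered points only
  expect_equal(st$mean_sml_per_cluster,
               mean(tabulate(labels[labels > 0L])))
  expect_lt(sum(cl$n_sml), 100)  # some localizations stayed noise
})

test_that("single-candidate optimization degenerates to that candidate", {
  p <- npc_field_params(roi = disk_roi(1500), seed = 2)
  opt <- optimize_min_cluster_size(p, candidates = 10L, n_reps = 1L,
                                   seed = 4)
  expect_equal(opt$best, 10L)
  expect_equal(nrow(opt$scores), 1L)
})

test_that("deterministic 24-SML pores give perfect scores and smallest-m ties", {
  roi <- disk_roi(radius = 2500)
  p <- npc_field_params(roi = roi, npc_density = 12 / roi$area,
                        label_prob = 1, mean_blinks = 3,
                        blink_law = "fixed", bg_rate = 0,
                        min_separation = 400, seed = 7)
  opt <- optimize_min_cluster_size(p, candidates = c(6L, 12L, 24L),
                                   n_reps = 2L, seed = 9)
  expect_equal(opt$scores$f1, rep(1, 3), tolerance = 1e-12)
  expect_equal(opt$best, 6L)  # ties break toward the smallest candidate
  # exhaustive check on one deterministic field: any m in 4..24 is perfect
  sim <- simulate_npc_field(p)
  tab <- filter_by_sigma(sim$table)
  for (m in c(4L, 9L, 17L, 24L)) {
    labels <- hdbscan_labels(cbind(tab$x, tab$y), m)
    cl <- npcquant:::.cluster_table(tab, labels)
    sc <- match_f1(cl, sim$truth$npc_centers)
    expect_equal(unname(sc["f1"]), 1.0)
  }
})

test_that("scaling coordinates scales diameters by c and densities by 1/c^2", {
  p <- npc_field_params(roi = disk_roi(2500), seed = 14)
  sim <- simulate_npc_field(p)
  tab <- filter_by_sigma(sim$table)
  cc <- 2  # a power of two keeps the scaling exact in floating point
  scaled <- tab
  scaled$x <- tab$x * cc
  scaled$y <- tab$y * cc
  lab1 <- cluster_localizations(tab, clustering_config(7L))
  lab2 <- cluster_localizations(scaled, clustering_config(7L))
  expect_equal(adjusted_rand(lab1, lab2), 1.0)  # same partition
  cl1 <- npcquant:::.cluster_table(tab, lab1)
  cl2 <- npcquant:::.cluster_table(scaled, lab2)
  expect_equal(cl2$diameter_nm, cl1$diameter_nm * cc, tolerance = 1e-9)
  st1 <- nucleus_stats(tab, cl1)
  st2 <- nucleus_stats(scaled, cl2)
  expect_equal(st2$npc_density, st1$npc_density / cc^2, tolerance = 1e-9)
})

test_that("pipeline is deterministic and preserves group structure", {
  sims <- lapply(1:4, function(i)
    simulate_npc_field(npc_field_params(roi = disk_roi(2000),
                                        seed = 40 + i)))
  tabs <- lapply(sims, `[[`, "table")
  cfg <- pipeline_config(min_cluster_size = 7L, drift_correct = FALSE)
  res <- run_npc_pipeline(c(tabs, tabs[1]), cfg,
                          groups = c("UD", "UD", "DF", "DF", "UD"))
  expect_equal(nrow(res$per_nucleus), 5L)
  expect_equal(res$per_nucleus$group, c("UD", "UD", "DF", "DF", "UD"))
  # identical input files give identical stats rows
  dup <- res$per_nucleus[c(1, 5), -1]
  for (cn in setdiff(names(dup), "group")) {
    expect_identical(dup[[cn]][1], dup[[cn]][2])
  }
  expect_equal(res$manifest$config$min_cluster_size, 7L)
  # per-cluster table keys resolve to per-nucleus rows
  expect_true(all(res$per_cluster$nucleus_id %in% res$per_nucleus$nucleus_id))
})

test_that("pipeline writes tidy CSVs and a manifest", {
  sim <- simulate_npc_field(npc_field_params(roi = disk_roi(1500), seed = 3))
  res <- run_npc_pipeline(list(sim$table),
                          pipeline_config(min_cluster_size = 7L,
                                          drift_correct = FALSE))
  d <- withr::local_tempdir()
  write_pipeline_result(res, d)
  expect_true(file.exists(file.path(d, "per_nucleus.csv")))
  expect_true(file.exists(file.path(d, "per_cluster.csv")))
  back <- utils::read.csv(file.path(d, "per_nucleus.csv"))
  expect_equal(back$n_npc, res$per_nucleus$n_npc)
  man <- jsonlite::fromJSON(file.path(d, "manifest.json"))
  expect_equal(man$config$sigma_max, 200)
})
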