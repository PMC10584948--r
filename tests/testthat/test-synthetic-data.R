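test_that("zero-rate field is empty and zero cases are consistent", {
  sim <- simulate_npc_field(npc_field_params(npc_density = 0, bg_rate = 0,
                                             seed = 1))
  expect_equal(nrow(sim$table), 0L)
  expect_equal(nrow(sim$truth$npc_centers), 0L)
  expect_equal(sim$truth$background_count, 0L)
})

test_that("fixed blink law with full labeling gives exact counts", {
  # force ~10 pores on a small disk; every corner labeled, exactly 3 blinks
  roi <- disk_roi(radius = 2500)
  p <- npc_field_params(roi = roi, npc_density = 10 / roi$area,
                        label_prob = 1, mean_blinks = 3,
                        blink_law = "fixed", bg_rate = 0,
                        min_separation = 400, seed = 7)
  sim <- simulate_npc_field(p)
  n_npc <- nrow(sim$truth$npc_centers)
  expect_equal(nrow(sim$table), n_npc * 8L * 3L)
  expect_true(all(unlist(sim$truth$blink_counts) == 3L))
})

test_that("same seed gives bit-identical output; bookkeeping always balances", {
  p <- npc_field_params(roi = disk_roi(radius = 2000), seed = 11)
  a <- simulate_npc_field(p)
  b <- simulate_npc_field(p)
  expect_identical(a$table, b$table)
  expect_identical(a$truth$npc_centers, b$truth$npc_centers)
  for (s in 1:5) {
    sim <- simulate_npc_field(npc_field_params(roi = disk_roi(radius = 2000),
                                               seed = s))
    expect_equal(nrow(sim$table),
                 sum(unlist(sim$truth$blink_counts)) +
                   sim$truth$background_count)
    # all centers inside the ROI and pairwise >= min_separation
    cen <- sim$truth$npc_centers
    if (nrow(cen) >= 2L) {
      expect_gte(min(dist(cen)), 150)
    }
    expect_true(all(npcquant:::.points_in_polygon(cen, disk_roi(2000)$polygon)))
  }
})

test_that("realized NPC counts and SML per pore match generator moments", {
  # Poisson count check over seeds on a smaller disk (faster, same law)
  roi <- disk_roi(radius = 2500)
  lambda <- 4.0 * roi$area
  counts <- vapply(1:40, function(s)
    nrow(simulate_npc_field(npc_field_params(roi = roi, bg_rate = 0,
                                             seed = s))$truth$npc_centers),
    numeric(1))
  # dart-throwing thins Poisson slightly; mean must sit within 3 sd of
  # the target rate's sampling band
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 40) + 0.05 * lambda)
  # SML per labeled pore: n_corners * label_prob * mean_blinks
  sml_per_npc <- unlist(lapply(1:40, function(s) {
    tr <- simulate_npc_field(npc_field_params(roi = roi, bg_rate = 0,
                                              seed = 100 + s))$truth
    vapply(tr$blink_counts, sum, numeric(1))
  }))
  expected <- 8 * 0.6 * 4.0
  expect_lt(abs(mean(sml_per_npc) - expected),
            3 * stats::sd(sml_per_npc) / sqrt(length(sml_per_npc)))
})

test_that("density error suggests lowering the dart-throwing pressure", {
  roi <- disk_roi(radius = 1000)
  expect_error(
    simulate_npc_field(npc_field_params(roi = roi, npc_density = 300,
                                        min_separation = 150, seed = 1)),
    "min_separation")
})

test_that("FRAP trace generator matches the closed-form curve", {
  tr <- simulate_frap_trace(f0 = 0, plateau = 1, k = 0.01,
                            t_grid = c(0, 10, 69.31471805599453, 500),
                            noise_sd = 0, seed = 1)
  expect_equal(tr$intensity[1], 0)
  expect_equal(tr$intensity[3], 0.5, tolerance = 1e-12)
  expect_error(simulate_frap_trace(k = -1), "positive")
  expect_error(simulate_frap_trace(f0 = 1, plateau = 0.5), "plateau")
  # noisy mean converges to the noiseless curve
  grid <- seq(0, 500, by = 50)
  mu <- 0.2 + 0.8 * (1 - exp(-0.01 * grid))
  acc <- matrix(0, 400, length(grid))
  for (s in 1:400) {
    acc[s, ] <- simulate_frap_trace(0.2, 1, 0.01, grid, noise_sd = 0.02,
                                    seed = s)$intensity
  }
  se <- 0.02 / sqrt(400)
  expect_true(all(abs(colMeans(acc) - mu) < 4 * se))
})

test_that("N:C image generator obeys its mask arithmetic", {
  g <- simulate_nc_image(nuc_mean = 3, cyto_mean = 1,
                         geometry = list(dim = c(30L, 30L),
                                         nucleus = matrix(rep(c(TRUE, FALSE),
                                                              c(100, 800)), 30),
                                         cell = matrix(rep(c(TRUE, FALSE),
                                                           c(400, 500)), 30)),
                         noise_sd = 0, seed = 1)
  expect_equal(sum(g$image[g$nucleus_mask]), 300)
  expect_equal(sum(g$image[g$cell_mask & !g$nucleus_mask]), 300)
  flat <- simulate_nc_image(nuc_mean = 2, cyto_mean = 2, noise_sd = 0)
  vals <- flat$image[flat$cell_mask]
  expect_true(all(vals == 2))
  expect_error(
    simulate_nc_image(geometry = list(dim = c(10L, 10L),
                                      nucleus = matrix(FALSE, 10, 10),
                                      cell = matrix(TRUE, 10, 10))),
    "empty")
  expect_error(
    simulate_nc_image(geometry = list(dim = c(10L, 10L),
                                      nucleus = matrix(TRUE, 10, 10),
                                      cell = matrix(FALSE, 10, 10))),
    "contained|empty")
})
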