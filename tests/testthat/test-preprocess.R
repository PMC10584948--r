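test_that("sigma filter keeps exactly the in-focus records, in order", {
  tab <- localization_table(frame = 1:4, x = 1:4, y = 1:4,
                            sigma = c(150, 250, 199, 201))
  out <- filter_by_sigma(tab, 200)
  expect_equal(out$sigma, c(150, 199))
  expect_equal(out$frame, c(1L, 3L))
  # default threshold is the 200 nm out-of-focus cutoff
  expect_equal(formals(filter_by_sigma)$sigma_max, 200)
  # identity when nothing exceeds the cutoff; idempotence
  all_in <- filter_by_sigma(tab, 300)
  expect_equal(as.data.frame(all_in), as.data.frame(tab))
  expect_equal(as.data.frame(filter_by_sigma(out, 200)),
               as.data.frame(out))
})

test_that("stricter sigma thresholds retain monotonically fewer records", {
  tab <- tiny_table(200L, seed = 9)
  ns <- vapply(c(250, 200, 160, 130, 111),
               function(s) nrow(filter_by_sigma(tab, s)), numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("drift on an undrifted field stays below one render pixel", {
  sim <- simulate_npc_field(npc_field_params(seed = 10))
  tr <- estimate_drift(sim$table, n_bins = 10L, render_px = 20)
  expect_lt(max(abs(tr$per_frame)), 20)
  expect_equal(tr$shifts[1, ], c(0, 0))
})

test_that("injected linear drift is recovered and removed", {
  sim <- simulate_npc_field(npc_field_params(drift = c(100, -50), seed = 9))
  tr <- estimate_drift(sim$table, n_bins = 10L, render_px = 20)
  tot <- drift_total(tr)
  expect_lt(abs(tot[1] - 100), 15)
  expect_lt(abs(tot[2] - (-50)), 15)
  # fixed point: correcting then re-estimating leaves sub-pixel residual
  corrected <- apply_drift(sim$table, tr)
  tr2 <- estimate_drift(corrected, n_bins = 10L, render_px = 20)
  expect_lt(max(abs(tr2$shifts)), 20)
})

test_that("drift estimation is invariant to global translation", {
  sim <- simulate_npc_field(npc_field_params(roi = disk_roi(3000),
                                             drift = c(60, 30), seed = 12))
  tr1 <- estimate_drift(sim$table)
  shifted <- sim$table
  shifted$x <- shifted$x + 12345
  shifted$y <- shifted$y - 54321
  tr2 <- estimate_drift(shifted)
  # identical up to floating-point regridding of bin edges
  expect_lt(max(abs(tr2$shifts - tr1$shifts)), 0.5)
})

test_that("drift estimation is equivariant under an added known drift", {
  base <- npc_field_params(roi = disk_roi(3000), seed = 21)
  sim0 <- simulate_npc_field(base)
  extra <- npc_field_params(roi = disk_roi(3000), drift = c(80, -40),
                            seed = 21)
  sim1 <- simulate_npc_field(extra)
  d0 <- drift_total(estimate_drift(sim0$table))
  d1 <- drift_total(estimate_drift(sim1$table))
  expect_lt(abs((d1[1] - d0[1]) - 80), 15)
  expect_lt(abs((d1[2] - d0[2]) - (-40)), 15)
})

test_that("apply_drift shifts coordinates by exactly the tracked amount", {
  tab <- localization_table(frame = 5L, x = 100, y = 200, sigma = 150,
                            frame_count = 10L)
  track <- structure(list(bin_mid_frames = c(1, 10),
                          shifts = rbind(c(0, 0), c(30, 0)),
                          per_frame = cbind(rep(c(0, 30), c(4, 6)),
                                            rep(0, 10))),
                     class = "drift_track")
  out <- apply_drift(tab, track)
  expect_equal(out$x, 70)
  expect_equal(out$y, 200)
  expect_equal(out$sigma, 150)
  # zero track is the identity
  zero <- structure(list(bin_mid_frames = c(1, 10),
                         shifts = matrix(0, 2, 2),
                         per_frame = matrix(0, 10, 2)),
                    class = "drift_track")
  expect_equal(as.data.frame(apply_drift(tab, zero)), as.data.frame(tab))
  # a frame beyond the track is a coverage error
  short <- structure(list(bin_mid_frames = 1, shifts = matrix(0, 1, 2),
                          per_frame = matrix(0, 3, 2)),
                     class = "drift_track")
  expect_error(apply_drift(tab, short), "covers")
})

test_that("drift correction tightens localizations around true centers", {
  p <- npc_field_params(drift = c(120, 80), seed = 33)
  sim <- simulate_npc_field(p)
  # RMS of NPC-member localizations about their true center, before/after
  rms_about_truth <- function(tab) {
    idx <- 0L
    tot <- 0
    nn <- 0L
    for (i in seq_along(sim$truth$blink_counts)) {
      b <- sum(sim$truth$blink_counts[[i]])
      if (b == 0L) next
      rows <- (idx + 1L):(idx + b)
      idx <- idx + b
      cen <- sim$truth$npc_centers[i, ]
      tot <- tot + sum((tab$x[rows] - cen[1])^2 + (tab$y[rows] - cen[2])^2)
      nn <- nn + b
    }
    sqrt(tot / nn)
  }
  before <- rms_about_truth(sim$table)
  after <- rms_about_truth(apply_drift(sim$table, estimate_drift(sim$table)))
  expect_lt(after, before)
})

test_that("under-populated bins are rejected with advice", {
  tab <- tiny_table(30L)
  expect_error(estimate_drift(tab, n_bins = 10L, min_per_bin = 50L),
               "fewer bins")
})

test_that("drift track CSV round trips per-frame shifts", {
  sim <- simulate_npc_field(npc_field_params(roi = disk_roi(2000),
                                             drift = c(50, 20), seed = 2))
  tr <- estimate_drift(sim$table)
  f <- withr::local_tempfile(fileext = ".csv")
  write_drift_track(tr, f)
  back <- read_drift_track(f)
  expect_equal(back$per_frame, unname(tr$per_frame), tolerance = 1e-6)
})
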