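test_that("frame subtraction matches hand arithmetic on a toy stack", {
  f1 <- matrix(0L, 4, 4)
  f2 <- f1; f2[2, 2] <- 10L; f2[3, 3] <- 4L
  f3 <- f2
  st <- list(frames = list(f1, f2, f3), timestamps_min = c(0, 5, 10))
  d <- subtract_stack(st)
  expect_length(d$frames, 2)
  expect_equal(d$timestamps_min, c(5, 10))
  expect_equal(sum(d$frames[[1]]), 14)          # |10| + |4| by hand
  expect_equal(d$frames[[1]][2, 2], 10)
  expect_equal(sum(d$frames[[2]]), 0)           # identical frames
  bad <- list(frames = list(f1, matrix(0L, 3, 3)), timestamps_min = c(0, 5))
  expect_error(subtract_stack(bad), "shape")
})

test_that("particle filter keeps only components above the minimum area", {
  mk <- function(blob_px) {
    d <- matrix(0, 32, 32)
    d[blob_pixels_test(5, 5, blob_px)] <- 20
    list(frames = list(d), timestamps_min = 5)
  }
  blob_pixels_test <- function(r, c, area) {
    w <- ceiling(sqrt(area))
    cbind(r + (seq_len(area) - 1) %/% w, c + (seq_len(area) - 1) %% w)
  }
  ev <- detect_events(mk(30), min_area_px = 20)
  expect_equal(ev$event_count, 1)
  expect_equal(ev$embolized_px, 30)
  ev <- detect_events(mk(10), min_area_px = 20)
  expect_equal(ev$event_count, 0)
  expect_equal(ev$embolized_px, 0)
})

test_that("component counting equals a flood-fill oracle on random masks", {
  set.seed(33)
  for (i in 1:15) {
    mask <- matrix(runif(32 * 32) < 0.25, 32, 32)
    d <- list(frames = list(mask * 20), timestamps_min = 5)
    for (conn in c(8, 4)) {
      lab_oracle <- flood_fill_label(mask, conn)
      sizes <- tabulate(lab_oracle[lab_oracle > 0])
      for (min_area in c(1, 3, 6)) {
        ev <- detect_events(d, min_area_px = min_area, connectivity = conn)
        expect_equal(ev$event_count, sum(sizes >= min_area))
        expect_equal(ev$embolized_px, sum(sizes[sizes >= min_area]))
      }
    }
  }
})

test_that("accumulation and PEP normalization behave as defined", {
  ev <- data.frame(embolized_px = c(100, 300, 100))
  out <- accumulate_events(ev)
  expect_equal(out$cumulative_px, c(100, 400, 500))
  expect_equal(out$pep, c(20, 80, 100))

  single <- accumulate_events(data.frame(embolized_px = c(0, 250, 0)))
  expect_equal(single$pep, c(0, 100, 100))

  none <- accumulate_events(data.frame(embolized_px = c(0, 0)))
  expect_true(all(is.na(none$pep)))
  expect_true(attr(none, "qc_no_events"))
})

test_that("water-potential mapping interpolates and refuses extrapolation", {
  tl <- data.frame(time_min = c(0, 30, 60), psi_mpa = c(-0.5, -1.0, -2.0))
  ev <- data.frame(time_min = c(15, 30, 45))
  out <- map_psi(ev, tl)
  expect_equal(out$psi_mpa, c(-0.75, -1.0, -1.5))
  expect_error(map_psi(data.frame(time_min = 75), tl), "span")

  # a sensor blip (psi briefly rising) is cleaned to the running minimum
  tlb <- data.frame(time_min = c(0, 30, 60), psi_mpa = c(-1.0, -0.6, -2.0))
  out <- map_psi(data.frame(time_min = 30), tlb)
  expect_equal(out$psi_mpa, -1.0)
})

test_that("noiseless stacks yield exact event recovery", {
  events <- data.frame(frame = c(3, 6, 9, 12, 15),
                       area_px = rep(30, 5),
                       row = c(3, 20, 40, 10, 30),
                       col = c(3, 30, 10, 45, 50))
  st <- gen_dehydration_stack(18, c(56, 56), events,
                              background_noise_sd = 0)
  ev <- detect_events(subtract_stack(st), min_area_px = 20)
  expect_equal(sum(ev$event_count), 5)
  expect_equal(sum(ev$embolized_px), 150)
  expect_equal(ev$frame_index[ev$event_count > 0], events$frame)

  # sub-threshold noise leaves recovery unchanged
  stn <- gen_dehydration_stack(18, c(56, 56), events,
                               background_noise_sd = 1, seed = 2)
  evn <- detect_events(subtract_stack(stn), intensity_threshold = 10,
                       min_area_px = 20)
  expect_equal(sum(evn$event_count), 5)
  expect_equal(sum(evn$embolized_px), 150)

  # events below the particle-filter minimum are not recovered
  small <- data.frame(frame = 3, area_px = 10, row = 3, col = 3)
  sts <- gen_dehydration_stack(6, c(32, 32), small, 0)
  evs <- detect_events(subtract_stack(sts), min_area_px = 20)
  expect_equal(sum(evs$event_count), 0)
})

test_that("cumulative PEP is non-decreasing in time and along the drydown", {
  set.seed(44)
  events <- data.frame(frame = sample(2:29, 12),
                       area_px = sample(20:60, 12, replace = TRUE),
                       row = sample(1:50, 12), col = sample(1:50, 12))
  st <- gen_dehydration_stack(30, c(64, 64), events, 0)
  tl <- gen_psi_timeline(-0.3, -4, duration_h = 30 * 5 / 60)
  res <- optical_pipeline(st, tl)
  expect_true(all(diff(res$events$cumulative_px) >= 0))
  expect_true(all(diff(res$events$pep) >= 0))
  expect_true(all(diff(res$events$psi_mpa) <= 0))
  expect_equal(res$events$pep[nrow(res$events)], 100)
})

test_that("optical pipeline recovers the generative psi50 end to end", {
  # events placed in time so their psi follows a sigmoid with
  # psi50 = -2, S = 60 under a linear drydown from -0.5 to -3.5 MPa
  truth_psi50 <- -2; truth_s <- 60
  n_frames <- 61
  tl <- gen_psi_timeline(-0.5, -3.5, duration_h = n_frames * 5 / 60)
  psi_of_t <- function(t) -0.5 + (-3.5 + 0.5) * t / (60 * n_frames * 5 / 60)
  # area deposited per frame proportional to the increment of the sigmoid
  frames <- 2:n_frames
  psi_f <- psi_of_t((frames - 1) * 5)
  pep_target <- pammenter_plc(psi_f, truth_psi50, truth_s)
  inc <- diff(c(0, pep_target))
  area <- round(inc * 12)
  keep <- area >= 22  # stay above the particle filter
  pos <- expand.grid(row = seq(2, 110, by = 14), col = seq(2, 110, by = 14))
  events <- data.frame(frame = frames[keep], area_px = area[keep],
                       row = pos$row[seq_len(sum(keep))],
                       col = pos$col[seq_len(sum(keep))])
  st <- gen_dehydration_stack(n_frames, c(128, 128), events, 0)
  res <- optical_pipeline(st, tl, min_area_px = 20)
  expect_true(res$fit$converged)
  expect_lt(abs(res$fit$psi50 - truth_psi50), 0.15)
})

test_that("a real inter-frame translation triggers the movement warning", {
  set.seed(88)
  base <- matrix(as.integer(sample(0:255, 48 * 48, replace = TRUE)), 48, 48)
  shifted <- base
  shifted[, 4:48] <- base[, 1:45]  # 3-px sideways shift of the whole leaf
  st <- list(frames = list(base, shifted, shifted),
             timestamps_min = c(0, 5, 10))
  tl <- gen_psi_timeline(-0.5, -3, duration_h = 0.5)
  expect_warning(
    try(optical_pipeline(st, tl), silent = TRUE),
    "shift")
})
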