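#' Default induced-pressure grid for flow-centrifuge sweeps
#'
#' The protocol starts at -0.8 MPa and steps by -0.5 MPa; ten points reach
#' -5.3 MPa, deep enough to saturate the sigmoid for all realistic grapevine
#' psi50 values.
#'
#' @return Numeric vector of pressures (MPa), strictly decreasing.
#' @export
default_pressures <- function() seq(-0.8, -5.3, by = -0.5)

#' Reference panel of synthetic variety truths
#'
#' A panel of generative ground-truth parameters emulating the spread of
#' summer stem vulnerability observed across cultivated grapevine: variety
#' mean psi50 spanning -1.8 to -3.4 MPa, sigmoid slopes around
#' 50 % MPa^-1, and modest plant-to-plant variation. The three most
#' resistant entries are tagged as rootstocks and the three most vulnerable
#' as interspecific hybrids, mirroring the qualitative ranking of variety
#' types reported in field screens.
#'
#' @param n_varieties Number of varieties (default 30).
#' @return Data frame with `variety_name`, `type`, `true_psi50`,
#'   `true_slope`, `plant_sd_psi50`, `plant_sd_slope`.
#' @export
default_variety_panel <- function(n_varieties = 30L) {
  stopifnot(n_varieties >= 1)
  psi50 <- seq(-1.8, -3.4, length.out = n_varieties)
  type <- rep("vinifera", n_varieties)
  if (n_varieties >= 6) {
    type[seq_len(3)] <- "hybrid"            # least negative: most vulnerable
    type[n_varieties - 2:0] <- "rootstock"  # most negative: most resistant
  }
  data.frame(
    variety_name = sprintf("VAR%02d", seq_len(n_varieties)),
    type = type,
    true_psi50 = psi50,
    true_slope = rep(50, n_varieties),
    plant_sd_psi50 = rep(0.15, n_varieties),
    plant_sd_slope = rep(8, n_varieties)
  )
}

check_variety_truth <- function(truth) {
  stopifnot(is.list(truth),
            truth$true_psi50 < 0, truth$true_slope > 0,
            truth$plant_sd_psi50 >= 0, truth$plant_sd_slope >= 0)
  invisible(truth)
}

#' Simulate one plant's conductivity sweep
#'
#' Generates the flow-centrifuge measurement of a plant whose true
#' vulnerability follows [pammenter_plc()] with the given parameters:
#' `k(psi) = k_max_true * (1 - PLC_true(psi)/100) * (1 + eps)`, with
#' multiplicative Gaussian noise `eps ~ N(0, noise_cv)` (conductivity errors
#' scale with magnitude). Note that the protocol's reference reading at the
#' first pressure already carries a little true embolism, so measured PLC is
#' renormalized relative to it — exactly as in real sweeps.
#'
#' @param truth List/row with `true_psi50` (< 0, MPa) and `true_slope`
#'   (> 0, % MPa^-1); `plant_sd_*` fields are ignored here (see
#'   [gen_cohort()]).
#' @param pressures Strictly decreasing pressure grid, MPa
#'   (default [default_pressures()]).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 gives a noiseless sweep).
#' @param k_max_true True unembolized conductivity (default 2 kg m^-1 s^-1
#'   MPa^-1, a typical young grapevine stem).
#' @param seed Optional integer seed for reproducibility.
#' @return Data frame with `psi_mpa`, `k`; attribute `truth` logs the
#'   generative parameters and seed.
#' @export
gen_sweep <- function(truth, pressures = default_pressures(),
                      noise_cv = 0.05, k_max_true = 2, seed = NULL) {
  stopifnot(truth$true_psi50 < 0, truth$true_slope > 0, noise_cv >= 0,
            k_max_true > 0, length(pressures) >= 2)
  if (any(diff(pressures) >= 0)) {
    stop("pressure grid must be strictly decreasing", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  plc_true <- pammenter_plc(pressures, truth$true_psi50, truth$true_slope)
  eps <- if (noise_cv > 0) stats::rnorm(length(pressures), 0, noise_cv) else 0
  k <- k_max_true * (1 - plc_true / 100) * (1 + eps)
  out <- data.frame(psi_mpa = pressures, k = pmax(k, 0))
  attr(out, "truth") <- list(psi50 = truth$true_psi50,
                             slope = truth$true_slope,
                             k_max_true = k_max_true,
                             noise_cv = noise_cv, seed = seed)
  out
}

#' Simulate a cohort of plants across varieties
#'
#' Draws per-plant (psi50, slope) from each variety's truth distribution
#' (Gaussian around the variety mean, slope truncated positive) and
#' generates one sweep per plant.
#'
#' @param varieties Data frame as from [default_variety_panel()].
#' @param n_plants_per_variety Plants per variety (>= 1).
#' @param pressures,noise_cv,k_max_true As in [gen_sweep()].
#' @param season Season tag attached to every sweep.
#' @param seed Integer seed; one seed governs all draws.
#' @return List with `sweeps` (long data frame: `plant_id`, `variety`,
#'   `season`, `organ`, `psi_mpa`, `k`) and `truth` (per-plant drawn
#'   parameters plus the seed).
#' @export
gen_cohort <- function(varieties, n_plants_per_variety = 6L,
                       pressures = default_pressures(), noise_cv = 0.05,
                       k_max_true = 2, season = "summer", seed = 1L) {
  stopifnot(n_plants_per_variety >= 1, nrow(varieties) >= 1)
  set.seed(seed)
  sweeps <- vector("list", nrow(varieties) * n_plants_per_variety)
  truth <- sweeps
  idx <- 0L
  for (v in seq_len(nrow(varieties))) {
    vt <- check_variety_truth(as.list(varieties[v, ]))
    for (p in seq_len(n_plants_per_variety)) {
      idx <- idx + 1L
      psi50_p <- stats::rnorm(1, vt$true_psi50, vt$plant_sd_psi50)
      psi50_p <- min(psi50_p, -1e-3)  # stays negative
      slope_p <- abs(stats::rnorm(1, vt$true_slope, vt$plant_sd_slope))
      slope_p <- max(slope_p, 1)
      sw <- gen_sweep(list(true_psi50 = psi50_p, true_slope = slope_p),
                      pressures = pressures, noise_cv = noise_cv,
                      k_max_true = k_max_true, seed = NULL)
      id <- sprintf("%s_p%02d", vt$variety_name, p)
      sweeps[[idx]] <- cbind(
        data.frame(plant_id = id, variety = vt$variety_name,
                   season = season, organ = "stem"),
        sw)
      truth[[idx]] <- data.frame(plant_id = id, variety = vt$variety_name,
                                 psi50 = psi50_p, slope = slope_p)
    }
  }
  list(sweeps = do.call(rbind, sweeps),
       truth = cbind(do.call(rbind, truth), seed = seed))
}

#' Simulate a leaf dehydration image stack with injected embolism events
#'
#' Builds an 8-bit grayscale stack (frames at 5-minute spacing) on a flat
#' leaf background. Each injected event is a contiguous pixel blob whose
#' intensity steps up at its event frame and persists afterwards, so the
#' between-frame difference shows the blob exactly once — the signature the
#' optical method detects. Gaussian background noise is added independently
#' per frame.
#'
#' @param n_frames Number of frames (>= 2).
#' @param frame_shape `c(rows, cols)` in pixels.
#' @param events Data frame with `frame` (2..n_frames), `area_px` (>= 1),
#'   `row`, `col` (top-left corner of the blob). Blobs are filled row-major
#'   inside a near-square bounding box, so each is 8-connected (indeed
#'   4-connected).
#' @param background_noise_sd Gray-level sd of additive noise (0 = none).
#' @param intensity_step Gray-level step of an event (default
#'   `max(40, 5 * background_noise_sd)` so events sit well above noise).
#' @param background_level Base gray level (default 30).
#' @param seed Optional seed.
#' @return List with `frames` (list of integer matrices, 0-255),
#'   `timestamps_min` (5-min spacing from 0) and `truth` (the event table,
#'   with overlaps between same-frame events logged in
#'   `truth$overlap_warnings`).
#' @export
gen_dehydration_stack <- function(n_frames, frame_shape = c(64L, 64L),
                                  events = NULL, background_noise_sd = 0,
                                  intensity_step = NULL,
                                  background_level = 30,
                                  seed = NULL) {
  stopifnot(n_frames >= 2, length(frame_shape) == 2, background_noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(intensity_step)) {
    intensity_step <- max(40, 5 * background_noise_sd)
  }
  nr <- frame_shape[1]; nc <- frame_shape[2]
  signal <- matrix(0, nr, nc)  # accumulated persistent event intensity
  frames <- vector("list", n_frames)
  overlaps <- character(0)
  ev_by_frame <- if (is.null(events)) list() else
    split(events, factor(events$frame, levels = seq_len(n_frames)))
  occupied_this_frame <- NULL
  for (f in seq_len(n_frames)) {
    evs <- if (f <= length(ev_by_frame)) ev_by_frame[[f]] else NULL
    if (!is.null(evs) && nrow(evs) > 0) {
      occupied <- matrix(FALSE, nr, nc)
      for (e in seq_len(nrow(evs))) {
        px <- blob_pixels(evs$row[e], evs$col[e], evs$area_px[e], nr, nc)
        if (any(occupied[px])) {
          overlaps <- c(overlaps, sprintf(
            "frame %d: event at (%d,%d) overlaps an earlier same-frame event",
            f, evs$row[e], evs$col[e]))
        }
        occupied[px] <- TRUE
        signal[px] <- signal[px] + intensity_step
      }
    }
    fr <- background_level + signal
    if (background_noise_sd > 0) {
      fr <- fr + matrix(stats::rnorm(nr * nc, 0, background_noise_sd), nr, nc)
    }
    frames[[f]] <- matrix(as.integer(pmin(pmax(round(fr), 0), 255)), nr, nc)
  }
  list(frames = frames,
       timestamps_min = (seq_len(n_frames) - 1) * 5,
       truth = list(events = events, intensity_step = intensity_step,
                    overlap_warnings = overlaps, seed = seed))
}

# linear indices of a contiguous blob of `area` pixels filled row-major in a
# near-square box anchored at (row, col); errors if it leaves the frame
blob_pixels <- function(row, col, area, nr, nc) {
  stopifnot(area >= 1)
  w <- ceiling(sqrt(area))
  rows <- row + (seq_len(area) - 1) %/% w
  cols <- col + (seq_len(area) - 1) %% w
  if (any(rows > nr) || any(cols > nc) || row < 1 || col < 1) {
    stop("event blob exceeds frame bounds", call. = FALSE)
  }
  cbind(rows, cols)
}

#' Simulate a stem water-potential drydown timeline
#'
#' Monotone non-increasing psi_stem readings at fixed spacing (psychrometer
#' default: every 30 minutes), following a linear or exponential-decay
#' trajectory from `psi_start` to `psi_end`. Optional Gaussian jitter
#' emulates raw sensor blips (which downstream cleaning removes).
#'
#' @param psi_start,psi_end Start/end water potential, MPa
#'   (`psi_start > psi_end`, both negative).
#' @param duration_h Drydown duration in hours (field drydowns of young
#'   grapevine run roughly 80-130 h).
#' @param interval_min Reading spacing, minutes (default 30).
#' @param shape `"linear"` or `"exponential"`.
#' @param jitter_sd Gaussian jitter sd in MPa (default 0).
#' @param seed Optional seed.
#' @return Data frame with `time_min`, `psi_mpa`.
#' @export
gen_psi_timeline <- function(psi_start, psi_end, duration_h,
                             interval_min = 30, shape = c("linear",
                                                          "exponential"),
                             jitter_sd = 0, seed = NULL) {
  stopifnot(psi_start < 0, psi_end < psi_start, duration_h > 0)
  shape <- match.arg(shape)
  if (!is.null(seed)) set.seed(seed)
  t_min <- seq(0, duration_h * 60, by = interval_min)
  frac <- t_min / max(t_min)
  if (shape == "exponential") {
    # decay towards psi_end, normalized to reach it exactly at the end
    rate <- 3
    frac <- (1 - exp(-rate * frac)) / (1 - exp(-rate))
  }
  psi <- psi_start + (psi_end - psi_start) * frac
  if (jitter_sd > 0) psi <- psi + stats::rnorm(length(psi), 0, jitter_sd)
  data.frame(time_min = t_min, psi_mpa = psi)
}

#' Simulate a vessel lumen table for one stem cross-section
#'
#' Draws vessel equivalent-circle diameters from a lognormal distribution
#' and converts them to lumen areas.
#'
#' @param n Number of vessels (>= 1).
#' @param meanlog,sdlog Lognormal parameters of diameter in micrometres
#'   (defaults give a median near 55 um, typical of grapevine stems).
#' @param xylem_area_mm2 Cross-section xylem area in mm^2.
#' @param seed Optional seed.
#' @return List with `vessels` (data frame: `vessel_area_um2`),
#'   `xylem_area_m2`, and `truth` (drawn diameters, um).
#' @export
gen_vessels <- function(n, meanlog = log(55), sdlog = 0.3,
                        xylem_area_mm2 = 1, seed = NULL) {
  stopifnot(n >= 1, xylem_area_mm2 > 0)
  if (!is.null(seed)) set.seed(seed)
  d_um <- stats::rlnorm(n, meanlog, sdlog)
  list(vessels = data.frame(vessel_area_um2 = pi * (d_um / 2)^2),
       xylem_area_m2 = xylem_area_mm2 * 1e-6,
       truth = list(diameters_um = d_um, seed = seed))
}

#' Simulate a regional winegrape bearing-area table
#'
#' Emulates the schema of regional bearing-area databases: long rows of
#' (region, country, variety, bearing_percent), where the panel varieties
#' cover only part of each region's winegrape area — the remainder belongs
#' to varieties outside the panel and is left uncovered. Panel shares within
#' the covered fraction are Dirichlet-distributed.
#'
#' @param n_regions Number of regions, or a character vector of region names.
#' @param varieties Character vector of panel variety names.
#' @param share_concentration Dirichlet concentration (small = one variety
#'   dominates; default 1 = uniform simplex).
#' @param uncovered_fraction_range Range (fractions of regional area) from
#'   which each region's uncovered share is drawn uniformly.
#' @param country Country label(s), recycled across regions.
#' @param seed Optional seed.
#' @return List with `table` (long data frame) and `truth` (per-region
#'   covered percent and per-variety intended shares).
#' @export
gen_bearing_table <- function(n_regions, varieties,
                              share_concentration = 1,
                              uncovered_fraction_range = c(0, 0.3),
                              country = "Synthia", seed = NULL) {
  regions <- if (is.character(n_regions)) n_regions else
    sprintf("Region%02d", seq_len(n_regions))
  stopifnot(length(varieties) >= 1, share_concentration > 0,
            all(uncovered_fraction_range >= 0),
            all(uncovered_fraction_range <= 1))
  if (!is.null(seed)) set.seed(seed)
  country <- rep_len(country, length(regions))
  rows <- vector("list", length(regions))
  truth <- rows
  for (i in seq_along(regions)) {
    unc <- stats::runif(1, uncovered_fraction_range[1],
                        uncovered_fraction_range[2])
    covered <- 100 * (1 - unc)
    g <- stats::rgamma(length(varieties), shape = share_concentration)
    shares <- covered * g / sum(g)
    rows[[i]] <- data.frame(region = regions[i], country = country[i],
                            variety = varieties,
                            bearing_percent = shares)
    truth[[i]] <- data.frame(region = regions[i], covered_percent = covered)
  }
  list(table = do.call(rbind, rows),
       truth = list(regions = do.call(rbind, truth), seed = seed))
}
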