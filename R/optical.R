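#' Between-frame difference stack
#'
#' Absolute intensity difference between successive frames of a leaf
#' dehydration stack, emphasizing abrupt changes in light transmission —
#' the optical signature of embolism events in the vein network. Difference
#' frame i is aligned to the timestamp of the later frame (i + 1).
#'
#' @param stack List with `frames` (list of >= 2 equal-shape numeric
#'   matrices) and `timestamps_min`.
#' @return List with `frames` (n - 1 difference matrices) and
#'   `timestamps_min` (later-frame timestamps).
#' @export
subtract_stack <- function(stack) {
  frames <- stack$frames
  stopifnot(length(frames) >= 2)
  shp <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), shp), logical(1)))) {
    stop("all frames must share the same shape", call. = FALSE)
  }
  diffs <- lapply(seq_len(length(frames) - 1), function(i) {
    abs(frames[[i + 1]] - frames[[i]])
  })
  list(frames = diffs, timestamps_min = stack$timestamps_min[-1])
}

#' Detect embolism events in a difference stack
#'
#' Thresholds each difference frame and labels connected components
#' (8-connectivity: diagonal neighbours belong to the same event), then
#' discards components smaller than `min_area_px` — the particle filter that
#' removes speckle noise while keeping large, structured embolism events.
#'
#' @param diff_stack As returned by [subtract_stack()].
#' @param intensity_threshold Gray-level threshold (> 0); pixels with
#'   difference strictly greater are candidate embolism pixels. Default 5.
#' @param min_area_px Minimum component area kept, pixels (default 20).
#' @param connectivity 8 (default) or 4.
#' @return Data frame with one row per difference frame: `frame_index`
#'   (index of the later original frame), `time_min`, `event_count`,
#'   `embolized_px`. Attribute `masks` holds the filtered binary masks.
#' @export
detect_events <- function(diff_stack, intensity_threshold = 5,
                          min_area_px = 20, connectivity = 8) {
  stopifnot(intensity_threshold > 0, min_area_px >= 1,
            connectivity %in% c(4, 8))
  n <- length(diff_stack$frames)
  counts <- integer(n); px <- integer(n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    mask <- diff_stack$frames[[i]] > intensity_threshold
    lab <- label_components(mask, connectivity)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0])
      keep <- which(sizes >= min_area_px)
      counts[i] <- length(keep)
      px[i] <- sum(sizes[keep])
      masks[[i]] <- matrix(lab %in% keep, nrow(mask), ncol(mask))
    } else {
      masks[[i]] <- mask & FALSE
    }
  }
  out <- data.frame(frame_index = seq_len(n) + 1L,
                    time_min = diff_stack$timestamps_min,
                    event_count = counts, embolized_px = px)
  attr(out, "masks") <- masks
  out
}

# connected-component labelling; EBImage::bwlabel is 4-connected, so for
# 8-connectivity diagonally adjacent 4-labels are merged by union-find
label_components <- function(mask, connectivity = 8) {
  storage.mode(mask) <- "integer"
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (connectivity == 4 || nlab <= 1) return(lab)
  parent <- seq_len(nlab)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  # diagonally adjacent distinct labels must be unified
  pairs <- rbind(
    diag_pairs(lab, 1L, 1L),
    diag_pairs(lab, 1L, -1L)
  )
  if (nrow(pairs) > 0) {
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

# distinct positive label pairs of pixels offset by (dr, dc)
diag_pairs <- function(lab, dr, dc) {
  nr <- nrow(lab); nc <- ncol(lab)
  r1 <- seq_len(nr - abs(dr)); c1 <- seq_len(nc - abs(dc))
  a <- lab[r1 + ifelse(dr > 0, 0L, abs(dr)),
           c1 + ifelse(dc > 0, 0L, abs(dc)), drop = FALSE]
  b <- lab[r1 + ifelse(dr > 0, abs(dr), 0L),
           c1 + ifelse(dc > 0, abs(dc), 0L), drop = FALSE]
  sel <- a > 0 & b > 0 & a != b
  cbind(a[sel], b[sel])
}

#' Cumulative embolized pixels and percentage of embolized pixels
#'
#' Sums embolized pixels across frames and normalizes the cumulative count
#' by the dehydration total, giving the percentage of embolized pixels
#' (PEP), which reaches 100 at the last event.
#'
#' @param events Data frame from [detect_events()] (needs `embolized_px`).
#' @return The input with `cumulative_px` and `pep` columns appended.
#'   Zero-event series get `pep = NA` and attribute `qc_no_events = TRUE`.
#' @export
accumulate_events <- function(events) {
  stopifnot("embolized_px" %in% names(events))
  out <- events
  out$cumulative_px <- cumsum(events$embolized_px)
  total <- out$cumulative_px[nrow(out)]
  if (total <= 0) {
    out$pep <- NA_real_
    attr(out, "qc_no_events") <- TRUE
  } else {
    out$pep <- 100 * out$cumulative_px / total
  }
  out
}

#' Map frame times onto stem water potential
#'
#' Interpolates the psychrometer timeline at each frame timestamp. The raw
#' series is first cleaned to its running minimum (monotone non-increasing):
#' embolism cannot reverse during a drydown, and uncorrected sensor blips
#' would otherwise invert the PEP-psi mapping. No extrapolation: frames
#' outside the timeline span are an error.
#'
#' @param events Data frame with `time_min` (frame timestamps).
#' @param timeline Data frame with `time_min` (strictly increasing) and
#'   `psi_mpa`.
#' @return `events` with a `psi_mpa` column appended.
#' @export
map_psi <- function(events, timeline) {
  stopifnot(all(c("time_min", "psi_mpa") %in% names(timeline)),
            "time_min" %in% names(events))
  if (any(diff(timeline$time_min) <= 0)) {
    stop("timeline times must be strictly increasing", call. = FALSE)
  }
  if (min(events$time_min) < min(timeline$time_min) ||
      max(events$time_min) > max(timeline$time_min)) {
    stop("frame timestamps outside the water-potential timeline span",
         call. = FALSE)
  }
  psi_clean <- cummin(timeline$psi_mpa)
  out <- events
  out$psi_mpa <- stats::approx(timeline$time_min, psi_clean,
                               xout = events$time_min)$y
  out
}

#' Optical vulnerability curve
#'
#' Fits the Pammenter sigmoid to the percentage of embolized pixels as a
#' function of stem water potential, yielding an optical analogue of the
#' hydraulic vulnerability fit (psi50, S, psi12, psi88).
#'
#' @param events Data frame with `psi_mpa` and `pep` (from
#'   [accumulate_events()] + [map_psi()]).
#' @param ... Passed to [fit_pammenter()].
#' @return A `vc_fit` object.
#' @export
optical_vc <- function(events, ...) {
  stopifnot(all(c("psi_mpa", "pep") %in% names(events)))
  ev <- events[is.finite(events$pep), , drop = FALSE]
  if (length(unique(ev$psi_mpa)) < 4) {
    stop("need at least 4 distinct water-potential values", call. = FALSE)
  }
  fit_pammenter(ev[order(-ev$psi_mpa), c("psi_mpa", "pep")], ...)
}

#' Run the full optical pipeline on a stack and timeline
#'
#' Convenience wrapper: subtract, detect, accumulate, map to water
#' potential, and fit. A QC warning is emitted when the global inter-frame
#' translation estimated by cross-correlation exceeds 2 px (leaf movement;
#' no registration is applied).
#'
#' @param stack As from [gen_dehydration_stack()] or [read_stack()].
#' @param timeline As from [gen_psi_timeline()].
#' @param intensity_threshold,min_area_px,connectivity See [detect_events()].
#' @param ... Passed to [fit_pammenter()].
#' @return List with `events` (per-frame table incl. `pep`, `psi_mpa`) and
#'   `fit` (a `vc_fit`).
#' @export
optical_pipeline <- function(stack, timeline, intensity_threshold = 5,
                             min_area_px = 20, connectivity = 8, ...) {
  shift <- max_frame_shift(stack$frames)
  if (shift > 2) {
    warning("inter-frame shift of ", shift,
            " px detected; leaf may have moved during the drydown")
  }
  ev <- detect_events(subtract_stack(stack), intensity_threshold,
                      min_area_px, connectivity)
  ev <- accumulate_events(ev)
  ev <- map_psi(ev, timeline)
  list(events = ev, fit = optical_vc(ev, ...))
}

# largest whole-pixel translation between consecutive frames, estimated by
# FFT cross-correlation of mean-centred frames; a shift is only trusted when
# the normalized correlation peak shows the frames really are shifted copies
# (unstructured or event-only differences give weak, random peaks)
max_frame_shift <- function(frames, min_peak_corr = 0.5) {
  best <- 0
  for (i in seq_len(length(frames) - 1)) {
    a <- frames[[i]] - mean(frames[[i]])
    b <- frames[[i + 1]] - mean(frames[[i + 1]])
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) next
    cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)),
                        inverse = TRUE)) / (length(a) * na * nb)
    if (max(cc) < min_peak_corr) next
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    dr <- pk[1] - 1; dc <- pk[2] - 1
    if (dr > nrow(a) / 2) dr <- dr - nrow(a)
    if (dc > ncol(a) / 2) dc <- dc - ncol(a)
    best <- max(best, abs(dr), abs(dc))
  }
  best
}
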