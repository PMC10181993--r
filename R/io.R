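# Plain-text I/O: sweeps/timelines/vessels/bearing tables as CSV, image
# stacks as multi-page 8-bit grayscale TIFF, truth logs and reports as JSON.

#' Read / write conductivity sweeps
#'
#' CSV columns: `plant_id`, `variety`, `season`, `organ`, `psi_mpa`, `k`.
#' @param path File path.
#' @param sweeps Long sweep data frame.
#' @return `read_sweeps()` returns the data frame.
#' @export
read_sweeps <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "psi_mpa", "k")
  if (!all(need %in% names(df))) {
    stop("sweeps CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_sweeps
#' @export
write_sweeps <- function(sweeps, path) {
  utils::write.csv(sweeps, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a water-potential timeline CSV
#'
#' Columns: `time_min`, `psi_mpa`.
#' @param path File path.
#' @param timeline Timeline data frame.
#' @export
read_timeline <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_min", "psi_mpa") %in% names(df))) {
    stop("timeline CSV must have columns time_min, psi_mpa", call. = FALSE)
  }
  df
}

#' @rdname read_timeline
#' @export
write_timeline <- function(timeline, path) {
  utils::write.csv(timeline, path, row.names = FALSE)
  invisible(path)
}

#' Read / write an image stack as multi-page grayscale TIFF
#'
#' Frames are stored as 8-bit grayscale pages; timestamps (5-min spacing)
#' are reconstructed on read.
#' @param path TIFF path.
#' @param stack List with `frames` (integer matrices 0-255) and
#'   `timestamps_min`.
#' @param interval_min Frame spacing used to rebuild timestamps on read.
#' @export
read_stack <- function(path, interval_min = 5) {
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # grayscale written as RGB
    matrix(as.integer(round(p * 255)), nrow(p), ncol(p))
  })
  list(frames = frames,
       timestamps_min = (seq_along(frames) - 1) * interval_min)
}

#' @rdname read_stack
#' @export
write_stack <- function(stack, path) {
  pages <- lapply(stack$frames, function(f) f / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' Read a vessels CSV
#'
#' Columns: `section_id`, `variety`, `vessel_area_um2`, `xylem_area_m2`.
#' @param path File path.
#' @export
read_vessels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("section_id", "vessel_area_um2", "xylem_area_m2")
  if (!all(need %in% names(df))) {
    stop("vessels CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a regional bearing-area CSV
#'
#' Long format: `region`, `country`, `variety`, `bearing_percent`
#' (optionally `hectares`). No assumption is made about region or country
#' counts; each row is treated as an independent record.
#' @param path File path.
#' @export
read_bearing <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "variety", "bearing_percent")
  if (!all(need %in% names(df))) {
    stop("bearing CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$bearing_percent < 0)) {
    stop("negative bearing_percent", call. = FALSE)
  }
  df
}
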