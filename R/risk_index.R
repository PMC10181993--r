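#' Per-region bearing area of each vulnerability cluster
#'
#' Joins a long regional bearing table with the variety-to-cluster
#' assignment and sums bearing percent per cluster within each region.
#' Varieties without a cluster label (outside the study panel) contribute
#' nothing to any cluster — they count only in the regional denominator —
#' and are recorded in the `unknown_varieties` attribute. Coverage is the
#' summed percent over all four clusters.
#'
#' @param bearing Data frame with `region`, `country`, `variety`,
#'   `bearing_percent` (>= 0, summing to <= 100 per region).
#' @param assignment Data frame with `variety`, `cluster`, `weight` (from
#'   [label_clusters()]).
#' @return Data frame, one row per region: `region`, `country`,
#'   `area_low`, `area_low_to_medium`, `area_medium_to_high`, `area_high`,
#'   `coverage_percent`.
#' @export
cluster_areas <- function(bearing, assignment) {
  stopifnot(all(c("region", "variety", "bearing_percent") %in%
                  names(bearing)),
            all(bearing$bearing_percent >= 0))
  labels <- names(cluster_weights())
  cl <- as.character(assignment$cluster[match(bearing$variety,
                                              assignment$variety)])
  unknown <- sort(unique(bearing$variety[is.na(cl)]))
  rows <- lapply(split(seq_len(nrow(bearing)), bearing$region), function(i) {
    g <- bearing[i, ]
    gc <- cl[i]
    areas <- vapply(labels, function(l) {
      sum(g$bearing_percent[!is.na(gc) & gc == l])
    }, numeric(1))
    data.frame(region = g$region[1],
               country = if ("country" %in% names(g)) g$country[1] else NA,
               area_low = areas[["low"]],
               area_low_to_medium = areas[["low-to-medium"]],
               area_medium_to_high = areas[["medium-to-high"]],
               area_high = areas[["high"]],
               coverage_percent = sum(areas))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "unknown_varieties") <- unknown
  out
}

#' Regional risk index of drought vulnerability
#'
#' Weighted sum of cluster bearing areas (percent of the regional winegrape
#' area) with the fixed vulnerability weights:
#' `RI = 0.125 a_low + 0.375 a_low_to_medium + 0.625 a_medium_to_high +
#' 0.875 a_high`. Full coverage bounds RI to [12.5, 87.5]; uncovered area
#' contributes zero, so partially covered regions can fall below 12.5.
#'
#' @param areas Numeric vector of length 4 (low, low-to-medium,
#'   medium-to-high, high; percents, >= 0, sum <= 100), or a data frame
#'   from [cluster_areas()].
#' @return RI value(s), dimensionless on the 0-87.5 scale.
#' @examples
#' compute_ri(c(25, 25, 25, 25))  # 50
#' @export
compute_ri <- function(areas) {
  w <- unname(cluster_weights())
  if (is.data.frame(areas)) {
    m <- as.matrix(areas[, c("area_low", "area_low_to_medium",
                             "area_medium_to_high", "area_high")])
    stopifnot(all(m >= 0), all(rowSums(m) <= 100 + 1e-9))
    return(as.numeric(m %*% w))
  }
  stopifnot(length(areas) == 4, all(areas >= 0), sum(areas) <= 100 + 1e-9)
  sum(w * areas)
}

#' Apply the minimum-coverage filter to regional risks
#'
#' Regions where the panel varieties cover less than `min_coverage` percent
#' of the winegrape bearing area are flagged as excluded (`included =
#' FALSE`) but kept in the table. The boundary is inclusive: coverage of
#' exactly `min_coverage` is retained.
#'
#' @param risks Data frame with `coverage_percent`.
#' @param min_coverage Threshold percent (default 40).
#' @return `risks` with a logical `included` column.
#' @export
filter_regions <- function(risks, min_coverage = 40) {
  stopifnot("coverage_percent" %in% names(risks))
  risks$included <- risks$coverage_percent >= min_coverage
  risks
}

#' Regional risk table and distribution summary
#'
#' Computes RI for every region, applies the coverage filter, and
#' summarizes the RI distribution over included regions: min, max, and the
#' share of regions with RI in the inclusive band [`band[1]`, `band[2]`].
#'
#' @param bearing Bearing table (see [cluster_areas()]).
#' @param assignment Variety-to-cluster assignment.
#' @param min_coverage Coverage threshold percent (default 40).
#' @param band RI band for the share statistic (default `c(20, 40)`).
#' @return List with `risks` (per-region data frame incl. `ri`,
#'   `included`) and `summary` (list: `n_regions`, `n_included`, `ri_min`,
#'   `ri_max`, `band`, `band_share_percent`).
#' @export
ri_report <- function(bearing, assignment, min_coverage = 40,
                      band = c(20, 40)) {
  risks <- cluster_areas(bearing, assignment)
  risks$ri <- compute_ri(risks)
  risks <- filter_regions(risks, min_coverage)
  inc <- risks[risks$included, , drop = FALSE]
  if (nrow(inc) == 0) stop("no region passes the coverage filter",
                           call. = FALSE)
  list(
    risks = risks,
    summary = list(
      n_regions = nrow(risks),
      n_included = nrow(inc),
      ri_min = min(inc$ri),
      ri_max = max(inc$ri),
      band = band,
      band_share_percent = 100 * mean(inc$ri >= band[1] & inc$ri <= band[2])
    )
  )
}
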