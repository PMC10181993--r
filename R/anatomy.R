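WATER_DENSITY_KG_M3 <- 998.2     # at 20 degrees C
WATER_VISCOSITY_MPA_S <- 1.002e-9  # 1.002e-3 Pa s expressed in MPa s

#' Xylem anatomical traits from a vessel lumen table
#'
#' From measured vessel lumen areas of one stem cross-section, computes the
#' equivalent circle diameters `D_i = 2 * sqrt(area_i / pi)` (um), the
#' hydraulically weighted diameter `D_H = sum(D^5) / sum(D^4)` (um; the
#' conductivity-weighted mean, always >= the arithmetic mean), and the
#' vessel density `V_D = n / xylem area` (vessels per mm^2).
#'
#' @param vessel_areas_um2 Vessel lumen areas, um^2 (> 0).
#' @param xylem_area_m2 Cross-section xylem area, m^2 (> 0).
#' @return List with `d_um` (per-vessel diameters), `d_mean_um`, `d_h_um`,
#'   `v_d_per_mm2`, `n_vessels`, `xylem_area_m2`.
#' @examples
#' vessel_metrics(2500 * pi, 1e-6)$d_h_um  # single 100-um vessel
#' @export
vessel_metrics <- function(vessel_areas_um2, xylem_area_m2) {
  stopifnot(length(vessel_areas_um2) >= 1, all(vessel_areas_um2 > 0),
            xylem_area_m2 > 0)
  d <- 2 * sqrt(vessel_areas_um2 / pi)
  list(d_um = d,
       d_mean_um = mean(d),
       d_h_um = sum(d^5) / sum(d^4),
       v_d_per_mm2 = length(d) / (xylem_area_m2 * 1e6),
       n_vessels = length(d),
       xylem_area_m2 = xylem_area_m2)
}

#' Theoretical specific hydraulic conductivity (Hagen-Poiseuille)
#'
#' Sums the Hagen-Poiseuille conductance of every vessel and normalizes by
#' xylem area:
#' \deqn{k_{th} = \sum \frac{\pi D^4 \rho}{128 \eta} \cdot \frac{1}{A_{xyl}}}
#' with D the equivalent circle diameter in metres, water density
#' rho = 998.2 kg m^-3 and viscosity eta = 1.002e-9 MPa s (both at 20 C),
#' giving k_th in kg s^-1 m^-1 MPa^-1.
#'
#' @param d_um Vessel diameters in micrometres.
#' @param xylem_area_m2 Xylem area, m^2 (> 0).
#' @return k_th, kg s^-1 m^-1 MPa^-1.
#' @examples
#' compute_kth(100, 1e-6)  # single 100-um vessel: about 2.445
#' @export
compute_kth <- function(d_um, xylem_area_m2) {
  stopifnot(length(d_um) >= 1, all(d_um > 0), xylem_area_m2 > 0)
  d_m <- d_um * 1e-6
  sum(pi * d_m^4 * WATER_DENSITY_KG_M3 /
        (128 * WATER_VISCOSITY_MPA_S)) / xylem_area_m2
}

#' Anatomy traits for a table of cross-sections
#'
#' @param vessels Long data frame with `section_id`, `variety`,
#'   `vessel_area_um2`, `xylem_area_m2`.
#' @return Data frame, one row per section: `section_id`, `variety`,
#'   `n_vessels`, `d_mean_um`, `d_h_um`, `v_d_per_mm2`, `k_th`.
#' @export
anatomy_table <- function(vessels) {
  stopifnot(all(c("section_id", "vessel_area_um2", "xylem_area_m2")
                %in% names(vessels)))
  rows <- lapply(split(vessels, vessels$section_id), function(g) {
    m <- vessel_metrics(g$vessel_area_um2, g$xylem_area_m2[1])
    data.frame(section_id = g$section_id[1],
               variety = if ("variety" %in% names(g)) g$variety[1] else NA,
               n_vessels = m$n_vessels, d_mean_um = m$d_mean_um,
               d_h_um = m$d_h_um, v_d_per_mm2 = m$v_d_per_mm2,
               k_th = compute_kth(m$d_um, m$xylem_area_m2))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screen hydraulic-anatomical trait relationships
#'
#' Pearson correlations (with two-sided p-values) between each anatomical
#' trait and each vulnerability parameter across matched varieties. A plain
#' descriptive screen — no mixed-effects structure.
#'
#' @param anatomy Data frame with `variety` and anatomical trait columns.
#' @param fits Data frame with `variety` and vulnerability columns
#'   (e.g. from [aggregate_variety()]).
#' @param anatomy_traits,hydraulic_traits Column names to correlate.
#' @return Data frame with `anatomy_trait`, `hydraulic_trait`, `n`, `r`,
#'   `slope`, `p`.
#' @export
correlate_traits <- function(anatomy, fits,
                             anatomy_traits = c("d_mean_um", "d_h_um",
                                                "v_d_per_mm2", "k_th"),
                             hydraulic_traits = c("psi12_mean", "psi50_mean",
                                                  "psi88_mean")) {
  merged <- merge(anatomy, fits, by = "variety")
  if (nrow(merged) < 3) {
    stop("need at least 3 matched varieties to correlate", call. = FALSE)
  }
  grid <- expand.grid(anatomy_trait = anatomy_traits,
                      hydraulic_trait = hydraulic_traits,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- merged[[grid$anatomy_trait[i]]]
    y <- merged[[grid$hydraulic_trait[i]]]
    ct <- stats::cor.test(x, y)
    data.frame(anatomy_trait = grid$anatomy_trait[i],
               hydraulic_trait = grid$hydraulic_trait[i],
               n = length(x), r = unname(ct$estimate),
               slope = unname(stats::coef(stats::lm(y ~ x))[2]),
               p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
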