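#' Percentage loss of conductivity from a single conductivity sweep
#'
#' Converts one plant's flow-centrifuge sweep — hydraulic conductivity `k`
#' measured at a series of strictly decreasing induced xylem pressures — into
#' a PLC curve: `plc_i = 100 * (1 - k_i / k_max)`, where `k_max` is the
#' conductivity at the FIRST (least negative) pressure of the sweep, the
#' protocol's reference reading. The first point is therefore 0 by
#' construction. Under measurement noise later readings can exceed `k_max`;
#' the resulting slightly negative PLC values are retained (least squares on
#' the raw values is unbiased) and flagged in the `qc_negative` attribute.
#'
#' @param sweep Data frame with columns `psi_mpa` (strictly decreasing, MPa)
#'   and `k` (conductivity, kg m^-1 s^-1 MPa^-1, >= 0). Extra id columns
#'   (`plant_id`, `variety`, `season`, `organ`) are carried through.
#' @return Data frame with the sweep columns plus `plc` (%). Attribute
#'   `qc_negative` gives the count of negative PLC values.
#' @examples
#' compute_plc(data.frame(psi_mpa = c(-0.8, -2, -4), k = c(2, 1, 0)))
#' @export
compute_plc <- function(sweep) {
  stopifnot(is.data.frame(sweep), all(c("psi_mpa", "k") %in% names(sweep)))
  if (any(diff(sweep$psi_mpa) >= 0)) {
    stop("sweep pressures must be strictly decreasing", call. = FALSE)
  }
  k_max <- sweep$k[1L]
  if (!is.finite(k_max) || k_max <= 0) {
    stop("unusable sweep: reference conductivity k_max is zero or invalid",
         call. = FALSE)
  }
  out <- sweep
  out$plc <- 100 * (1 - sweep$k / k_max)
  attr(out, "qc_negative") <- sum(out$plc < 0)
  out
}

#' Fit the Pammenter sigmoid to a vulnerability curve
#'
#' Least-squares estimation of (psi50, S) for [pammenter_plc()] on observed
#' (pressure, PLC) points, one curve per plant or leaf. Fitting is refused
#' for curves with fewer than `min_points` points or spanning fewer than
#' `min_span` PLC units, since the sigmoid is unidentifiable on flat data.
#'
#' psi50 is initialized at the linearly interpolated pressure where PLC
#' crosses 50 (falling back to the median pressure when the curve never
#' crosses), and S at 50 % MPa^-1. Bounds are psi50 in [-10, 0] and
#' S in (0, 500]. Levenberg-Marquardt least squares is used, with a bounded
#' quasi-Newton refinement as fallback if it fails to converge.
#'
#' @param curve Data frame with columns `psi_mpa` and `plc` (as from
#'   [compute_plc()]), or with `psi_mpa` and `pep` for optical curves.
#' @param min_points Minimum number of points (default 4).
#' @param min_span Minimum PLC span in percent (default 30).
#' @param lower,upper Parameter bounds, `c(psi50, slope)`.
#' @param tol Convergence tolerance on the sum of squares (default 1e-8).
#' @param max_iter Iteration cap (default 1000).
#' @return Object of class `vc_fit`: list with `psi50`, `slope`, `psi12`,
#'   `psi88`, `sse`, `converged`, `n_points`, and `data`.
#' @examples
#' psi <- seq(-0.8, -5.3, by = -0.5)
#' fit <- fit_pammenter(data.frame(psi_mpa = psi,
#'                                 plc = pammenter_plc(psi, -2.5, 50)))
#' fit$psi50
#' @export
fit_pammenter <- function(curve, min_points = 4L, min_span = 30,
                          lower = c(-10, 1e-6), upper = c(0, 500),
                          tol = 1e-8, max_iter = 1000L) {
  stopifnot(is.data.frame(curve), "psi_mpa" %in% names(curve))
  plc_col <- if ("plc" %in% names(curve)) "plc" else "pep"
  if (!plc_col %in% names(curve)) {
    stop("curve needs a `plc` (or `pep`) column", call. = FALSE)
  }
  psi <- curve$psi_mpa
  plc <- curve[[plc_col]]
  ok <- is.finite(psi) & is.finite(plc)
  psi <- psi[ok]; plc <- plc[ok]
  if (length(psi) < min_points) {
    stop("refusing to fit: fewer than ", min_points, " usable points",
         call. = FALSE)
  }
  if (diff(range(plc)) < min_span) {
    stop("refusing to fit: PLC span below ", min_span,
         " percent (flat curve)", call. = FALSE)
  }

  psi50_init <- init_psi50(psi, plc)
  start <- c(psi50 = min(max(psi50_init, lower[1]), upper[1]),
             slope = 50)

  sse_fun <- function(p) sum((plc - pammenter_plc(psi, p[1], p[2]))^2)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      plc ~ pammenter_plc(psi, psi50, slope),
      data = list(psi = psi, plc = plc),
      start = as.list(start), lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        maxiter = min(max_iter, 1024L), ftol = tol)),
    error = function(e) NULL)

  if (!is.null(fit)) {
    est <- stats::coef(fit)
    converged <- isTRUE(fit$convInfo$isConv)
  } else {
    est <- start
    converged <- FALSE
  }
  # polish (or rescue) with bounded quasi-Newton on the SSE surface
  opt <- stats::optim(est, sse_fun, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = max_iter, factr = 1e4))
  if (opt$value < sse_fun(est)) {
    est <- opt$par
    converged <- converged || opt$convergence == 0L
  }

  thr <- derive_thresholds(est[[1]], est[[2]])
  structure(list(
    psi50 = est[[1]], slope = est[[2]],
    psi12 = thr$psi12, psi88 = thr$psi88,
    sse = sse_fun(est), converged = converged,
    n_points = length(psi),
    data = data.frame(psi_mpa = psi, plc = plc)
  ), class = "vc_fit")
}

# pressure at which the observed curve crosses 50% PLC, by linear
# interpolation along the sweep; median pressure when it never crosses
init_psi50 <- function(psi, plc) {
  cross <- which(plc[-1] >= 50 & plc[-length(plc)] < 50)
  if (length(cross) == 0) return(stats::median(psi))
  i <- cross[1]
  w <- (50 - plc[i]) / (plc[i + 1] - plc[i])
  psi[i] + w * (psi[i + 1] - psi[i])
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("Pammenter vulnerability fit (", x$n_points, " points)\n", sep = "")
  cat(sprintf("  psi50 = %.3f MPa   S = %.1f %%/MPa\n", x$psi50, x$slope))
  cat(sprintf("  psi12 = %.3f MPa   psi88 = %.3f MPa\n", x$psi12, x$psi88))
  cat(sprintf("  SSE = %.4g   converged: %s\n", x$sse, x$converged))
  invisible(x)
}

#' @export
plot.vc_fit <- function(x, ...) {
  graphics::plot(x$data$psi_mpa, x$data$plc, xlab = "Xylem pressure (MPa)",
                 ylab = "PLC (%)", ylim = c(min(0, x$data$plc), 100), ...)
  ps <- seq(min(x$data$psi_mpa), max(x$data$psi_mpa), length.out = 200)
  graphics::lines(ps, pammenter_plc(ps, x$psi50, x$slope))
  graphics::abline(h = 50, lty = 3)
  invisible(x)
}

#' Fit every plant in a long sweep table
#'
#' Convenience wrapper: splits a long table of sweeps by plant, computes PLC
#' and fits each curve. Curves that are refused or fail to converge are
#' reported with `converged = FALSE` and NA parameters rather than dropped.
#'
#' @param sweeps Long data frame with `plant_id`, `variety`, `season`,
#'   `organ`, `psi_mpa`, `k`.
#' @param ... Passed to [fit_pammenter()].
#' @return Data frame, one row per plant: id columns, `psi50`, `slope`,
#'   `psi12`, `psi88`, `sse`, `converged`, `n_points`.
#' @export
fit_sweeps <- function(sweeps, ...) {
  stopifnot(all(c("plant_id", "psi_mpa", "k") %in% names(sweeps)))
  ids <- unique(sweeps$plant_id)
  rows <- lapply(ids, function(id) {
    sw <- sweeps[sweeps$plant_id == id, , drop = FALSE]
    sw <- sw[order(-sw$psi_mpa), , drop = FALSE]
    meta <- sw[1, intersect(c("plant_id", "variety", "season", "organ"),
                            names(sw)), drop = FALSE]
    fit <- tryCatch(fit_pammenter(compute_plc(sw), ...),
                    error = function(e) NULL)
    if (is.null(fit)) {
      cbind(meta, data.frame(psi50 = NA_real_, slope = NA_real_,
                             psi12 = NA_real_, psi88 = NA_real_,
                             sse = NA_real_, converged = FALSE,
                             n_points = nrow(sw)))
    } else {
      cbind(meta, data.frame(psi50 = fit$psi50, slope = fit$slope,
                             psi12 = fit$psi12, psi88 = fit$psi88,
                             sse = fit$sse, converged = fit$converged,
                             n_points = fit$n_points))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Variety-level summary of vulnerability parameters
#'
#' Averages converged per-plant fits by grouping keys (variety, season,
#' organ), reporting the arithmetic mean and standard error of each
#' parameter. SE is NA for single-plant groups.
#'
#' @param fits Data frame as returned by [fit_sweeps()] (converged rows are
#'   used; others are dropped with a warning).
#' @param by Character vector of grouping columns present in `fits`.
#' @return Data frame with one row per group: grouping keys, `n_plants`,
#'   and `<param>_mean` / `<param>_se` for psi12, psi50, psi88 and slope.
#' @export
aggregate_variety <- function(fits, by = c("variety", "season", "organ")) {
  by <- intersect(by, names(fits))
  stopifnot(length(by) >= 1, nrow(fits) >= 1)
  drop <- !fits$converged | is.na(fits$psi50)
  if (any(drop)) {
    warning(sum(drop), " non-converged fit(s) excluded from aggregation")
    fits <- fits[!drop, , drop = FALSE]
  }
  if (nrow(fits) == 0) stop("no converged fits to aggregate", call. = FALSE)
  params <- c("psi12", "psi50", "psi88", "slope")
  key <- interaction(fits[by], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(fits, key), function(g) {
    out <- g[1, by, drop = FALSE]
    out$n_plants <- nrow(g)
    for (p in params) {
      out[[paste0(p, "_mean")]] <- mean(g[[p]])
      out[[paste0(p, "_se")]] <- if (nrow(g) > 1) {
        stats::sd(g[[p]]) / sqrt(nrow(g))
      } else NA_real_
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-group comparison of a vulnerability parameter
#'
#' Pooled-variance two-sided Student's t-test on one fitted parameter
#' between two groups of plants (e.g. spring vs summer for one variety).
#'
#' @param group_a,group_b Data frames of per-plant fits (rows with the
#'   parameter column), n >= 2 each.
#' @param param Parameter column to compare (default `"psi50"`).
#' @return List with `delta` (mean_b - mean_a), `t`, `df`, `p`, and
#'   `degenerate` (TRUE when both groups have zero variance, in which case
#'   t and p are NA).
#' @export
compare_groups <- function(group_a, group_b, param = "psi50") {
  a <- group_a[[param]]; b <- group_b[[param]]
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least 2 plants per group", call. = FALSE)
  }
  delta <- mean(b) - mean(a)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(list(delta = delta, t = NA_real_, df = length(a) + length(b) - 2,
                p = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(b, a, var.equal = TRUE)
  list(delta = delta, t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Hydraulic vulnerability segmentation between leaf and stem
#'
#' Difference in embolism thresholds between a leaf (optical technique) and
#' the stem (flow centrifuge) of the same variety and season:
#' `HVS_psiX = psiX(leaf) - psiX(stem)`. Positive values mean the leaf
#' embolizes at less negative pressure than the stem, i.e. leaves act as
#' hydraulic fuses.
#'
#' @param leaf_summary,stem_summary One-row data frames with `variety`,
#'   `season`, `psi12_mean`, `psi50_mean` (as from [aggregate_variety()]);
#'   `leaf_summary` may carry a `leaf_position` column.
#' @return Data frame with `variety`, `season`, `leaf_position` (if
#'   present), `hvs_psi12`, `hvs_psi50` (MPa).
#' @export
compute_hvs <- function(leaf_summary, stem_summary) {
  stopifnot(nrow(leaf_summary) == 1, nrow(stem_summary) == 1)
  if (!identical(leaf_summary$variety, stem_summary$variety) ||
      !identical(leaf_summary$season, stem_summary$season)) {
    stop("leaf and stem summaries must match in variety and season",
         call. = FALSE)
  }
  out <- data.frame(variety = leaf_summary$variety,
                    season = leaf_summary$season)
  if ("leaf_position" %in% names(leaf_summary)) {
    out$leaf_position <- leaf_summary$leaf_position
  }
  out$hvs_psi12 <- leaf_summary$psi12_mean - stem_summary$psi12_mean
  out$hvs_psi50 <- leaf_summary$psi50_mean - stem_summary$psi50_mean
  out
}
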