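#' Cluster weights on the 0-1 vulnerability scale
#'
#' The four vulnerability classes partition the 0-1 scale into quarters;
#' each class is scored by its quarter's median: low 0.125, low-to-medium
#' 0.375, medium-to-high 0.625, high 0.875.
#' @return Named numeric vector of weights.
#' @export
cluster_weights <- function() {
  c(low = 0.125, `low-to-medium` = 0.375,
    `medium-to-high` = 0.625, high = 0.875)
}

#' Z-score a varietal trait matrix
#'
#' Column-wise standardization, `z = (observed - mean) / sd`, with the
#' sample (n - 1) standard deviation. Zero-variance columns are an error:
#' they carry no clustering information and would divide by zero.
#'
#' @param traits Numeric matrix or data frame (rows = varieties, columns =
#'   traits such as psi12/psi50/psi88 variety means); rownames identify
#'   varieties.
#' @return Numeric matrix of z-scores with the input's dimnames; the raw
#'   matrix is kept in attribute `raw`.
#' @export
zscore_traits <- function(traits) {
  m <- as.matrix(traits)
  stopifnot(is.numeric(m), nrow(m) >= 2, !anyNA(m))
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  z <- scale(m)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  attr(z, "raw") <- m
  z
}

#' Ward hierarchical clustering of varieties
#'
#' Agglomerative clustering on the Euclidean distance matrix of the
#' z-scored traits with the Ward criterion (Ward.D2: merges minimize the
#' increase in within-cluster variance), cut into `k` clusters. Entirely
#' deterministic.
#'
#' @param z Z-scored trait matrix from [zscore_traits()].
#' @param k Number of clusters (default 4).
#' @return List with `cluster` (named integer vector of arbitrary cluster
#'   ids), `hclust` (the dendrogram object) and `k`.
#' @export
ward_cluster <- function(z, k = 4L) {
  stopifnot(nrow(z) >= k, k >= 1)
  hc <- stats::hclust(stats::dist(z, method = "euclidean"),
                      method = "ward.D2")
  list(cluster = stats::cutree(hc, k = k), hclust = hc, k = k)
}

#' Order clusters by vulnerability and attach weights
#'
#' Ranks clusters by their centroid mean raw psi50, most negative first:
#' the most embolism-resistant cluster is labelled `low` (vulnerability),
#' the least negative `high`. Centroid ties are broken by psi88, then
#' psi12. Labels map to the weights of [cluster_weights()].
#'
#' @param clustering Result of [ward_cluster()].
#' @param raw_traits Raw (unscaled) trait matrix with a `psi50` column
#'   (and ideally `psi88`, `psi12` for tie-breaks), rows matching the
#'   clustered varieties.
#' @return Data frame with `variety`, `cluster` (ordered factor label) and
#'   `weight`.
#' @export
label_clusters <- function(clustering, raw_traits) {
  m <- as.matrix(raw_traits)
  stopifnot("psi50" %in% colnames(m),
            length(clustering$cluster) == nrow(m))
  ids <- sort(unique(clustering$cluster))
  if (length(ids) != 4) {
    stop("labelling expects exactly 4 clusters, got ", length(ids),
         call. = FALSE)
  }
  centroid <- function(col) {
    if (!col %in% colnames(m)) return(rep(0, length(ids)))
    vapply(ids, function(i) mean(m[clustering$cluster == i, col]),
           numeric(1))
  }
  ord <- order(centroid("psi50"), centroid("psi88"), centroid("psi12"))
  labels <- names(cluster_weights())
  lab_by_id <- character(length(ids))
  lab_by_id[ord] <- labels
  lab <- lab_by_id[match(clustering$cluster, ids)]
  data.frame(
    variety = rownames(m),
    cluster = factor(lab, levels = labels, ordered = TRUE),
    weight = unname(cluster_weights()[lab])
  )
}

#' Cluster varieties into four vulnerability classes
#'
#' One-call wrapper: z-score the threshold traits, Ward-cluster, and label
#' the four clusters from low to high vulnerability.
#'
#' @param summary_table Data frame with `variety` and `psi12_mean`,
#'   `psi50_mean`, `psi88_mean` columns (one row per variety), or a matrix
#'   with columns psi12/psi50/psi88 and variety rownames.
#' @param k Number of clusters (default 4).
#' @return List with `assignment` (variety, cluster, weight), `hclust`, `z`.
#' @export
cluster_varieties <- function(summary_table, k = 4L) {
  if (is.data.frame(summary_table) && "variety" %in% names(summary_table)) {
    m <- as.matrix(summary_table[, c("psi12_mean", "psi50_mean",
                                     "psi88_mean")])
    colnames(m) <- c("psi12", "psi50", "psi88")
    rownames(m) <- summary_table$variety
  } else {
    m <- as.matrix(summary_table)
  }
  z <- zscore_traits(m)
  cl <- ward_cluster(z, k = k)
  list(assignment = label_clusters(cl, m), hclust = cl$hclust, z = z)
}
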