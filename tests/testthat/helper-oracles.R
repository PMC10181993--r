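# Independent brute-force oracles used across tests. These deliberately do
# not share code with the package implementation.

# queue-based flood-fill connected-component labelling
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  cur <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c] && lab[r, c] == 0L) {
      cur <- cur + 1L
      queue <- list(c(r, c)); lab[r, c] <- cur
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(nb))) {
          rr <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              mask[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- cur
            queue[[length(queue) + 1]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

# grid-search SSE minimum for the sigmoid, the fit oracle
grid_search_sse <- function(psi, plc, n_grid = 200,
                            psi50_range = c(-8, 0), s_range = c(1, 300)) {
  psi50s <- seq(psi50_range[1], psi50_range[2], length.out = n_grid)
  slopes <- seq(s_range[1], s_range[2], length.out = n_grid)
  best <- Inf
  for (s in slopes) {
    # vectorized over the psi50 grid: n_grid x n_points model matrix
    dpsi <- outer(psi50s, psi, function(p50, p) p - p50)
    model <- 100 / (1 + exp(s / 25 * dpsi))
    sse <- rowSums((matrix(plc, n_grid, length(plc), byrow = TRUE) - model)^2)
    best <- min(best, min(sse))
  }
  best
}

# greedy O(n^3) Ward.D2 agglomeration: returns the sequence of merged
# member sets (each a sorted integer vector of original row indices)
ward_oracle_merges <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), identity)
  merges <- list()
  ward_d <- function(a, b) {
    ca <- colMeans(x[a, , drop = FALSE]); cb <- colMeans(x[b, , drop = FALSE])
    sqrt(2 * length(a) * length(b) / (length(a) + length(b))) *
      sqrt(sum((ca - cb)^2))
  }
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- ward_d(clusters[[i]], clusters[[j]])
        if (d < bestd) { bestd <- d; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# member sets merged at each step of an hclust tree, comparable to the oracle
hclust_merges <- function(hc) {
  sets <- list()
  members <- list()
  for (s in seq_len(nrow(hc$merge))) {
    get <- function(v) if (v < 0) -v else members[[v]]
    m <- sort(c(get(hc$merge[s, 1]), get(hc$merge[s, 2])))
    members[[s]] <- m
    sets[[s]] <- m
  }
  sets
}

# adjusted Rand index between two labelings (closed form over the
# contingency table); avoids depending on the implementation under test
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
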