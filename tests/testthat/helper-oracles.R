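# Fixture builders and independent brute-force oracles used across tests.
# Oracles deliberately use naive loops / closed forms, not the package's
# code paths.

# A random single-ligand expr_matrix over a full cell-line x time grid.
random_grid_matrix <- function(n_probes, cell_lines, ligand = "BMP4",
                               sd = 1, seed = 1) {
  set.seed(seed)
  ek <- event_key(rep(cell_lines, each = 6L), ligand,
                  rep(CANONICAL_TIMES, length(cell_lines)))
  v <- matrix(rnorm(n_probes * nrow(ek), 0, sd), n_probes, nrow(ek))
  rownames(v) <- sprintf("p%04d", seq_len(n_probes))
  expr_matrix(v, ek)
}

# --- brute-force filter oracles (per-cell scans) ---------------------------

oracle_cellline <- function(x, fc2 = 2) {
  keep <- character(0)
  for (p in rownames(x$values)) {
    hit <- FALSE
    for (j in seq_len(ncol(x$values))) {
      v <- x$values[p, j]
      if (!is.na(v) && abs(v) >= log2(fc2)) hit <- TRUE
    }
    if (hit) keep <- c(keep, p)
  }
  keep
}

oracle_timepoint <- function(x, tp, fc2 = 2) {
  cols <- which(x$events$time_h == tp)
  keep <- character(0)
  for (p in rownames(x$values)) {
    hit <- FALSE
    for (j in cols) {
      v <- x$values[p, j]
      if (!is.na(v) && abs(v) >= log2(fc2)) hit <- TRUE
    }
    if (hit) keep <- c(keep, p)
  }
  keep
}

oracle_general <- function(x, fc2 = 2, fc3 = 3, n3 = 3, n2 = 4) {
  keep <- character(0)
  for (p in rownames(x$values)) {
    c2 <- 0; c3 <- 0
    for (j in seq_len(ncol(x$values))) {
      v <- x$values[p, j]
      if (is.na(v)) next
      if (abs(v) >= log2(fc3)) c3 <- c3 + 1
      if (abs(v) >= log2(fc2)) c2 <- c2 + 1
    }
    if (c3 >= n3 || c2 >= n2) keep <- c(keep, p)
  }
  keep
}

oracle_counts <- function(x, fc2 = 2) {
  t(vapply(rownames(x$values), function(p) {
    up <- 0; down <- 0
    for (j in seq_len(ncol(x$values))) {
      v <- x$values[p, j]
      if (is.na(v)) next
      if (v >= log2(fc2)) up <- up + 1
      if (v <= -log2(fc2)) down <- down + 1
    }
    c(up = up, down = down)
  }, c(up = 0, down = 0)))
}

# --- naive O(n^3) UPGMA oracle ---------------------------------------------
# Returns merges in hclust encoding (negative = leaf) and heights.
oracle_upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))       # member leaf sets
  code <- -seq_len(n)                 # hclust node codes
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(active)) for (j in seq_len(i - 1L)) {
      # unweighted mean over all cross pairs
      h <- mean(d[active[[i]], active[[j]]])
      if (h < bh - 1e-15) { bh <- h; best <- c(j, i) }
    }
    i <- best[2L]; j <- best[1L]
    a <- code[j]; b <- code[i]
    merges[step, ] <- sort(c(a, b))
    heights[step] <- bh
    active[[j]] <- c(active[[j]], active[[i]])
    code[j] <- step
    active[[i]] <- NULL
    code <- code[-i]
  }
  list(merge = merges, height = heights)
}

# --- exact hypergeometric tail by enumeration ------------------------------
oracle_hyper_tail <- function(k, m, N, K) {
  i <- k:min(m, K)
  sum(choose(m, i) * choose(N - m, K - i)) / choose(N, K)
}
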