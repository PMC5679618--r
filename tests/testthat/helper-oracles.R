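# Independent oracles and fixture builders shared across the test files.
# Each oracle is a deliberately naive re-derivation of the quantity it
# checks, kept independent of the package's computation path.

# Brute-force Colwell metrics straight from the entropy definitions,
# base-2 logarithms on purpose (the package uses natural logs; the
# normalization by log s must make that invisible).
oracle_colwell <- function(counts) {
  Z <- sum(counts)
  s <- nrow(counts)
  h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  HX <- h(colSums(counts) / Z)
  HY <- h(rowSums(counts) / Z)
  HXY <- h(as.vector(counts) / Z)
  list(C = 1 - HY / log2(s),
       M = (HX + HY - HXY) / log2(s),
       P = 1 - (HXY - HX) / log2(s))
}

# Naive UPGMA: recompute every between-cluster average from the original
# distance matrix at every step; same lexicographic tie rule as the package.
oracle_upgma <- function(d) {
  n <- nrow(d)
  labels <- colnames(d)
  clusters <- lapply(seq_len(n), identity)   # member leaf indices
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    best <- NULL
    for (a in seq_len(k - 1L)) for (b in seq((a + 1L), k)) {
      avg <- mean(d[clusters[[a]], clusters[[b]]])
      la <- sort(c(min(labels[clusters[[a]]]), min(labels[clusters[[b]]])))
      if (is.null(best) || avg < best$avg ||
          (avg == best$avg && (la[1L] < best$la[1L] ||
            (la[1L] == best$la[1L] && la[2L] < best$la[2L])))) {
        best <- list(avg = avg, la = la, a = a, b = b)
      }
    }
    a <- best$a; b <- best$b
    merge[step, ] <- sort(c(ids[a], ids[b]))
    height[step] <- best$avg
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    ids[a] <- step
    clusters[[b]] <- NULL
    ids <- ids[-b]
  }
  list(merge = merge, height = height)
}

# Per-pixel classification oracle: literal transcription of the 2cA rule.
oracle_classify <- function(green, nir, mir, cloud) {
  if (cloud) return("cloud")
  idx <- if (green + mir == 0) 0 else (green - mir) / (green + mir)
  if (idx <= 0) return("soil")
  if (nir >= 0.4) return("salt")
  "water"
}

# Hand-built series: explicit dates/areas, cloud-free unless stated.
make_series <- function(dates, areas, area_max = areas, cf = 0, pond_id = 1) {
  pond_series(pond_id, as.Date(dates), areas, area_max, cf)
}

# Never-dry synthetic world: mild seasonality, small noise, no clouds.
never_dry_truth <- function(seed = 1) {
  series_truth(seasonal = function(d) 1 + 0.5 * cos(2 * pi * (d - 46) / 365.25),
               noise_sd = 0.1, dry_threshold = 0, cloud_prob = 0, seed = seed)
}

# Two latent model groups, group B negatively loaded; optional duplicate of
# the first model. Rows = ponds.
two_group_estimates <- function(n_ponds = 20, noise = 0.3, seed = 1,
                                duplicate = FALSE) {
  set.seed(seed)
  z <- rnorm(n_ponds)
  m <- cbind(A1 = 1.0 + z + rnorm(n_ponds, 0, noise),
             A2 = 2.0 + 0.8 * z + rnorm(n_ponds, 0, noise),
             A3 = 0.5 + 1.2 * z + rnorm(n_ponds, 0, noise),
             B1 = 1.0 - z + rnorm(n_ponds, 0, noise),
             B2 = 3.0 - 0.9 * z + rnorm(n_ponds, 0, noise))
  if (duplicate) m <- cbind(m, A1dup = m[, "A1"])
  rownames(m) <- sprintf("P%02d", seq_len(n_ponds))
  m
}

# Random contingency tables for fuzz tests.
random_table <- function(s, max_count = 30) {
  matrix(sample(0:max_count, s * 12L, replace = TRUE), nrow = s)
}

# Leaf indices under internal node s of an hclust-style merge matrix.
dendrogram_members <- function(dend, s) {
  unlist(lapply(dend$merge[s, ], function(v) {
    if (v < 0) -v else dendrogram_members(dend, v)
  }))
}

# Random symmetric distance matrix with zero diagonal.
random_dist <- function(n, labels = LETTERS[seq_len(n)]) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.05, 2)
  m + t(m)
}
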