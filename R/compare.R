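# Comparison of predictability estimates across models: Pearson correlation,
# chord distance, UPGMA, bootstrap clade support, threshold cut.

#' Build a ponds x models estimate matrix
#'
#' @param estimates either a numeric matrix (ponds in rows, models in
#'   columns, dimnames set) or a long data.frame with columns `pond_id`,
#'   `model`, `predictability`.
#' @param models optional column order (default: order of appearance).
#' @return numeric matrix with pond ids as rownames and model names as
#'   colnames; ponds with any missing or non-finite estimate are dropped
#'   listwise with a warning.
#' @export
estimate_matrix <- function(estimates, models = NULL) {
  if (is.matrix(estimates)) {
    m <- estimates
  } else {
    need <- c("pond_id", "model", "predictability")
    if (!all(need %in% names(estimates))) {
      stop_pond("pond_input_error", "estimates need columns: %s",
                paste(need, collapse = ", "))
    }
    models <- models %||% unique(estimates$model)
    ponds <- unique(estimates$pond_id)
    m <- matrix(NA_real_, length(ponds), length(models),
                dimnames = list(as.character(ponds), models))
    for (i in seq_len(nrow(estimates))) {
      m[as.character(estimates$pond_id[i]),
        as.character(estimates$model[i])] <- estimates$predictability[i]
    }
  }
  bad <- !apply(m, 1L, function(r) all(is.finite(r)))
  if (any(bad)) {
    warning(sprintf("dropping %d pond(s) with missing/non-finite estimates: %s",
                    sum(bad), paste(rownames(m)[bad], collapse = ", ")))
    m <- m[!bad, , drop = FALSE]
  }
  m
}

#' Pearson correlation matrix between models
#'
#' @param est ponds x models matrix from [estimate_matrix()].
#' @param exclude_ponds pond rownames to drop before correlating (the
#'   analysis is typically run with and without the most ephemeral ponds).
#' @return symmetric models x models correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(est, exclude_ponds = NULL) {
  if (!is.null(exclude_ponds)) {
    est <- est[!rownames(est) %in% as.character(exclude_ponds), , drop = FALSE]
  }
  if (nrow(est) < 3L) {
    stop_pond("pond_input_error", "need at least 3 ponds for correlations")
  }
  sds <- apply(est, 2L, sd)
  if (any(sds == 0)) {
    stop_pond("pond_estimation_error",
              "zero-variance model column(s): %s",
              paste(colnames(est)[sds == 0], collapse = ", "))
  }
  r <- cor(est)
  diag(r) <- 1
  r
}

#' Chord distance from a Pearson correlation
#'
#' `d = sqrt(2 - 2 r)`: 0 at r = 1, sqrt(2) at r = 0, 2 at r = -1. Strictly
#' decreasing in r, which turns a correlation matrix into a metric
#' dissimilarity.
#'
#' @param r correlation value(s) or matrix, in \[-1, 1\] (up to 1e-12
#'   rounding).
#' @return distance(s), same shape as `r`.
#' @export
chord_distance <- function(r) {
  if (any(r < -1 - 1e-12) || any(r > 1 + 1e-12)) {
    stop_pond("pond_input_error", "correlation outside [-1, 1]")
  }
  r <- pmin(pmax(r, -1), 1)
  out <- sqrt(pmax(2 - 2 * r, 0))
  if (is.matrix(r)) out <- matrix(out, nrow(r), ncol(r), dimnames = dimnames(r))
  out
}

#' UPGMA (average linkage) clustering
#'
#' Agglomerates with the unweighted pair-group average: the distance between
#' two clusters is the mean of all between-cluster leaf distances
#' (maintained by the Lance-Williams size-weighted update). The merge height
#' recorded is that average distance itself (not half of it). Ties on the
#' minimum distance are broken lexicographically on the pair of cluster
#' labels, a cluster being labeled by its lexicographically smallest leaf.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal;
#'   dimnames supply the leaf labels.
#' @return object of class `pond_dendrogram`: hclust-style `merge` matrix,
#'   `height` vector (non-decreasing), `labels`, and optionally per-merge
#'   bootstrap `support`.
#' @export
upgma <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop_pond("pond_input_error", "distance must be a square matrix")
  }
  if (max(abs(d - t(d))) > 1e-9 || any(abs(diag(d)) > 1e-12) || any(d < 0)) {
    stop_pond("pond_input_error",
              "distance matrix must be symmetric, non-negative, zero-diagonal")
  }
  n <- nrow(d)
  labels <- colnames(d) %||% paste0("L", seq_len(n))
  if (n < 2L) stop_pond("pond_input_error", "need at least two leaves")
  D <- d
  active <- seq_len(n)             # column indices still in play
  id <- -seq_len(n)                # hclust convention: negatives are leaves
  size <- rep(1L, n)
  lab <- labels                    # cluster label = smallest member leaf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- NULL
    for (a in seq_len(k - 1L)) for (b in seq(a + 1L, k)) {
      i <- active[a]; j <- active[b]
      cand <- list(dist = D[i, j],
                   lab = sort(c(lab[i], lab[j])), i = i, j = j)
      if (is.null(best) || cand$dist < best$dist ||
          (cand$dist == best$dist &&
           (cand$lab[1L] < best$lab[1L] ||
            (cand$lab[1L] == best$lab[1L] && cand$lab[2L] < best$lab[2L])))) {
        best <- cand
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- best$dist
    # Lance-Williams unweighted-average update into slot i
    for (m in setdiff(active, c(i, j))) {
      D[i, m] <- D[m, i] <-
        (size[i] * D[i, m] + size[j] * D[j, m]) / (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    lab[i] <- min(lab[i], lab[j])
    id[i] <- step
    active <- setdiff(active, j)
  }
  structure(list(merge = merge, height = height, labels = labels,
                 support = NULL, method = "upgma"),
            class = "pond_dendrogram")
}

# leaves (indices) under each internal node, in merge order
dendrogram_clades <- function(dend) {
  n <- length(dend$labels)
  clades <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    mem <- unlist(lapply(dend$merge[s, ], function(v) {
      if (v < 0) -v else clades[[v]]
    }))
    clades[[s]] <- sort(mem)
  }
  clades
}

clade_keys <- function(dend) {
  vapply(dendrogram_clades(dend),
         function(m) paste(sort(dend$labels[m]), collapse = "\r"), "")
}

#' @export
print.pond_dendrogram <- function(x, ...) {
  cat(sprintf("<pond_dendrogram> %d leaves (UPGMA), heights %.3g .. %.3g\n",
              length(x$labels), min(x$height), max(x$height)))
  if (!is.null(x$support)) {
    cat(sprintf("  bootstrap support (n_boot = %d): %s\n", x$n_boot,
                paste(sprintf("%.2f", x$support), collapse = ", ")))
  }
  invisible(x)
}

#' @export
as.hclust.pond_dendrogram <- function(x, ...) {
  n <- length(x$labels)
  ord <- integer(0)
  walk <- function(v) {
    if (v < 0) ord <<- c(ord, -v)
    else { walk(x$merge[v, 1L]); walk(x$merge[v, 2L]) }
  }
  walk(n - 1L)
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "chord"),
            class = "hclust")
}

#' Cut a dendrogram into clusters at a distance threshold
#'
#' Clusters are the connected components formed by the merges whose height
#' is at most the threshold. At threshold 0, only exact duplicates (merge
#' height 0) stay together; at or above the maximum height everything is one
#' cluster.
#'
#' @param dend a [upgma()] dendrogram.
#' @param threshold non-negative cut distance.
#' @return named list of character vectors (leaf labels per cluster),
#'   ordered by each cluster's first leaf.
#' @export
cut_clusters <- function(dend, threshold) {
  if (!is.numeric(threshold) || threshold < 0) {
    stop_pond("pond_input_error", "threshold must be >= 0")
  }
  n <- length(dend$labels)
  comp <- seq_len(n)
  clades <- dendrogram_clades(dend)
  for (s in seq_len(n - 1L)) {
    if (dend$height[s] <= threshold) {
      mem <- clades[[s]]
      comp[comp %in% comp[mem]] <- min(comp[mem])
    }
  }
  groups <- split(dend$labels, comp)
  names(groups) <- NULL
  groups[order(vapply(groups, function(g) min(match(g, dend$labels)), 1L))]
}

#' UPGMA with bootstrap clade support
#'
#' Resamples ponds (rows) with replacement `n_boot` times, rebuilds the
#' correlation, chord-distance and UPGMA tree for each resample, and scores
#' every internal node of the full-data tree by the proportion of bootstrap
#' trees containing the same set of leaves (ordinary bootstrap proportion,
#' not a multiscale-corrected value). Replicates in which some model column
#' has zero variance are skipped but remain in the denominator (conservative
#' support). Ponds are sorted by id before resampling, so the result is
#' invariant to input row order; it is reproducible for a fixed seed.
#'
#' @param est ponds x models matrix from [estimate_matrix()].
#' @param n_boot number of bootstrap resamples (>= 1).
#' @param seed integer RNG seed.
#' @param exclude_ponds passed to [correlation_matrix()].
#' @return the full-data [upgma()] dendrogram with `support` (per merge,
#'   in merge order), `n_boot` and `n_skipped` attached.
#' @export
bootstrap_support <- function(est, n_boot, seed = 1, exclude_ponds = NULL) {
  if (!is.numeric(n_boot) || n_boot < 1) {
    stop_pond("pond_input_error", "n_boot must be >= 1")
  }
  if (!is.null(exclude_ponds)) {
    est <- est[!rownames(est) %in% as.character(exclude_ponds), , drop = FALSE]
  }
  est <- est[order(rownames(est)), , drop = FALSE]
  base <- upgma(chord_distance(correlation_matrix(est)))
  keys <- clade_keys(base)
  hits <- setNames(numeric(length(keys)), keys)
  n_skipped <- 0L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  np <- nrow(est)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(np, np, replace = TRUE)
    bm <- est[idx, , drop = FALSE]
    if (any(apply(bm, 2L, sd) == 0)) { n_skipped <- n_skipped + 1L; next }
    bt <- upgma(chord_distance(cor(bm)))
    bk <- clade_keys(bt)
    present <- keys %in% bk
    hits[present] <- hits[present] + 1
  }
  base$support <- as.numeric(hits / n_boot)
  base$n_boot <- as.integer(n_boot)
  base$n_skipped <- n_skipped
  base
}

#' Export a dendrogram (with support) to Newick
#'
#' @param dend a [upgma()] / [bootstrap_support()] dendrogram.
#' @param path optional file; when `NULL` the Newick string is returned.
#' @return Newick string (invisibly when written to file). Internal node
#'   labels carry bootstrap support when present.
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  phy <- ape::as.phylo(as.hclust.pond_dendrogram(dend))
  if (!is.null(dend$support)) {
    # ape internal node numbering: root = Ntip+1 corresponds to last merge
    n <- length(dend$labels)
    m2node <- match(seq_len(n - 1L), (n - 1L):1L) + n
    lab <- rep(NA_character_, phy$Nnode)
    # map merges to phylo nodes via clade membership
    clades <- dendrogram_clades(dend)
    phy_cl <- lapply(seq_len(phy$Nnode) + n, function(nd) {
      sort(unlist(phangorn_descendants(phy, nd)))
    })
    for (s in seq_along(clades)) {
      tgt <- sort(match(dend$labels[clades[[s]]], phy$tip.label))
      hit <- which(vapply(phy_cl, identical, TRUE, y = tgt))
      if (length(hit) == 1L) lab[hit] <- sprintf("%.3f", dend$support[s])
    }
    phy$node.label <- lab
  }
  txt <- ape::write.tree(phy)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

# minimal descendant-tips helper (avoids a phangorn dependency)
phangorn_descendants <- function(phy, node) {
  n <- length(phy$tip.label)
  if (node <= n) return(node)
  kids <- phy$edge[phy$edge[, 1L] == node, 2L]
  unlist(lapply(kids, phangorn_descendants, phy = phy))
}
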