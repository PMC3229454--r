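# Correlation-based average-linkage clustering and synexpression groups.
#
# Probes surviving the general filter are clustered with UPGMA on the
# correlation distance d = 1 - Pearson(r). Tight clusters (the visually
# boxed groups on a clustered heat map) are operationalized as the groups
# obtained by cutting the tree at a height threshold, kept when they are
# large enough and internally correlated enough. The synexpression group
# shared between the two ligands is the probe-level intersection of one
# tight cluster per ligand.

#' Correlation distance between two profiles
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return `1 - cor(x, y)` (Pearson), in `[0, 2]`.
#' @export
correlation_distance <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length")
  if (length(x) < 3L) stop("profiles must have length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance profile")
  1 - stats::cor(x, y)
}

#' Average-linkage (UPGMA) clustering on correlation distance
#'
#' @param x `expr_matrix` or plain numeric matrix (rows = probes). Rows
#'   with zero variance across events are dropped with a warning; rows
#'   with missing values are dropped likewise (pairwise correlations on
#'   differing event subsets would break the metric).
#' @return object of class `bmp_dendrogram`: list with `hclust` (the
#'   `stats::hclust` tree, method `"average"`), `labels`, and `dist_matrix`
#'   (the correlation-distance `dist`).
#' @export
average_linkage_cluster <- function(x) {
  v <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  if (is.null(rownames(v))) rownames(v) <- paste0("row", seq_len(nrow(v)))
  ok <- stats::complete.cases(v)
  if (!all(ok)) {
    warning(sum(!ok), " probe(s) with missing values dropped before clustering")
    v <- v[ok, , drop = FALSE]
  }
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance probe(s) dropped before clustering")
    v <- v[sds > 0, , drop = FALSE]
  }
  if (nrow(v) < 2L) stop("need >= 2 usable probes to cluster")
  d <- stats::as.dist(1 - stats::cor(t(v)))
  h <- stats::hclust(d, method = "average")
  structure(list(hclust = h, labels = rownames(v), dist_matrix = d),
            class = "bmp_dendrogram")
}

#' @export
print.bmp_dendrogram <- function(x, ...) {
  cat(sprintf("bmp_dendrogram: %d leaves, %d merges, height range [%.4g, %.4g]\n",
              length(x$labels), nrow(x$hclust$merge),
              min(x$hclust$height), max(x$hclust$height)))
  invisible(x)
}

#' Export a dendrogram as a Newick string
#'
#' Merge heights become node depths, so branch lengths sum to the merge
#' height (ultrametric tree).
#'
#' @param dend `bmp_dendrogram`.
#' @param path optional file; when given the tree is written there.
#' @return the Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  phy <- ape::as.phylo(dend$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Export a dendrogram merge list as JSON
#'
#' @param dend `bmp_dendrogram`.
#' @param path optional output file.
#' @return JSON string with `labels` and a `merges` array of
#'   `[node_a, node_b, height]` triples (negative indices = leaves, as in
#'   `stats::hclust`).
#' @export
dendrogram_json <- function(dend, path = NULL) {
  h <- dend$hclust
  merges <- lapply(seq_len(nrow(h$merge)), function(i)
    list(a = h$merge[i, 1L], b = h$merge[i, 2L], height = h$height[i]))
  js <- jsonlite::toJSON(list(labels = dend$labels, merges = merges),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

# Mean pairwise Pearson correlation among a set of rows (off-diagonal mean).
.mean_pairwise_cor <- function(v) {
  if (nrow(v) < 2L) return(NA_real_)
  cm <- stats::cor(t(v))
  mean(cm[upper.tri(cm)])
}

#' Extract tight clusters from a dendrogram
#'
#' Cuts the tree at `cut_height` (groups = connected components below the
#' cut) and keeps groups with at least `min_size` members whose mean
#' pairwise Pearson correlation across events is at least `tightness`.
#'
#' @param dend `bmp_dendrogram` from [average_linkage_cluster()].
#' @param x the `expr_matrix` (or matrix) the tree was built from.
#' @param cut_height tree cut height on the correlation-distance scale
#'   (default 0.3, i.e. average within-group correlation around 0.7+).
#' @param min_size minimum cluster size (default 20).
#' @param tightness minimum mean pairwise correlation (default 0.8).
#' @return list of `tight_cluster` objects (fields `probes`, `mean_cor`,
#'   `cut_height`), sorted by size descending; possibly empty.
#' @export
extract_tight_clusters <- function(dend, x, cut_height = 0.3, min_size = 20L,
                                   tightness = 0.8) {
  if (cut_height < 0) stop("cut_height must be >= 0")
  if (min_size < 2L) stop("min_size must be >= 2")
  if (tightness <= 0 || tightness > 1) stop("tightness must be in (0, 1]")
  v <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  groups <- stats::cutree(dend$hclust, h = cut_height)
  out <- list()
  for (g in unique(groups)) {
    members <- names(groups)[groups == g]
    if (length(members) < min_size) next
    mc <- .mean_pairwise_cor(v[members, , drop = FALSE])
    if (is.na(mc) || mc < tightness) next
    out[[length(out) + 1L]] <- structure(
      list(probes = members, mean_cor = mc, cut_height = cut_height),
      class = "tight_cluster")
  }
  out[order(-vapply(out, function(cl) length(cl$probes), 1L))]
}

#' @export
print.tight_cluster <- function(x, ...) {
  cat(sprintf("tight_cluster: %d probes, mean pairwise r = %.3f (cut %.2f)\n",
              length(x$probes), x$mean_cor, x$cut_height))
  invisible(x)
}

#' Intersect tight clusters from two ligands into a synexpression group
#'
#' @param a,b `tight_cluster` objects (or plain character vectors of probe
#'   ids), one per ligand.
#' @param annotation optional `probe_annotation`; when given, the
#'   uniquely-annotated gene subset of the shared probes is reported.
#' @return object of class `synexpression_group`: `shared` probe ids,
#'   source sizes `size_a`/`size_b`, and `genes` (unique-annotation gene
#'   ids, `NULL` without annotation).
#' @export
intersect_clusters <- function(a, b, annotation = NULL) {
  pa <- if (inherits(a, "tight_cluster")) a$probes else as.character(a)
  pb <- if (inherits(b, "tight_cluster")) b$probes else as.character(b)
  if (!length(pa) || !length(pb)) stop("both clusters must be non-empty")
  shared <- sort(intersect(pa, pb))
  genes <- NULL
  if (!is.null(annotation)) {
    ann <- annotation[annotation$probe_id %in% shared &
                        annotation$status == "unique", , drop = FALSE]
    genes <- sort(unique(ann$gene_id))
  }
  structure(list(shared = shared, size_a = length(pa), size_b = length(pb),
                 genes = genes), class = "synexpression_group")
}

#' @export
print.synexpression_group <- function(x, ...) {
  cat(sprintf("synexpression_group: %d shared probes (sources: %d, %d)\n",
              length(x$shared), x$size_a, x$size_b))
  if (!is.null(x$genes))
    cat(sprintf("  uniquely annotated genes: %d\n", length(x$genes)))
  invisible(x)
}

#' Cluster samples (events) instead of probes
#'
#' Same correlation metric and average linkage applied to the transposed
#' matrix; used to check that samples from one cell line co-cluster.
#'
#' @param x `expr_matrix` or matrix.
#' @return `bmp_dendrogram` over event columns.
#' @export
cluster_samples <- function(x) {
  v <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  average_linkage_cluster(t(v))
}
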