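# GO term over-representation by Fisher's exact test.
#
# One-sided (over-representation) test of a study gene set against the
# whole-array universe of uniquely annotated genes: the p-value is the
# upper hypergeometric tail P(X >= k) for k study genes carrying the term
# out of K study genes, with m of N background genes carrying it.

#' Fisher's exact GO term enrichment
#'
#' @param study character vector of gene ids; must be a subset of
#'   `background`.
#' @param background character vector: the reference universe (all
#'   uniquely annotated genes on the array).
#' @param ontology gene-to-term mapping from [read_ontology()].
#' @param min_term_size terms annotated to fewer than this many background
#'   genes are skipped (default 5).
#' @return data.frame sorted by p ascending: `term_id`, `term_name`,
#'   `namespace`, `k` (study genes with term), `K` (study size), `m`
#'   (background genes with term), `N` (background size), `p_value`
#'   (one-sided hypergeometric upper tail), `q_value` (Benjamini-Hochberg,
#'   provided as a convenience; the primary statistic is the raw p).
#' @export
fisher_enrichment <- function(study, background, ontology,
                              min_term_size = 5L) {
  study <- unique(as.character(study))
  background <- unique(as.character(background))
  if (!length(study)) stop("empty study set")
  extra <- setdiff(study, background)
  if (length(extra))
    stop("study gene(s) missing from background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  onto <- ontology[ontology$gene_id %in% background, , drop = FALSE]
  N <- length(background)
  K <- length(study)
  terms <- split(onto$gene_id, onto$term_id)
  meta <- unique(onto[c("term_id", "term_name", "namespace")])
  rows <- lapply(names(terms), function(tid) {
    g <- unique(terms[[tid]])
    m <- length(g)
    if (m < min_term_size) return(NULL)
    k <- length(intersect(study, g))
    p <- stats::phyper(k - 1L, m, N - m, K, lower.tail = FALSE)
    data.frame(term_id = tid, k = k, K = K, m = m, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term_id = character(), term_name = character(),
                      namespace = character(), k = integer(), K = integer(),
                      m = integer(), N = integer(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE))
  res$term_name <- meta$term_name[match(res$term_id, meta$term_id)]
  res$namespace <- meta$namespace[match(res$term_id, meta$term_id)]
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$term_id),
             c("term_id", "term_name", "namespace", "k", "K", "m", "N",
               "p_value", "q_value")]
  rownames(res) <- NULL
  res
}

#' Per-category GO enrichment of temporal clusters
#'
#' Pools, for each responder category, the member probes of that
#' category's clusters, maps them to uniquely annotated genes, and runs
#' [fisher_enrichment()] against the supplied universe. Empty categories
#' are skipped with a message. Results from different cell lines are meant
#' to be combined by term-wise concatenation, not by pooling p-values.
#'
#' @param tc `temporal_clusters` from [temporal_pipeline()].
#' @param ontology gene-to-term mapping.
#' @param background gene universe (uniquely annotated genes on the array).
#' @param annotation `probe_annotation` used to map member probes to genes.
#' @param categories which categories to test (default: the four responder
#'   categories, excluding `undetermined`).
#' @param min_term_size passed to [fisher_enrichment()].
#' @return named list of enrichment data.frames, one per non-empty
#'   category.
#' @export
category_enrichment <- function(tc, ontology, background, annotation,
                                categories = setdiff(TEMPORAL_CATEGORIES,
                                                     "undetermined"),
                                min_term_size = 5L) {
  members <- category_members(tc)
  out <- list()
  for (cat_i in categories) {
    probes <- members[[cat_i]]
    if (is.null(probes) || !length(probes)) {
      message("category ", cat_i, " is empty; skipped")
      next
    }
    ann <- annotation[annotation$probe_id %in% probes &
                        annotation$status == "unique", , drop = FALSE]
    genes <- intersect(unique(ann$gene_id), background)
    if (!length(genes)) {
      message("category ", cat_i, " has no uniquely annotated genes; skipped")
      next
    }
    out[[cat_i]] <- fisher_enrichment(genes, background, ontology,
                                      min_term_size = min_term_size)
  }
  out
}
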