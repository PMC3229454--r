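# Fold-change filtering and event-count ranking.
#
# A probe is "regulated" at an event when its |log2 ratio| meets the
# fold-change cutoff (inclusive; a 2-fold cutoff is |log2 ratio| >= 1).
# Three filters operate on this notion:
#   * cell-line-specific: >= 2-fold at >= 1 of the 6 time points of one line;
#   * time-point-specific: >= 2-fold at a given time point;
#   * general (per ligand, all lines): >= 3-fold in >= 3 events and/or
#     >= 2-fold in >= 4 events, an event being any time point of any line.
# Missing values never count as regulated.

#' Filter configuration
#'
#' @param fc2 fold-change cutoff of the 2-fold clause (default 2).
#' @param fc3 fold-change cutoff of the 3-fold clause (default 3).
#' @param min_events_fc3 minimum events at `fc3` for the general filter
#'   (default 3).
#' @param min_events_fc2 minimum events at `fc2` for the general filter
#'   (default 4).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(fc2 = 2, fc3 = 3, min_events_fc3 = 3,
                          min_events_fc2 = 4) {
  if (!(fc2 > 1)) stop("fc2 must exceed 1")
  if (fc3 < fc2) stop("fc3 must be >= fc2")
  if (min_events_fc3 < 1 || min_events_fc2 < 1)
    stop("event minima must be >= 1")
  structure(list(fc2 = fc2, fc3 = fc3,
                 min_events_fc3 = as.integer(min_events_fc3),
                 min_events_fc2 = as.integer(min_events_fc2)),
            class = "filter_config")
}

#' Regulation call for a log2 ratio
#'
#' @param log2_ratio numeric vector of log2(treatment/vehicle) ratios.
#' @param fold_threshold fold-change cutoff (> 1), e.g. 2 for 2-fold.
#' @return character vector in {`up`, `down`, `none`}; `NA` input gives
#'   `none` (missing values are never regulation events).
#' @export
is_regulated <- function(log2_ratio, fold_threshold) {
  if (!is.numeric(fold_threshold) || length(fold_threshold) != 1L ||
      !(fold_threshold > 1))
    stop("fold_threshold must be a single value > 1")
  lt <- log2(fold_threshold)
  out <- rep("none", length(log2_ratio))
  out[!is.na(log2_ratio) & log2_ratio >= lt] <- "up"
  out[!is.na(log2_ratio) & log2_ratio <= -lt] <- "down"
  out
}

# Per-probe event counts at a fold cutoff; NA counts as not regulated.
.event_counts <- function(values, fold) {
  lt <- log2(fold)
  up <- rowSums(values >= lt, na.rm = TRUE)
  down <- rowSums(values <= -lt, na.rm = TRUE)
  cbind(up = up, down = down)
}

#' Cell-line-specific filter
#'
#' Retains probes differentially expressed at least `fc2`-fold at a minimum
#' of one of the six time points of a single (cell line, ligand) series.
#'
#' @param x `expr_matrix` restricted to exactly one cell line and ligand
#'   with the six canonical time points.
#' @param config [filter_config()].
#' @return character vector of retained probe ids (input row order).
#' @export
cellline_filter <- function(x, config = filter_config()) {
  ev <- x$events
  if (length(unique(ev$cell_line)) != 1L || length(unique(ev$ligand)) != 1L)
    stop("matrix must hold exactly one (cell line, ligand)")
  if (!identical(sort(ev$time_h), CANONICAL_TIMES))
    stop("expected the six canonical time points, got: ",
         paste(sort(ev$time_h), collapse = ", "))
  cnt <- .event_counts(x$values, config$fc2)
  rownames(x$values)[cnt[, "up"] + cnt[, "down"] >= 1L]
}

#' Time-point-specific filter
#'
#' Retains probes at least `fc2`-fold regulated at the given time point in
#' any cell line present in the matrix.
#'
#' @param x `expr_matrix`.
#' @param time_point time in hours, one of the canonical six.
#' @param config [filter_config()].
#' @return character vector of retained probe ids.
#' @export
timepoint_filter <- function(x, time_point, config = filter_config()) {
  if (!time_point %in% x$events$time_h)
    stop("time point ", time_point, " not present in matrix")
  sub <- x$values[, x$events$time_h == time_point, drop = FALSE]
  cnt <- .event_counts(sub, config$fc2)
  rownames(x$values)[cnt[, "up"] + cnt[, "down"] >= 1L]
}

#' General (event-count) filter
#'
#' Retains probes regulated at least `fc3`-fold in `min_events_fc3` events
#' and/or at least `fc2`-fold in `min_events_fc2` events, over all cell
#' lines of a single ligand. An event at the stronger cutoff also counts
#' toward the weaker clause.
#'
#' @param x `expr_matrix` for a single ligand (any number of cell lines).
#' @param config [filter_config()].
#' @return character vector of retained probe ids.
#' @export
general_filter <- function(x, config = filter_config()) {
  if (length(unique(x$events$ligand)) != 1L)
    stop("general filter operates on one ligand at a time; got: ",
         paste(unique(x$events$ligand), collapse = ", "))
  c3 <- .event_counts(x$values, config$fc3)
  c2 <- .event_counts(x$values, config$fc2)
  keep <- (c3[, "up"] + c3[, "down"] >= config$min_events_fc3) |
          (c2[, "up"] + c2[, "down"] >= config$min_events_fc2)
  rownames(x$values)[keep]
}

# Collapse probes to genes: uniquely annotated probes only; when several
# unique probes map to one gene, keep the probe with the largest mean
# |log2 ratio| across events (ties by probe id).
.gene_representatives <- function(x, annotation) {
  ann <- annotation[annotation$status == "unique" &
                      annotation$probe_id %in% rownames(x$values), ,
                    drop = FALSE]
  if (nrow(ann) == 0L)
    return(data.frame(gene_id = character(), probe_id = character(),
                      stringsAsFactors = FALSE))
  score <- rowMeans(abs(x$values[ann$probe_id, , drop = FALSE]), na.rm = TRUE)
  ord <- order(ann$gene_id, -score, ann$probe_id)
  ann <- ann[ord, , drop = FALSE]
  ann <- ann[!duplicated(ann$gene_id), , drop = FALSE]
  data.frame(gene_id = ann$gene_id, probe_id = ann$probe_id,
             stringsAsFactors = FALSE)
}

#' Up/down regulation event counts
#'
#' Counts, at the `fc2` cutoff, the events in which each identifier is up-
#' or downregulated. With 5 cell lines and 6 time points per ligand the
#' total is bounded by 30.
#'
#' @param x `expr_matrix` (single ligand for the canonical 30-event bound).
#' @param ids probe ids, or gene ids when `annotation` is supplied
#'   (uniquely annotated probes only; multi-probe genes are collapsed to
#'   the probe with the largest mean absolute ratio). `NULL` counts every
#'   probe (or, with annotation, every uniquely annotated gene).
#' @param config [filter_config()].
#' @param annotation optional `probe_annotation` switching to gene-level
#'   counting.
#' @return data.frame `gene_id` (or probe id), `up_events`, `down_events`,
#'   `total_events`.
#' @export
count_events <- function(x, ids = NULL, config = filter_config(),
                         annotation = NULL) {
  if (is.null(annotation)) {
    map <- data.frame(gene_id = rownames(x$values),
                      probe_id = rownames(x$values), stringsAsFactors = FALSE)
  } else {
    map <- .gene_representatives(x, annotation)
  }
  if (!is.null(ids)) {
    miss <- setdiff(ids, map$gene_id)
    if (length(miss))
      stop("unknown id: ", paste(utils::head(miss, 5), collapse = ", "))
    map <- map[match(ids, map$gene_id), , drop = FALSE]
  }
  cnt <- .event_counts(x$values[map$probe_id, , drop = FALSE], config$fc2)
  data.frame(gene_id = map$gene_id,
             up_events = as.integer(cnt[, "up"]),
             down_events = as.integer(cnt[, "down"]),
             total_events = as.integer(cnt[, "up"] + cnt[, "down"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank genes by regulation event count
#'
#' Orders descending by total events, breaking ties by up events
#' (descending) then gene id (ascending); rows below `min_total` are
#' dropped.
#'
#' @param counts data.frame from [count_events()].
#' @param min_total minimum total events to keep (default 1).
#' @return the ranked data.frame with a `rank` column (ties share order,
#'   ranks are positional).
#' @export
rank_genes <- function(counts, min_total = 1L) {
  counts <- counts[counts$total_events >= min_total, , drop = FALSE]
  ord <- order(-counts$total_events, -counts$up_events, counts$gene_id)
  out <- counts[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$rank <- seq_len(nrow(out))
  out
}

#' Fraction of upregulation events among top-ranked genes
#'
#' @param ranked output of [rank_genes()].
#' @param top_n number of top rows to pool (must be in 1..nrow).
#' @return sum of up events over the top rows divided by the sum of their
#'   total events.
#' @export
up_fraction <- function(ranked, top_n) {
  if (top_n < 1L || top_n > nrow(ranked))
    stop("top_n must be between 1 and ", nrow(ranked))
  top <- ranked[seq_len(top_n), , drop = FALSE]
  sum(top$up_events) / sum(top$total_events)
}
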