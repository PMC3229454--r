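# Domain containers and file I/O for the BMP time-course pipeline.
#
# An "event" is one (cell line, ligand, time point) combination; the
# expression matrix holds log2(treatment/vehicle) ratios with one column
# per event and one row per probe.

#' Canonical sampling times (hours)
#'
#' The experimental design samples each treated cell line at 30 min, 1 h,
#' 3 h, 6 h, 12 h and 24 h.
#' @export
CANONICAL_TIMES <- c(0.5, 1, 3, 6, 12, 24)

#' Ligands handled by the pipeline
#' @export
LIGANDS <- c("BMP4", "BMP7")

#' Construct an event key table
#'
#' Each row identifies one array: a (cell line, ligand, time point) triple.
#' Time points must come from the canonical six-point design.
#'
#' @param cell_line character vector of cell-line identifiers (must not
#'   contain underscores; the column-name grammar reserves them).
#' @param ligand character vector, each element one of `"BMP4"`, `"BMP7"`.
#' @param time_h numeric vector of time points in hours.
#' @return data.frame with columns `cell_line`, `ligand`, `time_h` and
#'   `token` (the `CELLLINE_LIGAND_TIMEh` column label).
#' @export
event_key <- function(cell_line, ligand, time_h) {
  n <- max(length(cell_line), length(ligand), length(time_h))
  cell_line <- rep_len(as.character(cell_line), n)
  ligand <- rep_len(as.character(ligand), n)
  time_h <- rep_len(as.numeric(time_h), n)
  if (any(grepl("_", cell_line, fixed = TRUE)))
    stop("cell line identifiers must not contain '_'")
  bad <- !ligand %in% LIGANDS
  if (any(bad))
    stop("unknown ligand: ", paste(unique(ligand[bad]), collapse = ", "))
  bad <- !time_h %in% CANONICAL_TIMES
  if (any(bad))
    stop("non-canonical time point: ",
         paste(unique(time_h[bad]), collapse = ", "),
         " (allowed: ", paste(CANONICAL_TIMES, collapse = ", "), ")")
  ek <- data.frame(cell_line = cell_line, ligand = ligand, time_h = time_h,
                   stringsAsFactors = FALSE)
  ek$token <- event_token(ek)
  if (anyDuplicated(ek$token))
    stop("duplicate event key: ",
         paste(unique(ek$token[duplicated(ek$token)]), collapse = ", "))
  ek
}

#' Serialize event keys to column tokens
#' @param ek event key data.frame
#' @return character vector like `"HCC1954_BMP4_0.5h"`.
#' @export
event_token <- function(ek) {
  # format() would pad; use as.character for exact 0.5/1/3/... rendering
  sprintf("%s_%s_%sh", ek$cell_line, ek$ligand, as.character(ek$time_h))
}

#' Parse event tokens of the form CELLLINE_LIGAND_TIMEh
#'
#' The cell line may contain hyphens (e.g. MDA-MB-361) but not underscores;
#' the last two underscore-separated fields are the ligand and the time.
#'
#' @param tokens character vector of column labels.
#' @return event key data.frame.
#' @export
parse_event_token <- function(tokens) {
  parts <- strsplit(tokens, "_", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad))
    stop("malformed event column (expected CELLLINE_LIGAND_TIMEh): ",
         paste(tokens[bad], collapse = ", "))
  cl <- vapply(parts, function(p) paste(p[seq_len(length(p) - 2L)],
                                        collapse = "_"), "")
  lig <- vapply(parts, function(p) p[length(p) - 1L], "")
  traw <- vapply(parts, function(p) p[length(p)], "")
  if (any(!grepl("h$", traw)))
    stop("time field must end in 'h' in column(s): ",
         paste(tokens[!grepl("h$", traw)], collapse = ", "))
  th <- suppressWarnings(as.numeric(sub("h$", "", traw)))
  bad <- is.na(th) | !th %in% CANONICAL_TIMES
  if (any(bad))
    stop("non-canonical time point in column(s): ",
         paste(tokens[bad], collapse = ", "))
  bad <- !lig %in% LIGANDS
  if (any(bad))
    stop("unknown ligand in column(s): ", paste(tokens[bad], collapse = ", "))
  event_key(cl, lig, th)
}

#' Construct an expression matrix object
#'
#' Bundles a probes-by-events numeric matrix of log2(treatment/vehicle)
#' ratios with its event key. Columns are reordered canonically: by ligand,
#' then by cell line (order of first appearance), then ascending time.
#'
#' @param values numeric matrix, rows = probes (rownames required and
#'   unique), one column per event.
#' @param events event key data.frame with one row per column of `values`.
#' @return object of class `expr_matrix`: list with elements `values`
#'   (matrix, colnames = event tokens) and `events`.
#' @export
expr_matrix <- function(values, events) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("expression matrix must be non-empty")
  if (is.null(rownames(values))) stop("probe ids (rownames) are required")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (nrow(events) != ncol(values))
    stop("event key has ", nrow(events), " rows but matrix has ",
         ncol(values), " columns")
  if (any(!is.finite(values) & !is.na(values)))
    stop("values must be finite or NA")
  ord <- order(match(events$ligand, LIGANDS),
               match(events$cell_line, unique(events$cell_line)),
               events$time_h)
  events <- events[ord, , drop = FALSE]
  rownames(events) <- NULL
  values <- values[, ord, drop = FALSE]
  colnames(values) <- events$token
  structure(list(values = values, events = events), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  ev <- x$events
  cat(sprintf("expr_matrix: %d probes x %d events\n",
              nrow(x$values), ncol(x$values)))
  for (lg in unique(ev$ligand)) {
    cl <- unique(ev$cell_line[ev$ligand == lg])
    cat(sprintf("  %s: %d cell line(s): %s\n", lg, length(cl),
                paste(cl, collapse = ", ")))
  }
  cat(sprintf("  missing values: %d\n", sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by event
#'
#' @param x `expr_matrix`.
#' @param cell_line,ligand,time_h optional filters; `NULL` keeps all.
#' @param probes optional character vector of probe ids to keep.
#' @return `expr_matrix` restricted to the selected rows/columns.
#' @export
subset_events <- function(x, cell_line = NULL, ligand = NULL, time_h = NULL,
                          probes = NULL) {
  keep <- rep(TRUE, nrow(x$events))
  if (!is.null(cell_line)) keep <- keep & x$events$cell_line %in% cell_line
  if (!is.null(ligand)) keep <- keep & x$events$ligand %in% ligand
  if (!is.null(time_h)) keep <- keep & x$events$time_h %in% time_h
  if (!any(keep)) stop("no events match the selection")
  vals <- x$values[, keep, drop = FALSE]
  if (!is.null(probes)) {
    miss <- setdiff(probes, rownames(vals))
    if (length(miss))
      stop("unknown probe id: ", paste(utils::head(miss, 5), collapse = ", "))
    vals <- vals[probes, , drop = FALSE]
  }
  expr_matrix(vals, x$events[keep, , drop = FALSE])
}

#' Check that a matrix carries a complete cell-line-by-time grid
#'
#' Every (cell line, ligand) pair present must carry all six canonical
#' time points exactly once.
#'
#' @param x `expr_matrix`.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_grid <- function(x) {
  ev <- x$events
  for (lg in unique(ev$ligand)) {
    for (cl in unique(ev$cell_line[ev$ligand == lg])) {
      t <- sort(ev$time_h[ev$ligand == lg & ev$cell_line == cl])
      if (!identical(t, CANONICAL_TIMES))
        stop(sprintf("cell line %s (%s) carries time points {%s}, expected {%s}",
                     cl, lg, paste(t, collapse = ", "),
                     paste(CANONICAL_TIMES, collapse = ", ")))
    }
  }
  invisible(TRUE)
}

#' Read an expression matrix
#'
#' @param path TSV file. For `dialect = "tsv"` the first column holds probe
#'   ids and the remaining column names are `CELLLINE_LIGAND_TIMEh` tokens.
#'   For `dialect = "geo_series_matrix"`, metadata lines prefixed `!` are
#'   skipped and quoting is stripped; data column names must carry the same
#'   tokens.
#' @param dialect `"tsv"` (default) or `"geo_series_matrix"`.
#' @return `expr_matrix`; missing values (`NA`, empty fields) preserved.
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "geo_series_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "geo_series_matrix") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    df <- utils::read.delim(text = lines, header = TRUE, sep = "\t",
                            quote = "\"", check.names = FALSE,
                            stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                            check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (ncol(df) < 2L) stop("expected a probe-id column plus >= 1 event column")
  pid <- as.character(df[[1L]])
  if (anyDuplicated(pid))
    stop("duplicate probe id: ",
         paste(unique(pid[duplicated(pid)]), collapse = ", "))
  ek <- parse_event_token(colnames(df)[-1L])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- pid
  expr_matrix(vals, ek)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()] (tsv dialect): probe ids in the
#' first column, event tokens as headers, `.` decimal separator, NA for
#' missing values.
#'
#' @param x `expr_matrix`.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(probe_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene annotation table
#'
#' @param path 2-column TSV: `probe_id`, then semicolon-separated gene ids
#'   (empty field = unannotated probe). A header row is detected when the
#'   first field of the first line is `probe_id`.
#' @return data.frame of class `probe_annotation` with columns `probe_id`,
#'   `gene_ids` (list column), `gene_id` (the single id for uniquely
#'   annotated probes, else NA) and `status` in
#'   {`unique`, `multiple`, `unannotated`}.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[1L], "probe_id"))
    lines <- lines[-1L]
  if (!length(lines)) stop("empty annotation file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  pid <- vapply(parts, `[`, "", 1L)
  gstr <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "", "")
  genes <- lapply(gstr, function(s) {
    g <- strsplit(s, ";", fixed = TRUE)[[1L]]
    sort(unique(g[nzchar(g)]))
  })
  key <- vapply(genes, paste, "", collapse = ";")
  if (anyDuplicated(pid)) {
    dup <- unique(pid[duplicated(pid)])
    for (d in dup) {
      if (length(unique(key[pid == d])) > 1L)
        stop("probe ", d, " listed with conflicting gene sets")
    }
    keep <- !duplicated(pid)
    pid <- pid[keep]; genes <- genes[keep]
  }
  probe_annotation(pid, genes)
}

#' Build a probe annotation table from ids and gene lists
#'
#' @param probe_id character vector.
#' @param gene_ids list of character vectors (may be empty vectors).
#' @return `probe_annotation` data.frame; see [read_annotation()].
#' @export
probe_annotation <- function(probe_id, gene_ids) {
  n <- vapply(gene_ids, length, 1L)
  status <- ifelse(n == 0L, "unannotated", ifelse(n == 1L, "unique", "multiple"))
  ann <- data.frame(probe_id = as.character(probe_id), status = status,
                    stringsAsFactors = FALSE)
  ann$gene_ids <- gene_ids
  ann$gene_id <- ifelse(n == 1L, vapply(gene_ids, `[`, "", 1L), NA_character_)
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

#' Summarize annotation status proportions
#'
#' @param ann `probe_annotation`.
#' @return named numeric vector with proportions of `unique`, `multiple`
#'   and `unannotated` probes (sums to 1).
#' @export
annotation_summary <- function(ann) {
  if (nrow(ann) == 0L) stop("empty annotation")
  tab <- table(factor(ann$status,
                      levels = c("unique", "multiple", "unannotated")))
  prop <- as.numeric(tab) / nrow(ann)
  names(prop) <- names(tab)
  prop
}

#' Read a gene-to-GO-term mapping
#'
#' @param path TSV with columns `gene_id`, `term_id`, `term_name`,
#'   `namespace` (header optional, detected on `gene_id`). A 2-column file
#'   (gene_id, term_id — the core of a GAF-style mapping) is accepted; the
#'   term id then doubles as its name and the namespace defaults to
#'   `biological_process`.
#' @return data.frame with the four columns; duplicate (gene, term) pairs
#'   collapsed; inconsistent term metadata is an error.
#' @export
read_ontology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  if (nrow(df) && df[1, 1] == "gene_id") {
    colnames(df) <- as.character(df[1, ])
    df <- df[-1, , drop = FALSE]
  }
  if (ncol(df) == 2L) {
    df <- data.frame(gene_id = df[[1]], term_id = df[[2]],
                     term_name = df[[2]], namespace = "biological_process",
                     stringsAsFactors = FALSE)
  } else if (ncol(df) >= 4L) {
    df <- data.frame(gene_id = df[[1]], term_id = df[[2]],
                     term_name = df[[3]], namespace = df[[4]],
                     stringsAsFactors = FALSE)
  } else stop("ontology file must have 2 or 4 columns")
  ok_ns <- c("biological_process", "molecular_function", "cellular_component")
  if (any(!df$namespace %in% ok_ns))
    stop("unknown namespace: ",
         paste(setdiff(unique(df$namespace), ok_ns), collapse = ", "))
  df <- df[!duplicated(df[c("gene_id", "term_id")]), , drop = FALSE]
  meta <- unique(df[c("term_id", "term_name", "namespace")])
  if (anyDuplicated(meta$term_id))
    stop("term(s) with inconsistent name/namespace: ",
         paste(unique(meta$term_id[duplicated(meta$term_id)]), collapse = ", "))
  rownames(df) <- NULL
  df
}
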