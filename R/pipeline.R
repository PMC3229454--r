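# End-to-end pipeline: normalize -> filter -> rank -> cluster ->
# synexpression -> temporal -> enrichment, driven by one config.
#
# Every stage is a pure function of (inputs, config, seed); the run
# manifest records the config snapshot, input digests, stage parameters
# and an md5 digest of every output file, so a rerun with the same config
# yields a byte-identical manifest.

.pipeline_defaults <- function() {
  list(normalize = list(method = "median_center"),
       filter = list(fc2 = 2, fc3 = 3, min_events_fc3 = 3,
                     min_events_fc2 = 4),
       rank = list(min_total = 1),
       cluster = list(cut_height = 0.3, min_size = 20, tightness = 0.8),
       temporal = list(kmin = 2, kmax = 12,
                       families = c("spherical_varying", "diagonal_varying"),
                       seed = 7, n_starts = 5, threshold = 2),
       enrichment = list(min_term_size = 5))
}

.merge_config <- function(user, defaults) {
  for (nm in names(defaults)) {
    if (is.null(user[[nm]])) user[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      user[[nm]] <- utils::modifyList(defaults[[nm]], as.list(user[[nm]]))
  }
  user
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  basename(path)
}

#' Run the full analysis pipeline
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   Required block: `inputs` with `expression` (named per-ligand TSV
#'   paths), `annotation` and `ontology`. Optional blocks `normalize`,
#'   `filter`, `rank`, `cluster`, `temporal`, `enrichment` override the
#'   stage defaults (see the methods vignette).
#' @param out_dir output directory; created if missing.
#' @return the run manifest (also written to `out_dir/manifest.json`):
#'   config snapshot, input digests, per-stage log counts, output file
#'   digests. On stage failure a partial manifest naming the failed stage
#'   is written before the error propagates.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- .merge_config(config, .pipeline_defaults())
  if (is.null(cfg$inputs$expression) || is.null(cfg$inputs$annotation) ||
      is.null(cfg$inputs$ontology))
    stop("config must provide inputs: expression (per ligand), annotation, ontology")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  inputs <- c(unlist(cfg$inputs$expression),
              annotation = cfg$inputs$annotation,
              ontology = cfg$inputs$ontology)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))

  manifest <- list(config = cfg,
                   inputs = as.list(tools::md5sum(inputs)),
                   counts = list(), outputs = character())
  current_stage <- "setup"
  finish <- function(failed = NULL) {
    if (!is.null(failed)) manifest$failed_stage <<- failed
    manifest$outputs <<- as.list(manifest$outputs)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }
  run <- function(stage, expr) {
    current_stage <<- stage
    tryCatch(expr, error = function(e) {
      finish(failed = stage)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(name) {
    path <- file.path(out_dir, name)
    manifest$outputs[name] <<- unname(tools::md5sum(path))
    name
  }

  fcfg <- do.call(filter_config, cfg$filter[c("fc2", "fc3", "min_events_fc3",
                                              "min_events_fc2")])
  ligands <- names(cfg$inputs$expression)

  annotation <- run("read_annotation", read_annotation(cfg$inputs$annotation))
  ontology <- run("read_ontology", read_ontology(cfg$inputs$ontology))
  background <- sort(unique(
    annotation$gene_id[annotation$status == "unique"]))

  norm <- list(); general <- list(); cl_survivors <- list()
  tight <- list()
  for (lg in ligands) {
    x <- run(paste0("read_expression_", lg), {
      m <- read_expression_matrix(cfg$inputs$expression[[lg]])
      validate_grid(m)
      m
    })

    nm <- run(paste0("normalize_", lg),
              linear_normalize(x, method = cfg$normalize$method))
    norm[[lg]] <- nm$matrix
    run(paste0("write_normalized_", lg), {
      write_expression_matrix(nm$matrix,
                              file.path(out_dir, paste0("normalized_", lg, ".tsv")))
      emit(paste0("normalized_", lg, ".tsv"))
      emit(.write_tsv(nm$report,
                      file.path(out_dir, paste0("normalization_report_", lg, ".tsv"))))
    })

    run(paste0("filter_", lg), {
      lines <- unique(norm[[lg]]$events$cell_line)
      per_line <- lapply(lines, function(cl)
        cellline_filter(subset_events(norm[[lg]], cell_line = cl), fcfg))
      names(per_line) <- lines
      cl_survivors[[lg]] <- per_line
      long <- data.frame(
        cell_line = rep(lines, vapply(per_line, length, 1L)),
        probe_id = unlist(per_line, use.names = FALSE),
        stringsAsFactors = FALSE)
      emit(.write_tsv(long, file.path(out_dir,
                                      paste0("retained_cellline_", lg, ".tsv"))))
      tp_counts <- vapply(CANONICAL_TIMES, function(tp)
        length(timepoint_filter(norm[[lg]], tp, fcfg)), 1L)
      general[[lg]] <- general_filter(norm[[lg]], fcfg)
      writeLines(general[[lg]],
                 file.path(out_dir, paste0("retained_general_", lg, ".txt")))
      emit(paste0("retained_general_", lg, ".txt"))
      manifest$counts[[lg]] <- list(
        cellline_deps = lapply(per_line, length),
        timepoint_deps = as.list(stats::setNames(tp_counts,
                                                 paste0(CANONICAL_TIMES, "h"))),
        general_deps = length(general[[lg]]))
      message(sprintf("[%s] general filter retained %d probes", lg,
                      length(general[[lg]])))
    })

    run(paste0("rank_", lg), {
      counts <- count_events(norm[[lg]], config = fcfg,
                             annotation = annotation)
      ranked <- rank_genes(counts, min_total = cfg$rank$min_total)
      emit(.write_tsv(ranked, file.path(out_dir,
                                        paste0("event_counts_", lg, ".tsv"))))
    })

    run(paste0("cluster_", lg), {
      if (length(general[[lg]]) < 2L) {
        tight[[lg]] <- list()
      } else {
        sub <- subset_events(norm[[lg]], probes = general[[lg]])
        dend <- average_linkage_cluster(sub)
        dendrogram_newick(dend, file.path(out_dir,
                                          paste0("dendrogram_", lg, ".nwk")))
        emit(paste0("dendrogram_", lg, ".nwk"))
        dendrogram_json(dend, file.path(out_dir,
                                        paste0("dendrogram_", lg, ".json")))
        emit(paste0("dendrogram_", lg, ".json"))
        tight[[lg]] <- extract_tight_clusters(
          dend, sub, cut_height = cfg$cluster$cut_height,
          min_size = cfg$cluster$min_size, tightness = cfg$cluster$tightness)
      }
      tc_df <- do.call(rbind, lapply(seq_along(tight[[lg]]), function(i)
        data.frame(cluster_id = i, probe_id = tight[[lg]][[i]]$probes,
                   mean_cor = tight[[lg]][[i]]$mean_cor,
                   stringsAsFactors = FALSE)))
      if (is.null(tc_df))
        tc_df <- data.frame(cluster_id = integer(), probe_id = character(),
                            mean_cor = numeric())
      emit(.write_tsv(tc_df, file.path(out_dir,
                                       paste0("tight_clusters_", lg, ".tsv"))))
      message(sprintf("[%s] %d tight cluster(s)", lg, length(tight[[lg]])))
    })
  }

  group <- NULL
  if (length(ligands) >= 2L) {
    group <- run("synexpression", {
      a <- tight[[ligands[1L]]]; b <- tight[[ligands[2L]]]
      g <- NULL
      if (length(a) && length(b))
        g <- intersect_clusters(a[[1L]], b[[1L]], annotation)
      df <- if (is.null(g))
        data.frame(probe_id = character(), unique_gene = character())
      else data.frame(probe_id = g$shared,
                      unique_gene = annotation$gene_id[
                        match(g$shared, annotation$probe_id)],
                      stringsAsFactors = FALSE)
      emit(.write_tsv(df, file.path(out_dir, "synexpression_group.tsv")))
      g
    })
  }

  temporal_results <- list()
  for (lg in ligands) {
    for (cl in names(cl_survivors[[lg]])) {
      key <- paste0(lg, "_", cl)
      tc <- run(paste0("temporal_", key), {
        temporal_pipeline(subset_events(norm[[lg]], cell_line = cl,
                                        ligand = lg),
                          probes = cl_survivors[[lg]][[cl]],
                          K_range = cfg$temporal$kmin:cfg$temporal$kmax,
                          families = unlist(cfg$temporal$families),
                          seed = cfg$temporal$seed,
                          n_starts = cfg$temporal$n_starts,
                          threshold = cfg$temporal$threshold)
      })
      temporal_results[[key]] <- tc
      run(paste0("write_temporal_", key), {
        emit(.write_tsv(tc$summary,
                        file.path(out_dir,
                                  paste0("temporal_summary_", key, ".tsv"))))
        mem <- data.frame(probe_id = names(tc$assignment),
                          cluster_id = unname(tc$assignment),
                          stringsAsFactors = FALSE)
        emit(.write_tsv(mem, file.path(out_dir,
                                       paste0("temporal_members_", key, ".tsv"))))
      })
      run(paste0("enrich_categories_", key), {
        enr <- suppressMessages(
          category_enrichment(tc, ontology, background, annotation,
                              min_term_size = cfg$enrichment$min_term_size))
        for (cat_i in names(enr))
          emit(.write_tsv(enr[[cat_i]],
                          file.path(out_dir,
                                    paste0("enrichment_", key, "_", cat_i,
                                           ".tsv"))))
      })
    }
  }

  if (!is.null(group) && length(group$genes)) {
    run("enrich_group", {
      enr <- fisher_enrichment(intersect(group$genes, background), background,
                               ontology,
                               min_term_size = cfg$enrichment$min_term_size)
      emit(.write_tsv(enr, file.path(out_dir, "enrichment_group.tsv")))
    })
  }

  finish()
}
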