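# Seeded synthetic datasets with the structure the pipeline assumes.
#
# The generator emulates the study layout: per ligand, 5 cell lines x 6
# time points of log2 treatment/vehicle ratios, with 3 cell lines shared
# between the two ligands. Probes are null (pure Normal(0, sigma^2) noise),
# responders (a sustained step of magnitude A from a category-specific
# onset time, with cell-line-dependent sign), or members of a planted
# synexpression group that shares one latent profile per (cell line,
# ligand) and reuses identical latent profiles across ligands in the
# shared cell lines. A flat ontology is generated with one term planted
# on genes of one onset category.

#' Simulation configuration
#'
#' Defaults mirror the study design: 5 cell lines per ligand with a
#' 3-line overlap, six time points, and modest array noise.
#'
#' @param n_probes probes per ligand matrix (default 2000).
#' @param cell_lines named list with a character vector of cell lines per
#'   ligand.
#' @param noise_sd per-event noise standard deviation in log2 units
#'   (default 0.25).
#' @param responder_fraction fraction of probes that respond (default 0.2).
#' @param onset_mix mixture over the four onset categories.
#' @param response_magnitude response amplitude A in log2 units
#'   (default 1.5, i.e. ~2.8-fold).
#' @param sign_flip_prob probability that a (probe, cell line) response
#'   flips the probe's base sign (default 0.3).
#' @param response_shape `"step"` (sustained, default) or `"pulse"` (single
#'   time point).
#' @param group_size synexpression-group size per ligand (default 40).
#' @param group_shared_fraction fraction of each ligand's group shared with
#'   the other ligand (default 0.75).
#' @param annotation_props proportions of unique/multiple/unannotated
#'   probes (defaults 0.66/0.16/0.18).
#' @param n_terms ontology terms (default 200).
#' @param genes_per_term genes per term (default 40).
#' @param planted_term_category onset category whose genes populate the
#'   planted enriched term (default `"early"`).
#' @param seed integer RNG seed; a fixed seed reproduces the dataset
#'   exactly.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 2000L,
                       cell_lines = list(
                         BMP4 = c("HCC1954", "MDA-MB-361", "ZR-75-30",
                                  "HCC1419", "SK-BR-3"),
                         BMP7 = c("HCC1954", "MDA-MB-361", "ZR-75-30",
                                  "MDA-MB-231", "T-47D")),
                       noise_sd = 0.25, responder_fraction = 0.2,
                       onset_mix = c(early = 0.25, early_intermediate = 0.25,
                                     late_intermediate = 0.25, late = 0.25),
                       response_magnitude = 1.5, sign_flip_prob = 0.3,
                       response_shape = c("step", "pulse"),
                       group_size = 40L, group_shared_fraction = 0.75,
                       annotation_props = c(unique = 0.66, multiple = 0.16,
                                            unannotated = 0.18),
                       n_terms = 200L, genes_per_term = 40L,
                       planted_term_category = "early", seed = 1L) {
  response_shape <- match.arg(response_shape)
  stopifnot(n_probes >= 10L, noise_sd > 0, response_magnitude > 0,
            responder_fraction >= 0, responder_fraction <= 1,
            sign_flip_prob >= 0, sign_flip_prob <= 1,
            group_shared_fraction >= 0, group_shared_fraction <= 1)
  if (!setequal(names(cell_lines), LIGANDS))
    stop("cell_lines must be a named list over ", paste(LIGANDS, collapse = ", "))
  if (2L * group_size > n_probes) stop("group size exceeds probe count")
  if (abs(sum(onset_mix) - 1) > 1e-9) stop("onset_mix must sum to 1")
  if (!planted_term_category %in% names(onset_mix))
    stop("unknown planted_term_category")
  structure(list(n_probes = as.integer(n_probes), cell_lines = cell_lines,
                 noise_sd = noise_sd,
                 responder_fraction = responder_fraction,
                 onset_mix = onset_mix,
                 response_magnitude = response_magnitude,
                 sign_flip_prob = sign_flip_prob,
                 response_shape = response_shape,
                 group_size = as.integer(group_size),
                 group_shared_fraction = group_shared_fraction,
                 annotation_props = annotation_props,
                 n_terms = as.integer(n_terms),
                 genes_per_term = as.integer(genes_per_term),
                 planted_term_category = planted_term_category,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.onset_windows <- list(early = c(0.5, 1), early_intermediate = c(3, 6),
                       late_intermediate = 12, late = 24)

# Response time course of magnitude 1 from a given onset.
.response_profile <- function(onset, shape, times = CANONICAL_TIMES) {
  if (shape == "step") as.numeric(times >= onset)
  else as.numeric(times == onset)
}

#' Generate a synthetic two-ligand time-course dataset
#'
#' @param config [sim_config()].
#' @return list with `matrices` (named list of `expr_matrix`, one per
#'   ligand), `annotation` (`probe_annotation`), `ontology` (gene-to-term
#'   data.frame), `truth` (ground-truth list, see Details) and `config`.
#'
#' @details `truth` holds: `probes` (data.frame with `probe_id`, `class`
#'   in {null, responder}, `onset_category` — NA for nulls and for
#'   synexpression-group probes, whose time course follows the group
#'   latent profile — and `onset_time`); `signs` (per ligand, a probe x
#'   cell-line sign matrix); `group` (probe ids per ligand plus the
#'   `shared` set); `planted_term` and `planted_category`.
#' @export
generate_dataset <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_probes
  probe_ids <- sprintf("P%05d", seq_len(n))
  times <- CANONICAL_TIMES

  # -- classes, onsets, signs -----------------------------------------------
  n_resp <- round(cfg$responder_fraction * n)
  resp_idx <- sort(sample.int(n, n_resp))
  class <- rep("null", n)
  class[resp_idx] <- "responder"
  onset_cat <- rep(NA_character_, n)
  onset_cat[resp_idx] <- sample(names(cfg$onset_mix), n_resp, replace = TRUE,
                                prob = cfg$onset_mix)
  onset_time <- rep(NA_real_, n)
  for (i in resp_idx) {
    w <- .onset_windows[[onset_cat[i]]]
    onset_time[i] <- if (length(w) == 1L) w else sample(w, 1L)
  }
  base_sign <- ifelse(stats::runif(n) < 0.5, 1, -1)

  # -- synexpression group membership ---------------------------------------
  n_shared <- round(cfg$group_shared_fraction * cfg$group_size)
  pool <- sample(resp_idx, min(length(resp_idx),
                               2L * cfg$group_size - n_shared))
  if (length(pool) < 2L * cfg$group_size - n_shared)
    stop("not enough responder probes to host the synexpression group")
  shared_idx <- pool[seq_len(n_shared)]
  only4 <- pool[n_shared + seq_len(cfg$group_size - n_shared)]
  only7 <- pool[cfg$group_size + seq_len(cfg$group_size - n_shared)]
  group <- list(BMP4 = sort(probe_ids[c(shared_idx, only4)]),
                BMP7 = sort(probe_ids[c(shared_idx, only7)]),
                shared = sort(probe_ids[shared_idx]))
  group_idx_all <- unique(c(shared_idx, only4, only7))
  # group probes follow the latent profile, not their own onset
  onset_cat[group_idx_all] <- NA_character_
  onset_time[group_idx_all] <- NA_real_

  # -- latent synexpression profiles ----------------------------------------
  shared_lines <- intersect(cfg$cell_lines$BMP4, cfg$cell_lines$BMP7)
  latent <- list()  # latent[[ligand]][[cell line]] = 6-vector
  latent_for <- function() {
    s <- ifelse(stats::runif(1) < 0.5, 1, -1)
    onset <- sample(c(0.5, 1, 3, 6), 1L)
    s * cfg$response_magnitude * .response_profile(onset, cfg$response_shape,
                                                   times)
  }
  for (cl in shared_lines) {
    prof <- latent_for()
    for (lg in LIGANDS) latent[[lg]][[cl]] <- prof
  }
  for (lg in LIGANDS) {
    for (cl in setdiff(cfg$cell_lines[[lg]], shared_lines))
      latent[[lg]][[cl]] <- latent_for()
  }

  # -- per-ligand matrices ---------------------------------------------------
  matrices <- list()
  signs <- list()
  for (lg in LIGANDS) {
    lines <- cfg$cell_lines[[lg]]
    sgn <- matrix(NA_real_, n, length(lines),
                  dimnames = list(probe_ids, lines))
    flip <- matrix(stats::runif(n * length(lines)) < cfg$sign_flip_prob,
                   n, length(lines))
    for (j in seq_along(lines))
      sgn[, j] <- ifelse(flip[, j], -base_sign, base_sign)
    vals <- matrix(stats::rnorm(n * 6L * length(lines), 0, cfg$noise_sd),
                   n, 6L * length(lines))
    gmask <- probe_ids %in% group[[lg]]
    for (j in seq_along(lines)) {
      cols <- (j - 1L) * 6L + seq_len(6L)
      for (i in resp_idx) {
        if (gmask[i] || is.na(onset_time[i])) next
        vals[i, cols] <- vals[i, cols] + sgn[i, j] * cfg$response_magnitude *
          .response_profile(onset_time[i], cfg$response_shape, times)
      }
      if (any(gmask)) {
        lat <- latent[[lg]][[lines[j]]]
        gn <- sum(gmask)
        vals[gmask, cols] <- matrix(lat, gn, 6L, byrow = TRUE) +
          matrix(stats::rnorm(gn * 6L, 0, cfg$noise_sd / 2), gn, 6L)
      }
    }
    rownames(vals) <- probe_ids
    ek <- event_key(rep(lines, each = 6L), lg, rep(times, length(lines)))
    matrices[[lg]] <- expr_matrix(vals, ek)
    sgn[class == "null", ] <- NA_real_
    signs[[lg]] <- sgn
  }

  # -- annotation ------------------------------------------------------------
  status <- sample(names(cfg$annotation_props), n, replace = TRUE,
                   prob = cfg$annotation_props)
  gene_of <- sprintf("G%05d", seq_len(n))
  gene_ids <- vector("list", n)
  for (i in seq_len(n)) {
    gene_ids[[i]] <- switch(status[i],
                            unique = gene_of[i],
                            multiple = sort(c(gene_of[i],
                                              gene_of[sample.int(n, 1L)])),
                            unannotated = character(0))
  }
  # guard: "multiple" must really have 2 ids (self-draw would collapse)
  for (i in which(status == "multiple")) {
    while (length(gene_ids[[i]]) < 2L)
      gene_ids[[i]] <- sort(c(gene_of[i], gene_of[sample.int(n, 1L)]))
  }
  annotation <- probe_annotation(probe_ids, gene_ids)

  # -- flat ontology with one planted term ----------------------------------
  universe <- annotation$gene_id[annotation$status == "unique"]
  planted_genes <- annotation$gene_id[
    annotation$status == "unique" &
      !is.na(onset_cat) & onset_cat == cfg$planted_term_category]
  if (!length(planted_genes))  # tiny simulations: fall back to any responder
    planted_genes <- annotation$gene_id[annotation$status == "unique" &
                                          !is.na(onset_cat)]
  planted_genes <- sample(planted_genes,
                          min(length(planted_genes), cfg$genes_per_term))
  term_ids <- sprintf("T%04d", seq_len(cfg$n_terms))
  onto_rows <- list()
  if (length(planted_genes)) {
    planted_term <- term_ids[1L]
    onto_rows <- list(data.frame(gene_id = planted_genes,
                                 term_id = planted_term,
                                 stringsAsFactors = FALSE))
  } else {
    # nothing to plant on (e.g. a pure-noise simulation)
    planted_term <- NA_character_
  }
  for (t in term_ids[-1L]) {
    g <- sample(universe, min(length(universe), cfg$genes_per_term))
    onto_rows[[length(onto_rows) + 1L]] <-
      data.frame(gene_id = g, term_id = t, stringsAsFactors = FALSE)
  }
  ontology <- do.call(rbind, onto_rows)
  ontology$term_name <- paste0("synthetic term ", ontology$term_id)
  ontology$namespace <- "biological_process"

  # per-ligand responders: probes that actually carry signal in that matrix
  responders_by_ligand <- lapply(stats::setNames(LIGANDS, LIGANDS),
                                 function(lg)
    sort(union(probe_ids[!is.na(onset_time)], group[[lg]])))
  truth <- list(probes = data.frame(probe_id = probe_ids, class = class,
                                    onset_category = onset_cat,
                                    onset_time = onset_time,
                                    stringsAsFactors = FALSE),
                responders = responders_by_ligand,
                signs = signs, group = group,
                planted_term = planted_term,
                planted_category = cfg$planted_term_category)
  list(matrices = matrices, annotation = annotation, ontology = ontology,
       truth = truth, config = cfg)
}

#' Write a synthetic dataset to a directory
#'
#' Emits the per-ligand matrix TSVs, the annotation TSV, the ontology TSV
#' and the ground truth as JSON.
#'
#' @param ds output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, named vector of the written paths.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (lg in names(ds$matrices)) {
    p <- file.path(dir, paste0("expression_", lg, ".tsv"))
    write_expression_matrix(ds$matrices[[lg]], p)
    paths[paste0("matrix_", lg)] <- p
  }
  ann <- ds$annotation
  p <- file.path(dir, "annotation.tsv")
  writeLines(c("probe_id\tgene_ids",
               paste(ann$probe_id,
                     vapply(ann$gene_ids, paste, "", collapse = ";"),
                     sep = "\t")), p)
  paths["annotation"] <- p
  p <- file.path(dir, "ontology.tsv")
  utils::write.table(ds$ontology, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["ontology"] <- p
  p <- file.path(dir, "truth.json")
  truth <- ds$truth
  truth$signs <- lapply(truth$signs, function(m)
    as.data.frame(m, stringsAsFactors = FALSE))
  jsonlite::write_json(truth, p, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns")
  paths["truth"] <- p
  invisible(paths)
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjustment of the Rand index; 1 for identical partitions,
#' ~0 for independent random ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(length(a), 2)
  expected <- ai * bj / nn
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(ifelse(nij == expected, 1, 0))
  (nij - expected) / (maxi - expected)
}

#' Score pipeline outputs against the simulation ground truth
#'
#' Every argument beyond `truth` is optional; only the metrics whose
#' inputs are supplied are computed.
#'
#' @param truth the `truth` element of [generate_dataset()].
#' @param retained named list (per ligand) of probe ids retained by
#'   [general_filter()] — yields per-ligand precision/recall against the
#'   responder class.
#' @param assignment named integer vector of cluster labels (names = probe
#'   ids) — yields the adjusted Rand index against the true onset
#'   categories of the probes that have one.
#' @param synexpression character vector of probe ids (a recovered shared
#'   group) — yields the Jaccard index against the planted shared set.
#' @param categories named character vector mapping probe ids to predicted
#'   responder categories — yields per-category accuracy and a confusion
#'   matrix on probes with a true category.
#' @param enrichment named list of enrichment tables per category — yields
#'   the rank of the planted term within its planted category.
#' @return list of metrics; unattainable entries absent.
#' @export
evaluate_recovery <- function(truth, retained = NULL, assignment = NULL,
                              synexpression = NULL, categories = NULL,
                              enrichment = NULL) {
  probes <- truth$probes
  out <- list()
  if (!is.null(retained)) {
    out$filter <- lapply(stats::setNames(names(retained), names(retained)),
                         function(lg) {
      r <- retained[[lg]]
      # signal-bearing probes for this ligand when known, else any responder
      responders <- if (!is.null(truth$responders[[lg]]))
        truth$responders[[lg]]
      else probes$probe_id[probes$class == "responder"]
      if (length(setdiff(r, probes$probe_id)))
        stop("retained probes outside the simulated probe universe")
      tp <- length(intersect(r, responders))
      list(precision = if (length(r)) tp / length(r) else NA_real_,
           recall = tp / length(responders),
           fpr = length(setdiff(r, responders)) /
             (nrow(probes) - length(responders)))
    })
  }
  if (!is.null(assignment)) {
    ids <- intersect(names(assignment),
                     probes$probe_id[!is.na(probes$onset_category)])
    if (!length(ids)) stop("no labelled probes among the assignment")
    out$ari <- adjusted_rand_index(
      assignment[ids],
      probes$onset_category[match(ids, probes$probe_id)])
  }
  if (!is.null(synexpression)) {
    if (length(setdiff(synexpression, probes$probe_id)))
      stop("synexpression probes outside the simulated probe universe")
    s <- truth$group$shared
    out$synexpression_jaccard <-
      length(intersect(synexpression, s)) /
      length(union(synexpression, s))
  }
  if (!is.null(categories)) {
    ids <- intersect(names(categories),
                     probes$probe_id[!is.na(probes$onset_category)])
    truecat <- probes$onset_category[match(ids, probes$probe_id)]
    cm <- table(true = factor(truecat, levels = TEMPORAL_CATEGORIES),
                predicted = factor(categories[ids],
                                   levels = TEMPORAL_CATEGORIES))
    acc <- diag(cm) / pmax(rowSums(cm), 1L)
    out$confusion <- cm
    out$category_accuracy <- acc[rowSums(cm) > 0]
    out$overall_accuracy <- sum(diag(cm)) / sum(cm)
  }
  if (!is.null(enrichment)) {
    tab <- enrichment[[truth$planted_category]]
    if (!is.null(tab) && nrow(tab))
      out$planted_term_rank <- match(truth$planted_term, tab$term_id)
  }
  out
}
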