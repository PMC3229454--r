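test_that("correlation distance is 1 - Pearson", {
  x <- c(1, 2, 3, 5, 4, 6)
  expect_equal(correlation_distance(x, x), 0)
  expect_equal(correlation_distance(x, -x), 2)
  set.seed(10)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(correlation_distance(a, b), 1 - cor(a, b),
               tolerance = 1e-12)
  expect_error(correlation_distance(rep(1, 5), a[1:5]), "zero-variance")
  expect_error(correlation_distance(a, b[1:10]), "length")
})

test_that("average-linkage tree matches a naive UPGMA oracle", {
  set.seed(12)
  for (n in c(5, 8, 12)) {
    v <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(sprintf("p%02d", 1:n), NULL))
    dend <- average_linkage_cluster(v)
    oracle <- oracle_upgma(1 - cor(t(v)))
    expect_equal(dend$hclust$height, oracle$height, tolerance = 1e-9)
    got <- t(apply(dend$hclust$merge, 1, sort))
    expect_equal(got, oracle$merge)
  }
})

test_that("identical rows merge at height zero", {
  v <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 1, 3, 9))
  dend <- average_linkage_cluster(v)
  expect_equal(min(dend$hclust$height), 0, tolerance = 1e-12)

  # duplicating every row: first n merges all at height ~0
  set.seed(13)
  w <- matrix(rnorm(5 * 8), 5, 8)
  dup <- rbind(w, w)
  rownames(dup) <- sprintf("r%d", 1:10)
  dd <- average_linkage_cluster(dup)
  expect_true(all(abs(sort(dd$hclust$height)[1:5]) < 1e-9))
})

test_that("zero-variance and incomplete probes are dropped with a warning", {
  v <- rbind(a = c(1, 2, 3, 4), b = rep(2, 4), c = c(4, 1, 3, 9),
             d = c(NA, 1, 2, 3))
  expect_warning(expect_warning(dend <- average_linkage_cluster(v),
                                "missing"), "zero-variance")
  expect_setequal(dend$labels, c("a", "c"))
  suppressWarnings(expect_error(average_linkage_cluster(v[1:2, ]),
                                "usable probes"))
})

test_that("tight clusters recover a planted correlated block", {
  set.seed(14)
  n_null <- 400; n_block <- 40; d <- 30
  latent <- rnorm(d, 0, 1.5)
  block <- matrix(rep(latent, each = n_block), n_block, d) +
    matrix(rnorm(n_block * d, 0, 0.25), n_block, d)
  nulls <- matrix(rnorm(n_null * d), n_null, d)
  v <- rbind(block, nulls)
  rownames(v) <- c(sprintf("blk%02d", 1:n_block),
                   sprintf("nul%03d", 1:n_null))
  dend <- average_linkage_cluster(v)
  tc <- extract_tight_clusters(dend, v)
  expect_equal(length(tc), 1L)
  expect_gte(sum(startsWith(tc[[1]]$probes, "blk")), 36L)
  expect_gte(tc[[1]]$mean_cor, 0.8)

  # pure noise yields nothing at the default tightness
  dn <- average_linkage_cluster(nulls)
  expect_length(extract_tight_clusters(dn, nulls), 0L)

  # cut height zero on distinct rows yields nothing
  expect_length(extract_tight_clusters(dend, v, cut_height = 0), 0L)
  expect_error(extract_tight_clusters(dend, v, min_size = 1), "min_size")
  expect_error(extract_tight_clusters(dend, v, tightness = 0), "tightness")
})

test_that("tight clusters partition a subset of the leaves", {
  set.seed(15)
  v <- matrix(rnorm(60 * 12), 60, 12,
              dimnames = list(sprintf("p%02d", 1:60), NULL))
  dend <- average_linkage_cluster(v)
  tc <- extract_tight_clusters(dend, v, cut_height = 1.2, min_size = 2,
                               tightness = 0.01)
  all_members <- unlist(lapply(tc, `[[`, "probes"))
  expect_equal(anyDuplicated(all_members), 0L)
  expect_true(all(all_members %in% dend$labels))
})

test_that("cluster intersection builds the shared synexpression group", {
  ann <- probe_annotation(c("p1", "p2", "p3", "p4"),
                          list("g1", c("g2", "g2b"), "g3", "g4"))
  g <- intersect_clusters(c("p1", "p2", "p3"), c("p2", "p3", "p4"), ann)
  expect_equal(g$shared, c("p2", "p3"))
  expect_equal(g$genes, "g3")  # p2 is multiply annotated
  expect_equal(g$size_a, 3L)

  g2 <- intersect_clusters(c("p2", "p3", "p4"), c("p1", "p2", "p3"), ann)
  expect_equal(g2$shared, g$shared)  # commutative in the shared set

  disjoint <- intersect_clusters("p1", "p4", ann)
  expect_length(disjoint$shared, 0L)
  expect_error(intersect_clusters(character(0), "p1"), "non-empty")
})

test_that("samples co-cluster by cell line when lines dominate correlation", {
  ds <- generate_dataset(sim_config(n_probes = 400, seed = 6))
  x <- ds$matrices$BMP4
  surv <- general_filter(x)
  v <- x$values[surv, ]
  cm <- cor(v)
  same_line <- outer(x$events$cell_line, x$events$cell_line, "==")
  diag(same_line) <- NA
  within <- mean(cm[same_line & upper.tri(cm)], na.rm = TRUE)
  between <- mean(cm[!same_line & upper.tri(cm)], na.rm = TRUE)
  expect_gt(within, between)
  # and the transposed clustering runs on the same metric
  sd_tree <- cluster_samples(expr_matrix(v, x$events))
  expect_equal(length(sd_tree$labels), 30L)
})

test_that("dendrograms export to Newick and JSON merge lists", {
  set.seed(16)
  v <- matrix(rnorm(6 * 10), 6, 10,
              dimnames = list(sprintf("p%d", 1:6), NULL))
  dend <- average_linkage_cluster(v)
  nwk <- dendrogram_newick(dend)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, rownames(v))

  f <- withr::local_tempfile(fileext = ".json")
  dendrogram_json(dend, f)
  js <- jsonlite::read_json(f)
  expect_length(js$merges, 5L)
  expect_equal(vapply(js$merges, function(m) m$height, 1),
               dend$hclust$height)
})
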