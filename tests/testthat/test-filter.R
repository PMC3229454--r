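test_that("regulation calls use inclusive symmetric log2 cutoffs", {
  expect_equal(is_regulated(1.0, 2), "up")
  expect_equal(is_regulated(-1.0, 2), "down")
  expect_equal(is_regulated(0.99, 2), "none")
  expect_equal(is_regulated(log2(3), 3), "up")
  expect_equal(is_regulated(NA_real_, 2), "none")
  expect_equal(is_regulated(c(2, -3, 0), 2), c("up", "down", "none"))
  expect_error(is_regulated(1, 1), "> 1")
  expect_error(is_regulated(1, 0.5), "> 1")
})

test_that("cell-line filter keeps probes regulated at >= 1 time point", {
  ek <- event_key("A", "BMP4", CANONICAL_TIMES)
  v <- rbind(p1 = c(0, 0, 0, 0, 0, 1.1),
             p2 = c(0.9, -0.9, 0.5, 0.2, 0, -0.85),
             p3 = c(-1.0, 0, 0, 0, 0, 0))
  x <- expr_matrix(v, ek)
  expect_equal(cellline_filter(x), c("p1", "p3"))

  # brute-force any-column scan oracle on a 200-probe synthetic line
  y <- random_grid_matrix(200, "HCC1954", sd = 0.6, seed = 21)
  expect_identical(cellline_filter(y), oracle_cellline(y))

  two_lines <- random_grid_matrix(5, c("A", "B"), seed = 1)
  expect_error(cellline_filter(two_lines), "exactly one")
  partial <- expr_matrix(x$values[, 1:5], x$events[1:5, ])
  expect_error(cellline_filter(partial), "canonical time points")
})

test_that("time-point filter is specific to its time point", {
  ek <- event_key("A", "BMP4", CANONICAL_TIMES)
  v <- rbind(p1 = c(0, 0, 1.0, 0, 0, 0))
  x <- expr_matrix(v, ek)
  expect_equal(timepoint_filter(x, 3), "p1")
  expect_equal(timepoint_filter(x, 6), character(0))
  expect_error(timepoint_filter(x, 2), "not present")

  y <- random_grid_matrix(200, c("A", "B"), sd = 0.6, seed = 22)
  for (tp in CANONICAL_TIMES)
    expect_identical(timepoint_filter(y, tp), oracle_timepoint(y, tp))
})

test_that("general filter applies the 3-fold/3-event or 2-fold/4-event rule", {
  ek <- event_key(rep(c("A", "B"), each = 6), "BMP4", rep(CANONICAL_TIMES, 2))
  v <- rbind(p_3x3 = c(log2(3), log2(3), log2(3), rep(0, 9)),
             p_2x3 = c(1, 1, 1, rep(0, 9)),
             p_2x4 = c(-1, -1, -1, -1, rep(0, 8)),
             p_null = rep(0.9, 12))
  x <- expr_matrix(v, ek)
  expect_equal(general_filter(x), c("p_3x3", "p_2x4"))

  y <- random_grid_matrix(200, c("A", "B", "C"), sd = 0.7, seed = 23)
  expect_identical(general_filter(y), oracle_general(y))

  mixed <- expr_matrix(matrix(0:3, 2, 2, dimnames = list(c("a", "b"), NULL)),
                       event_key("A", c("BMP4", "BMP7"), 1))
  expect_error(general_filter(mixed), "one ligand")
})

test_that("fold-change events at the stronger cutoff count toward the weaker", {
  ek <- event_key("A", "BMP4", CANONICAL_TIMES)
  # 2 events at 3-fold + 2 events at 2-fold: fails the fc3 clause (2 < 3)
  # but passes fc2 with 4 qualifying events
  v <- rbind(p = c(log2(3), -log2(3), 1, -1, 0, 0))
  expect_equal(general_filter(expr_matrix(v, ek)), "p")
})

test_that("filters are monotone in the fold-change threshold", {
  y <- random_grid_matrix(150, c("A", "B"), sd = 0.8, seed = 31)
  thresholds <- c(1.5, 2, 2.5, 3)
  prev_cl <- NULL; prev_gen <- NULL
  for (i in seq_along(thresholds)) {
    cfg <- filter_config(fc2 = thresholds[i], fc3 = max(3, thresholds[i]))
    gen <- general_filter(y, cfg)
    cl <- cellline_filter(subset_events(y, cell_line = "A"), cfg)
    if (i > 1) {
      expect_true(all(gen %in% prev_gen))
      expect_true(all(cl %in% prev_cl))
    }
    prev_gen <- gen; prev_cl <- cl
  }
})

test_that("general-filter survivors pass the cell-line filter somewhere", {
  y <- random_grid_matrix(150, c("A", "B"), sd = 0.8, seed = 32)
  gen <- general_filter(y)
  per_line <- unique(unlist(lapply(c("A", "B"), function(cl)
    cellline_filter(subset_events(y, cell_line = cl)))))
  expect_true(all(gen %in% per_line))
})

test_that("event counting matches exhaustive scans and the 30-event bound", {
  full <- random_grid_matrix(1, paste0("L", 1:5), seed = 1)
  full$values[1, ] <- 1.0
  cnt <- count_events(full)
  expect_equal(cnt$up_events, 30L)
  expect_equal(cnt$down_events, 0L)
  expect_equal(cnt$total_events, 30L)

  ek3 <- event_key("A", "BMP4", c(0.5, 1, 3))
  x3 <- expr_matrix(matrix(c(1.2, -1.5, 0.3), 1, 3,
                           dimnames = list("g", NULL)), ek3)
  expect_equal(unlist(count_events(x3)[, 2:4], use.names = FALSE),
               c(1L, 1L, 2L))

  y <- random_grid_matrix(100, paste0("L", 1:5), sd = 0.8, seed = 33)
  got <- count_events(y)
  oc <- oracle_counts(y)
  expect_equal(got$up_events, unname(oc[, "up"]))
  expect_equal(got$down_events, unname(oc[, "down"]))
  expect_true(all(got$total_events <= 30L))

  # invariance under column permutation
  perm <- sample(ncol(y$values))
  yp <- expr_matrix(y$values[, perm], y$events[perm, ])
  expect_equal(count_events(yp)[order(count_events(yp)$gene_id), ],
               got[order(got$gene_id), ])
  expect_error(count_events(y, ids = "nope"), "unknown id")
})

test_that("gene-level counts use uniquely annotated probes", {
  y <- random_grid_matrix(4, "A", seed = 3)
  y$values[] <- 0
  y$values[1, 1:3] <- 1.5   # p0001 -> gene gA
  y$values[2, 1:5] <- -1.5  # p0002 -> gene gA too (weaker mean |ratio|? no: 5 events)
  y$values[3, 1] <- 1.5     # p0003 -> multiple annotation, excluded
  ann <- probe_annotation(rownames(y$values),
                          list("gA", "gA", c("gB", "gC"), character(0)))
  cnt <- count_events(y, annotation = ann)
  expect_equal(cnt$gene_id, "gA")
  # representative = probe with larger mean |log2 ratio| (p0002: 5 events)
  expect_equal(cnt$total_events, 5L)
  expect_equal(cnt$down_events, 5L)
})

test_that("gene ranking orders by total, then up events, then id", {
  counts <- data.frame(gene_id = c("gA", "gB"),
                       up_events = c(5L, 0L), down_events = c(0L, 7L),
                       total_events = c(5L, 7L))
  expect_equal(rank_genes(counts)$gene_id, c("gB", "gA"))

  tie <- data.frame(gene_id = c("gB", "gA"),
                    up_events = c(3L, 4L), down_events = c(2L, 1L),
                    total_events = c(5L, 5L))
  expect_equal(rank_genes(tie)$gene_id, c("gA", "gB"))

  # full sort oracle on 500 genes
  set.seed(44)
  up <- rpois(500, 3); down <- rpois(500, 3)
  big <- data.frame(gene_id = sprintf("g%03d", sample(500)),
                    up_events = up, down_events = down,
                    total_events = up + down)
  ranked <- rank_genes(big, min_total = 6L)
  oracle <- big[big$total_events >= 6L, ]
  oracle <- oracle[order(-oracle$total_events, -oracle$up_events,
                         oracle$gene_id), ]
  expect_equal(ranked$gene_id, oracle$gene_id)
  expect_true(all(ranked$total_events >= 6L))
})

test_that("up-event fraction pools counts over the top rows", {
  allup <- rank_genes(data.frame(gene_id = c("a", "b"),
                                 up_events = c(4L, 2L),
                                 down_events = c(0L, 0L),
                                 total_events = c(4L, 2L)))
  expect_equal(up_fraction(allup, 2), 1.0)
  one <- rank_genes(data.frame(gene_id = "a", up_events = 3L,
                               down_events = 1L, total_events = 4L))
  expect_equal(up_fraction(one, 1), 0.75)
  expect_error(up_fraction(one, 0), "between 1 and")

  set.seed(45)
  up <- rpois(120, 4); down <- rpois(120, 2)
  tab <- rank_genes(data.frame(gene_id = sprintf("g%03d", 1:120),
                               up_events = up, down_events = down,
                               total_events = up + down))
  manual <- sum(tab$up_events[1:100]) / sum(tab$total_events[1:100])
  expect_equal(up_fraction(tab, 100), manual)
})
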