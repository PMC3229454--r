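test_that("profiles scale to unit Euclidean length", {
  sp <- scale_profiles(rbind(a = c(1, 0, 0, 0, 0, 0)))
  expect_equal(unname(sp$scaled[1, ]), c(1, 0, 0, 0, 0, 0))
  sp <- scale_profiles(rbind(a = c(3, 4, 0, 0, 0, 0)))
  expect_equal(unname(sp$scaled[1, ]), c(0.6, 0.8, 0, 0, 0, 0))

  set.seed(20)
  m <- matrix(rnorm(1000 * 6), 1000, 6)
  rownames(m) <- sprintf("p%04d", 1:1000)
  norms <- sqrt(rowSums(scale_profiles(m)$scaled^2))
  expect_true(all(abs(norms - 1) < 1e-9))

  withzero <- rbind(a = rep(0, 6), b = rnorm(6))
  expect_warning(sp <- scale_profiles(withzero), "all-zero")
  expect_equal(rownames(sp$scaled), "b")
})

test_that("responder categories follow the earliest threshold crossing", {
  expect_equal(classify_category(c(1.2, 0.5, 0, 0, 0, 0)), "early")
  expect_equal(classify_category(c(0, 1.1, 0, 0, 0, 0)), "early")
  expect_equal(classify_category(c(0, 0, -1.4, 0, 0, 0)),
               "early_intermediate")
  expect_equal(classify_category(c(0, 0, 0, 1.0, 2, 2)),
               "early_intermediate")
  expect_equal(classify_category(c(0, 0, 0, 0, -1.2, 0)),
               "late_intermediate")
  expect_equal(classify_category(c(0, 0, 0, 0, 0, 1.5)), "late")
  expect_equal(classify_category(c(0.2, 0.3, 0.1, 0.4, 0.2, 0.3)),
               "undetermined")
  # "regardless of their expression at later time points"
  expect_equal(classify_category(c(1.2, 0, 0, 0, 0, 3)), "early")
})

test_that("raising the category threshold never moves a profile earlier", {
  set.seed(21)
  ranks <- setNames(seq_along(TEMPORAL_CATEGORIES), TEMPORAL_CATEGORIES)
  for (i in 1:50) {
    p <- rnorm(6, 0, 1.5)
    c1 <- classify_category(p, threshold = 2)
    c2 <- classify_category(p, threshold = 3)
    expect_gte(ranks[c2], ranks[c1])
  }
})

test_that("BIC selects the true number of well-separated components", {
  set.seed(30)
  centers <- rbind(c(0, 0, 0, 0, 0, 0), c(10, 0, 0, 0, 0, 0),
                   c(0, 10, 0, 0, 0, 0))
  X <- do.call(rbind, lapply(1:2, function(k)
    sweep(matrix(rnorm(150 * 6), 150, 6), 2, centers[k, ], "+")))
  fit <- fit_mixture(X, K_range = 1:5, families = "spherical_varying",
                     seed = 1, n_starts = 5)
  expect_equal(fit$K, 2L)
  expect_equal(sum(fit$weight), 1, tolerance = 1e-9)
  expect_true(all(fit$weight > 0))

  # single tight blob: K = 1 wins when allowed
  X1 <- matrix(rnorm(120 * 4), 120, 4)
  fit1 <- fit_mixture(X1, K_range = 1:3, families = "spherical_varying",
                      seed = 1, n_starts = 5)
  expect_equal(fit1$K, 1L)
})

test_that("one-component spherical BIC equals the closed form", {
  set.seed(31)
  X <- matrix(rnorm(80 * 5, 2, 1.3), 80, 5)
  fit <- fit_mixture(X, K_range = 1L, families = "spherical_equal",
                     seed = 1)
  n <- nrow(X); d <- ncol(X)
  mu <- colMeans(X)
  s2 <- sum(sweep(X, 2, mu, "-")^2) / (n * d)
  ll <- sum(dnorm(sweep(X, 2, mu, "-"), 0, sqrt(s2), log = TRUE))
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
  expect_equal(fit$bic, 2 * ll - (d + 1) * log(n), tolerance = 1e-6)
})

test_that("EM log-likelihood is non-decreasing and assignments partition", {
  set.seed(32)
  X <- rbind(matrix(rnorm(90 * 6, 0, 1), 90, 6),
             matrix(rnorm(90 * 6, 4, 1), 90, 6))
  for (fam in MIXTURE_FAMILIES) {
    fit <- fit_mixture(X, K_range = 2:3, families = fam, seed = 2,
                       n_starts = 3)
    expect_true(all(diff(fit$loglik_trace) >= -1e-6))
    expect_equal(length(fit$cluster), nrow(X))
    expect_true(all(fit$cluster >= 1 & fit$cluster <= fit$K))
    expect_equal(rowSums(fit$resp), rep(1, nrow(X)), tolerance = 1e-9)
  }
  expect_error(fit_mixture(X[1:10, ], K_range = 2:25), "n >= 2")
})

test_that("mixture fits agree with an independent implementation", {
  set.seed(33)
  X <- rbind(matrix(rnorm(100 * 4, 0, 1), 100, 4),
             matrix(rnorm(100 * 4, 6, 1), 100, 4),
             matrix(rnorm(100 * 4, -6, 1), 100, 4))
  fit <- fit_mixture(X, K_range = 2:5, families = "spherical_varying",
                     seed = 3, n_starts = 5)
  suppressPackageStartupMessages(library(mclust))
  mc <- mclust::Mclust(X, G = 2:5, modelNames = "VII", verbose = FALSE)
  expect_equal(fit$K, mc$G)
  expect_equal(adjusted_rand_index(fit$cluster, mc$classification), 1,
               tolerance = 1e-9)
  # same model family and K: log-likelihoods should coincide at the optimum
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-3)
})

test_that("seeded fits are reproducible and leave the RNG state alone", {
  set.seed(34)
  X <- matrix(rnorm(100 * 4), 100, 4)
  before <- .Random.seed
  f1 <- fit_mixture(X, K_range = 2:3, families = "diagonal_varying",
                    seed = 9, n_starts = 3)
  expect_identical(.Random.seed, before)
  f2 <- fit_mixture(X, K_range = 2:3, families = "diagonal_varying",
                    seed = 9, n_starts = 3)
  expect_identical(f1$cluster, f2$cluster)
  expect_identical(f1$bic, f2$bic)
})

test_that("parameter recovery on synthetic mixtures reaches ARI >= 0.9", {
  aris <- vapply(1:5, function(seed) {
    set.seed(seed + 100)
    K <- if (seed %% 2) 3L else 5L
    centers <- matrix(rnorm(K * 6), K, 6)
    centers <- centers / sqrt(rowSums(centers^2)) * 8  # >= 6 sigma apart-ish
    labels <- rep(seq_len(K), each = 100)
    X <- centers[labels, ] + matrix(rnorm(length(labels) * 6), ncol = 6)
    fit <- fit_mixture(X, K_range = 2:7, families = "spherical_varying",
                       seed = seed, n_starts = 5)
    adjusted_rand_index(fit$cluster, labels)
  }, 1)
  expect_gte(median(aris), 0.9)
})

test_that("temporal pipeline categorizes planted blocks and partitions probes", {
  ds <- generate_dataset(sim_config(n_probes = 800, seed = 4))
  x <- subset_events(ds$matrices$BMP4, cell_line = "MDA-MB-361")
  surv <- cellline_filter(x)
  tc <- temporal_pipeline(x, surv, K_range = 2:16,
                          families = "spherical_varying", seed = 1,
                          n_starts = 5)
  # partition: category totals sum to the number of clustered probes
  expect_equal(sum(tc$summary$n_probes), length(tc$assignment))
  expect_equal(anyDuplicated(unlist(lapply(tc$clusters, `[[`, "probes"))), 0L)
  # cluster categories are consistent with their mean profiles
  for (cl in tc$clusters)
    expect_equal(classify_category(cl$mean_profile), cl$category)
  cm <- category_members(tc)
  cats <- setNames(rep(names(cm), lengths(cm)), unlist(cm))
  ev <- evaluate_recovery(ds$truth, categories = cats)
  expect_gte(ev$overall_accuracy, 0.9)

  # empty survivor set: empty summary, no error
  empty <- temporal_pipeline(x, character(0))
  expect_equal(nrow(empty$summary), 0L)
  expect_length(empty$clusters, 0L)
})
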