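# Model-based temporal clustering and responder categorization.
#
# Per cell line, the six-point log2-ratio profiles of filter survivors are
# scaled to unit Euclidean length and clustered with a finite Gaussian
# mixture fitted by EM. Five covariance families are fitted over a range
# of cluster counts K and the (family, K) pair maximizing
# BIC = 2*loglik - p*log(n) is selected. Each cluster is then categorized
# by the earliest time its mean original-scale profile crosses the
# regulation threshold: 0.5/1 h = early, 3/6 h = early-intermediate,
# 12 h = late-intermediate, 24 h = late, never = undetermined.

MIXTURE_FAMILIES <- c("spherical_equal", "spherical_varying",
                      "diagonal_equal", "diagonal_varying", "full")

TEMPORAL_CATEGORIES <- c("early", "early_intermediate", "late_intermediate",
                         "late", "undetermined")

#' Scale time profiles to unit Euclidean length
#'
#' @param x `expr_matrix` restricted to one (cell line, ligand) series, or
#'   a plain numeric matrix with one profile per row (values already on the
#'   log2-ratio scale). Profiles with missing values or zero norm are
#'   excluded with a warning.
#' @return list with `scaled` (rows of norm 1), `original` (matching rows,
#'   original scale) and `times` (column times when available).
#' @export
scale_profiles <- function(x) {
  times <- NULL
  if (inherits(x, "expr_matrix")) {
    times <- x$events$time_h
    v <- x$values
  } else v <- as.matrix(x)
  ok <- stats::complete.cases(v)
  if (!all(ok)) {
    warning(sum(!ok), " profile(s) with missing values excluded")
    v <- v[ok, , drop = FALSE]
  }
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0)) {
    warning(sum(nrm == 0), " all-zero profile(s) excluded")
    v <- v[nrm > 0, , drop = FALSE]
    nrm <- nrm[nrm > 0]
  }
  list(scaled = v / nrm, original = v, times = times)
}

# ---- Gaussian mixture internals ------------------------------------------

# Per-component log densities: n x K matrix.
.log_dens <- function(X, par) {
  n <- nrow(X); d <- ncol(X); K <- nrow(par$mu)
  ld <- matrix(0, n, K)
  for (k in seq_len(K)) {
    Xc <- sweep(X, 2L, par$mu[k, ], "-")
    cov <- par$cov[[k]]
    if (par$family %in% c("spherical_equal", "spherical_varying")) {
      s2 <- cov
      ld[, k] <- -0.5 * (d * log(2 * pi * s2) + rowSums(Xc^2) / s2)
    } else if (par$family %in% c("diagonal_equal", "diagonal_varying")) {
      ld[, k] <- -0.5 * (d * log(2 * pi) + sum(log(cov)) +
                           rowSums(sweep(Xc^2, 2L, cov, "/")))
    } else {
      ch <- chol(cov)
      z <- backsolve(ch, t(Xc), transpose = TRUE)
      ld[, k] <- -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) +
                           colSums(z^2))
    }
  }
  ld
}

# E-step: responsibilities and total log-likelihood via log-sum-exp.
.e_step <- function(X, par) {
  lw <- sweep(.log_dens(X, par), 2L, log(par$weight), "+")
  m <- apply(lw, 1L, max)
  lse <- m + log(rowSums(exp(lw - m)))
  list(resp = exp(lw - lse), loglik = sum(lse))
}

# M-step with variance floor; returns NULL when a component empties out.
.m_step <- function(X, resp, family, var_floor) {
  n <- nrow(X); d <- ncol(X); K <- ncol(resp)
  nk <- colSums(resp)
  if (any(nk < 1e-8)) return(NULL)
  weight <- nk / n
  mu <- crossprod(resp, X) / nk
  cov <- vector("list", K)
  if (family == "spherical_equal") {
    tot <- 0
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2L, mu[k, ], "-")
      tot <- tot + sum(resp[, k] * rowSums(Xc^2))
    }
    s2 <- max(tot / (n * d), var_floor)
    cov <- rep(list(s2), K)
  } else if (family == "spherical_varying") {
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2L, mu[k, ], "-")
      cov[[k]] <- max(sum(resp[, k] * rowSums(Xc^2)) / (nk[k] * d), var_floor)
    }
  } else if (family == "diagonal_equal") {
    tot <- numeric(d)
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2L, mu[k, ], "-")
      tot <- tot + colSums(resp[, k] * Xc^2)
    }
    v <- pmax(tot / n, var_floor)
    cov <- rep(list(v), K)
  } else if (family == "diagonal_varying") {
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2L, mu[k, ], "-")
      cov[[k]] <- pmax(colSums(resp[, k] * Xc^2) / nk[k], var_floor)
    }
  } else {
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2L, mu[k, ], "-")
      S <- crossprod(Xc * resp[, k], Xc) / nk[k]
      # ridge until positive definite; floor guards collapsed clusters
      ridge <- var_floor
      repeat {
        ok <- tryCatch({ chol(S + diag(ridge, d)); TRUE },
                       error = function(e) FALSE)
        if (ok) break
        ridge <- ridge * 10
        if (ridge > 1) return(NULL)
      }
      cov[[k]] <- S + diag(ridge, d)
    }
  }
  list(weight = weight, mu = mu, cov = cov, family = family)
}

# Free parameters in the covariance structure.
.cov_params <- function(family, K, d) {
  switch(family,
         spherical_equal = 1,
         spherical_varying = K,
         diagonal_equal = d,
         diagonal_varying = K * d,
         full = K * d * (d + 1) / 2)
}

# One EM run from a hard initial partition.
.em_run <- function(X, init, family, var_floor, max_iter, tol) {
  K <- max(init)
  resp <- matrix(0, nrow(X), K)
  resp[cbind(seq_len(nrow(X)), init)] <- 1
  par <- .m_step(X, resp, family, var_floor)
  if (is.null(par)) return(NULL)
  trace <- numeric(0)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    es <- .e_step(X, par)
    trace <- c(trace, es$loglik)
    if (is.finite(ll_prev) &&
        abs(es$loglik - ll_prev) / (abs(ll_prev) + 1e-12) < tol) break
    ll_prev <- es$loglik
    par <- .m_step(X, es$resp, family, var_floor)
    if (is.null(par)) return(NULL)
  }
  es <- .e_step(X, par)
  # degenerate solutions (a component owning < 2 points) ride variance-floor
  # likelihood spikes and would bias BIC toward spurious extra clusters
  if (any(colSums(es$resp) < 2)) return(NULL)
  list(par = par, loglik = es$loglik, resp = es$resp, trace = trace,
       iterations = length(trace))
}

# Deterministic initial partitions: k-means restarts (random partition
# fallback when k-means rejects the start).
.init_partition <- function(X, K, start_seed) {
  set.seed(start_seed)
  if (K == 1L) return(rep(1L, nrow(X)))
  km <- tryCatch(stats::kmeans(X, centers = K, nstart = 1L, iter.max = 50L),
                 error = function(e) NULL)
  if (!is.null(km) && max(km$cluster) == K) return(km$cluster)
  part <- rep(seq_len(K), length.out = nrow(X))
  sample(part)
}

#' Fit a Gaussian mixture with BIC model selection
#'
#' Fits finite Gaussian mixtures by expectation-maximization for every
#' combination of covariance family and cluster count, each with seeded
#' k-means multi-start, and returns the fit maximizing
#' `BIC = 2*loglik - p*log(n)` (maximize-is-better convention).
#'
#' @param x numeric matrix, rows = observations (e.g. unit-scaled time
#'   profiles), or the `scaled` element of [scale_profiles()].
#' @param K_range integer vector of cluster counts to try (default `2:25`);
#'   requires `nrow(x) >= 2 * max(K_range)`.
#' @param families subset of
#'   `c("spherical_equal", "spherical_varying", "diagonal_equal",
#'   "diagonal_varying", "full")`.
#' @param seed integer; all initialization randomness derives from it. The
#'   caller's RNG state is left untouched.
#' @param n_starts k-means restarts per (family, K) (default 10).
#' @param max_iter,tol EM stopping rule: relative log-likelihood change
#'   below `tol` (default 1e-8) or `max_iter` (default 500) iterations.
#' @param var_floor lower bound on variances (default 1e-6), guarding
#'   against singular covariances.
#' @return object of class `bmp_mixture`: selected `family`, `K`,
#'   `weight`, `mu` (K x d means), `cov`, `loglik`, `bic`,
#'   `loglik_trace` (per EM iteration of the winning run), `resp`
#'   (responsibilities), `cluster` (hard assignments), and `bic_table`
#'   over all (family, K) fits.
#' @export
fit_mixture <- function(x, K_range = 2:25, families = MIXTURE_FAMILIES,
                        seed = 1L, n_starts = 10L, max_iter = 500L,
                        tol = 1e-8, var_floor = 1e-6) {
  X <- as.matrix(x)
  families <- match.arg(families, MIXTURE_FAMILIES, several.ok = TRUE)
  K_range <- sort(unique(as.integer(K_range)))
  if (any(K_range < 1L)) stop("cluster counts must be >= 1")
  n <- nrow(X)
  if (n < 2L * max(K_range))
    stop("need n >= 2*max(K_range); n = ", n, ", max K = ", max(K_range))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  bic_table <- data.frame()
  best <- NULL
  for (fam in families) {
    for (K in K_range) {
      fit_k <- NULL
      starts <- if (K == 1L) 1L else n_starts
      for (s in seq_len(starts)) {
        ss <- (abs(seed) * 97L + match(fam, MIXTURE_FAMILIES) * 7919L +
                 K * 131L + s) %% 2147483647L
        init <- .init_partition(X, K, ss)
        run <- .em_run(X, init, fam, var_floor, max_iter, tol)
        if (!is.null(run) && (is.null(fit_k) || run$loglik > fit_k$loglik))
          fit_k <- run
      }
      if (is.null(fit_k)) next
      p <- (K - 1) + K * ncol(X) + .cov_params(fam, K, ncol(X))
      bic <- 2 * fit_k$loglik - p * log(n)
      bic_table <- rbind(bic_table,
                         data.frame(family = fam, K = K, n_params = p,
                                    loglik = fit_k$loglik, bic = bic,
                                    stringsAsFactors = FALSE))
      if (is.null(best) || bic > best$bic)
        best <- c(fit_k, list(family = fam, K = K, bic = bic, n_params = p))
    }
  }
  if (is.null(best)) stop("no (family, K) combination produced a valid fit")
  cluster <- max.col(best$resp, ties.method = "first")
  structure(list(family = best$family, K = best$K,
                 weight = best$par$weight, mu = best$par$mu,
                 cov = best$par$cov, loglik = best$loglik, bic = best$bic,
                 n_params = best$n_params, loglik_trace = best$trace,
                 resp = best$resp, cluster = cluster, n = n, d = ncol(X),
                 bic_table = bic_table, seed = seed),
            class = "bmp_mixture")
}

#' @export
print.bmp_mixture <- function(x, ...) {
  cat(sprintf("bmp_mixture: %d clusters, family %s (n = %d, d = %d)\n",
              x$K, x$family, x$n, x$d))
  cat(sprintf("  loglik = %.3f, BIC = %.3f (%d free parameters)\n",
              x$loglik, x$bic, x$n_params))
  cat("  cluster sizes:", paste(tabulate(x$cluster, x$K), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.bmp_mixture <- function(object, ...) {
  tab <- object$bic_table
  best_by_k <- do.call(rbind, lapply(split(tab, tab$K), function(g)
    g[which.max(g$bic), , drop = FALSE]))
  cat("BIC by cluster count (best family per K):\n")
  print(best_by_k, row.names = FALSE)
  cat(sprintf("\nselected: K = %d, family = %s, BIC = %.3f\n",
              object$K, object$family, object$bic))
  invisible(best_by_k)
}

#' @export
predict.bmp_mixture <- function(object, newdata, type = c("class", "resp"),
                                ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  par <- list(weight = object$weight, mu = object$mu, cov = object$cov,
              family = object$family)
  es <- .e_step(X, par)
  if (type == "resp") return(es$resp)
  max.col(es$resp, ties.method = "first")
}

# ---- Responder categories -------------------------------------------------

#' Classify a temporal profile into a responder category
#'
#' The earliest time point at which |log2 ratio| reaches the regulation
#' threshold determines the category: 0.5 or 1 h = `early`, 3 or 6 h =
#' `early_intermediate`, 12 h = `late_intermediate`, 24 h = `late`
#' (regulated exclusively at 24 h), never = `undetermined`.
#'
#' @param profile numeric vector of six log2 ratios ordered by time, or a
#'   matrix with one profile per row.
#' @param threshold fold-change cutoff (default 2).
#' @param times time points in hours (default the canonical six).
#' @return character vector of categories.
#' @export
classify_category <- function(profile, threshold = 2,
                              times = CANONICAL_TIMES) {
  m <- if (is.matrix(profile)) profile else matrix(profile, nrow = 1L)
  if (ncol(m) != length(times))
    stop("profiles must have one value per time point")
  lt <- log2(threshold)
  ord <- order(times)
  m <- m[, ord, drop = FALSE]
  tt <- times[ord]
  apply(m, 1L, function(v) {
    idx <- which(abs(v) >= lt)
    if (!length(idx)) return("undetermined")
    t0 <- tt[idx[1L]]
    if (t0 <= 1) "early"
    else if (t0 <= 6) "early_intermediate"
    else if (t0 <= 12) "late_intermediate"
    else "late"
  })
}

#' Temporal clustering pipeline for one cell line
#'
#' Unit-scales the profiles of cell-line-filter survivors, fits the
#' BIC-selected Gaussian mixture, assigns each probe to its maximum-
#' responsibility cluster, and categorizes each cluster from its mean
#' original-scale profile.
#'
#' @param x `expr_matrix` restricted to one (cell line, ligand) series.
#' @param probes probe ids to cluster (typically [cellline_filter()]
#'   survivors); an empty vector yields an empty result.
#' @param K_range,families,seed,n_starts passed to [fit_mixture()];
#'   `K_range` is truncated to at most `floor(n/2)` clusters.
#' @param threshold regulation threshold for category calls (default 2).
#' @param classify `"cluster"` (default; categories assigned to clusters
#'   via their mean profile) or `"probe"` (each probe categorized from its
#'   own profile).
#' @return object of class `temporal_clusters`: `clusters` (list with
#'   `cluster_id`, `probes`, `mean_profile`, `category`), `assignment`
#'   (named vector), `fit` (`bmp_mixture`), `summary` (data.frame:
#'   category, cluster_id, n_probes) and `category_genes` helper input.
#' @export
temporal_pipeline <- function(x, probes, K_range = 2:25,
                              families = MIXTURE_FAMILIES, seed = 1L,
                              n_starts = 10L, threshold = 2,
                              classify = c("cluster", "probe")) {
  classify <- match.arg(classify)
  if (length(unique(x$events$cell_line)) != 1L ||
      length(unique(x$events$ligand)) != 1L)
    stop("temporal pipeline runs on one (cell line, ligand) at a time")
  empty <- structure(list(clusters = list(),
                          assignment = setNames(integer(0), character(0)),
                          fit = NULL,
                          summary = data.frame(category = character(),
                                               cluster_id = integer(),
                                               n_probes = integer(),
                                               stringsAsFactors = FALSE)),
                     class = "temporal_clusters")
  if (!length(probes)) return(empty)
  sub <- subset_events(x, probes = probes)
  sp <- scale_profiles(sub)
  if (nrow(sp$scaled) < 2L) return(empty)
  K_range <- K_range[K_range <= floor(nrow(sp$scaled) / 2)]
  if (!length(K_range)) K_range <- 1L
  fit <- fit_mixture(sp$scaled, K_range = K_range, families = families,
                     seed = seed, n_starts = n_starts)
  ids <- rownames(sp$scaled)
  assignment <- stats::setNames(fit$cluster, ids)
  clusters <- lapply(seq_len(fit$K), function(k) {
    members <- ids[fit$cluster == k]
    mp <- colMeans(sp$original[members, , drop = FALSE])
    cat_k <- if (classify == "cluster") {
      classify_category(mp, threshold, sp$times)
    } else {
      # majority probe-level category; ties to the earlier category
      pc <- classify_category(sp$original[members, , drop = FALSE],
                              threshold, sp$times)
      tab <- table(factor(pc, levels = TEMPORAL_CATEGORIES))
      names(tab)[which.max(tab)]
    }
    list(cluster_id = k, probes = members, mean_profile = mp,
         category = cat_k)
  })
  summary <- data.frame(
    category = vapply(clusters, `[[`, "", "category"),
    cluster_id = vapply(clusters, `[[`, 1L, "cluster_id"),
    n_probes = vapply(clusters, function(cl) length(cl$probes), 1L),
    stringsAsFactors = FALSE)
  summary <- summary[order(match(summary$category, TEMPORAL_CATEGORIES),
                           summary$cluster_id), , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(clusters = clusters, assignment = assignment, fit = fit,
                 summary = summary),
            class = "temporal_clusters")
}

#' @export
print.temporal_clusters <- function(x, ...) {
  if (!length(x$clusters)) {
    cat("temporal_clusters: empty\n")
    return(invisible(x))
  }
  cat(sprintf("temporal_clusters: %d clusters over %d probes (family %s)\n",
              length(x$clusters), length(x$assignment), x$fit$family))
  agg <- stats::aggregate(n_probes ~ category, data = x$summary, FUN = sum)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-18s %d probes\n", agg$category[i], agg$n_probes[i]))
  invisible(x)
}

#' Probe ids per temporal category
#'
#' @param tc `temporal_clusters`.
#' @return named list mapping each non-empty category to the union of its
#'   clusters' member probes.
#' @export
category_members <- function(tc) {
  out <- list()
  for (cl in tc$clusters)
    out[[cl$category]] <- c(out[[cl$category]], cl$probes)
  lapply(out, sort)
}
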