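#' Min-max normalise engagement metrics
#'
#' Scales each metric column to span \[0, 1\]. A constant column carries no
#' clustering information and is mapped to all-zero with a warning.
#'
#' @param x Numeric matrix or data frame (volunteers x metrics).
#' @return Numeric matrix in \[0, 1\] with the same dimnames.
#' @export
normalize_metrics <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("metrics must be numeric", call. = FALSE)
  if (nrow(x) < 2) stop("need at least 2 volunteers", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite metric values", call. = FALSE)
  out <- apply(x, 2, function(col) {
    rng <- range(col)
    if (rng[1] == rng[2]) {
      warning("constant metric column normalised to 0", call. = FALSE)
      rep(0, length(col))
    } else {
      (col - rng[1]) / (rng[2] - rng[1])
    }
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Ward hierarchical tree with within-group sum of squares curve
#'
#' Agglomerates volunteers under Ward's minimum-variance criterion
#' (Ward.D2 on Euclidean distances) and reports the within-group sum of
#' squares obtained by cutting the tree at each k. Cutting at k = 1 gives
#' the total sum of squares; the curve is non-increasing because each cut
#' refines the previous partition.
#'
#' @param x Numeric matrix of normalised metrics.
#' @param k_max Largest cut examined (default 8, capped at n).
#' @return A list with `tree` (an `hclust`) and `wss_by_k` (named numeric).
#' @export
ward_tree <- function(x, k_max = 8) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite values", call. = FALSE)
  k_max <- min(k_max, nrow(x))
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  wss <- vapply(seq_len(k_max), function(k) {
    lab <- stats::cutree(hc, k)
    .wss(x, lab)
  }, numeric(1))
  names(wss) <- seq_len(k_max)
  list(tree = hc, wss_by_k = wss)
}

.wss <- function(x, labels) {
  sum(vapply(split(seq_len(nrow(x)), labels), function(idx) {
    xs <- x[idx, , drop = FALSE]
    ctr <- colMeans(xs)
    sum(sweep(xs, 2, ctr)^2)
  }, numeric(1)))
}

.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  if (k > 1) {
    for (j in 2:k) {
      if (all(d2 == 0)) {
        idx <- sample.int(n, 1)
      } else {
        idx <- sample.int(n, 1, prob = d2)
      }
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  centers
}

#' K-means engagement clustering
#'
#' Lloyd's algorithm with k-means++ initialisation, keeping the best of
#' `n_restarts` runs by total within-cluster sum of squares. Deterministic
#' given `seed`. Clusters are relabelled so that cluster indices are stable:
#' ordered by their centroid's first coordinate sum (ties by index).
#'
#' @param x Numeric matrix (volunteers x metrics).
#' @param k Number of clusters (2 <= k <= n).
#' @param seed Integer RNG seed.
#' @param n_restarts Restarts (default 25).
#' @return A list: `cluster` (integer assignments), `centers`, `tot_withinss`.
#' @export
kmeans_profiles <- function(x, k, seed = 1, n_restarts = 25) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k exceeds the number of volunteers", call. = FALSE)
  if (k < 1) stop("k must be positive", call. = FALSE)
  best <- NULL
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    init <- .kmeanspp_init(x, k)
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = init, iter.max = 100,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed for every restart", call. = FALSE)
  list(cluster = as.integer(best$cluster),
       centers = best$centers,
       tot_withinss = best$tot.withinss)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Average silhouette width
#'
#' For each point, a is the mean distance to its own cluster (excluding
#' itself) and b the smallest mean distance to any other cluster; the
#' silhouette is (b - a) / max(a, b). Singletons (and points with a = b = 0)
#' contribute 0. The average over points lies in \[-1, 1\].
#'
#' @param x Numeric matrix, or `NULL` if `dmat` is supplied.
#' @param cluster Integer/factor assignments, every cluster non-empty.
#' @param dmat Optional precomputed distance matrix (full square form).
#' @return The average silhouette width (scalar).
#' @export
average_silhouette_width <- function(x, cluster, dmat = NULL) {
  cluster <- as.integer(factor(cluster))
  if (length(unique(cluster)) < 2) {
    stop("silhouette needs at least 2 clusters", call. = FALSE)
  }
  if (is.null(dmat)) dmat <- as.matrix(stats::dist(as.matrix(x)))
  n <- length(cluster)
  stopifnot(nrow(dmat) == n)
  ks <- sort(unique(cluster))
  # mean distance from every point to every cluster
  md <- sapply(ks, function(k) rowMeans(dmat[, cluster == k, drop = FALSE]))
  sizes <- tabulate(cluster)
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- cluster[i]
    if (sizes[ci] == 1) {
      s[i] <- 0
      next
    }
    a <- md[i, ci] * sizes[ci] / (sizes[ci] - 1) # exclude self (distance 0)
    b <- min(md[i, setdiff(ks, ci)])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Choose the number of engagement profiles
#'
#' Fits k-means at every k in `k_range`, computes the average silhouette
#' width of each solution, and returns the k maximising it. The partition is
#' flagged as accepted only when the best width reaches `asw_threshold`
#' (default 0.51, the conventional sufficiency mark for these profiles);
#' otherwise the result reports insufficient partitioning rather than
#' raising an error. The Ward within-group sum-of-squares curve is a
#' diagnostic, not a selector.
#'
#' @param x Normalised metric matrix.
#' @param k_range Candidate cluster counts (default 2:8).
#' @param asw_threshold Acceptance threshold on the silhouette width.
#' @param seed Integer RNG seed for the k-means restarts.
#' @param n_restarts Restarts per k.
#' @return A list: `k`, `accepted`, `asw`, `asw_by_k`, `models` (k-means
#'   fits keyed by k).
#' @export
select_k <- function(x, k_range = 2:8, asw_threshold = 0.51, seed = 1,
                     n_restarts = 25) {
  x <- as.matrix(x)
  k_range <- k_range[k_range >= 2 & k_range <= nrow(x)]
  if (length(k_range) == 0) stop("empty candidate k range", call. = FALSE)
  dmat <- as.matrix(stats::dist(x))
  models <- list()
  asw_by_k <- stats::setNames(numeric(length(k_range)),
                              as.character(k_range))
  for (j in seq_along(k_range)) {
    k <- k_range[j]
    fit <- kmeans_profiles(x, k, seed = seed + k, n_restarts = n_restarts)
    models[[as.character(k)]] <- fit
    asw_by_k[j] <- average_silhouette_width(NULL, fit$cluster, dmat = dmat)
  }
  best <- which.max(asw_by_k)
  list(k = k_range[best],
       accepted = asw_by_k[best] >= asw_threshold,
       asw = unname(asw_by_k[best]),
       asw_by_k = asw_by_k,
       models = models)
}

#' Fit volunteer engagement profiles
#'
#' End-to-end profiling of an engagement table: min-max normalisation of the
#' four metrics, Ward tree (within-group sum-of-squares diagnostic),
#' silhouette-validated choice of k, and a best-of-restarts k-means
#' partition. When three profiles are selected they are named dabbler,
#' steady and enthusiast in ascending order of mean raw observation count;
#' otherwise profiles are named `profile_1`, ... in the same order.
#'
#' @param engagement Output of [engagement_table()].
#' @param k_range,asw_threshold,n_restarts Passed to [select_k()].
#' @param seed Integer RNG seed; the whole fit is deterministic given the
#'   data and this seed.
#' @return An object of class `profile_model`: `k`, `accepted`, `asw`,
#'   `asw_by_k`, `wss_by_k`, `assignments` (tibble recorder_id/profile),
#'   `centroids_normalized`, `centroids_raw`, `seed`.
#' @export
fit_profiles <- function(engagement, k_range = 2:8, asw_threshold = 0.51,
                         seed = 1, n_restarts = 25) {
  metrics <- c("n_observations", "activity_ratio",
               "relative_activity_duration", "variation_in_periodicity")
  stopifnot(all(metrics %in% names(engagement)))
  raw <- as.matrix(engagement[metrics])
  xn <- normalize_metrics(raw)
  wt <- ward_tree(xn, k_max = max(k_range))
  sel <- select_k(xn, k_range = k_range, asw_threshold = asw_threshold,
                  seed = seed, n_restarts = n_restarts)
  fit <- sel$models[[as.character(sel$k)]]
  k <- sel$k
  # order profiles by ascending mean raw observation count
  mean_obs <- vapply(seq_len(k), function(j) {
    mean(raw[fit$cluster == j, "n_observations"])
  }, numeric(1))
  ord <- order(mean_obs)
  relabel <- match(seq_len(k), ord)
  labels <- if (k == 3) {
    c("dabbler", "steady", "enthusiast")
  } else {
    paste0("profile_", seq_len(k))
  }
  profile <- labels[relabel[fit$cluster]]
  cent_raw <- t(vapply(ord, function(j) {
    colMeans(raw[fit$cluster == j, , drop = FALSE])
  }, numeric(ncol(raw))))
  cent_norm <- t(vapply(ord, function(j) {
    colMeans(xn[fit$cluster == j, , drop = FALSE])
  }, numeric(ncol(xn))))
  rownames(cent_raw) <- rownames(cent_norm) <- labels
  structure(list(
    k = k,
    accepted = sel$accepted,
    asw = sel$asw,
    asw_by_k = sel$asw_by_k,
    wss_by_k = wt$wss_by_k,
    assignments = tibble::tibble(recorder_id = engagement$recorder_id,
                                 profile = profile),
    centroids_normalized = cent_norm,
    centroids_raw = cent_raw,
    seed = seed
  ), class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat("Volunteer engagement profile model\n")
  cat(sprintf("  k = %d (%s), average silhouette width = %.3f\n",
              x$k, if (x$accepted) "accepted" else "insufficient partitioning",
              x$asw))
  tab <- table(x$assignments$profile)
  for (nm in rownames(x$centroids_raw)) {
    cat(sprintf("  %-12s n = %4d  mean obs = %8.1f  AR = %.2f  RAD = %.3f  VP = %.2f\n",
                nm, tab[[nm]],
                x$centroids_raw[nm, "n_observations"],
                x$centroids_raw[nm, "activity_ratio"],
                x$centroids_raw[nm, "relative_activity_duration"],
                x$centroids_raw[nm, "variation_in_periodicity"]))
  }
  invisible(x)
}

#' Profile summary table
#'
#' Per-profile mean raw metrics (the cluster centroids in original units),
#' volunteer counts, percentage shares rounded to the nearest whole number,
#' and the percentage of each profile's volunteers active for one day only.
#'
#' @param model A [fit_profiles()] result.
#' @param engagement The engagement table the model was fitted to.
#' @return A tibble, one row per profile in ascending engagement order.
#' @export
profile_summary <- function(model, engagement) {
  stopifnot(inherits(model, "profile_model"))
  df <- dplyr::inner_join(engagement, model$assignments, by = "recorder_id")
  out <- df |>
    dplyr::group_by(.data$profile) |>
    dplyr::summarise(
      n_observations = mean(.data$n_observations),
      activity_ratio = mean(.data$activity_ratio),
      relative_activity_duration = mean(.data$relative_activity_duration),
      variation_in_periodicity = mean(.data$variation_in_periodicity),
      n_volunteers = dplyr::n(),
      percent_single_day = round(100 * mean(.data$single_day)),
      .groups = "drop"
    ) |>
    dplyr::mutate(percent_volunteers =
                    round(100 * .data$n_volunteers / sum(.data$n_volunteers)))
  out[match(rownames(model$centroids_raw), out$profile), ]
}

#' Spearman correlations among engagement metrics
#'
#' Pairwise Spearman rank correlations (average ranks for ties, two-sided
#' t-approximation p-values) among the four engagement metrics. A constant
#' metric has no defined rank correlation and is reported as `NA`.
#'
#' @param engagement An [engagement_table()] result (>= 3 volunteers).
#' @return A list with matrices `rho` and `p`.
#' @export
metric_correlations <- function(engagement) {
  metrics <- c("n_observations", "activity_ratio",
               "relative_activity_duration", "variation_in_periodicity")
  x <- as.matrix(engagement[metrics])
  if (nrow(x) < 3) stop("need at least 3 volunteers", call. = FALSE)
  m <- length(metrics)
  rho <- p <- matrix(NA_real_, m, m, dimnames = list(metrics, metrics))
  diag(rho) <- 1
  diag(p) <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (stats::sd(x[, i]) == 0 || stats::sd(x[, j]) == 0) next
      ct <- suppressWarnings(
        stats::cor.test(x[, i], x[, j], method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(rho = rho, p = p)
}
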