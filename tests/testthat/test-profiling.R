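two_clouds <- function(n_per = 10, sep = 5, d = 2, sd = 0.1, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d, 0, sd), ncol = d),
             matrix(rnorm(n_per * d, sep, sd), ncol = d))
  list(x = x, labels = rep(1:2, each = n_per))
}

test_that("min-max normalisation maps columns onto [0,1]", {
  x <- cbind(a = c(2, 4, 6), b = c(0, 0.5, 1))
  out <- normalize_metrics(x)
  expect_equal(out[, "a"], c(0, 0.5, 1))
  expect_equal(out[, "b"], c(0, 0.5, 1)) # already spanning [0,1]: unchanged
  expect_warning(norm_const <- normalize_metrics(cbind(c(3, 3, 3), 1:3)),
                 "constant")
  expect_equal(norm_const[, 1], c(0, 0, 0))
  expect_error(normalize_metrics(matrix(1, 1, 2)), "2 volunteers")
  expect_error(normalize_metrics(cbind(c(1, NA), 1:2)), "non-finite")
})

test_that("Ward tree separates planted clouds and WSS starts at TSS", {
  tc <- two_clouds()
  wt <- ward_tree(tc$x, k_max = 4)
  cut2 <- stats::cutree(wt$tree, 2)
  expect_equal(ari(cut2, tc$labels), 1)
  tss <- sum(sweep(tc$x, 2, colMeans(tc$x))^2)
  expect_equal(unname(wt$wss_by_k["1"]), tss)
  expect_true(all(diff(wt$wss_by_k) <= 1e-9)) # non-increasing in k

  tiny <- ward_tree(matrix(c(0, 0, 1, 1), 2, 2), k_max = 2)
  expect_equal(unname(tiny$wss_by_k["2"]), 0)
  expect_error(ward_tree(matrix(c(1, NA, 2, 3), 2, 2)), "non-finite")
})

test_that("k-means recovers the exhaustively optimal 1-D split", {
  x <- matrix(c(0, 0.01, 0.99, 1.0), ncol = 1)
  fit <- kmeans_profiles(x, 2, seed = 9)
  expect_equal(fit$cluster[1], fit$cluster[2])
  expect_equal(fit$cluster[3], fit$cluster[4])
  expect_false(fit$cluster[1] == fit$cluster[3])
  # exhaustive check: no 2-partition beats the returned WSS
  parts <- utils::combn(4, 2, simplify = FALSE)
  best <- min(vapply(parts, function(idx) {
    sum((x[idx] - mean(x[idx]))^2) + sum((x[-idx] - mean(x[-idx]))^2)
  }, numeric(1)))
  expect_equal(fit$tot_withinss, best)

  expect_equal(kmeans_profiles(x, 4, seed = 1)$tot_withinss, 0) # k = n
  expect_error(kmeans_profiles(x, 5), "exceeds")
})

test_that("duplicating every point leaves the k-means centroids unchanged", {
  tc <- two_clouds(n_per = 8)
  f1 <- kmeans_profiles(tc$x, 2, seed = 4)
  f2 <- kmeans_profiles(rbind(tc$x, tc$x), 2, seed = 4)
  ord1 <- order(f1$centers[, 1])
  ord2 <- order(f2$centers[, 1])
  expect_equal(f1$centers[ord1, ], f2$centers[ord2, ], ignore_attr = TRUE)
})

test_that("k-means is deterministic given the seed", {
  tc <- two_clouds(n_per = 20, sep = 2)
  a <- kmeans_profiles(tc$x, 3, seed = 123)
  b <- kmeans_profiles(tc$x, 3, seed = 123)
  expect_identical(a, b)
})

test_that("silhouette width behaves at its analytic reference points", {
  # two tight pairs, separation 1000x the spread
  x <- matrix(c(0, 0.001, 1, 1.001), ncol = 1)
  expect_gte(average_silhouette_width(x, c(1, 1, 2, 2)), 0.99)

  # random labels on one blob are near zero
  set.seed(21)
  blob <- matrix(rnorm(400), ncol = 2)
  expect_lt(abs(average_silhouette_width(blob, sample(1:2, 200, TRUE))),
            0.1)

  # the middle point is equidistant between clusters (a = b): silhouette 0;
  # the singleton also contributes 0, so ASW = (0.5 + 0 + 0) / 3
  x3 <- matrix(c(0, 0.5, 1), ncol = 1)
  expect_equal(average_silhouette_width(x3, c(1, 1, 2)), 0.5 / 3)
  expect_error(average_silhouette_width(x3, c(1, 1, 1)), "2 clusters")

  # agreement with the cluster package on random data
  set.seed(22)
  y <- matrix(rnorm(60 * 3), ncol = 3)
  lab <- sample(1:3, 60, replace = TRUE)
  ours <- average_silhouette_width(y, lab)
  ref <- mean(cluster::silhouette(lab, dist(y))[, "sil_width"])
  expect_equal(ours, ref)
})

test_that("planted partitions beat random relabelings on silhouette", {
  tc <- two_clouds(n_per = 15, sep = 3)
  planted <- average_silhouette_width(tc$x, tc$labels)
  set.seed(33)
  for (i in 1:100) {
    rnd <- sample(tc$labels)
    expect_gte(planted, average_silhouette_width(tc$x, rnd))
  }
})

test_that("k selection finds planted archetypes and flags single blobs", {
  set.seed(8)
  x <- rbind(matrix(rnorm(60, 0, 0.05), ncol = 2),
             matrix(rnorm(60, 1, 0.05), ncol = 2),
             cbind(rnorm(30, 0, 0.05), rnorm(30, 1, 0.05)))
  sel <- select_k(x, 2:8, seed = 2)
  expect_equal(sel$k, 3)
  expect_true(sel$accepted)

  blob <- matrix(rnorm(200), ncol = 2)
  sel2 <- select_k(blob, 2:6, seed = 2)
  expect_false(sel2$accepted)
  # threshold -1 always accepts the argmax
  sel3 <- select_k(blob, 2:6, asw_threshold = -1, seed = 2)
  expect_true(sel3$accepted)
  expect_equal(sel3$k, as.integer(names(which.max(sel3$asw_by_k))))
})

test_that("profile model orders labels by engagement and summarises shares", {
  sim <- simulate_volunteers(300, seed = 14)
  eng <- engagement_table(volunteer_day_records(sim),
                          study_window("2010-01-01",
                                       as.Date("2010-01-01") + 729))
  model <- fit_profiles(eng, seed = 14)
  expect_s3_class(model, "profile_model")
  expect_equal(model$k, 3)
  expect_equal(rownames(model$centroids_raw),
               c("dabbler", "steady", "enthusiast"))
  expect_true(all(diff(model$centroids_raw[, "n_observations"]) > 0))

  ps <- profile_summary(model, eng)
  expect_equal(ps$profile, c("dabbler", "steady", "enthusiast"))
  expect_equal(sum(ps$n_volunteers), nrow(eng))
  expect_lte(abs(sum(ps$percent_volunteers) - 100), 2) # rounding slack
  expect_equal(ps$n_observations,
               unname(model$centroids_raw[, "n_observations"]))

  # identical refit: full pipeline deterministic given data and seed
  model2 <- fit_profiles(eng, seed = 14)
  expect_identical(model$assignments, model2$assignments)
  expect_identical(model$asw, model2$asw)
})

test_that("metric correlations match the rank formula and handle ties", {
  eng <- tibble::tibble(
    recorder_id = sprintf("v%d", 1:6),
    n_observations = c(1, 2, 3, 4, 5, 6),
    activity_ratio = c(2, 4, 6, 8, 10, 12) / 12,  # monotone with n_obs
    relative_activity_duration = c(6, 5, 4, 3, 2, 1) / 10, # reversed
    variation_in_periodicity = c(0.3, 1.2, 0.7, 1.9, 0.2, 1.1)
  )
  mc <- metric_correlations(eng)
  expect_equal(mc$rho["n_observations", "activity_ratio"], 1)
  expect_equal(mc$rho["n_observations", "relative_activity_duration"], -1)
  expect_equal(mc$rho["n_observations", "variation_in_periodicity"],
               oracle_spearman(eng$n_observations,
                               eng$variation_in_periodicity))

  eng$variation_in_periodicity <- 1 # constant -> undefined
  mc2 <- metric_correlations(eng)
  expect_true(is.na(mc2$rho["n_observations", "variation_in_periodicity"]))
  expect_error(metric_correlations(eng[1:2, ]), "3 volunteers")
})
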