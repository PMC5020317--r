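test_that("identical seeds reproduce cohorts and record tables exactly", {
  v1 <- simulate_volunteers(50, seed = 77)
  v2 <- simulate_volunteers(50, seed = 77)
  expect_identical(v1, v2)

  r1 <- simulate_records(v1[1:10, ], seed = 8, coarse_fraction = 0.1,
                         synonym_fraction = 0.1)
  r2 <- simulate_records(v1[1:10, ], seed = 8, coarse_fraction = 0.1,
                         synonym_fraction = 0.1)
  expect_identical(r1, r2)

  # byte-identical CSV output
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write.csv(r1, f1, row.names = FALSE); write.csv(r2, f2, row.names = FALSE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # the generator restores the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_volunteers(5, seed = 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("degenerate and infeasible archetype specs are handled", {
  arch <- default_archetypes()[1, ]
  arch$weight <- 1
  arch$mean_activity_ratio <- 1.5
  expect_error(simulate_volunteers(10, arch), "\\(0, 1\\]")

  # single-day archetype: activity ratio is forced to 1
  one_day <- default_archetypes()[1, ]
  one_day$weight <- 1
  one_day$mean_rad <- 1 / 730
  one_day$rel_sd_rad <- 0
  one_day$mean_activity_ratio <- 1
  vols <- simulate_volunteers(40, one_day, seed = 2)
  expect_true(all(vols$n_active_days == 1))
  expect_true(all(vols$linked_days == 1))
})

test_that("realized cohort means track the archetype targets", {
  vols <- simulate_volunteers(1000, seed = 10)
  eng <- engagement_table(volunteer_day_records(vols),
                          study_window("2010-01-01",
                                       as.Date("2010-01-01") + 729))
  eng$archetype <- vols$archetype[match(eng$recorder_id, vols$recorder_id)]
  arch <- default_archetypes()
  for (a in c("dabbler", "steady")) {
    sub <- eng[eng$archetype == a, ]
    tgt <- arch[arch$name == a, ]
    expect_lt(abs(mean(sub$activity_ratio) - tgt$mean_activity_ratio) /
                tgt$mean_activity_ratio, 0.1)
    expect_lt(abs(mean(sub$relative_activity_duration) - tgt$mean_rad) /
                tgt$mean_rad, 0.1)
    expect_lt(abs(mean(sub$n_observations) - tgt$mean_n_obs) /
                tgt$mean_n_obs, 0.1)
  }
  # mixture shares roughly match the weights
  shares <- table(vols$archetype) / nrow(vols)
  expect_lt(abs(shares[["dabbler"]] - 0.67), 0.05)
})

test_that("records respect volunteers' planted day structure", {
  vols <- simulate_volunteers(20, seed = 5)
  recs <- simulate_records(vols, seed = 6)
  expect_equal(nrow(recs), sum(vols$n_observations))
  # per-volunteer record counts match
  cnt <- table(recs$recordedBy)
  expect_equal(unname(c(cnt[vols$recorder_id])), vols$n_observations)
  expect_error(simulate_records(vols, species_pool = default_species_pool()[0, ]),
               "empty species pool")
})

test_that("hotspot weighting concentrates records as expected", {
  land <- default_landscape(n_cols = 10, n_rows = 10,
                            hotspot_cells = "TQ0505",
                            hotspot_multiplier = 10)
  # one volunteer with 10,000 records on one day keeps this cheap
  vols <- tibble::tibble(recorder_id = "v", archetype = "x",
                         n_active_days = 1L, linked_days = 1L,
                         start_day = 1L, n_observations = 10000L,
                         active_days = list(1L), obs_per_day = list(10000L))
  recs <- simulate_records(vols, landscape = land, seed = 12)
  share <- mean(recs$gridReference == "TQ0505")
  p <- 10 / 109
  expect_lt(abs(share - p), 3 * sqrt(p * (1 - p) / 10000))

  # uniform cells follow the categorical distribution (chi-square GOF)
  flat <- default_landscape(n_cols = 5, n_rows = 5,
                            hotspot_cells = "TQ0000",
                            hotspot_multiplier = 1)
  recs2 <- simulate_records(vols, landscape = flat, seed = 13)
  obs <- table(factor(recs2$gridReference, levels = flat$monad))
  expect_gt(chisq.test(obs)$p.value, 0.01)
})

test_that("coarse references and name synonyms exercise the ingest filters", {
  vols <- simulate_volunteers(30, seed = 21)
  recs <- simulate_records(vols, seed = 22, coarse_fraction = 0.2,
                           synonym_fraction = 0.2)
  res <- clean_records(recs)
  expect_gt(res$audit$n_rejected_precision, 0)
  expect_equal(res$audit$n_rejected_precision +
                 res$audit$n_output, res$audit$n_input)
  expect_true(any(grepl("\\.$", recs$recordedBy)))
  # coarse refs really are 10-km references of the right square
  coarse <- recs$gridReference[nchar(recs$gridReference) == 4]
  expect_true(all(parse_gridref(coarse)$precision_m == 10000))
})

test_that("trait-linked recording rates favour easy, abundant species", {
  pool <- default_species_pool(trait_slopes =
                                 c(identification_difficulty = -0.8))
  vols <- simulate_volunteers(150, seed = 41)
  recs <- simulate_records(vols, species_pool = pool, seed = 42)
  counts <- as.data.frame(table(recs$scientificName),
                          stringsAsFactors = FALSE)
  names(counts) <- c("scientific_name", "n_records")
  d <- merge(pool, counts, all.x = TRUE)
  d$n_records[is.na(d$n_records)] <- 0
  fit <- fit_trait_model(d, "identification_difficulty")
  expect_lt(fit$coefficients[2], 0)
  expect_lt(fit$p_value, 0.05)
})
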