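# Independent oracles used across tests. These deliberately take different
# routes from the package implementation: the OSGB oracle is a literal
# two-level lookup table rather than index arithmetic; the engagement oracle
# is a naive per-volunteer loop over sorted dates; the Spearman oracle is the
# textbook rank-difference formula.

# --- OSGB lookup-table oracle -------------------------------------------

# 500-km squares of the GB grid (literal)
oracle_first <- list(
  S = c(0, 0), T = c(500000, 0),
  N = c(0, 500000), O = c(500000, 500000),
  H = c(0, 1000000), J = c(500000, 1000000)
)

# 100-km squares within a 500-km square: 5x5, A top-left, I skipped (literal)
oracle_second <- list(
  A = c(0, 400000), B = c(100000, 400000), C = c(200000, 400000),
  D = c(300000, 400000), E = c(400000, 400000),
  F = c(0, 300000), G = c(100000, 300000), H = c(200000, 300000),
  J = c(300000, 300000), K = c(400000, 300000),
  L = c(0, 200000), M = c(100000, 200000), N = c(200000, 200000),
  O = c(300000, 200000), P = c(400000, 200000),
  Q = c(0, 100000), R = c(100000, 100000), S = c(200000, 100000),
  T = c(300000, 100000), U = c(400000, 100000),
  V = c(0, 0), W = c(100000, 0), X = c(200000, 0),
  Y = c(300000, 0), Z = c(400000, 0)
)

# DINTY tetrad letters (literal): 2-km offsets within a 10-km square
oracle_dinty <- list(
  A = c(0, 0), B = c(0, 2000), C = c(0, 4000), D = c(0, 6000), E = c(0, 8000),
  F = c(2000, 0), G = c(2000, 2000), H = c(2000, 4000), I = c(2000, 6000),
  J = c(2000, 8000),
  K = c(4000, 0), L = c(4000, 2000), M = c(4000, 4000), N = c(4000, 6000),
  P = c(4000, 8000),
  Q = c(6000, 0), R = c(6000, 2000), S = c(6000, 4000), T = c(6000, 6000),
  U = c(6000, 8000),
  V = c(8000, 0), W = c(8000, 2000), X = c(8000, 4000), Y = c(8000, 6000),
  Z = c(8000, 8000)
)

oracle_parse <- function(ref) {
  l1 <- oracle_first[[substr(ref, 1, 1)]]
  l2 <- oracle_second[[substr(ref, 2, 2)]]
  digits <- substr(ref, 3, nchar(ref))
  half <- nchar(digits) / 2
  unit <- 10^(5 - half)
  de <- if (half > 0) as.numeric(substr(digits, 1, half)) else 0
  dn <- if (half > 0) as.numeric(substr(digits, half + 1, 2 * half)) else 0
  c(easting = l1[1] + l2[1] + de * unit,
    northing = l1[2] + l2[2] + dn * unit,
    precision_m = unit)
}

# random valid 1-km references drawn from the oracle's own tables
oracle_random_monads <- function(n) {
  paste0(sample(names(oracle_first), n, replace = TRUE),
         sample(names(oracle_second), n, replace = TRUE),
         sprintf("%02d", sample(0:99, n, replace = TRUE)),
         sprintf("%02d", sample(0:99, n, replace = TRUE)))
}

# --- naive engagement oracle --------------------------------------------

oracle_engagement <- function(records, window) {
  ids <- sort(unique(records$recorder_id))
  rows <- lapply(ids, function(id) {
    dts <- sort(records$date[records$recorder_id == id])
    days <- unique(dts)
    linked <- as.numeric(max(days) - min(days)) + 1
    g <- if (length(days) >= 2) mean(as.numeric(diff(days))) else NA_real_
    data.frame(recorder_id = id, n_observations = length(dts),
               n_active_days = length(days), linked_days = linked,
               activity_ratio = length(days) / linked,
               relative_activity_duration = length(days) / window$length_days,
               mean_gap = g)
  })
  df <- do.call(rbind, rows)
  G <- mean(df$mean_gap, na.rm = TRUE)
  df$variation_in_periodicity <- ifelse(is.na(df$mean_gap), 0,
                                        df$mean_gap / G)
  df
}

# random small cohort of (recorder_id, date) records
random_cohort <- function(n_volunteers, window_days = 200,
                          start = as.Date("2010-01-01")) {
  rows <- lapply(seq_len(n_volunteers), function(i) {
    n_days <- sample(1:12, 1)
    days <- sort(sample(0:(window_days - 1), n_days))
    reps <- sample(1:3, n_days, replace = TRUE)
    data.frame(recorder_id = sprintf("v%03d", i),
               date = start + rep(days, reps))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

# --- textbook Spearman (no ties) ----------------------------------------

oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# --- adjusted Rand index (via mclust) -----------------------------------

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
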