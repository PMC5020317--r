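#' Quasipoisson trait screen for species record counts
#'
#' Opportunistic record counts per species are strongly overdispersed, so
#' trait effects are screened with log-link Poisson-family regressions whose
#' dispersion is estimated from the Pearson statistic and whose significance
#' comes from an F-test against the intercept-only model — the standard
#' quasipoisson workflow. Each trait is tested singly: traits differ in
#' their exclusion sets (e.g. non-natives lack a conservation status), so a
#' joint model would silently drop species.
#'
#' @name traits
NULL

#' Fit a single-trait quasipoisson model
#'
#' @param rows Data frame with a nonnegative integer `n_records` column and
#'   one column per trait (factor/character for categorical traits, numeric
#'   otherwise; numeric traits should already be on the scale to model,
#'   e.g. log body length).
#' @param trait Name of the trait column to test.
#' @return A list of class `trait_model`: `trait`, `n_species` (rows fitted
#'   after dropping missing trait values), `n_excluded`, `coefficients`
#'   (log-rate effects, intercept included), `dispersion` (Pearson
#'   chi-square / residual df), `f_statistic`, `df` (numerator, denominator),
#'   `p_value`, `direction` (sign of the first non-intercept coefficient).
#'
#' @details The F statistic is the deviance drop per numerator df divided by
#'   the Pearson dispersion of the trait model, referred to
#'   F(df_trait, df_residual). With dispersion fixed at 1 this reduces to
#'   the Poisson likelihood-ratio scale; estimating it from the data is what
#'   makes the test robust to overdispersion.
#' @export
fit_trait_model <- function(rows, trait) {
  stopifnot("n_records" %in% names(rows), trait %in% names(rows))
  v <- rows[[trait]]
  keep <- !is.na(v) & !is.na(rows$n_records)
  d <- rows[keep, c("n_records", trait)]
  if (is.character(d[[trait]])) d[[trait]] <- factor(d[[trait]])
  if (is.factor(d[[trait]])) d[[trait]] <- droplevels(d[[trait]])
  if (nrow(d) < 3) stop("fewer than 3 species after exclusions for trait '",
                        trait, "'", call. = FALSE)
  degenerate <- if (is.factor(d[[trait]])) {
    nlevels(d[[trait]]) < 2
  } else {
    stats::sd(d[[trait]]) == 0
  }
  if (degenerate) {
    stop("trait '", trait, "' has a single observed level/value",
         call. = FALSE)
  }
  fml <- stats::as.formula(paste("n_records ~", sprintf("`%s`", trait)))
  m1 <- stats::glm(fml, data = d, family = stats::quasipoisson())
  m0 <- stats::glm(n_records ~ 1, data = d, family = stats::quasipoisson())
  if (!m1$converged) {
    stop("quasipoisson fit for trait '", trait, "' did not converge ",
         "(possible separation or degenerate counts)", call. = FALSE)
  }
  disp <- sum(stats::residuals(m1, type = "pearson")^2) / m1$df.residual
  df1 <- m0$df.residual - m1$df.residual
  df2 <- m1$df.residual
  f <- ((m0$deviance - m1$deviance) / df1) / disp
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  cf <- stats::coef(m1)
  structure(list(
    trait = trait,
    n_species = nrow(d),
    n_excluded = sum(!keep),
    coefficients = cf,
    dispersion = disp,
    f_statistic = f,
    df = c(df1, df2),
    p_value = p,
    direction = if (length(cf) > 1) sign(cf[2]) else NA_real_
  ), class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf(
    "Quasipoisson trait screen: %s\n  n = %d (excluded %d), dispersion = %.2f\n  F(%d, %d) = %.2f, p = %.3g\n",
    x$trait, x$n_species, x$n_excluded, x$dispersion,
    x$df[1], x$df[2], x$f_statistic, x$p_value))
  invisible(x)
}

#' Bonferroni-adjusted alpha level
#'
#' Family alpha divided by the number of tests, plus the 3-decimal
#' (round-half-even) display form conventionally printed alongside it:
#' 8 tests at 0.05 give 0.00625, displayed "0.006"; 4 tests give 0.0125,
#' displayed "0.012".
#'
#' @param n_tests Number of tests in the family (>= 1).
#' @param family_alpha Family-wise level in (0, 1), default 0.05.
#' @return A list: `alpha` (exact) and `display` (character, 3 decimals).
#' @export
bonferroni_alpha <- function(n_tests, family_alpha = 0.05) {
  if (!is.numeric(n_tests) || n_tests < 1 || n_tests != round(n_tests)) {
    stop("n_tests must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(family_alpha) || family_alpha <= 0 || family_alpha >= 1) {
    stop("family_alpha must be in (0, 1)", call. = FALSE)
  }
  a <- family_alpha / n_tests
  # decimal round-half-even at 3 places: the quotient of two short decimals
  # often sits exactly on a half (0.05/4 = 0.0125), where binary doubles
  # land a hair above it and round() would misprint the conventional value
  scaled <- a * 1000
  lo <- floor(scaled)
  frac <- scaled - lo
  d3 <- if (abs(frac - 0.5) < 1e-9) {
    if (lo %% 2 == 0) lo else lo + 1
  } else {
    round(scaled)
  }
  list(alpha = a, display = sprintf("%.3f", d3 / 1000))
}

#' Screen a set of traits against record counts
#'
#' Fits one single-trait quasipoisson model per trait and annotates each
#' with significance at the raw alpha and at the Bonferroni-adjusted alpha.
#' The adjustment is reported, not enforced: exploratory screens are
#' conventionally read at both levels.
#'
#' @param rows Species-count table (see [fit_trait_model()]).
#' @param traits Character vector of trait column names (may be empty).
#' @param family_alpha Family-wise level, default 0.05.
#' @return A tibble: `trait`, `n_species`, `n_excluded`, `coefficient`
#'   (first non-intercept effect), `dispersion`, `f_statistic`, `df1`,
#'   `df2`, `p_value`, `sig_raw`, `sig_bonferroni`, `adjusted_alpha`.
#' @export
trait_screen <- function(rows, traits, family_alpha = 0.05) {
  if (length(traits) == 0) {
    return(tibble::tibble(trait = character(), n_species = integer(),
                          n_excluded = integer(), coefficient = numeric(),
                          dispersion = numeric(), f_statistic = numeric(),
                          df1 = numeric(), df2 = numeric(),
                          p_value = numeric(), sig_raw = logical(),
                          sig_bonferroni = logical(),
                          adjusted_alpha = numeric()))
  }
  adj <- bonferroni_alpha(length(traits), family_alpha)
  fits <- lapply(traits, function(tr) fit_trait_model(rows, tr))
  tibble::tibble(
    trait = traits,
    n_species = vapply(fits, `[[`, integer(1), "n_species"),
    n_excluded = vapply(fits, `[[`, integer(1), "n_excluded"),
    coefficient = vapply(fits, function(f) {
      if (length(f$coefficients) > 1) unname(f$coefficients[2]) else NA_real_
    }, numeric(1)),
    dispersion = vapply(fits, `[[`, numeric(1), "dispersion"),
    f_statistic = vapply(fits, `[[`, numeric(1), "f_statistic"),
    df1 = vapply(fits, function(f) f$df[1], numeric(1)),
    df2 = vapply(fits, function(f) f$df[2], numeric(1)),
    p_value = vapply(fits, `[[`, numeric(1), "p_value"),
    sig_raw = vapply(fits, function(f) f$p_value < family_alpha, logical(1)),
    sig_bonferroni = vapply(fits, function(f) f$p_value < adj$alpha,
                            logical(1)),
    adjusted_alpha = adj$alpha
  )
}
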