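#' Component biomass from ln-linear allometric models
#'
#' Evaluates the fixed ginkgo-plantation allometric models
#' `ln W = a + b ln DBH (+ c ln H)` for the six biomass components:
#' leaf (LB), branch (BB), trunk (TB), above-ground (AGB), root (RB) and
#' whole-plant (WPB). Units: DBH in cm, H in m, W in kg. Coefficients are
#' constants of the method (fitted on destructively sampled plantation
#' trees), not refit here.
#'
#' @param dbh diameter at breast height (cm), vectorized.
#' @param h tree height (m), vectorized (recycled against `dbh`).
#' @return data.frame with columns `LB, BB, TB, AGB, RB, WPB` (kg).
#' @examples
#' biomass(13.233, 7.757)
#' @export
biomass <- function(dbh, h) {
  if (any(dbh <= 0) || any(h <= 0)) stop("dbh and h must be positive")
  n <- max(length(dbh), length(h))
  dbh <- rep_len(dbh, n); h <- rep_len(h, n)
  ld <- log(dbh); lh <- log(h)
  data.frame(
    LB  = exp(-5.21 + 2.37 * ld),
    BB  = exp(-6.95 + 3.36 * ld),
    TB  = exp(-1.61 + 2.27 * ld - 0.36 * lh),
    AGB = exp(-2.56 + 2.40 * ld),
    RB  = exp(-2.64 + 2.63 * ld - 0.64 * lh),
    WPB = exp(-1.01 + 2.61 * ld - 0.73 * lh)
  )
}

#' The allometric model table
#'
#' Coefficients of the six component models as a data.frame
#' (`component, intercept, b_ln_dbh, b_ln_h`), for inspection and export.
#' @export
biomass_models <- function() {
  data.frame(
    component = c("LB", "BB", "TB", "AGB", "RB", "WPB"),
    intercept = c(-5.21, -6.95, -1.61, -2.56, -2.64, -1.01),
    b_ln_dbh  = c(2.37, 3.36, 2.27, 2.40, 2.63, 2.61),
    b_ln_h    = c(0, 0, -0.36, 0, -0.64, -0.73)
  )
}

#' Descriptive statistics of a trait table
#'
#' Per-trait mean, sample standard deviation (n-1), coefficient of variation
#' (CV% = SD/mean x 100), maximum and minimum. A zero mean leaves CV as `NaN`
#' with a warning (undefined).
#'
#' @param traits data.frame of numeric trait columns (one row per tree).
#' @return data.frame: `trait, mean, sd, cv, max, min`.
#' @export
descriptive_stats <- function(traits) {
  num <- vapply(traits, is.numeric, logical(1))
  traits <- traits[num]
  if (nrow(traits) < 2L) stop("need at least 2 trees for descriptive statistics")
  out <- data.frame(
    trait = names(traits),
    mean = vapply(traits, mean, 0),
    sd = vapply(traits, stats::sd, 0),
    max = vapply(traits, max, 0),
    min = vapply(traits, min, 0),
    row.names = NULL
  )
  out$cv <- ifelse(out$mean == 0, NaN, out$sd / out$mean * 100)
  if (any(out$mean == 0)) warning("CV undefined for zero-mean trait(s)")
  out[, c("trait", "mean", "sd", "cv", "max", "min")]
}

#' Accuracy metrics of estimated vs measured characteristics
#'
#' Computes the evaluation triple used for LiDAR-vs-field comparison:
#' `adj_r2` = 1 - SSres/SStot (as conventionally printed for this workflow;
#' despite the name it carries no degrees-of-freedom adjustment, hence the
#' explicit `adj_r2_paper` alias in the output), RMSE, and relative RMSE
#' (% of the measured mean).
#'
#' @param measured,estimated equal-length numeric vectors (n >= 2).
#' @return list: `adj_r2`, `adj_r2_paper` (identical), `rmse`, `rrmse`.
#' @export
fit_metrics <- function(measured, estimated) {
  stopifnot(length(measured) == length(estimated), length(measured) >= 2)
  ss_tot <- sum((measured - mean(measured))^2)
  ss_res <- sum((measured - estimated)^2)
  r2 <- if (ss_tot == 0) {
    warning("zero variance in measured values: adj_r2 undefined")
    NaN
  } else 1 - ss_res / ss_tot
  rmse <- sqrt(mean((measured - estimated)^2))
  list(adj_r2 = r2, adj_r2_paper = r2, rmse = rmse,
       rrmse = rmse / mean(measured) * 100)
}

#' Spearman correlation matrix of a trait table
#'
#' Rank-based correlation with average ranks for ties; symmetric with a unit
#' diagonal. Constant columns yield `NA` correlations with a warning.
#'
#' @param traits data.frame of numeric trait columns, >= 3 rows.
#' @return correlation matrix (traits x traits).
#' @export
spearman_matrix <- function(traits) {
  num <- vapply(traits, is.numeric, logical(1))
  traits <- traits[num]
  if (nrow(traits) < 3L) stop("need at least 3 trees for a correlation matrix")
  const <- vapply(traits, function(x) stats::sd(x) == 0, logical(1))
  if (any(const)) warning("constant trait(s): correlations undefined for ",
                          paste(names(traits)[const], collapse = ", "))
  suppressWarnings(stats::cor(traits, method = "spearman"))
}
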