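#' Standardize a trait table within genetic groups
#'
#' Within each group, each trait is z-scored: `(x - mean) / SD` (sample SD by
#' default). Zero-SD traits are dropped for that group with a warning; groups
#' of fewer than 2 trees pass through unscaled, flagged in the result.
#'
#' @param traits data.frame of numeric traits, one row per tree.
#' @param groups group label per row.
#' @param sd_type `"sample"` (n-1, default) or `"population"` (n).
#' @return named list over groups; each element a list with `z` (data.frame),
#'   `dropped` (character), `scaled` (logical).
#' @export
standardize_traits <- function(traits, groups, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(nrow(traits) == length(groups))
  num <- vapply(traits, is.numeric, logical(1))
  traits <- traits[num]
  out <- list()
  for (grp in unique(groups)) {
    sub <- traits[groups == grp, , drop = FALSE]
    if (nrow(sub) < 2L) {
      out[[as.character(grp)]] <- list(z = sub, dropped = character(0), scaled = FALSE)
      next
    }
    sds <- vapply(sub, function(x) {
      s <- stats::sd(x)
      if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
      s
    }, 0)
    drop <- names(sds)[sds == 0]
    if (length(drop)) warning("group ", grp, ": constant trait(s) dropped: ",
                              paste(drop, collapse = ", "))
    keep <- setdiff(names(sub), drop)
    z <- as.data.frame(mapply(function(x, s) (x - mean(x)) / s,
                              sub[keep], sds[keep], SIMPLIFY = FALSE))
    rownames(z) <- rownames(sub)
    out[[as.character(grp)]] <- list(z = z, dropped = drop, scaled = TRUE)
  }
  out
}

#' Principal component analysis of a standardized trait table
#'
#' Eigendecomposition of the correlation matrix of the traits. Loadings are
#' eigenvectors scaled by sqrt(eigenvalue) (so each entry is the correlation
#' between trait and component, bounded by 1); the contribution rate of
#' component j is `100 * lambda_j / n_traits` and contributions sum to 100%.
#' Each eigenvector's sign is fixed so its largest-magnitude loading is
#' positive.
#'
#' @param z data.frame or matrix of (standardized) traits, >= 2 rows.
#' @return a `pca_fit`: list with `eigenvalues`, `vectors` (trait x PC
#'   eigenvectors), `loadings`, `contribution` (%), `ccr` (cumulative %),
#'   `n_traits`.
#' @export
pca_fit <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 2L) stop("need at least 2 rows for PCA")
  R <- suppressWarnings(stats::cor(z))
  R[is.na(R)] <- 0; diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  V <- ev$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(z)
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  loadings <- sweep(V, 2, sqrt(lam), "*")
  contribution <- 100 * lam / ncol(z)
  structure(list(eigenvalues = lam, vectors = V, loadings = loadings,
                 contribution = contribution, ccr = cumsum(contribution),
                 n_traits = ncol(z)),
            class = "pca_fit")
}

#' @export
print.pca_fit <- function(x, ...) {
  cat("pca_fit on", x$n_traits, "traits\n")
  show <- min(5L, length(x$eigenvalues))
  tab <- rbind(eigenvalue = x$eigenvalues[1:show],
               `contribution %` = x$contribution[1:show],
               `CCR %` = x$ccr[1:show])
  colnames(tab) <- paste0("PC", 1:show)
  print(round(tab, 3))
  invisible(x)
}

#' Number of components at a cumulative-contribution threshold
#'
#' The smallest m whose cumulative contribution rate reaches the threshold.
#'
#' @param fit a [pca_fit()] — or a numeric vector of contribution rates (%).
#' @param ccr_threshold cumulative contribution threshold in percent.
#' @return integer m.
#' @export
select_components <- function(fit, ccr_threshold = 85) {
  contribution <- if (inherits(fit, "pca_fit")) fit$contribution else fit
  ccr <- cumsum(contribution)
  m <- which(ccr >= ccr_threshold - 1e-9)[1]
  if (is.na(m)) m <- length(contribution)
  as.integer(m)
}

#' Per-tree principal component scores
#'
#' `F_n` is the linear combination of the (standardized) trait values with
#' the component's coefficients. The coefficient convention is configurable
#' because published score scales differ between software: `"eigenvector"`
#' (unit-norm coefficients, default) or `"loading"` (eigenvector x
#' sqrt(lambda)). The convention used is recorded in the result's
#' `"convention"` attribute.
#'
#' @param z standardized trait table (rows = trees).
#' @param fit a [pca_fit()] of the same traits.
#' @param m number of components to score.
#' @param coef coefficient convention.
#' @return matrix trees x m of scores `F1..Fm`, with attribute `convention`.
#' @export
pc_scores <- function(z, fit, m, coef = c("eigenvector", "loading")) {
  coef <- match.arg(coef)
  z <- as.matrix(z)
  stopifnot(m >= 1, m <= ncol(fit$vectors))
  if (anyNA(z)) stop("missing trait values: score the complete rows only")
  W <- if (coef == "eigenvector") fit$vectors[, seq_len(m), drop = FALSE]
       else fit$loadings[, seq_len(m), drop = FALSE]
  sc <- z %*% W
  colnames(sc) <- paste0("F", seq_len(m))
  attr(sc, "convention") <- coef
  sc
}

#' Contribution-weighted composite score
#'
#' `F = sum_n w_n F_n` with the retained components' contribution rates as
#' weights (fractions, e.g. 0.958 for 95.8%). Accepts a vector (one tree) or
#' a matrix (trees x components).
#'
#' @param scores numeric vector or matrix of PC scores.
#' @param weights numeric vector of weights, same length as the number of
#'   components.
#' @return numeric composite score(s).
#' @export
composite_score <- function(scores, weights) {
  if (is.matrix(scores)) {
    if (ncol(scores) != length(weights)) stop("length mismatch: scores vs weights")
    return(as.vector(scores %*% weights))
  }
  if (length(scores) != length(weights)) stop("length mismatch: scores vs weights")
  sum(scores * weights)
}

#' Rank trees within groups and select the top fraction
#'
#' Ranks descending by composite score within each genetic group and selects
#' the top `max(1, ceiling(inclusion_rate * group size))` trees (at least one
#' tree per group, however small the group — distant groups deserve a
#' representative). Ties are broken by tree id (stable).
#'
#' @param scores named numeric vector of composite scores (names = tree ids).
#' @param groups group label per tree (same order as `scores`).
#' @param inclusion_rate fraction selected per group.
#' @return data.frame: `id, group, score, rank, selected`, ordered by group
#'   then rank.
#' @export
rank_and_select <- function(scores, groups, inclusion_rate = 0.10) {
  stopifnot(length(scores) == length(groups), inclusion_rate > 0)
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  out <- list()
  for (grp in unique(groups)) {
    sel <- groups == grp
    if (!any(sel)) { warning("empty group ", grp, " skipped"); next }
    sc <- scores[sel]; gid <- ids[sel]
    o <- order(-sc, gid)
    n_sel <- max(1L, ceiling(inclusion_rate * sum(sel)))
    out[[as.character(grp)]] <- data.frame(
      id = gid[o], group = grp, score = sc[o],
      rank = seq_along(o), selected = seq_along(o) <= n_sel,
      row.names = NULL)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Evaluate and select within genetic groups
#'
#' Convenience wrapper running the whole evaluation for a trait table:
#' standardize per group, PCA per group, retain components at the CCR
#' threshold, score, weight by contribution rates, rank and select.
#'
#' @inheritParams standardize_traits
#' @inheritParams rank_and_select
#' @param ccr_threshold cumulative contribution threshold (%).
#' @param ids tree identifiers (default row names of `traits`).
#' @return list: `selection` (the [rank_and_select()] table), `pca` (list of
#'   per-group [pca_fit()]s), `m` (components retained per group), `scores`
#'   (per-group score matrices).
#' @export
evaluate_groups <- function(traits, groups, ids = NULL, ccr_threshold = 85,
                            inclusion_rate = 0.10) {
  if (is.null(ids)) ids <- rownames(traits)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(traits)))
  std <- standardize_traits(traits, groups)
  all_scores <- numeric(0); all_groups <- character(0)
  pcas <- list(); ms <- list(); smats <- list()
  for (grp in names(std)) {
    sel <- as.character(groups) == grp
    z <- std[[grp]]$z
    if (!std[[grp]]$scaled || nrow(z) < 2L) {
      # degenerate group: every tree scores 0, selection rule still applies
      sc <- stats::setNames(rep(0, sum(sel)), ids[sel])
    } else {
      fit <- pca_fit(z)
      m <- select_components(fit, ccr_threshold)
      fs <- pc_scores(z, fit, m)
      w <- fit$contribution[seq_len(m)] / 100
      sc <- stats::setNames(composite_score(fs, w), ids[sel])
      pcas[[grp]] <- fit; ms[[grp]] <- m; smats[[grp]] <- fs
    }
    all_scores <- c(all_scores, sc)
    all_groups <- c(all_groups, rep(grp, sum(sel)))
  }
  list(selection = rank_and_select(all_scores, all_groups, inclusion_rate),
       pca = pcas, m = ms, scores = smats)
}
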