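#' Per-locus allele frequencies
#'
#' Counts allele copies over non-missing genotypes; frequency = count /
#' (2 x non-missing individuals). Fully missing loci are dropped with a
#' warning.
#'
#' @param g a [genotype_matrix()].
#' @return named list over loci of named frequency vectors (each sums to 1).
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  out <- list()
  for (j in seq_along(g$loci)) {
    al <- c(g$a1[, j], g$a2[, j])
    al <- al[!is.na(al)]
    if (!length(al)) {
      warning("locus ", g$loci[j], " fully missing: excluded")
      next
    }
    tab <- table(al)
    out[[g$loci[j]]] <- stats::setNames(as.vector(tab) / sum(tab), names(tab))
  }
  out
}

#' SSR diversity statistics per locus
#'
#' For each locus: observed allele count (Na), effective allele count
#' (Ne = 1/sum p^2), observed heterozygosity (Ho, fraction of heterozygous
#' non-missing individuals), expected heterozygosity (He = 1 - sum p^2;
#' `unbiased = TRUE` applies the n/(n-1) small-sample correction), Shannon's
#' information index (I = -sum p ln p), polymorphism information content
#' (PIC = 1 - sum p^2 - sum_{i<j} 2 p_i^2 p_j^2), and a Hardy-Weinberg
#' chi-square test on genotype classes (df = G - Na with G = Na(Na+1)/2;
#' skipped for monomorphic loci). Across-locus means are appended.
#'
#' @param g a [genotype_matrix()].
#' @param unbiased apply the n/(n-1) correction to He.
#' @return list with `per_locus` (data.frame) and `means` (named vector of
#'   across-locus means of Na, Ne, Ho, He, I, PIC).
#' @export
diversity_stats <- function(g, unbiased = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  freqs <- allele_frequencies(g)
  rows <- list()
  for (loc in names(freqs)) {
    j <- match(loc, g$loci)
    p <- freqs[[loc]]
    na <- length(p)
    ne <- 1 / sum(p^2)
    ok <- !is.na(g$a1[, j])
    n_ind <- sum(ok)
    ho <- mean(g$a1[ok, j] != g$a2[ok, j])
    he <- 1 - sum(p^2)
    if (unbiased) he <- he * n_ind / max(n_ind - 1, 1)
    shannon <- -sum(p * log(p))
    pic <- 1 - sum(p^2) - .pic_pair_term(p)
    hw <- .hwe_chisq(g$a1[ok, j], g$a2[ok, j], p)
    rows[[loc]] <- data.frame(locus = loc, n = n_ind, Na = na, Ne = ne,
                              Ho = ho, He = he, I = shannon, PIC = pic,
                              hwe_chisq = hw$chisq, hwe_df = hw$df, hwe_p = hw$p)
  }
  per_locus <- do.call(rbind, rows)
  rownames(per_locus) <- NULL
  means <- colMeans(per_locus[, c("Na", "Ne", "Ho", "He", "I", "PIC")])
  list(per_locus = per_locus, means = means)
}

.pic_pair_term <- function(p) {
  if (length(p) < 2L) return(0)
  s2 <- sum(p^2); s4 <- sum(p^4)
  (s2^2 - s4)  # = sum_{i<j} 2 p_i^2 p_j^2
}

.hwe_chisq <- function(a1, a2, p) {
  na <- length(p)
  if (na < 2L) return(list(chisq = NA_real_, df = 0L, p = NA_real_))
  alleles <- names(p)
  n <- length(a1)
  # observed genotype counts over unordered pairs
  g1 <- pmin(match(a1, alleles), match(a2, alleles))
  g2 <- pmax(match(a1, alleles), match(a2, alleles))
  obs_tab <- table(factor(paste(g1, g2), levels = {
    ij <- which(upper.tri(matrix(0, na, na), diag = TRUE), arr.ind = TRUE)
    paste(ij[, 1], ij[, 2])
  }))
  ij <- which(upper.tri(matrix(0, na, na), diag = TRUE), arr.ind = TRUE)
  exp_p <- ifelse(ij[, 1] == ij[, 2], p[ij[, 1]]^2, 2 * p[ij[, 1]] * p[ij[, 2]])
  expected <- n * exp_p
  chisq <- sum((as.vector(obs_tab) - expected)^2 / pmax(expected, .Machine$double.eps))
  df <- length(expected) - na
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Nei's standard genetic distance between individuals
#'
#' Each individual is represented by per-locus allele-frequency vectors
#' (1 for a homozygous allele, 0.5/0.5 for a heterozygote). For a pair,
#' `D = -ln( sum_loci sum_a p_a q_a / sqrt(sum_loci sum p^2 * sum_loci sum q^2) )`.
#' Pairs sharing no alleles anywhere get the capped maximum (flagged).
#' The alternative `method = "shared_allele"` returns
#' `1 - (proportion of shared alleles)` averaged over loci.
#'
#' @param g a [genotype_matrix()].
#' @param method `"nei"` (default) or `"shared_allele"`.
#' @param max_d cap for infinite Nei distances (no shared alleles).
#' @return symmetric distance matrix (individuals x individuals).
#' @export
nei_distance <- function(g, method = c("nei", "shared_allele"), max_d = 10) {
  stopifnot(inherits(g, "genotype_matrix"))
  method <- match.arg(method)
  n <- length(g$ids); L <- length(g$loci)
  if (n < 2L) stop("need at least 2 individuals")
  if (method == "shared_allele") return(.shared_allele_dist(g))
  # per-individual stacked frequency vectors, one block per locus
  blocks <- list()
  for (j in seq_len(L)) {
    alleles <- sort(unique(stats::na.omit(c(g$a1[, j], g$a2[, j]))))
    if (!length(alleles)) next
    m <- matrix(0, n, length(alleles))
    i1 <- match(g$a1[, j], alleles); i2 <- match(g$a2[, j], alleles)
    ok <- !is.na(i1)
    m[cbind(seq_len(n), i1)[ok, , drop = FALSE]] <-
      m[cbind(seq_len(n), i1)[ok, , drop = FALSE]] + 0.5
    m[cbind(seq_len(n), i2)[ok, , drop = FALSE]] <-
      m[cbind(seq_len(n), i2)[ok, , drop = FALSE]] + 0.5
    blocks[[length(blocks) + 1L]] <- m
  }
  Fm <- do.call(cbind, blocks)
  cross <- Fm %*% t(Fm)            # sum_loci sum_a p_a q_a for every pair
  selfs <- diag(cross)             # sum_loci sum_a p_a^2
  I <- cross / sqrt(outer(selfs, selfs))
  D <- -log(pmax(I, 0))
  if (any(is.infinite(D))) {
    warning("pair(s) sharing no alleles: distance capped at ", max_d)
    D[is.infinite(D)] <- max_d
  }
  D <- pmin(D, max_d)
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(g$ids, g$ids)
  D
}

.shared_allele_dist <- function(g) {
  n <- length(g$ids)
  D <- matrix(0, n, n, dimnames = list(g$ids, g$ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sh <- 0; tot <- 0
    for (l in seq_along(g$loci)) {
      a <- c(g$a1[i, l], g$a2[i, l]); b <- c(g$a1[j, l], g$a2[j, l])
      if (anyNA(a) || anyNA(b)) next
      # shared-allele count for unordered pairs (0..2)
      s <- sum(pmin(table(factor(a, unique(c(a, b)))), table(factor(b, unique(c(a, b))))))
      sh <- sh + s / 2; tot <- tot + 1
    }
    D[i, j] <- D[j, i] <- if (tot == 0) NA_real_ else 1 - sh / tot
  }
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \pkg{ape}). Negative branch lengths
#' are clamped to zero and the clamped amount added to the sister branch of
#' the same cherry, preserving pairwise path lengths where possible. Two taxa
#' yield a single split edge (d/2 each side).
#'
#' @param d symmetric non-negative distance matrix with at least 2 taxa.
#' @return list: `tree` (an \pkg{ape} `phylo`) and `newick` (string).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (anyNA(d)) stop("NaN/NA in the distance matrix")
  stopifnot(nrow(d) >= 2, isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
  if (nrow(d) == 2L) {
    lab <- rownames(d); if (is.null(lab)) lab <- c("t1", "t2")
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);", lab[1], d[1, 2] / 2,
                                        lab[2], d[1, 2] / 2))
    return(list(tree = tr, newick = ape::write.tree(tr)))
  }
  tr <- ape::nj(stats::as.dist(d))
  tr <- .clamp_negative_edges(tr)
  list(tree = tr, newick = ape::write.tree(tr))
}

# clamp negative edge lengths to 0, compensating on the sister edge sharing
# the same parent node so root-to-tip distances are preserved on the cherry
.clamp_negative_edges <- function(tr) {
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    take <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs)) tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + take
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
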