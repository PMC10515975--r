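# Bayesian admixture model for co-dominant markers, fitted by a single-chain
# Gibbs sampler. The data model: each allele copy of individual i draws its
# ancestral population k from the individual's ancestry proportions Q[i,],
# then the allele from that population's locus frequencies P[[l]][k,].
# Conditionals are conjugate throughout (categorical ancestry given (Q,P);
# Dirichlet updates for P with prior alpha=1 and for Q with prior alpha=1/K).

# encode a genotype_matrix into integer allele indices per locus
.encode_geno <- function(g) {
  L <- length(g$loci); n <- length(g$ids)
  alleles <- vector("list", L)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    al <- sort(unique(stats::na.omit(c(g$a1[, j], g$a2[, j]))))
    alleles[[j]] <- al
    a1[, j] <- match(g$a1[, j], al)
    a2[, j] <- match(g$a2[, j], al)
  }
  list(a1 = a1, a2 = a2, alleles = alleles, n = n, L = L,
       A = lengths(alleles))
}

# vectorized categorical sampling from unnormalised probability columns (K x n)
.sample_cols <- function(pr) {
  K <- nrow(pr); n <- ncol(pr)
  if (K == 1L) return(rep(1L, n))
  cs <- pr
  for (k in 2:K) cs[k, ] <- cs[k, ] + cs[k - 1L, ]   # column cumsums, K is tiny
  u <- stats::runif(n) * cs[K, ]
  as.integer(colSums(cs < rep(u, each = K)) + 1L)
}

#' Fit the admixture model by Gibbs sampling
#'
#' Estimates ancestry proportions `Q` (individuals x K) and ancestral allele
#' frequencies `P` (per locus, K x alleles) for a fixed number of ancestral
#' populations `K`, and the run's mean data log-likelihood `L(K)` over the
#' kept iterations (the model-choice input for [delta_k()]). `K = 1` is
#' closed-form: `Q` is identically 1 and `L(1)` is the multinomial
#' log-likelihood at the observed allele frequencies. Deterministic given
#' `seed`.
#'
#' @param g a [genotype_matrix()].
#' @param K number of ancestral populations (>= 1).
#' @param iters total Gibbs sweeps.
#' @param burn_in sweeps discarded before averaging (must be < `iters`).
#' @param seed integer seed.
#' @return an `admixture_fit`: list with `K`, `Q` (posterior mean, rows sum
#'   to 1), `P` (list over loci of posterior-mean K x alleles matrices),
#'   `loglik` (mean over kept sweeps), `loglik_trace`, `seed`.
#' @export
admixture_fit <- function(g, K, iters = 2000L, burn_in = 500L, seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"), K >= 1)
  if (iters <= burn_in) stop("iters must exceed burn_in")
  enc <- .encode_geno(g)
  n <- enc$n; L <- enc$L; A <- enc$A

  if (K == 1L) {
    P <- vector("list", L); ll <- 0
    for (l in seq_len(L)) {
      a <- c(enc$a1[, l], enc$a2[, l]); a <- a[!is.na(a)]
      cnt <- tabulate(a, nbins = A[l])
      p <- cnt / sum(cnt)
      P[[l]] <- matrix(p, 1, A[l], dimnames = list(NULL, enc$alleles[[l]]))
      ll <- ll + sum(cnt * log(pmax(p, .Machine$double.xmin)))
    }
    names(P) <- g$loci
    return(structure(list(K = 1L, Q = matrix(1, n, 1, dimnames = list(g$ids, NULL)),
                          P = P, loglik = ll, loglik_trace = ll, seed = seed),
                     class = "admixture_fit"))
  }

  .with_seed(seed, {
    Q <- matrix(1 / K, n, K)
    P <- lapply(seq_len(L), function(l) .rdirichlet(K, rep(1, A[l])))
    Qsum <- matrix(0, n, K)
    Psum <- lapply(seq_len(L), function(l) matrix(0, K, A[l]))
    ll_trace <- numeric(iters)
    kept <- 0L
    obs <- lapply(seq_len(L), function(l) {
      list(c1 = which(!is.na(enc$a1[, l])), c2 = which(!is.na(enc$a2[, l])))
    })

    for (it in seq_len(iters)) {
      Nq <- matrix(0, n, K)      # ancestry copy counts per individual
      ll <- 0
      for (l in seq_len(L)) {
        Np <- matrix(0, K, A[l]) # allele counts per ancestry at this locus
        for (copy in 1:2) {
          ii <- if (copy == 1) obs[[l]]$c1 else obs[[l]]$c2
          if (!length(ii)) next
          a <- if (copy == 1) enc$a1[ii, l] else enc$a2[ii, l]
          pr <- t(Q[ii, , drop = FALSE]) * P[[l]][, a, drop = FALSE]  # K x m
          ll <- ll + sum(log(pmax(colSums(pr), .Machine$double.xmin)))
          z <- .sample_cols(pr)
          Nq_add <- tabulate((z - 1L) * n + ii, nbins = n * K)
          Nq <- Nq + matrix(Nq_add, n, K)
          Np_add <- tabulate((a - 1L) * K + z, nbins = K * A[l])
          Np <- Np + matrix(Np_add, K, A[l])
        }
        # P | ancestry counts ~ Dirichlet(1 + counts), row per ancestry
        gd <- matrix(stats::rgamma(K * A[l], shape = 1 + Np), K, A[l])
        gd[gd == 0] <- .Machine$double.xmin
        P[[l]] <- gd / rowSums(gd)
      }
      # Q | ancestry counts ~ Dirichlet(1/K + counts), row per individual
      gdraw <- matrix(stats::rgamma(n * K, shape = 1 / K + Nq), n, K)
      gdraw[gdraw == 0] <- .Machine$double.xmin
      Q <- gdraw / rowSums(gdraw)
      ll_trace[it] <- ll
      if (it > burn_in) {
        kept <- kept + 1L
        Qsum <- Qsum + Q
        for (l in seq_len(L)) Psum[[l]] <- Psum[[l]] + P[[l]]
      }
    }
    Qm <- Qsum / kept
    Pm <- lapply(seq_len(L), function(l) {
      m <- Psum[[l]] / kept
      colnames(m) <- enc$alleles[[l]]
      m
    })
    names(Pm) <- g$loci
    rownames(Qm) <- g$ids
    structure(list(K = as.integer(K), Q = Qm, P = Pm,
                   loglik = mean(ll_trace[(burn_in + 1L):iters]),
                   loglik_trace = ll_trace, seed = seed),
              class = "admixture_fit")
  })
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: K = %d, %d individuals, mean log-likelihood %.2f\n",
              x$K, nrow(x$Q), x$loglik))
  invisible(x)
}

#' Run the admixture model over a range of K
#'
#' Repeats [admixture_fit()] `n_runs` times per K (distinct derived seeds)
#' and collects the mean log-likelihoods, the input for [delta_k()].
#'
#' @inheritParams admixture_fit
#' @param K_range contiguous integer vector of K values.
#' @param n_runs independent runs per K.
#' @return list: `loglik` (matrix runs x K, colnames the K values) and
#'   `fits` (list over K of the run fits).
#' @export
admixture_scan <- function(g, K_range = 1:6, n_runs = 5L, iters = 2000L,
                           burn_in = 500L, seed = 1L) {
  stopifnot(all(diff(sort(K_range)) == 1L))
  Lm <- matrix(NA_real_, n_runs, length(K_range),
               dimnames = list(NULL, as.character(K_range)))
  fits <- vector("list", length(K_range))
  names(fits) <- as.character(K_range)
  for (ki in seq_along(K_range)) {
    fits[[ki]] <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      s <- (seed * 1000L + K_range[ki] * 100L + r) %% .Machine$integer.max
      f <- admixture_fit(g, K_range[ki], iters = iters, burn_in = burn_in, seed = s)
      Lm[r, ki] <- f$loglik
      fits[[ki]][[r]] <- f
    }
  }
  list(loglik = Lm, fits = fits)
}

#' Evanno delta-K from a log-likelihood table
#'
#' `dK(K) = mean_runs |L(K+1) - 2 L(K) + L(K-1)| / sd_runs L(K)`, defined on
#' the interior of a contiguous K range; the optimal K is the argmax. A zero
#' run-to-run sd leaves dK undefined (`NA`, flagged); a flat profile (all
#' dK = 0 or undefined) reports `optimal_k = NA` with `no_peak = TRUE`.
#'
#' @param L_table numeric matrix, runs x K values; colnames are the K values
#'   (contiguous, >= 3 of them); >= 2 runs.
#' @return list: `delta_k` (named vector over interior K), `optimal_k`,
#'   `no_peak`.
#' @export
delta_k <- function(L_table) {
  L_table <- as.matrix(L_table)
  Ks <- as.integer(colnames(L_table))
  stopifnot(length(Ks) >= 3, all(diff(Ks) == 1L), nrow(L_table) >= 2)
  inner <- 2:(length(Ks) - 1L)
  dk <- vapply(inner, function(j) {
    second <- abs(L_table[, j + 1L] - 2 * L_table[, j] + L_table[, j - 1L])
    s <- stats::sd(L_table[, j])
    if (s == 0) {
      warning("zero sd of L(K) at K = ", Ks[j], ": delta-K undefined")
      return(NA_real_)
    }
    mean(second) / s
  }, 0)
  names(dk) <- Ks[inner]
  if (all(is.na(dk)) || all(dk[!is.na(dk)] == 0)) {
    return(list(delta_k = dk, optimal_k = NA_integer_, no_peak = TRUE))
  }
  list(delta_k = dk, optimal_k = Ks[inner][which.max(dk)], no_peak = FALSE)
}

#' Align ancestry matrices up to column permutation
#'
#' Admixture components are only identified up to relabelling. Greedily
#' matches columns of `Q` to columns of `ref` by smallest total absolute
#' difference, so two fits (or a fit and the simulation truth) can be
#' compared directly.
#'
#' @param Q,ref ancestry matrices with the same dimensions.
#' @return `Q` with columns permuted to best match `ref`.
#' @export
align_q <- function(Q, ref) {
  stopifnot(all(dim(Q) == dim(ref)))
  K <- ncol(Q)
  cost <- sapply(seq_len(K), function(j)
    sapply(seq_len(K), function(k) sum(abs(Q[, j] - ref[, k]))))
  # cost[k, j]: assign Q column j to ref slot k; greedy minimum
  perm <- integer(K)
  used_j <- logical(K); used_k <- logical(K)
  for (step in seq_len(K)) {
    m <- which(cost == min(cost[!used_k, !used_j, drop = FALSE][is.finite(cost[!used_k, !used_j, drop = FALSE])])[1], arr.ind = TRUE)
    m <- m[!used_k[m[, 1]] & !used_j[m[, 2]], , drop = FALSE][1, ]
    perm[m[1]] <- m[2]
    used_k[m[1]] <- TRUE; used_j[m[2]] <- TRUE
    cost[m[1], ] <- Inf; cost[, m[2]] <- Inf
  }
  Q[, perm, drop = FALSE]
}

#' Export a population-structure bar chart
#'
#' Writes the classic stacked-bar ancestry figure (one bar per individual,
#' segment heights = ancestry proportions) to a PNG file.
#'
#' @param fit an `admixture_fit` (or any Q matrix).
#' @param path output PNG path.
#' @param width,height device size in pixels.
#' @return `path`, invisibly.
#' @export
plot_structure_bars <- function(fit, path, width = 900, height = 300) {
  Q <- if (inherits(fit, "admixture_fit")) fit$Q else as.matrix(fit)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::barplot(t(Q), col = grDevices::hcl.colors(ncol(Q), "Dark 3"),
                    border = NA, space = 0, las = 2,
                    ylab = "ancestry proportion",
                    cex.names = if (nrow(Q) > 40) 0.4 else 0.7)
  invisible(path)
}

#' Assign individuals to genetic groups
#'
#' Two routes, mirroring the two structure analyses: `method = "admixture"`
#' labels each individual by the argmax of its ancestry row (ties go to the
#' lower group index, with a warning); `method = "tree"` cuts a
#' neighbour-joining tree into `k` clusters by removing the `k - 1` longest
#' edges and labelling leaves by connected component.
#'
#' @param x an `admixture_fit` (for `"admixture"`) or the `tree` element of
#'   [nj_tree()] (an \pkg{ape} `phylo`, for `"tree"`).
#' @param method `"admixture"` or `"tree"`.
#' @param k group count for the tree cut (ignored for admixture, where it is
#'   the fit's K).
#' @return integer group label per individual (named).
#' @export
assign_groups <- function(x, method = c("admixture", "tree"), k = NULL) {
  method <- match.arg(method)
  if (method == "admixture") {
    stopifnot(inherits(x, "admixture_fit"))
    Q <- x$Q
    ties <- apply(Q, 1, function(r) sum(r == max(r)) > 1L)
    if (any(ties)) warning(sum(ties), " tied ancestry row(s): lower group index used")
    labs <- apply(Q, 1, which.max)   # which.max takes the first (lower) index
    return(stats::setNames(as.integer(labs), rownames(Q)))
  }
  stopifnot(inherits(x, "phylo"), !is.null(k), k >= 1)
  n_tip <- length(x$tip.label)
  if (k == 1L) return(stats::setNames(rep(1L, n_tip), x$tip.label))
  g <- igraph::graph_from_edgelist(matrix(as.character(x$edge), ncol = 2),
                                   directed = FALSE)
  igraph::E(g)$weight <- x$edge.length
  drop <- order(x$edge.length, decreasing = TRUE)[seq_len(min(k - 1L, nrow(x$edge)))]
  g2 <- igraph::delete_edges(g, drop)
  comp <- igraph::components(g2)$membership
  tipnames <- as.character(seq_len(n_tip))
  labs <- comp[match(tipnames, igraph::V(g2)$name)]
  labs <- as.integer(factor(labs, levels = unique(labs)))
  stats::setNames(labs, x$tip.label)
}
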