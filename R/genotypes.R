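#' Diploid SSR genotype container
#'
#' Holds co-dominant microsatellite calls: for each individual and locus an
#' unordered pair of allele labels, with `NA` marking missing calls. This is
#' the input type for every genetic statistic in the package.
#'
#' @param a1,a2 character (or integer) matrices, individuals x loci, the two
#'   allele calls per locus. Missing data as `NA` in both.
#' @param ids individual identifiers (default `I1..In`).
#' @param loci locus identifiers (default `L1..LL`).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(a1, a2, ids = NULL, loci = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  stopifnot(all(dim(a1) == dim(a2)))
  if (any(is.na(a1) != is.na(a2)))
    stop("half-missing genotypes are not allowed: mark both alleles NA")
  if (is.null(ids)) ids <- paste0("I", seq_len(nrow(a1)))
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(a1)))
  storage.mode(a1) <- "character"; storage.mode(a2) <- "character"
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  structure(list(a1 = a1, a2 = a2, ids = ids, loci = loci),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$ids), "individuals x", length(x$loci), "loci\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$ids), length(x$loci))

#' Specify an admixed SSR genotype simulation
#'
#' Parameters for [generate_genotypes()]: `K` ancestral populations whose
#' per-locus allele frequencies diverge from a common base frequency by a
#' Dirichlet draw with concentration `drift_concentration` (small values =
#' strong drift = well-separated populations), and individuals whose ancestry
#' proportions are Dirichlet(`admixture_alpha`) rows (small alpha = nearly
#' pure individuals). Defaults emulate a plantation panel: 14 SSR loci with
#' 3-12 alleles each and moderate admixture.
#'
#' @param K number of ancestral populations (>= 1).
#' @param n number of individuals.
#' @param L number of loci.
#' @param alleles_per_locus integer vector recycled to `L` (3-12 typical);
#'   `NULL` draws each uniformly from 3:12.
#' @param drift_concentration positive scalar; ancestral frequencies are
#'   Dirichlet(`drift_concentration` * base frequency * n_alleles).
#' @param admixture_alpha symmetric Dirichlet concentration of the ancestry
#'   rows Q.
#' @param seed integer seed.
#' @return an object of class `geno_sim_spec`.
#' @export
geno_sim_spec <- function(K = 3, n = 102, L = 14, alleles_per_locus = NULL,
                          drift_concentration = 0.5, admixture_alpha = 0.1,
                          seed = 1L) {
  stopifnot(K >= 1, n >= 1, L >= 1, drift_concentration > 0, admixture_alpha > 0)
  if (!is.null(alleles_per_locus)) {
    alleles_per_locus <- rep_len(as.integer(alleles_per_locus), L)
    stopifnot(all(alleles_per_locus >= 1))
  }
  structure(list(K = as.integer(K), n = as.integer(n), L = as.integer(L),
                 alleles_per_locus = alleles_per_locus,
                 drift_concentration = drift_concentration,
                 admixture_alpha = admixture_alpha, seed = as.integer(seed)),
            class = "geno_sim_spec")
}

#' Simulate genotypes under the admixture model
#'
#' For each allele copy of each individual at each locus: draw the copy's
#' ancestral population from the individual's ancestry proportions Q, then
#' draw the allele from that population's locus frequency profile. This is
#' exactly the data model the admixture Gibbs sampler inverts, so simulated
#' truth (`Q`, `P`) calibrates the sampler end to end.
#'
#' @param spec a [geno_sim_spec()].
#' @return list with `genotypes` (a [genotype_matrix()]), `Q` (n x K true
#'   ancestry proportions, rows sum to 1) and `P` (list over loci of K x
#'   n_alleles frequency matrices, rows sum to 1).
#' @export
generate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "geno_sim_spec"))
  .with_seed(spec$seed, {
    K <- spec$K; n <- spec$n; L <- spec$L
    A <- spec$alleles_per_locus
    if (is.null(A)) A <- sample(3:12, L, replace = TRUE)
    P <- vector("list", L)
    for (l in seq_len(L)) {
      base <- as.vector(.rdirichlet(1, rep(1, A[l])))
      P[[l]] <- .rdirichlet(K, spec$drift_concentration * base * A[l])
    }
    Q <- if (K == 1) matrix(1, n, 1) else .rdirichlet(n, rep(spec$admixture_alpha, K))
    a1 <- matrix(NA_character_, n, L)
    a2 <- matrix(NA_character_, n, L)
    for (l in seq_len(L)) {
      for (copy in 1:2) {
        anc <- vapply(seq_len(n), function(i) sample.int(K, 1L, prob = Q[i, ]), 1L)
        al <- vapply(seq_len(n), function(i) sample.int(A[l], 1L, prob = P[[l]][anc[i], ]), 1L)
        lab <- sprintf("%03d", al)
        if (copy == 1) a1[, l] <- lab else a2[, l] <- lab
      }
    }
    g <- genotype_matrix(a1, a2)
    names(P) <- g$loci
    list(genotypes = g, Q = Q, P = P)
  })
}

#' Read/write genotype tables
#'
#' Two plain-text dialects are supported: a GenAlEx-like CSV with two columns
#' per locus (`<locus>.1`, `<locus>.2`, first column the individual id,
#' missing as empty or `0`), and the STRUCTURE two-row-per-individual format
#' (whitespace-separated, one row per allele copy, missing as `-9`).
#'
#' @param g a [genotype_matrix()].
#' @param path file path.
#' @return `read_*` return a [genotype_matrix()]; `write_*` return `path`
#'   invisibly.
#' @name genotype_io
NULL

#' @rdname genotype_io
#' @export
write_genalex_csv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  out <- data.frame(id = g$ids, stringsAsFactors = FALSE)
  for (j in seq_along(g$loci)) {
    out[[paste0(g$loci[j], ".1")]] <- ifelse(is.na(g$a1[, j]), "0", g$a1[, j])
    out[[paste0(g$loci[j], ".2")]] <- ifelse(is.na(g$a2[, j]), "0", g$a2[, j])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname genotype_io
#' @export
read_genalex_csv <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  ids <- tab[[1]]
  cols <- names(tab)[-1]
  loci <- unique(sub("\\.[12]$", "", cols))
  a1 <- sapply(loci, function(l) tab[[paste0(l, ".1")]])
  a2 <- sapply(loci, function(l) tab[[paste0(l, ".2")]])
  a1 <- matrix(a1, nrow = length(ids)); a2 <- matrix(a2, nrow = length(ids))
  a1[a1 %in% c("", "0", "-9")] <- NA; a2[a2 %in% c("", "0", "-9")] <- NA
  miss <- is.na(a1) | is.na(a2); a1[miss] <- NA; a2[miss] <- NA
  genotype_matrix(a1, a2, ids = ids, loci = loci)
}

#' @rdname genotype_io
#' @export
write_structure_txt <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(g$loci, collapse = "\t"), con)
  for (i in seq_along(g$ids)) {
    r1 <- ifelse(is.na(g$a1[i, ]), "-9", g$a1[i, ])
    r2 <- ifelse(is.na(g$a2[i, ]), "-9", g$a2[i, ])
    writeLines(paste(c(g$ids[i], r1), collapse = "\t"), con)
    writeLines(paste(c(g$ids[i], r2), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname genotype_io
#' @export
read_structure_txt <- function(path) {
  lines <- readLines(path)
  loci <- strsplit(lines[1], "\\s+")[[1]]
  body <- strsplit(lines[-1], "\\s+")
  if (length(body) %% 2 != 0) stop("STRUCTURE file must have two rows per individual")
  m <- do.call(rbind, body)
  ids <- m[seq(1, nrow(m), by = 2), 1]
  a1 <- m[seq(1, nrow(m), by = 2), -1, drop = FALSE]
  a2 <- m[seq(2, nrow(m), by = 2), -1, drop = FALSE]
  a1[a1 == "-9"] <- NA; a2[a2 == "-9"] <- NA
  miss <- is.na(a1) | is.na(a2); a1[miss] <- NA; a2[miss] <- NA
  genotype_matrix(a1, a2, ids = ids, loci = loci)
}
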