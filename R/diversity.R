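#' Per-population, per-locus diversity table
#'
#' Observed heterozygosity Ho, unbiased expected heterozygosity
#' He = 2p(1-p) * 2n/(2n-1), the inbreeding coefficient F_IS = 1 - Ho/He
#' (undefined at monomorphic loci, reported as \code{NA}), and allelic
#' richness A_R rarefied to a common number of gene copies
#' g: A_R = sum over alleles of [1 - choose(2n - n_a, g)/choose(2n, g)].
#'
#' @param gm a \code{genotype_matrix}.
#' @param rarefaction_g gene-copy count g for rarefaction; default
#'   (\code{NULL}) uses, per locus, twice the smallest per-population
#'   non-missing sample size.
#' @return data frame of class \code{"diversity_table"} with columns
#'   pop, locus, n, Ho, He, Fis, Ar, g.
#' @export
diversity <- function(gm, rarefaction_g = NULL) {
  pops <- sort(unique(gm$pop))
  loci <- colnames(gm$calls)
  nmat <- sapply(pops, function(p)
    colSums(!is.na(gm$calls[gm$pop == p, , drop = FALSE])))
  if (is.null(dim(nmat))) nmat <- matrix(nmat, nrow = 1L)
  g_default <- 2L * apply(nmat, 1L, min)   # per locus

  out <- vector("list", length(pops))
  for (ip in seq_along(pops)) {
    g <- gm$calls[gm$pop == pops[ip], , drop = FALSE]
    n <- colSums(!is.na(g))
    nref <- colSums(g, na.rm = TRUE)
    p <- ifelse(n > 0, nref / (2 * n), NA_real_)
    ho <- ifelse(n > 0, colSums(g == 1L, na.rm = TRUE) / n, NA_real_)
    he <- ifelse(n > 1, 2 * p * (1 - p) * (2 * n) / (2 * n - 1), NA_real_)
    fis <- ifelse(!is.na(he) & he > 0, 1 - ho / he, NA_real_)
    gg <- if (is.null(rarefaction_g)) g_default else
      rep_len(rarefaction_g, length(loci))
    ar <- rarefied_richness(nref, 2 * n - nref, 2 * n, gg)
    out[[ip]] <- data.frame(pop = pops[ip], locus = loci, n = n,
                            Ho = ho, He = he, Fis = fis, Ar = ar, g = gg,
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("diversity_table", "data.frame")
  res
}

# expected number of distinct alleles in a random draw of g gene copies
rarefied_richness <- function(n_ref, n_alt, n_tot, g) {
  term <- function(n_a) {
    out <- 1 - exp(lchoose(n_tot - n_a, g) - lchoose(n_tot, g))
    out[n_a == 0L] <- 0            # absent allele contributes nothing
    out
  }
  res <- term(n_ref) + term(n_alt)
  res[n_tot == 0L | g > n_tot | g < 1] <- NA_real_
  res
}

#' @export
print.diversity_table <- function(x, ...) {
  cat("per-population diversity (", length(unique(x$pop)), " pops x ",
      length(unique(x$locus)), " loci)\n", sep = "")
  agg <- stats::aggregate(x[, c("Ho", "He", "Fis", "Ar")],
                          by = list(pop = x$pop), mean, na.rm = TRUE)
  print(agg, digits = 3)
  invisible(x)
}

#' Hardy-Weinberg exact test by complete enumeration
#'
#' Two-sided exact test of Hardy-Weinberg proportions for one biallelic
#' locus, enumerating every heterozygote count compatible with the observed
#' allele counts under the Levene conditional distribution. The p-value is
#' the summed probability of all configurations no more probable than the
#' observed one.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return exact p-value in (0, 1]; monomorphic input gives 1.
#' @examples
#' hwe_exact(1, 0, 1)   # two homozygotes, no het
#' @export
hwe_exact <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 2L) stop("need at least 2 individuals")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n - nA
  if (nA == 0L || na == 0L) return(1)
  hs <- seq.int(nA %% 2L, min(nA, na), by = 2L)
  logp <- lfactorial(n) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial((na - hs) / 2) + hs * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2L * n)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  p_obs <- p[match(n_Aa, hs)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Population-pair correlation of allele frequencies
#'
#' Pearson correlation of per-locus reference-allele frequencies for every
#' population pair; loci with no data in either member of a pair are
#' excluded pairwise, and a zero-variance frequency vector yields
#' \code{NA}.
#'
#' @param gm a \code{genotype_matrix} with at least two populations.
#' @return symmetric matrix of Pearson r with unit diagonal.
#' @export
allele_freq_correlation <- function(gm) {
  pf <- allele_freqs(gm, by = "pop")
  if (nrow(pf) < 2L) stop("need at least two populations")
  pops <- rownames(pf)
  r <- matrix(NA_real_, nrow(pf), nrow(pf), dimnames = list(pops, pops))
  diag(r) <- 1
  for (i in seq_len(nrow(pf) - 1L)) for (j in (i + 1L):nrow(pf)) {
    ok <- is.finite(pf[i, ]) & is.finite(pf[j, ])
    x <- pf[i, ok]; y <- pf[j, ok]
    if (length(x) >= 2L && stats::sd(x) > 0 && stats::sd(y) > 0)
      r[i, j] <- r[j, i] <- stats::cor(x, y)
  }
  r
}
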