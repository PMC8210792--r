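# Weir & Cockerham (1984) variance components for biallelic loci.
# Returns per-locus a (among populations), b (among individuals within
# populations) and c (within individuals); theta = a / (a + b + c).
wc_components <- function(calls, pop) {
  pops <- sort(unique(pop))
  r_max <- length(pops)
  L <- ncol(calls)
  N <- matrix(0, r_max, L); P <- matrix(0, r_max, L); H <- matrix(0, r_max, L)
  for (i in seq_len(r_max)) {
    g <- calls[pop == pops[i], , drop = FALSE]
    n <- colSums(!is.na(g))
    N[i, ] <- n
    P[i, ] <- ifelse(n > 0, colSums(g, na.rm = TRUE) / (2 * n), 0)
    H[i, ] <- ifelse(n > 0, colSums(g == 1L, na.rm = TRUE) / n, 0)
  }
  r    <- colSums(N > 0)
  S1   <- colSums(N)
  nbar <- S1 / r
  nc   <- (S1 - colSums(N^2) / S1) / (r - 1)
  pbar <- colSums(N * P) / S1
  hbar <- colSums(N * H) / S1
  s2   <- colSums(N * sweep(P, 2L, pbar)^2) / ((r - 1) * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  # undefined where fewer than two populations carry data, or n too small
  bad <- r < 2 | nbar <= 1 | !is.finite(nc) | nc <= 0
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  list(a = a, b = b, c = cc,
       theta = a / (a + b + cc),
       loci = colnames(calls))
}

# multilocus theta = ratio of summed components (never the mean of ratios)
wc_multilocus <- function(comp) {
  ok <- is.finite(comp$a) & is.finite(comp$b) & is.finite(comp$c)
  sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
}

#' Pairwise and global Weir-Cockerham F_ST
#'
#' Estimates theta (Weir & Cockerham 1984) for every population pair and
#' globally over all populations. Multilocus estimates are the
#' ratio-of-sums of the a, b, c variance components across loci. Pair
#' significance comes from a seeded Monte-Carlo test: either a permutation
#' test on theta (population labels shuffled between the pair,
#' \code{method = "permutation"}) or a Fisher-exact-style contingency test
#' on per-locus genotype counts whose simulated per-locus p-values are
#' combined across loci by Fisher's method (\code{method = "exact"}).
#' Pairwise p-values are Bonferroni-flagged over all pairs.
#'
#' @param gm a \code{genotype_matrix} with at least two populations.
#' @param n_permutations Monte-Carlo replicates per pair (default 5000).
#' @param seed integer seed controlling the Monte-Carlo draws.
#' @param method \code{"permutation"} or \code{"exact"}.
#' @param alpha significance level for the Bonferroni flag (default 0.05).
#' @return object of class \code{"fst_result"}: \code{$pairs} (data frame
#'   with pop1, pop2, theta, p_value, significant), \code{$theta_matrix},
#'   \code{$per_locus} (locus-by-pair theta matrix), \code{$global}
#'   (multilocus theta over all populations), \code{$global_per_locus}.
#' @export
pairwise_fst <- function(gm, n_permutations = 5000L, seed = 1L,
                         method = c("permutation", "exact"), alpha = 0.05) {
  method <- match.arg(method)
  tb <- table(gm$pop)
  small <- names(tb)[tb < 2L]
  if (length(small)) {
    warning("excluding population(s) with fewer than 2 individuals: ",
            paste(small, collapse = ", "))
    gm <- gm[!(gm$pop %in% small), ]
  }
  pops <- sort(unique(gm$pop))
  if (length(pops) < 2L) stop("need at least two populations with n >= 2")

  comp_all <- wc_components(gm$calls, gm$pop)
  prs <- utils::combn(pops, 2L)
  n_pairs <- ncol(prs)
  per_locus <- matrix(NA_real_, ncol(gm$calls), n_pairs,
                      dimnames = list(colnames(gm$calls),
                                      paste(prs[1L, ], prs[2L, ], sep = ":")))
  theta <- pval <- numeric(n_pairs)
  set.seed(seed)
  for (k in seq_len(n_pairs)) {
    sel <- gm$pop %in% prs[, k]
    calls <- gm$calls[sel, , drop = FALSE]
    lab <- gm$pop[sel]
    comp <- wc_components(calls, lab)
    per_locus[, k] <- comp$theta
    theta[k] <- wc_multilocus(comp)
    pval[k] <- if (method == "permutation")
      fst_perm_pvalue(calls, lab, theta[k], n_permutations)
    else
      fst_exact_pvalue(calls, lab, n_permutations)
  }
  pairs <- data.frame(pop1 = prs[1L, ], pop2 = prs[2L, ], theta = theta,
                      p_value = pval,
                      significant = bonferroni(pval, alpha),
                      stringsAsFactors = FALSE)
  tm <- matrix(NA_real_, length(pops), length(pops),
               dimnames = list(pops, pops))
  for (k in seq_len(n_pairs)) {
    tm[prs[1L, k], prs[2L, k]] <- theta[k]
    tm[prs[2L, k], prs[1L, k]] <- theta[k]
  }
  structure(list(pairs = pairs, theta_matrix = tm, per_locus = per_locus,
                 global = wc_multilocus(comp_all),
                 global_per_locus = comp_all$theta,
                 method = method, n_permutations = n_permutations,
                 seed = seed),
            class = "fst_result")
}

fst_perm_pvalue <- function(calls, lab, observed, B) {
  if (!is.finite(observed)) return(NA_real_)
  hits <- 0L
  for (b in seq_len(B)) {
    t_b <- wc_multilocus(wc_components(calls, sample(lab)))
    if (is.finite(t_b) && t_b >= observed) hits <- hits + 1L
  }
  (hits + 1L) / (B + 1L)
}

# Monte-Carlo contingency exact test per locus (genotype counts x pair),
# per-locus p-values combined over loci by Fisher's method against the
# chi-square reference.
fst_exact_pvalue <- function(calls, lab, B) {
  pl <- rep(NA_real_, ncol(calls))
  for (l in seq_len(ncol(calls))) {
    g <- calls[, l]; ok <- !is.na(g)
    tab <- table(factor(g[ok], levels = 0:2), lab[ok])
    tab <- tab[rowSums(tab) > 0L, , drop = FALSE]
    if (nrow(tab) < 2L || any(colSums(tab) == 0L)) next
    pl[l] <- stats::fisher.test(tab, simulate.p.value = TRUE, B = B)$p.value
  }
  pl <- pl[is.finite(pl)]
  if (!length(pl)) return(NA_real_)
  stat <- -2 * sum(log(pmax(pl, 1e-300)))
  stats::pchisq(stat, df = 2 * length(pl), lower.tail = FALSE)
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham F_ST (global multilocus theta = %.4f)\n",
              x$global))
  cat(sprintf("significance: %s, %d Monte-Carlo replicates, seed %d\n",
              x$method, x$n_permutations, x$seed))
  print(x$pairs, digits = 4)
  invisible(x)
}

#' Bonferroni significance flags
#'
#' @param pvals numeric vector of p-values.
#' @param alpha family-wise significance level.
#' @return logical vector: \code{p <= alpha / length(pvals)}.
#' @export
bonferroni <- function(pvals, alpha = 0.05) {
  if (!length(pvals)) stop("no p-values supplied")
  pvals <= alpha / length(pvals)
}
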