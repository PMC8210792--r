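# ancestry-pattern table: phi[z, o] = P(a locus of class z carries o
# alleles of population-A origin), columns o = 2, 1, 0
class_phi <- function() {
  phi <- rbind(PureA = c(1, 0, 0),
               PureB = c(0, 0, 1),
               F1    = c(0, 1, 0),
               F2    = c(0.25, 0.5, 0.25),
               BCA   = c(0.5, 0.5, 0),
               BCB   = c(0, 0.5, 0.5))
  colnames(phi) <- c("o2", "o1", "o0")
  phi
}

#' Genotype probability under a hybrid class
#'
#' P(genotype | class) at one biallelic locus, marginalized over the
#' ancestral origin of the two allele copies: with probability phi[z, o]
#' the individual carries o copies of population-A origin, and each copy
#' independently carries the reference allele with its pool's frequency
#' (p_A or p_B). Missing genotypes (\code{NA}) return probability 1, so
#' the locus drops out of a product over loci.
#'
#' @param g genotype (reference-allele count 0, 1, 2, or \code{NA});
#'   vectorized over loci together with \code{p_A}, \code{p_B}.
#' @param p_A,p_B reference-allele frequency in populations A and B.
#' @param z a class label from \code{\link{hybrid_classes}()}.
#' @return numeric vector of probabilities.
#' @examples
#' class_genotype_prob(1, p_A = 1, p_B = 0, z = "F1")    # 1: diagnostic locus
#' class_genotype_prob(2, p_A = 0.9, p_B = 0.2, z = "BCA")
#' @export
class_genotype_prob <- function(g, p_A, p_B, z) {
  phi <- class_phi()
  if (!(z %in% rownames(phi))) stop("unknown class label: ", z)
  stopifnot(all(p_A >= 0 & p_A <= 1), all(p_B >= 0 & p_B <= 1))
  w <- phi[z, ]
  p_A <- rep_len(p_A, length(g)); p_B <- rep_len(p_B, length(g))
  qA <- 1 - p_A; qB <- 1 - p_B
  # P(g | o) for o = 2 (both A), 1 (one each), 0 (both B); columns g = 0,1,2
  P2 <- cbind(qA * qA, 2 * p_A * qA, p_A * p_A)
  P1 <- cbind(qA * qB, p_A * qB + qA * p_B, p_A * p_B)
  P0 <- cbind(qB * qB, 2 * p_B * qB, p_B * p_B)
  out <- rep(1, length(g))
  ok <- !is.na(g)
  idx <- cbind(seq_along(g)[ok], g[ok] + 1L)
  out[ok] <- w["o2"] * P2[idx] + w["o1"] * P1[idx] + w["o0"] * P0[idx]
  out
}

new_hybrid_posterior <- function(posterior, freq_A, freq_B, settings,
                                 diagnostics = list()) {
  colnames(posterior) <- hybrid_classes()
  structure(list(posterior = posterior, freq_A = freq_A, freq_B = freq_B,
                 settings = settings, diagnostics = diagnostics),
            class = "hybrid_posterior")
}

#' @export
print.hybrid_posterior <- function(x, ...) {
  cat(sprintf("hybrid_posterior: %d individuals x 6 classes (%s)\n",
              nrow(x$posterior), x$settings$method))
  modal <- hybrid_classes()[max.col(x$posterior)]
  print(table(modal))
  if (!is.null(x$diagnostics$discrepancy))
    cat(sprintf("max between-chain posterior discrepancy: %.4f (%s)\n",
                x$diagnostics$discrepancy,
                if (isTRUE(x$diagnostics$converged)) "converged"
                else "NOT converged"))
  invisible(x)
}

#' Fixed-frequency maximum-likelihood classification
#'
#' Fast classification path with the parental allele frequencies held
#' fixed (e.g. the known frequencies of a simulation, or frequencies
#' estimated from reference samples): the posterior over the six classes
#' is proportional to prior times the product of per-locus genotype
#' probabilities.
#'
#' @param gm a \code{genotype_matrix}.
#' @param p_A,p_B per-locus reference-allele frequencies covering every
#'   locus of \code{gm} (matched by name when named).
#' @param prior prior weight per class (default uniform).
#' @return a \code{"hybrid_posterior"}; individuals with no genotypes get
#'   a posterior equal to the normalized prior and are flagged.
#' @export
classify_ml <- function(gm, p_A, p_B, prior = rep(1 / 6, 6)) {
  L <- ncol(gm$calls)
  if (!is.null(names(p_A))) p_A <- p_A[colnames(gm$calls)]
  if (!is.null(names(p_B))) p_B <- p_B[colnames(gm$calls)]
  if (length(p_A) != L || length(p_B) != L || anyNA(p_A) || anyNA(p_B))
    stop("frequencies must cover every locus")
  classes <- hybrid_classes()
  n <- nrow(gm$calls)
  ll <- matrix(rep(log(prior), each = n), n, 6)
  for (k in seq_along(classes)) {
    Tz <- log(pmax(vapply(0:2, function(g)
      class_genotype_prob(rep(g, L), p_A, p_B, classes[k]),
      numeric(L)), 1e-300))                           # L x 3
    g <- gm$calls
    v <- matrix(0, n, L)
    ok <- !is.na(g)
    v[ok] <- Tz[cbind(rep(seq_len(L), each = n)[ok], g[ok] + 1L)]
    ll[, k] <- ll[, k] + rowSums(v)
  }
  m <- apply(ll, 1L, max)
  post <- exp(ll - m)
  post <- post / rowSums(post)
  all_missing <- rowSums(!is.na(gm$calls)) == 0L
  new_hybrid_posterior(post, p_A, p_B,
                       settings = list(method = "ml", prior = prior),
                       diagnostics = list(all_missing = all_missing))
}

#' Gibbs-sampled six-class hybrid classification
#'
#' NewHybrids-style Gibbs sampler: class labels and parental allele
#' frequencies are unknown and sampled alternately — each individual's
#' class from its conditional under the current frequencies, then each
#' pool's frequencies from Beta posteriors (uniform priors) using allele
#' origins imputed from the current classes. Two independent chains are
#' run; chain two is aligned to chain one (the A/B labelling of a chain is
#' arbitrary) and the maximum per-individual discrepancy of posterior
#' means is reported. If it exceeds \code{max_discrepancy} the pair of
#' chains is rerun with fresh derived seeds, up to \code{max_restarts}
#' times. Final posteriors average the two chains; clusters are then
#' oriented so that cluster A has the higher mean reference-allele
#' frequency across loci.
#'
#' @param gm a \code{genotype_matrix}. Identifiability of all six classes
#'   needs individuals from both pure clusters in the data.
#' @param burnin discarded sweeps (default 5000; the full-scale setting
#'   of 50000 is available by argument).
#' @param sweeps retained sweeps (default 30000; full scale 300000).
#' @param seed integer seed.
#' @param prior prior over the six classes (default uniform).
#' @param max_discrepancy convergence tolerance on between-chain posterior
#'   means (default 0.1).
#' @param max_restarts reruns allowed on non-convergence (default 2).
#' @return a \code{"hybrid_posterior"} with posterior-mean frequencies
#'   \code{freq_A}, \code{freq_B} and convergence diagnostics.
#' @export
classify_gibbs <- function(gm, burnin = 5000L, sweeps = 30000L, seed = 1L,
                           prior = rep(1 / 6, 6), max_discrepancy = 0.1,
                           max_restarts = 2L) {
  if (sweeps <= 0L) stop("sweeps must exceed 0")
  if (burnin < 0L) stop("burnin must be non-negative")
  calls <- gm$calls
  attempt <- 0L
  repeat {
    s1 <- (seed + 2L * attempt * 49999L) %% .Machine$integer.max
    s2 <- (seed + (2L * attempt + 1L) * 49999L + 7L) %% .Machine$integer.max
    ch1 <- .gibbs_chain(calls, prior, as.integer(burnin), as.integer(sweeps),
                        as.double(s1))
    ch2 <- .gibbs_chain(calls, prior, as.integer(burnin), as.integer(sweeps),
                        as.double(s2))
    ch2 <- align_chain(ch2, ch1)
    disc <- max(abs(ch1$posterior - ch2$posterior))
    if (disc <= max_discrepancy || attempt >= max_restarts) break
    attempt <- attempt + 1L
  }
  post <- (ch1$posterior + ch2$posterior) / 2
  freq_A <- (ch1$freq_A + ch2$freq_A) / 2
  freq_B <- (ch1$freq_B + ch2$freq_B) / 2
  # orientation rule: cluster A = higher mean reference-allele frequency
  if (mean(freq_A) < mean(freq_B)) {
    tmp <- freq_A; freq_A <- freq_B; freq_B <- tmp
    post <- swap_ab(post)
  }
  names(freq_A) <- names(freq_B) <- colnames(calls)
  new_hybrid_posterior(
    post, freq_A, freq_B,
    settings = list(method = "gibbs", burnin = burnin, sweeps = sweeps,
                    seed = seed, prior = prior),
    diagnostics = list(discrepancy = disc,
                       converged = disc <= max_discrepancy,
                       restarts = attempt))
}

# swap the A/B orientation of a 6-class posterior matrix
# (PureA <-> PureB, BCA <-> BCB; column names keep the canonical order)
swap_ab <- function(post) {
  out <- post[, c(2L, 1L, 3L, 4L, 6L, 5L), drop = FALSE]
  colnames(out) <- colnames(post)
  out
}

align_chain <- function(ch, ref) {
  same <- stats::cor(c(ch$freq_A, ch$freq_B), c(ref$freq_A, ref$freq_B))
  swapped <- stats::cor(c(ch$freq_B, ch$freq_A), c(ref$freq_A, ref$freq_B))
  if (is.na(same) || is.na(swapped) || same >= swapped) return(ch)
  list(posterior = swap_ab(ch$posterior),
       freq_A = ch$freq_B, freq_B = ch$freq_A)
}

#' Threshold-based class assignment
#'
#' Assigns each individual the class whose posterior probability exceeds
#' the threshold, or \code{"unassigned"} when none does. With
#' \code{pooling}, posteriors of the pooled classes are summed before
#' thresholding (e.g. the four hybrid classes as one \code{"hybrid"}
#' group), so a pooled label can be assigned even when no single member
#' class passes.
#'
#' @param post a \code{"hybrid_posterior"} (or bare posterior matrix with
#'   the six class columns).
#' @param threshold posterior probability threshold (values below 0.5
#'   warn: assignments are then not necessarily unique, ties broken by the
#'   larger posterior).
#' @param pooling optional named list of class groupings, e.g.
#'   \code{list(hybrid = c("F1", "F2", "BCA", "BCB"))}; classes not named
#'   in any group keep their own label.
#' @return character vector of labels.
#' @export
assign_classes <- function(post, threshold = 0.5, pooling = NULL) {
  if (inherits(post, "hybrid_posterior")) post <- post$posterior
  if (threshold < 0.5)
    warning("threshold below 0.5: assignment may not be unique")
  if (threshold >= 1) stop("threshold must be < 1")
  p <- post
  if (!is.null(pooling)) {
    pooled_members <- unlist(pooling, use.names = FALSE)
    bad <- setdiff(pooled_members, colnames(post))
    if (length(bad)) stop("unknown class in pooling: ", paste(bad, collapse = ", "))
    singles <- setdiff(colnames(post), pooled_members)
    p <- cbind(post[, singles, drop = FALSE],
               vapply(pooling, function(cl)
                 rowSums(post[, cl, drop = FALSE]), numeric(nrow(post))))
    colnames(p) <- c(singles, names(pooling))
  }
  best <- max.col(p, ties.method = "first")
  lab <- colnames(p)[best]
  lab[p[cbind(seq_len(nrow(p)), best)] <= threshold] <- "unassigned"
  lab
}
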