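#' Maximum-likelihood admixture proportions (EM)
#'
#' Estimates per-individual ancestry proportions q and per-cluster allele
#' frequencies under the admixture likelihood in which each of an
#' individual's 2L allele copies is drawn from cluster k with probability
#' q_ik and then carries the reference allele with frequency f_kl. Fitted
#' by EM; the log-likelihood is non-decreasing at every iteration and the
#' run stops when the increase falls below \code{tol} or at
#' \code{max_iter}. Missing genotypes drop out of the likelihood.
#'
#' @param gm a \code{genotype_matrix}.
#' @param K number of clusters (1 to n_individuals).
#' @param seed integer seed for the initialization.
#' @param max_iter,tol stopping rule (defaults 2000 iterations, 1e-6
#'   log-likelihood units).
#' @param init \code{"random"} or \code{"labels"} (supervised start from
#'   the population labels, the analogue of clustering with sampling
#'   location as prior information).
#' @return object of class \code{"qmatrix"}: \code{$q} (n x K),
#'   \code{$freqs} (K x L), \code{$loglik}, \code{$loglik_trace},
#'   \code{$K}, \code{$converged}, \code{$iterations}, \code{$seed}.
#' @export
admixture_em <- function(gm, K, seed = 1L, max_iter = 2000L, tol = 1e-6,
                         init = c("random", "labels")) {
  init <- match.arg(init)
  G <- gm$calls; storage.mode(G) <- "double"
  n <- nrow(G); L <- ncol(G)
  if (K < 1L) stop("K must be >= 1")
  if (K > n) stop("K exceeds the number of individuals")
  obs <- !is.na(G)
  G0 <- G; G0[!obs] <- 0                  # contributes nothing where missing
  n_copies <- 2 * rowSums(obs)
  set.seed(seed)
  if (init == "labels" && K > 1L) {
    pops <- sort(unique(gm$pop))
    grp <- (match(gm$pop, pops) - 1L) %% K + 1L
    Q <- matrix(0.05 / (K - 1), n, K)
    Q[cbind(seq_len(n), grp)] <- 0.95
  } else {
    Q <- matrix(stats::runif(n * K, 0.2, 1), n, K)
    Q <- Q / rowSums(Q)
  }
  f <- matrix(stats::runif(K * L, 0.05, 0.95), K, L)

  eps <- 1e-9
  loglik <- function(MU) sum((G0 * log(MU) + (2 - G0) * log(1 - MU))[obs])
  trace <- numeric(0)
  ll_old <- -Inf; converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    MU <- Q %*% f
    MU <- pmin(pmax(MU, eps), 1 - eps)
    ll <- loglik(MU)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
    Qn <- matrix(0, n, K); f_num <- matrix(0, K, L); f_den <- matrix(0, K, L)
    for (k in seq_len(K)) {
      Ak <- outer(Q[, k], f[k, ]) / MU            # ref-copy responsibility
      Bk <- outer(Q[, k], 1 - f[k, ]) / (1 - MU)  # alt-copy responsibility
      ref_k <- G0 * Ak; alt_k <- (2 - G0) * Bk
      ref_k[!obs] <- 0; alt_k[!obs] <- 0
      Qn[, k] <- rowSums(ref_k) + rowSums(alt_k)
      f_num[k, ] <- colSums(ref_k)
      f_den[k, ] <- colSums(ref_k) + colSums(alt_k)
    }
    Q <- Qn / n_copies
    Q <- Q / rowSums(Q)                  # guard against numerical drift
    f <- ifelse(f_den > 0, f_num / f_den, f)
    f <- pmin(pmax(f, eps), 1 - eps)
  }
  rownames(Q) <- rownames(G)
  structure(list(q = Q, freqs = f, loglik = trace[length(trace)],
                 loglik_trace = trace, K = K, converged = converged,
                 iterations = it, seed = seed),
            class = "qmatrix")
}

#' @export
print.qmatrix <- function(x, ...) {
  cat(sprintf("qmatrix: %d individuals, K = %d, logL = %.2f (%s, %d EM iterations)\n",
              nrow(x$q), x$K, x$loglik,
              if (x$converged) "converged" else "max_iter reached",
              x$iterations))
  invisible(x)
}

#' Evanno delta-K over replicated clustering runs
#'
#' The second-difference statistic used to pick the uppermost level of
#' population hierarchy: for each interior K,
#' delta-K = mean over replicates of |L(K-1) - 2 L(K) + L(K+1)| divided by
#' the standard deviation of L(K) over replicates. Undefined at the edge
#' Ks and wherever sd(L(K)) is zero (flagged \code{NA}).
#'
#' @param runs data frame with columns \code{K}, \code{replicate},
#'   \code{loglik} covering at least three consecutive K values with at
#'   least two replicates each.
#' @return data frame of class \code{"delta_k_table"} with per-K mean and
#'   sd of the log-likelihood and delta-K; attribute \code{"best_K"} holds
#'   the argmax.
#' @export
evanno_delta_k <- function(runs) {
  stopifnot(all(c("K", "replicate", "loglik") %in% names(runs)))
  ks <- sort(unique(runs$K))
  if (length(ks) < 3L || any(diff(ks) != 1L))
    stop("need at least 3 consecutive K values")
  reps <- sort(unique(runs$replicate))
  if (length(reps) < 2L) stop("need at least 2 replicates per K")
  Lmat <- sapply(ks, function(k) {
    v <- runs$loglik[runs$K == k][order(runs$replicate[runs$K == k])]
    if (length(v) != length(reps)) stop("unbalanced replicates at K = ", k)
    v
  })                                        # replicates x K
  mu <- colMeans(Lmat); sdv <- apply(Lmat, 2L, stats::sd)
  dK <- rep(NA_real_, length(ks))
  for (j in 2:(length(ks) - 1L)) {
    second <- abs(Lmat[, j - 1L] - 2 * Lmat[, j] + Lmat[, j + 1L])
    dK[j] <- if (sdv[j] > 0) mean(second) / sdv[j] else NA_real_
  }
  out <- data.frame(K = ks, mean_loglik = mu, sd_loglik = sdv, delta_K = dK)
  class(out) <- c("delta_k_table", "data.frame")
  attr(out, "best_K") <- if (all(is.na(dK))) NA_integer_ else
    ks[which.max(dK)]
  out
}

#' Genotype PCA
#'
#' Principal component analysis of the 0/1/2 genotype matrix with columns
#' centred but not scaled and missing calls replaced by the column mean
#' (so they fall at the centroid and carry no signal).
#'
#' @param gm a \code{genotype_matrix} with at least two individuals.
#' @return object of class \code{"genotype_pca"}: \code{$scores},
#'   \code{$percent_variance}, \code{$rotation}, \code{$constant} flag for
#'   an all-constant matrix.
#' @export
pca_genotypes <- function(gm) {
  X <- gm$calls; storage.mode(X) <- "double"
  if (nrow(X) < 2L) stop("need at least two individuals")
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2L]]
  Xc <- sweep(X, 2L, colMeans(X))
  constant <- all(abs(Xc) < 1e-12)
  if (constant) warning("constant genotype matrix: zero total variance")
  pc <- stats::prcomp(Xc, center = FALSE, scale. = FALSE)
  pv <- 100 * pc$sdev^2 / max(sum(pc$sdev^2), .Machine$double.eps)
  structure(list(scores = pc$x, percent_variance = pv,
                 rotation = pc$rotation, constant = constant),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf("genotype_pca: %d individuals, PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), x$percent_variance[1L],
              if (length(x$percent_variance) > 1L) x$percent_variance[2L] else 0))
  invisible(x)
}

#' @export
plot.genotype_pca <- function(x, groups = NULL, ...) {
  col <- if (!is.null(groups)) as.integer(factor(groups)) else 1L
  graphics::plot(x$scores[, 1L], x$scores[, 2L], col = col, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", x$percent_variance[1L]),
                 ylab = sprintf("PC2 (%.1f%%)", x$percent_variance[2L]), ...)
  invisible(x)
}
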