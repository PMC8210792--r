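#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Three-level genotype AMOVA on squared Euclidean distances between
#' allele-count genotype vectors (missing calls imputed with the population
#' mean): variation between geographic groups, between populations within
#' groups, and within populations. Variance components come from the
#' standard nested moments equations with unequal-size coefficients;
#' significance from seeded permutations — populations permuted among
#' groups (between-group component), individuals permuted among populations
#' within groups (between-population component), and individuals permuted
#' among all populations (within-population component).
#'
#' @param gm a \code{genotype_matrix} whose \code{group} labels define at
#'   least two geographic groups.
#' @param n_permutations permutation replicates (default 999).
#' @param seed integer seed.
#' @return object of class \code{"amova_result"}: \code{$table} with df,
#'   sum of squares, variance component sigma2, percent of total variation
#'   and permutation p-value per stratum, plus \code{$phi} statistics.
#'   Negative components are reported as-is; percentages are computed over
#'   the sum of positive components and flagged when any component is
#'   negative.
#' @export
amova <- function(gm, n_permutations = 999L, seed = 1L) {
  if (is.null(gm$group)) stop("genotype matrix carries no group labels")
  if (length(unique(gm$group)) < 2L)
    stop("between-group stratum undefined with a single group")
  X <- impute_pop_mean(gm$calls, gm$pop)
  obs <- amova_components(X, gm$pop, gm$group)
  if (all(abs(obs$sigma2) < 1e-12)) {
    warning("all individuals identical: variance components are zero, ",
            "percentages undefined")
    degenerate <- TRUE
  } else degenerate <- FALSE

  set.seed(seed)
  B <- n_permutations
  hits <- c(0L, 0L, 0L)
  pops <- unique(gm$pop)
  pop_group <- gm$group[match(pops, gm$pop)]
  for (b in seq_len(B)) {
    # (i) whole populations reassigned to groups
    pg <- sample(pop_group)
    g1 <- pg[match(gm$pop, pops)]
    if (amova_components(X, gm$pop, g1)$sigma2[1L] >= obs$sigma2[1L])
      hits[1L] <- hits[1L] + 1L
    # (ii) individuals shuffled among populations within their group
    p2 <- gm$pop
    for (g in unique(gm$group)) {
      sel <- gm$group == g
      p2[sel] <- sample(gm$pop[sel])
    }
    if (amova_components(X, p2, gm$group)$sigma2[2L] >= obs$sigma2[2L])
      hits[2L] <- hits[2L] + 1L
    # (iii) individuals shuffled among all populations
    idx <- sample(length(gm$pop))
    if (amova_components(X, gm$pop[idx], gm$group[idx])$sigma2[3L] <=
        obs$sigma2[3L])
      hits[3L] <- hits[3L] + 1L
  }
  pval <- (hits + 1L) / (B + 1L)

  pos <- pmax(obs$sigma2, 0)
  pct <- if (degenerate) rep(NA_real_, 3L) else 100 * pos / sum(pos)
  tab <- data.frame(
    stratum = c("between_groups", "between_pops_within_groups",
                "within_pops"),
    df = obs$df, SS = obs$SS, sigma2 = obs$sigma2, percent = pct,
    p_value = pval, row.names = NULL, stringsAsFactors = FALSE)
  tot <- sum(obs$sigma2)
  structure(list(table = tab,
                 phi = c(phi_CT = obs$sigma2[1L] / tot,
                         phi_SC = obs$sigma2[2L] / sum(obs$sigma2[2:3]),
                         phi_ST = sum(obs$sigma2[1:2]) / tot),
                 negative_components = any(obs$sigma2 < 0),
                 degenerate = degenerate,
                 distance = "squared Euclidean on 0/1/2 genotype vectors, population-mean imputation",
                 n_permutations = B, seed = seed),
            class = "amova_result")
}

impute_pop_mean <- function(calls, pop) {
  X <- calls; storage.mode(X) <- "double"
  for (p in unique(pop)) {
    sel <- pop == p
    sub <- X[sel, , drop = FALSE]
    mu <- colMeans(sub, na.rm = TRUE)
    mu[is.nan(mu)] <- mean(X, na.rm = TRUE)
    idx <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(idx)) sub[idx] <- mu[idx[, 2L]]
    X[sel, ] <- sub
  }
  X
}

# nested sums of squares and moment estimators of the variance components
amova_components <- function(X, pop, group) {
  N <- nrow(X)
  pops <- unique(pop)
  groups <- unique(group)
  G <- length(groups); P <- length(pops)
  pop_group <- group[match(pops, pop)]

  grand <- colMeans(X)
  ss_total <- sum(sweep(X, 2L, grand)^2)
  ss_wp <- 0; ss_ap <- 0; ss_ag <- 0
  n_p <- numeric(P); names(n_p) <- pops
  for (g in groups) {
    selg <- group == g
    gbar <- colMeans(X[selg, , drop = FALSE])
    ss_ag <- ss_ag + sum(selg) * sum((gbar - grand)^2)
    for (p in pops[pop_group == g]) {
      selp <- pop == p
      n_p[p] <- sum(selp)
      pbar <- colMeans(X[selp, , drop = FALSE])
      ss_wp <- ss_wp + sum(sweep(X[selp, , drop = FALSE], 2L, pbar)^2)
      ss_ap <- ss_ap + n_p[p] * sum((pbar - gbar)^2)
    }
  }
  N_g <- tapply(n_p, pop_group, sum)
  df <- c(G - 1L, P - G, N - P)
  ss <- unname(c(ss_ag, ss_ap, ss_wp))
  # unequal-sample-size coefficients of the nested moments equations
  sum_np2_by_g <- sum(tapply(n_p^2, pop_group, sum) / N_g)
  n_dprime <- (sum_np2_by_g - sum(n_p^2) / N) / (G - 1L)
  n_tprime <- (N - sum(N_g^2) / N) / (G - 1L)
  s2_w <- ss[3L] / df[3L]
  s2_b <- if (df[2L] > 0L) {
    n_prime <- (N - sum_np2_by_g) / (P - G)
    (ss[2L] / df[2L] - s2_w) / n_prime
  } else 0   # one population per group: the stratum vanishes
  s2_a <- (ss[1L] / df[1L] - s2_w - n_dprime * s2_b) / n_tprime
  list(df = df, SS = ss,
       sigma2 = unname(c(s2_a, s2_b, s2_w)), ss_total = ss_total)
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", x$distance, ")\n", sep = "")
  print(transform(x$table, SS = round(SS, 1), sigma2 = round(sigma2, 3),
                  percent = round(percent, 1)), row.names = FALSE)
  cat(sprintf("phi_CT = %.3f, phi_SC = %.3f, phi_ST = %.3f; %d permutations\n",
              x$phi[1L], x$phi[2L], x$phi[3L], x$n_permutations))
  if (x$negative_components)
    cat("note: negative variance component(s); percentages use positive components only\n")
  invisible(x)
}
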