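# Independent oracles used to freeze expected values. These deliberately
# re-derive each quantity along a different route from the package code
# (scalar loops, exhaustive enumeration, grid search).

# Weir & Cockerham (1984) per-locus variance components, transcribed
# directly from the printed equations, one population at a time.
oracle_wc84_locus <- function(genos_by_pop) {
  r <- length(genos_by_pop)
  n_i <- p_i <- h_i <- numeric(r)
  for (i in seq_len(r)) {
    g <- genos_by_pop[[i]]
    g <- g[!is.na(g)]
    n_i[i] <- length(g)
    p_i[i] <- sum(g) / (2 * length(g))
    h_i[i] <- mean(g == 1)
  }
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

oracle_wc84_multilocus <- function(calls, pop) {
  pops <- sort(unique(pop))
  A <- B <- C <- 0
  per_locus <- numeric(ncol(calls))
  for (l in seq_len(ncol(calls))) {
    comp <- oracle_wc84_locus(lapply(pops, function(p) calls[pop == p, l]))
    per_locus[l] <- comp["theta"]
    if (all(is.finite(comp[1:3]))) {
      A <- A + comp["a"]; B <- B + comp["b"]; C <- C + comp["c"]
    }
  }
  list(per_locus = per_locus, multilocus = unname(A / (A + B + C)))
}

# Hardy-Weinberg exact p-value by brute-force enumeration: lay out the 2n
# gene copies (nA reference, rest alternate), enumerate every way to choose
# which copies carry the reference allele, pair copies (1,2), (3,4), ... and
# tally the heterozygote count of each equally likely arrangement.
oracle_hwe_bruteforce <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n) return(1)
  sets <- utils::combn(2 * n, nA)
  het_of <- function(idx) {
    copies <- rep(0L, 2 * n)
    copies[idx] <- 1L
    pairs <- matrix(copies, nrow = 2)
    sum(colSums(pairs) == 1L)
  }
  hets <- apply(sets, 2, het_of)
  tab <- table(hets) / ncol(sets)
  p_obs <- tab[[as.character(n_Aa)]]
  sum(tab[tab <= p_obs * (1 + 1e-12)])
}

# grid-search ML cline fit, fixed asymptotes (0, 1)
oracle_cline_grid <- function(x, y, n, c_grid, w_grid) {
  best <- c(NA, NA, -Inf)
  for (cc in c_grid) for (w in w_grid) {
    p <- 1 / (1 + exp(-4 * (x - cc) / w))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll <- sum(y * log(p) + (n - y) * log(1 - p))
    if (ll > best[3]) best <- c(cc, w, ll)
  }
  names(best) <- c("centre", "width", "logL")
  best
}

# enumeration of two-generation gamete origins for the class genotype model
oracle_class_prob <- function(g, p_A, p_B, z) {
  phi <- switch(z,
                PureA = c(1, 0, 0), PureB = c(0, 0, 1), F1 = c(0, 1, 0),
                F2 = c(0.25, 0.5, 0.25), BCA = c(0.5, 0.5, 0),
                BCB = c(0, 0.5, 0.5))
  prob <- 0
  for (o in 0:2) {                 # o = number of A-origin copies
    w <- phi[3 - o]                # phi stored for o = 2, 1, 0
    ps <- c(rep(p_A, o), rep(p_B, 2 - o))
    # enumerate the two copies' reference/alternate states
    for (c1 in 0:1) for (c2 in 0:1) {
      if (c1 + c2 != g) next
      prob <- prob + w * (c1 * ps[1] + (1 - c1) * (1 - ps[1])) *
        (c2 * ps[2] + (1 - c2) * (1 - ps[2]))
    }
  }
  prob
}

# small labelled genotype fixture shared by several tests
toy_two_group_gm <- function() {
  calls <- rbind(
    a1 = c(2L, 2L, 2L, 2L), a2 = c(2L, 2L, 2L, 2L),
    b1 = c(2L, 2L, 2L, 2L), b2 = c(2L, 2L, 2L, 2L),
    c1 = c(0L, 0L, 0L, 0L), c2 = c(0L, 0L, 0L, 0L),
    d1 = c(0L, 0L, 0L, 0L), d2 = c(0L, 0L, 0L, 0L))
  genotype_matrix(calls,
                  pop = rep(c("A", "B", "C", "D"), each = 2),
                  group = rep(c("west", "east"), each = 4))
}
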