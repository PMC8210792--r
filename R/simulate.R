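#' Simulate two diverged reference populations
#'
#' Draws a biallelic reference panel under the Balding-Nichols model:
#' ancestral frequencies uniform on \code{anc_range}, population
#' frequencies Beta(p(1-F)/F, (1-p)(1-F)/F) independently for the two
#' populations, genotypes Binomial(2, p_pop). \code{F_div} is
#' interpretable as the expected Weir-Cockerham divergence between the two
#' populations; the package's wrasse-inspired default study condition is
#' \code{F_div = 0.5}, matching a strong west-vs-south-east coastal break.
#'
#' @param n_loci number of loci.
#' @param n_per_pop diploid individuals per population (default 40).
#' @param F_div Balding-Nichols divergence in (0, 1).
#' @param seed integer seed (deterministic output).
#' @param anc_range support of the ancestral frequency draw; the default
#'   \code{c(0.05, 0.95)} avoids monomorphic ancestral loci.
#' @param pop_names names of the two populations.
#' @return list with \code{$panel} (class \code{"reference_panel"}: p_A,
#'   p_B, ancestral_p, F_div) and \code{$gm} (a \code{genotype_matrix}
#'   of the 2 x n_per_pop reference individuals).
#' @export
simulate_reference_pops <- function(n_loci, n_per_pop = 40L, F_div,
                                    seed = 1L, anc_range = c(0.05, 0.95),
                                    pop_names = c("popA", "popB")) {
  stopifnot(n_loci >= 1L, n_per_pop >= 2L)
  if (!(F_div > 0 && F_div < 1)) stop("F_div must lie strictly in (0, 1)")
  set.seed(seed)
  anc <- stats::runif(n_loci, anc_range[1L], anc_range[2L])
  shape <- (1 - F_div) / F_div
  p_A <- stats::rbeta(n_loci, anc * shape, (1 - anc) * shape)
  p_B <- stats::rbeta(n_loci, anc * shape, (1 - anc) * shape)
  loci <- sprintf("locus_%04d", seq_len(n_loci))
  calls <- rbind(
    matrix(stats::rbinom(n_per_pop * n_loci, 2L, rep(p_A, each = n_per_pop)),
           n_per_pop, n_loci),
    matrix(stats::rbinom(n_per_pop * n_loci, 2L, rep(p_B, each = n_per_pop)),
           n_per_pop, n_loci))
  dimnames(calls) <- list(
    c(sprintf("%s_%03d", pop_names[1L], seq_len(n_per_pop)),
      sprintf("%s_%03d", pop_names[2L], seq_len(n_per_pop))), loci)
  panel <- structure(list(p_A = stats::setNames(p_A, loci),
                          p_B = stats::setNames(p_B, loci),
                          ancestral_p = stats::setNames(anc, loci),
                          F_div = F_div, n_loci = n_loci,
                          pop_names = pop_names),
                     class = "reference_panel")
  gm <- genotype_matrix(calls, pop = rep(pop_names, each = n_per_pop))
  list(panel = panel, gm = gm)
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference_panel: %d loci, F_div = %.3f (%s vs %s)\n",
              x$n_loci, x$F_div, x$pop_names[1L], x$pop_names[2L]))
  cat(sprintf("mean |p_A - p_B| = %.3f\n", mean(abs(x$p_A - x$p_B))))
  invisible(x)
}

#' The six hybrid classes
#'
#' @return character vector: PureA, PureB, F1, F2, BCA, BCB (the two pure
#'   parental classes, first- and second-generation hybrids, and the two
#'   first-generation backcrosses).
#' @export
hybrid_classes <- function() c("PureA", "PureB", "F1", "F2", "BCA", "BCB")

# Frequencies of a reference panel, or estimated from an observed
# two-population reference genotype matrix (point estimates).
panel_freqs <- function(ref) {
  if (inherits(ref, "reference_panel"))
    return(list(p_A = ref$p_A, p_B = ref$p_B))
  if (inherits(ref, "genotype_matrix")) {
    pops <- sort(unique(ref$pop))
    if (length(pops) != 2L)
      stop("reference genotype matrix must hold exactly two populations")
    pf <- allele_freqs(ref, by = "pop")
    return(list(p_A = pf[1L, ], p_B = pf[2L, ]))
  }
  stop("ref must be a reference_panel or a genotype_matrix")
}

#' Simulate Mendelian hybrid classes
#'
#' Draws individuals of the requested hybrid classes from per-locus
#' reference allele frequencies, locus by locus (unlinked loci):
#' pure individuals are two independent gametes from their population's
#' frequencies; an F1 takes one gamete from each population; an F2 takes
#' one gamete from each of two independently simulated F1 parents (an F1
#' gamete carries the A-derived or the B-derived allele with probability
#' 1/2); a backcross takes one F1 gamete plus one pure-population gamete.
#'
#' @param ref a \code{"reference_panel"} or an observed two-population
#'   reference \code{genotype_matrix} (allele frequencies taken as point
#'   estimates).
#' @param n_per_class individuals per simulated class.
#' @param classes subset of \code{\link{hybrid_classes}()}.
#' @param seed integer seed.
#' @return list with \code{$gm} (a \code{genotype_matrix}; populations
#'   labelled by true class) and \code{$labels} (character vector of true
#'   classes).
#' @export
simulate_hybrid_classes <- function(ref, n_per_class,
                                    classes = hybrid_classes(), seed = 1L) {
  bad <- setdiff(classes, hybrid_classes())
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  fr <- panel_freqs(ref)
  set.seed(seed)
  n_vec <- stats::setNames(rep(n_per_class, length(classes)), classes)
  sim <- simulate_class_counts(fr$p_A, fr$p_B, n_vec)
  sim
}

# workhorse: named vector of class sizes -> genotype matrix + labels
simulate_class_counts <- function(p_A, p_B, n_vec) {
  L <- length(p_A)
  loci <- names(p_A)
  if (is.null(loci)) loci <- sprintf("locus_%04d", seq_len(L))
  gam_pure <- function(n, p)          # n x L gametes from population freqs
    matrix(stats::rbinom(n * L, 1L, rep(p, each = n)), n, L)
  gam_F1 <- function(n) {
    # each F1 parent carries one A-derived and one B-derived allele per
    # locus; its gamete passes one of the two with probability 1/2
    a_allele <- gam_pure(n, p_A)
    b_allele <- gam_pure(n, p_B)
    from_a <- matrix(stats::runif(n * L) < 0.5, n, L)
    ifelse(from_a, a_allele, b_allele)
  }
  draw <- function(cls, n) {
    if (n == 0L) return(matrix(0L, 0L, L))
    switch(cls,
           PureA = gam_pure(n, p_A) + gam_pure(n, p_A),
           PureB = gam_pure(n, p_B) + gam_pure(n, p_B),
           F1    = gam_pure(n, p_A) + gam_pure(n, p_B),
           F2    = gam_F1(n) + gam_F1(n),
           BCA   = gam_F1(n) + gam_pure(n, p_A),
           BCB   = gam_F1(n) + gam_pure(n, p_B))
  }
  mats <- lapply(names(n_vec), function(cl) draw(cl, n_vec[[cl]]))
  calls <- do.call(rbind, mats)
  labels <- rep(names(n_vec), times = n_vec)
  rownames(calls) <- sprintf("%s_%04d", labels,
                             unlist(lapply(n_vec, seq_len), use.names = FALSE))
  colnames(calls) <- loci
  list(gm = genotype_matrix(calls, pop = labels), labels = labels)
}

#' Build labelled datasets for the power study
#'
#' Replicated simulated datasets with (near-)equal numbers of the six
#' hybrid classes, the layout used to calibrate assignment power
#' (by default 3 replicates x 3 datasets of 288 individuals = 48 per
#' class). When \code{n_individuals} is not divisible by the number of
#' classes the remainder is spread round-robin over the first classes.
#'
#' @param ref a \code{"reference_panel"} or two-population reference
#'   \code{genotype_matrix}.
#' @param n_individuals individuals per dataset (default 288).
#' @param n_datasets independent datasets per replicate (default 3).
#' @param n_replicates replicates (default 3).
#' @param classes classes included (default all six).
#' @param seed integer seed; each (replicate, dataset) uses a distinct
#'   derived sub-seed.
#' @return list of length \code{n_replicates * n_datasets}; each element
#'   has \code{$gm}, \code{$labels}, \code{$replicate}, \code{$dataset},
#'   \code{$seed}.
#' @export
build_power_datasets <- function(ref, n_individuals = 288L, n_datasets = 3L,
                                 n_replicates = 3L,
                                 classes = hybrid_classes(), seed = 1L) {
  k <- length(classes)
  base <- n_individuals %/% k
  n_vec <- stats::setNames(rep(base, k), classes)
  extra <- n_individuals - base * k
  if (extra > 0L) n_vec[seq_len(extra)] <- n_vec[seq_len(extra)] + 1L
  fr <- panel_freqs(ref)
  out <- vector("list", n_replicates * n_datasets)
  i <- 0L
  for (r in seq_len(n_replicates)) for (d in seq_len(n_datasets)) {
    i <- i + 1L
    sub_seed <- (seed + 7919L * r + 104729L * d) %% .Machine$integer.max
    set.seed(sub_seed)
    sim <- simulate_class_counts(fr$p_A, fr$p_B, n_vec)
    out[[i]] <- list(gm = sim$gm, labels = sim$labels,
                     replicate = r, dataset = d, seed = sub_seed)
  }
  out
}
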