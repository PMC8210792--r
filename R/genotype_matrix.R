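#' Construct a genotype matrix
#'
#' The central container of the package: an individuals-by-loci matrix of
#' biallelic genotype calls coded as the count of the reference allele
#' (0, 1, 2; \code{NA} = missing), together with per-sample population and
#' optional geographic-group labels and optional per-locus contig
#' identifiers. The reference allele is whichever allele was listed first in
#' the source file; every downstream frequency refers to it.
#'
#' @param calls numeric or integer matrix, samples in rows and loci in
#'   columns; entries must be 0, 1, 2 or \code{NA}. Row names are sample ids,
#'   column names locus ids (generated when absent).
#' @param pop character vector of population labels, one per sample.
#' @param group optional character vector of geographic-group labels, one per
#'   sample; must be constant within each population.
#' @param contig optional character vector of contig ids, one per locus.
#' @return an object of class \code{"genotype_matrix"}.
#' @examples
#' gm <- genotype_matrix(rbind(s1 = c(L1 = 0, L2 = 2), s2 = c(1, 1)),
#'                       pop = c("A", "B"))
#' dim(gm)
#' @export
genotype_matrix <- function(calls, pop, group = NULL, contig = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("ind_", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("locus_", seq_len(ncol(calls)))
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad))
    stop("genotype calls must be 0, 1, 2 or NA; offending entry at row ",
         which(bad, arr.ind = TRUE)[1, 1])
  if (anyDuplicated(rownames(calls)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(calls)[duplicated(rownames(calls))]), collapse = ", "))
  if (anyDuplicated(colnames(calls)))
    stop("duplicate locus ids: ",
         paste(unique(colnames(calls)[duplicated(colnames(calls))]), collapse = ", "))
  pop <- as.character(pop)
  if (length(pop) != nrow(calls))
    stop("length(pop) must equal the number of samples")
  if (anyNA(pop)) stop("every sample needs a population label")
  if (!is.null(group)) {
    group <- as.character(group)
    if (length(group) != nrow(calls))
      stop("length(group) must equal the number of samples")
    # a population must sit in exactly one geographic group
    per_pop <- tapply(group, pop, function(g) length(unique(g)))
    if (any(per_pop > 1))
      stop("population(s) assigned to multiple groups: ",
           paste(names(per_pop)[per_pop > 1], collapse = ", "))
  }
  if (!is.null(contig)) {
    contig <- as.character(contig)
    if (length(contig) != ncol(calls))
      stop("length(contig) must equal the number of loci")
  }
  structure(list(calls = calls, pop = pop, group = group, contig = contig),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param x a \code{genotype_matrix}.
#' @param i,j sample and locus indices (any form accepted by matrix
#'   subsetting).
#' @param ... unused.
#' @return a \code{genotype_matrix} restricted to the selected samples/loci.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  if (is.character(i)) i <- match(i, rownames(x$calls))
  if (is.character(j)) j <- match(j, colnames(x$calls))
  if (is.logical(i)) i <- which(i)
  if (is.logical(j)) j <- which(j)
  genotype_matrix(x$calls[i, j, drop = FALSE],
                  pop    = x$pop[i],
                  group  = if (!is.null(x$group)) x$group[i],
                  contig = if (!is.null(x$contig)) x$contig[j])
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci\n",
              nrow(x$calls), ncol(x$calls)))
  tb <- table(x$pop)
  cat("populations:",
      paste(sprintf("%s (n=%d)", names(tb), as.integer(tb)), collapse = ", "),
      "\n")
  if (!is.null(x$group))
    cat("groups:", paste(unique(x$group), collapse = ", "), "\n")
  cat(sprintf("missing calls: %.2f%%\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
summary.genotype_matrix <- function(object, ...) {
  calls <- object$calls
  out <- list(
    n_samples  = nrow(calls),
    n_loci     = ncol(calls),
    pops       = table(object$pop),
    missing    = mean(is.na(calls)),
    het        = mean(calls == 1L, na.rm = TRUE),
    freq_range = range(allele_freqs(object), na.rm = TRUE)
  )
  class(out) <- "summary.genotype_matrix"
  out
}

#' @export
print.summary.genotype_matrix <- function(x, ...) {
  cat(sprintf("%d samples x %d loci; %.2f%% missing; %.1f%% heterozygous calls\n",
              x$n_samples, x$n_loci, 100 * x$missing, 100 * x$het))
  cat(sprintf("reference-allele frequency range: %.3f-%.3f\n",
              x$freq_range[1], x$freq_range[2]))
  print(x$pops)
  invisible(x)
}

sample_ids <- function(gm) rownames(gm$calls)
locus_ids  <- function(gm) colnames(gm$calls)

#' Per-locus reference-allele frequencies
#'
#' @param gm a \code{genotype_matrix}.
#' @param by \code{"all"} for pooled frequencies, \code{"pop"} for a
#'   population-by-locus matrix.
#' @return numeric vector (pooled) or matrix with one row per population.
#' @export
allele_freqs <- function(gm, by = c("all", "pop")) {
  by <- match.arg(by)
  if (by == "all")
    return(colMeans(gm$calls, na.rm = TRUE) / 2)
  pops <- sort(unique(gm$pop))
  out <- t(vapply(pops, function(p)
    colMeans(gm$calls[gm$pop == p, , drop = FALSE], na.rm = TRUE) / 2,
    numeric(ncol(gm$calls))))
  rownames(out) <- pops
  out
}

#' Per-sample metadata table
#'
#' A plain data frame holding the optional per-individual covariates used by
#' downstream stages (transect position for cline fitting, technical
#' replicate pairing for concordance QC, age/length/sex for tabulation).
#'
#' @param sample_id character vector of sample ids.
#' @param collection_year,transect_distance,age,length,sex,replicate_of
#'   optional per-sample columns; \code{transect_distance} is kilometres
#'   along the coastal transect and must be non-negative;
#'   \code{replicate_of} names the technical-replicate partner.
#' @return a \code{data.frame} of class \code{"sample_metadata"}.
#' @export
sample_metadata <- function(sample_id, collection_year = NA_integer_,
                            transect_distance = NA_real_, age = NA_real_,
                            length = NA_real_, sex = NA_character_,
                            replicate_of = NA_character_) {
  df <- data.frame(sample_id = as.character(sample_id),
                   collection_year = collection_year,
                   transect_distance = transect_distance,
                   age = age, length = length, sex = sex,
                   replicate_of = as.character(replicate_of),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  if (any(df$transect_distance < 0, na.rm = TRUE))
    stop("transect_distance must be >= 0")
  ref <- df$replicate_of[!is.na(df$replicate_of)]
  if (!all(ref %in% df$sample_id))
    stop("replicate_of refers to unknown sample id(s): ",
         paste(setdiff(ref, df$sample_id), collapse = ", "))
  class(df) <- c("sample_metadata", "data.frame")
  df
}
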