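#' Site-level QC filter
#'
#' Removes loci with too much missing data or an excess of heterozygotes
#' (a heterozygote fraction above 0.5 flags possibly lumped paralogs).
#' A locus is retained iff its missing fraction is \code{<= max_missing}
#' AND its heterozygote fraction among non-missing calls is
#' \code{<= max_het}. The sample set is unchanged.
#'
#' @param gm a \code{genotype_matrix}.
#' @param max_missing maximum tolerated missing-call fraction per locus
#'   (default 0.1).
#' @param max_het maximum tolerated heterozygote fraction per locus
#'   (default 0.5).
#' @return the filtered \code{genotype_matrix}, with attribute
#'   \code{"removed"}: a data frame of removed loci, their missing and
#'   heterozygote fractions, and the rule that fired.
#' @export
filter_sites <- function(gm, max_missing = 0.1, max_het = 0.5) {
  stopifnot(max_missing >= 0, max_missing <= 1, max_het >= 0, max_het <= 1)
  if (nrow(gm$calls) == 0L || ncol(gm$calls) == 0L)
    stop("empty genotype matrix")
  miss <- colMeans(is.na(gm$calls))
  het  <- colMeans(gm$calls == 1L, na.rm = TRUE)
  het[is.nan(het)] <- 0                      # locus with zero non-missing calls
  keep <- miss <= max_missing & het <= max_het
  removed <- data.frame(locus_id = colnames(gm$calls)[!keep],
                        missing_frac = miss[!keep], het_frac = het[!keep],
                        reason = ifelse(miss[!keep] > max_missing,
                                        "missing", "heterozygote_excess"),
                        row.names = NULL, stringsAsFactors = FALSE)
  out <- gm[, keep]
  attr(out, "removed") <- removed
  out
}

#' Individual-level QC filter
#'
#' Removes individuals whose missing-call fraction exceeds
#' \code{max_missing}.
#'
#' @param gm a \code{genotype_matrix}.
#' @param max_missing maximum tolerated missing fraction per individual
#'   (default 0.2).
#' @return the filtered \code{genotype_matrix} with attribute
#'   \code{"removed"}: data frame of removed samples and their missing
#'   fractions.
#' @export
filter_individuals <- function(gm, max_missing = 0.2) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  if (nrow(gm$calls) == 0L || ncol(gm$calls) == 0L)
    stop("empty genotype matrix")
  miss <- rowMeans(is.na(gm$calls))
  keep <- miss <= max_missing
  if (!any(keep))
    stop("max_missing = ", max_missing, " removes every individual")
  removed <- data.frame(sample_id = rownames(gm$calls)[!keep],
                        missing_frac = miss[!keep],
                        row.names = NULL, stringsAsFactors = FALSE)
  out <- gm[keep, ]
  attr(out, "removed") <- removed
  out
}

#' Technical-replicate concordance QC
#'
#' Scores genotyping robustness from technical replicate pairs declared in
#' the sample metadata (\code{replicate_of}). Per locus, a pair is
#' discordant when both of its calls are non-missing and unequal; loci with
#' more than \code{max_discordant} discordant pairs are removed. One member
#' of each pair is then dropped, keeping the member with fewer missing
#' calls (ties: the lexicographically first sample id).
#'
#' @param gm a \code{genotype_matrix}.
#' @param meta a \code{\link{sample_metadata}} data frame with
#'   \code{replicate_of} set for the duplicate member of each pair.
#' @param max_discordant maximum tolerated discordant pairs per locus
#'   (default 2).
#' @return the filtered \code{genotype_matrix} with attributes
#'   \code{"discordance"} (per-locus data frame: discordant pair count,
#'   pairs compared, removed flag) and \code{"dropped_replicates"}.
#' @export
replicate_concordance <- function(gm, meta, max_discordant = 2L) {
  rep_rows <- meta[!is.na(meta$replicate_of), , drop = FALSE]
  if (nrow(rep_rows) == 0L) stop("no replicate pairs declared in metadata")
  pairs <- cbind(rep_rows$sample_id, rep_rows$replicate_of)
  if (any(pairs[, 1L] == pairs[, 2L]))
    stop("replicate_of cycle: a sample declared as its own replicate")
  # two-step (or longer) chains count as cycles for this pairwise design
  if (any(pairs[, 2L] %in% pairs[, 1L]))
    stop("replicate_of cycle or chain: ",
         paste(intersect(pairs[, 2L], pairs[, 1L]), collapse = ", "))
  present <- pairs[, 1L] %in% rownames(gm$calls) &
             pairs[, 2L] %in% rownames(gm$calls)
  pairs <- pairs[present, , drop = FALSE]
  if (nrow(pairs) == 0L) stop("no replicate pair has both members genotyped")

  g1 <- gm$calls[pairs[, 1L], , drop = FALSE]
  g2 <- gm$calls[pairs[, 2L], , drop = FALSE]
  disc <- colSums(!is.na(g1) & !is.na(g2) & g1 != g2)
  compared <- colSums(!is.na(g1) & !is.na(g2))
  keep_locus <- disc <= max_discordant

  drop_ids <- character(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    m <- rowSums(is.na(gm$calls[pairs[k, ], , drop = FALSE]))
    keep_id <- if (m[1L] != m[2L]) pairs[k, which.min(m)] else
      sort(pairs[k, ])[1L]
    drop_ids[k] <- setdiff(pairs[k, ], keep_id)
  }
  out <- gm[!(rownames(gm$calls) %in% drop_ids), keep_locus]
  attr(out, "discordance") <- data.frame(
    locus_id = colnames(gm$calls), discordant_pairs = as.integer(disc),
    pairs_compared = as.integer(compared), removed = !keep_locus,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "dropped_replicates") <- drop_ids
  out
}
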