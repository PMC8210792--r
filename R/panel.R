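#' Rank loci by pairwise F_ST against a focal population
#'
#' Per-locus Weir-Cockerham theta for each (focal, comparison) population
#' pair, sorted descending. Ties — and loci with undefined theta, ranked
#' last — are broken lexicographically by locus id, so the ranking is
#' deterministic and invariant to locus input order.
#'
#' @param gm a \code{genotype_matrix}.
#' @param focal_pop focal population label (the import region).
#' @param comparison_pops labels of the populations compared against the
#'   focal one (the export region).
#' @return named list of data frames (one per comparison) with columns
#'   locus_id, theta, rank.
#' @export
rank_loci <- function(gm, focal_pop, comparison_pops) {
  pops <- unique(gm$pop)
  missing_pops <- setdiff(c(focal_pop, comparison_pops), pops)
  if (length(missing_pops))
    stop("population(s) not in data: ", paste(missing_pops, collapse = ", "))
  out <- list()
  for (cp in comparison_pops) {
    sel <- gm$pop %in% c(focal_pop, cp)
    if (sum(gm$pop == focal_pop) < 2L || sum(gm$pop == cp) < 2L)
      stop("both populations of a pair need >= 2 individuals")
    comp <- wc_components(gm$calls[sel, , drop = FALSE], gm$pop[sel])
    th <- comp$theta
    ord <- order(-ifelse(is.finite(th), th, -Inf), comp$loci)
    out[[paste(focal_pop, cp, sep = ":")]] <-
      data.frame(locus_id = comp$loci[ord], theta = th[ord],
                 rank = seq_along(ord), row.names = NULL,
                 stringsAsFactors = FALSE)
  }
  out
}

#' Select a diagnostic SNP panel
#'
#' Intersects the top-K loci of every ranked pairwise comparison, then
#' keeps the subset whose theta is at least \code{min_fst} in every
#' comparison. The number of distinct contigs represented is reported when
#' locus metadata carries contig ids.
#'
#' @param ranked output of \code{\link{rank_loci}}.
#' @param top_k number of top-ranked loci considered per comparison
#'   (default 500).
#' @param min_fst absolute per-comparison theta threshold applied to the
#'   intersection (default 0.4).
#' @param contig optional named character vector mapping locus ids to
#'   contigs.
#' @return object of class \code{"panel_selection"}: \code{$intersection}
#'   (loci in every top-K list, lexicographic order),
#'   \code{$panel} (thresholded subset), \code{$contig_count},
#'   \code{$ranked}, \code{$top_k}, \code{$min_fst}.
#' @export
select_panel <- function(ranked, top_k = 500L, min_fst = 0.4, contig = NULL) {
  stopifnot(length(ranked) >= 1L)
  if (top_k > nrow(ranked[[1L]]))
    stop("top_k exceeds the number of ranked loci")
  tops <- lapply(ranked, function(df) df$locus_id[seq_len(top_k)])
  inter <- sort(Reduce(intersect, tops))
  if (!length(inter))
    warning("empty intersection of the top-", top_k, " lists")
  theta_of <- function(df) stats::setNames(df$theta, df$locus_id)
  keep <- inter
  for (df in ranked) {
    th <- theta_of(df)[keep]
    keep <- keep[!is.na(th) & th >= min_fst]
  }
  cc <- if (!is.null(contig)) length(unique(contig[keep])) else NA_integer_
  structure(list(intersection = inter, panel = keep, contig_count = cc,
                 ranked = ranked, top_k = top_k, min_fst = min_fst),
            class = "panel_selection")
}

#' @export
print.panel_selection <- function(x, ...) {
  cat(sprintf("panel_selection: %d comparisons, top-%d intersection = %d loci",
              length(x$ranked), x$top_k, length(x$intersection)))
  cat(sprintf(", %d at theta >= %.2f in every comparison\n",
              length(x$panel), x$min_fst))
  if (!is.na(x$contig_count))
    cat(sprintf("panel spans %d contigs\n", x$contig_count))
  invisible(x)
}
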