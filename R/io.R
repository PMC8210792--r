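#' Read a biallelic genotype matrix
#'
#' Reads SNP genotypes from one of three dialects into a
#' \code{\link{genotype_matrix}}. Loci must be biallelic; a locus showing
#' more than two alleles raises an error naming the locus. The reference
#' allele is taken from the file, per locus (the REF column in VCF, the
#' smallest allele code in Genepop, the count-coded allele in TSV), and all
#' downstream allele frequencies refer to it.
#'
#' Supported formats:
#' \describe{
#'   \item{\code{genepop}}{title line, locus names (one per line or one
#'     comma-separated line), \code{Pop} separators, and
#'     \code{id , 0101 0202 ...} individual lines; both 2-digit and 3-digit
#'     allele codes are accepted and \code{00}/\code{000} is missing.}
#'   \item{\code{tsv}}{tab-separated matrix with header
#'     \code{sample_id<TAB>pop_label<TAB><locus ids...>} and entries 0/1/2
#'     or \code{NA} (empty also accepted as missing).}
#'   \item{\code{vcf}}{a VCF whose GT field is used; multi-allelic records
#'     are rejected.}
#' }
#'
#' @param path path to the input file.
#' @param format one of \code{"genepop"}, \code{"tsv"}, \code{"vcf"}.
#' @return a \code{genotype_matrix}. For Genepop input the population label
#'   of each \code{Pop} block is the id of its last individual (the format's
#'   convention); for VCF input all samples get population label
#'   \code{"pop1"} unless relabelled afterwards.
#' @export
read_genotypes <- function(path, format = c("genepop", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         genepop = read_genepop(path),
         tsv     = read_tsv_matrix(path),
         vcf     = read_vcf_matrix(path))
}

read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) == 1L]
  if (length(lines) < 3L) stop("parse error: Genepop file too short: ", path)
  body <- lines[-1L]                       # drop title line
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_idx) == 0L)
    stop("parse error at line ", length(lines), ": no 'Pop' line found")
  locus_lines <- body[seq_len(pop_idx[1L] - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (anyDuplicated(loci)) stop("parse error: duplicate locus names")

  ids <- character(0); pops <- character(0)
  rows <- list(); block <- 0L; block_ids <- list()
  for (k in seq(pop_idx[1L], length(body))) {
    ln <- body[k]
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) {
      block <- block + 1L
      block_ids[[block]] <- integer(0)
      next
    }
    parts <- strsplit(ln, ",")[[1L]]
    if (length(parts) < 2L)
      stop("parse error at line ", k + 1L, ": expected 'id , genotypes'")
    id <- trimws(parts[1L])
    geno <- strsplit(trimws(paste(parts[-1L], collapse = " ")), "\\s+")[[1L]]
    if (length(geno) != length(loci))
      stop("parse error at line ", k + 1L, ": ", length(geno),
           " genotypes for ", length(loci), " loci")
    ids <- c(ids, id)
    block_ids[[block]] <- c(block_ids[[block]], length(ids))
    rows[[length(ids)]] <- geno
  }
  # Genepop convention: a population is named after its last listed member
  pops <- character(length(ids))
  for (b in seq_len(block)) {
    memb <- block_ids[[b]]
    if (length(memb)) pops[memb] <- ids[memb[length(memb)]]
  }
  # decode 2x2-digit or 2x3-digit strings into per-locus allele pairs
  n <- length(ids); L <- length(loci)
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    g <- rows[[i]]
    w <- nchar(g)
    digits <- ifelse(w == 4L, 2L, ifelse(w == 6L, 3L, NA_integer_))
    if (anyNA(digits))
      stop("parse error: genotype '", g[which(is.na(digits))[1L]],
           "' for ", ids[i], " is neither 4 nor 6 digits")
    x1 <- as.integer(substr(g, 1L, digits))
    x2 <- as.integer(substr(g, digits + 1L, 2L * digits))
    x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
    # half-missing genotypes are treated as missing calls
    miss <- is.na(x1) | is.na(x2)
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    a1[i, ] <- x1; a2[i, ] <- x2
  }
  calls <- matrix(NA_integer_, n, L, dimnames = list(ids, loci))
  for (l in seq_len(L)) {
    alleles <- c(rbind(a1[, l], a2[, l]))   # file order: ind 1 allele 1, 2, ...
    seen <- unique(alleles[!is.na(alleles)])
    if (length(seen) > 2L)
      stop("locus ", loci[l], " is not biallelic (",
           length(seen), " alleles observed)")
    if (length(seen) == 0L) next
    # standard 01/02 coding: allele 1 is the reference even when absent
    # (a locus monomorphic for allele 2 then reads as all zero copies);
    # other codings fall back to the smallest observed code
    ref <- if (all(seen %in% 1:2)) 1L else min(seen)
    calls[, l] <- (a1[, l] == ref) + (a2[, l] == ref)
  }
  genotype_matrix(calls, pop = pops)
}

read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(df) < 3L || names(df)[1L] != "sample_id" || names(df)[2L] != "pop_label")
    stop("parse error: TSV must start with columns sample_id, pop_label")
  calls <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(calls) <- "integer"
  rownames(calls) <- df$sample_id
  genotype_matrix(calls, pop = df$pop_label)
}

read_vcf_matrix <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi))
    stop("locus ", fix[multi, "ID"][1L], " is not biallelic (multi-allelic ALT)")
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  count_ref <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- !is.na(x) & !grepl("\\.", x)
    al <- strsplit(gsub("\\|", "/", x[ok]), "/")
    out[ok] <- vapply(al, function(a) sum(a == "0"), integer(1))
    out
  }
  calls <- t(vapply(colnames(gt),
                    function(s) count_ref(gt[, s]),
                    integer(nrow(gt))))   # samples x loci
  dimnames(calls) <- list(colnames(gt), ids)
  genotype_matrix(calls, pop = rep("pop1", nrow(calls)),
                  contig = fix[, "CHROM"])
}

#' Write a genotype matrix
#'
#' Inverse of \code{\link{read_genotypes}} for the same three dialects;
#' write-then-read round-trips calls, sample ids and locus ids exactly.
#' Genepop output uses 2-digit allele codes (reference allele = 01); VCF
#' output uses placeholder REF/ALT alleles A and C.
#'
#' @param gm a \code{genotype_matrix}.
#' @param path output path.
#' @param format one of \code{"genepop"}, \code{"tsv"}, \code{"vcf"}.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("genepop", "tsv", "vcf")) {
  format <- match.arg(format)
  calls <- gm$calls
  if (format == "tsv") {
    df <- data.frame(sample_id = rownames(calls), pop_label = gm$pop,
                     calls, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "genepop") {
    code <- matrix("0000", nrow(calls), ncol(calls))
    code[!is.na(calls) & calls == 2L] <- "0101"
    code[!is.na(calls) & calls == 1L] <- "0102"
    code[!is.na(calls) & calls == 0L] <- "0202"
    con <- file(path, "w"); on.exit(close(con))
    writeLines("hybridscan genepop export", con)
    writeLines(colnames(calls), con)
    for (p in unique(gm$pop)) {
      writeLines("Pop", con)
      for (i in which(gm$pop == p))
        writeLines(paste0(rownames(calls)[i], " ,  ",
                          paste(code[i, ], collapse = " ")), con)
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##source=hybridscan",
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", rownames(calls)),
                       collapse = "\t")), con)
    gt_of <- c(`0` = "1/1", `1` = "0/1", `2` = "0/0")
    contig <- if (!is.null(gm$contig)) gm$contig else rep("chr1", ncol(calls))
    for (l in seq_len(ncol(calls))) {
      g <- calls[, l]
      gt <- ifelse(is.na(g), "./.", gt_of[as.character(g)])
      writeLines(paste(c(contig[l], l, colnames(calls)[l], "A", "C", ".",
                         ".", ".", "GT", gt), collapse = "\t"), con)
    }
  }
  invisible(path)
}
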