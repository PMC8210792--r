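test_that("genotype_matrix validates calls, labels and duplicates", {
  gm <- genotype_matrix(rbind(s1 = c(L1 = 0L, L2 = 2L), s2 = c(1L, 1L)),
                        pop = c("A", "B"))
  expect_identical(dim(gm), c(2L, 2L))
  expect_error(genotype_matrix(matrix(3L, 1, 1), pop = "A"), "0, 1, 2")
  expect_error(genotype_matrix(matrix(0L, 2, 1,
                                      dimnames = list(c("x", "x"), "L")),
                               pop = c("A", "A")), "duplicate sample")
  expect_error(genotype_matrix(matrix(0L, 2, 1), pop = c("A", "A"),
                               group = c("g1", "g2")), "multiple groups")
})

test_that("TSV round-trip is the identity on calls and ids", {
  calls <- rbind(s1 = c(L1 = 0L, L2 = 2L), s2 = c(1L, NA))
  gm <- genotype_matrix(calls, pop = c("A", "B"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gm, path, "tsv")
  back <- read_genotypes(path, "tsv")
  expect_identical(back$calls, gm$calls)
  expect_identical(back$pop, gm$pop)
})

test_that("every supported format round-trips calls, sample and locus ids", {
  set.seed(42)
  calls <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 6, 10,
                  dimnames = list(sprintf("ind%02d", 1:6),
                                  sprintf("SNP_%02d", 1:10)))
  gm <- genotype_matrix(calls, pop = rep(c("P1", "P2"), each = 3))
  for (fmt in c("tsv", "genepop", "vcf")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_genotypes(gm, path, fmt)
    back <- read_genotypes(path, fmt)
    expect_identical(back$calls, gm$calls, label = fmt)
  }
})

test_that("Genepop dialect: 00/000 codes are missing calls, both digit widths parse", {
  path <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy", "locA", "locB", "Pop",
               "fishA1 , 0101 0000",
               "fishA2 , 0102 0202",
               "Pop",
               "fishB1 , 0202 0101"), path)
  gm <- read_genotypes(path, "genepop")
  expect_true(is.na(gm$calls["fishA1", "locB"]))
  expect_identical(gm$calls["fishA1", "locA"], 2L)
  expect_identical(gm$calls["fishA2", "locA"], 1L)
  expect_identical(gm$calls["fishB1", "locA"], 0L)

  path3 <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy3", "locA", "Pop",
               "x1 , 001002", "x2 , 000000"), path3)
  gm3 <- read_genotypes(path3, "genepop")
  expect_identical(gm3$calls["x1", "locA"], 1L)
  expect_true(is.na(gm3$calls["x2", "locA"]))
})

test_that("multi-allelic loci are rejected with the locus named", {
  path <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy", "locA", "Pop",
               "x1 , 0102", "x2 , 0303"), path)
  expect_error(read_genotypes(path, "genepop"), "locA.*not biallelic")

  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
               "chr1\t10\trs1\tA\tC,G\t.\t.\t.\tGT\t0/1\t1/2"), vcf)
  expect_error(read_genotypes(vcf, "vcf"), "not biallelic")
})

test_that("site filter removes loci by missingness and heterozygote excess", {
  # 10 samples; locus m2 has 2/10 missing, locus h6 has 6/10 heterozygotes
  calls <- cbind(ok = rep(c(0L, 2L), 5),
                 m2 = c(rep(0L, 8), NA, NA),
                 h6 = c(rep(1L, 6), rep(0L, 4)))
  rownames(calls) <- sprintf("s%02d", 1:10)
  gm <- genotype_matrix(calls, pop = rep("A", 10))
  out <- filter_sites(gm, max_missing = 0.10, max_het = 0.5)
  expect_identical(colnames(out$calls), "ok")
  rem <- attr(out, "removed")
  expect_setequal(rem$locus_id, c("m2", "h6"))
  expect_equal(rem$missing_frac[rem$locus_id == "m2"], 0.2)
  expect_equal(rem$het_frac[rem$locus_id == "h6"], 0.6)
  # fully called homozygous matrix passes untouched; filter is idempotent
  gm2 <- genotype_matrix(matrix(rep(c(0L, 2L), 10), 4, 5), pop = rep("A", 4))
  expect_identical(filter_sites(gm2, 0.1, 0.5)$calls, gm2$calls)
  again <- filter_sites(out, max_missing = 0.10, max_het = 0.5)
  expect_identical(again$calls, out$calls)
})

test_that("individual filter enforces the missingness threshold exactly", {
  calls <- matrix(0L, 3, 100,
                  dimnames = list(c("keep20", "drop21", "full"), NULL))
  calls["keep20", 1:20] <- NA
  calls["drop21", 1:21] <- NA
  gm <- genotype_matrix(calls, pop = rep("A", 3))
  out <- filter_individuals(gm, max_missing = 0.20)
  expect_setequal(rownames(out$calls), c("keep20", "full"))
  expect_identical(attr(out, "removed")$sample_id, "drop21")
  # boundary: zero tolerance removes any individual with a missing call
  out0 <- filter_individuals(gm, max_missing = 0)
  expect_identical(rownames(out0$calls), "full")
  expect_error(filter_individuals(gm[1:2, ], max_missing = 0),
               "every individual")
})

test_that("replicate concordance counts discordant pairs and drops duplicates", {
  calls <- rbind(
    a  = c(0L, 1L, 2L), a_r = c(0L, 2L, 2L),
    b  = c(1L, 0L, NA), b_r = c(1L, 2L, 0L),
    c  = c(2L, 1L, 1L), c_r = c(2L, 0L, 1L),
    d  = c(0L, 0L, 0L))
  colnames(calls) <- c("L1", "L2", "L3")
  gm <- genotype_matrix(calls, pop = rep("P", 7))
  meta <- sample_metadata(rownames(calls),
                          replicate_of = c(NA, "a", NA, "b", NA, "c", NA))
  out <- replicate_concordance(gm, meta, max_discordant = 2)
  disc <- attr(out, "discordance")
  # L2 discordant in all 3 pairs -> removed; L3 pair b has a missing call
  expect_identical(disc$discordant_pairs, c(0L, 3L, 0L))
  expect_identical(colnames(out$calls), c("L1", "L3"))
  # one member per pair kept: b has a missing call, so b_r wins that pair;
  # the a/a_r and c/c_r ties resolve to the lexicographically first id
  expect_setequal(rownames(out$calls), c("a", "b_r", "c", "d"))
  meta_bad <- sample_metadata(c("a", "b"), replicate_of = c("b", "a"))
  expect_error(replicate_concordance(gm[1:4, ], meta_bad, 2), "cycle")
})

test_that("per-locus missing fraction identity holds on random matrices", {
  set.seed(7)
  for (rep in 1:5) {
    calls <- matrix(sample(c(0:2, NA), 200, replace = TRUE,
                           prob = c(.3, .3, .3, .1)), 20, 10)
    gm <- genotype_matrix(calls, pop = rep("A", 20))
    expect_equal(colMeans(is.na(gm$calls)),
                 1 - colSums(!is.na(gm$calls)) / nrow(gm$calls))
  }
})
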