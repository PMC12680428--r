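test_that("PED parsing counts the panel minor allele and maps 0 0 to missing", {
  dir <- withr::local_tempdir()
  writeLines(c("F1 ind1 0 0 0 -9 A A G G",
               "F1 ind2 0 0 0 -9 A G 0 0"),
             file.path(dir, "toy.ped"))
  writeLines(c("1\tsnp1\t0\t1", "1\tsnp2\t0\t2"), file.path(dir, "toy.map"))
  pm <- data.frame(individual = c("ind1", "ind2"),
                   population = c("p1", "p1"))
  G <- load_genotypes(file.path(dir, "toy.ped"), "ped", pm)
  # snp1: alleles A A / A G -> G is minor (1 of 4), dosages 0 and 1
  expect_equal(unname(G$values[, "snp1"]), c(0L, 1L))
  expect_equal(unname(G$alleles["snp1", ]), c("G", "A"))
  # snp2: second individual missing
  expect_equal(G$values["ind2", "snp2"], GT_MISSING)
})

test_that("malformed PED lines and unmapped individuals raise errors", {
  dir <- withr::local_tempdir()
  writeLines("F1 ind1 0 0 0 -9 A", file.path(dir, "bad.ped"))
  writeLines("1\tsnp1\t0\t1", file.path(dir, "bad.map"))
  pm <- data.frame(individual = "ind1", population = "p1")
  expect_error(load_genotypes(file.path(dir, "bad.ped"), "ped", pm),
               "line 1")
  writeLines("F1 ind9 0 0 0 -9 A A", file.path(dir, "bad.ped"))
  expect_error(load_genotypes(file.path(dir, "bad.ped"), "ped", pm),
               "population map")
})

test_that("VCF import codes ALT dosage, skips multiallelic records", {
  skip_if_not_installed("vcfR")
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tind1\tind2\tind3",
    "1\t100\ts1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\ts2\tC\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2",
    "1\t300\ts3\tC\tT\t.\tPASS\t.\tGT\t./.\t0/0\t0/1"), vcf)
  pm <- data.frame(individual = c("ind1", "ind2", "ind3"),
                   population = "p1")
  expect_warning(G <- load_genotypes(vcf, "vcf", pm), "multiallelic")
  expect_setequal(G$locus_ids, c("s1", "s3"))
  # s1: ALT G carried 0/1/2 times; panel-wide G count 3 of 6 -> MAF tie,
  # broken to the lexicographically smaller character (A), so dosages flip
  expect_equal(unname(G$values[, "s1"]), c(2L, 1L, 0L))
  expect_equal(G$values["ind1", "s3"], GT_MISSING)
  expect_equal(unname(G$values[c("ind2", "ind3"), "s3"]), c(0L, 1L))
})

test_that("write_fixture / load_genotypes round-trips the dosage matrix", {
  panel <- small_panel(seed = 11, n_neutral = 60, n_adaptive = 5)
  dir <- withr::local_tempdir()
  paths <- write_fixture(panel, dir)
  G2 <- load_genotypes(paths$ped, "ped", paths$pop_map)
  expect_identical(G2$values, panel$genotypes$values)
  expect_identical(G2$alleles, panel$genotypes$alleles)
  # coordinates CSV has one row per population
  expect_equal(nrow(read.csv(paths$coords)), panel$spec$n_pops)
  # fixture survives default QC without losing every locus
  qc <- apply_qc_filters(G2)
  expect_gt(ncol(qc$genotypes$values), 0)
})

test_that("QC removes loci by MAF and missingness in the documented order", {
  # 4 diploids, locus 1 dosages (0,0,0,1): MAF 1/8 = 0.125 >= 0.05, retained
  # locus 2 monomorphic: removed; locus 3 fine
  v <- cbind(c(0, 0, 0, 1), c(0, 0, 0, 0), c(0, 1, 2, 1))
  G <- make_gt(v, rep("p1", 4))
  out <- apply_qc_filters(G)
  expect_setequal(out$genotypes$locus_ids, c("L001", "L003"))
  expect_equal(out$report$loci_removed_maf, 1)

  # locus missing in 2 of 10 individuals (20% > 10%) is removed
  v2 <- matrix(rep(c(0, 1, 2, 1, 0), 4), nrow = 10, ncol = 2)
  v2[1:2, 1] <- GT_MISSING
  G2 <- make_gt(v2, rep(c("p1", "p2"), each = 5))
  out2 <- apply_qc_filters(G2)
  expect_equal(out2$report$loci_removed_missing, 1)
  expect_equal(ncol(out2$genotypes$values), 1)
})

test_that("apply_qc_filters is idempotent and errors when nothing survives", {
  panel <- default_panel()
  once <- apply_qc_filters(panel$genotypes)
  twice <- apply_qc_filters(once$genotypes)
  expect_identical(twice$genotypes$values, once$genotypes$values)
  expect_equal(twice$report$loci_removed_maf, 0)
  expect_equal(twice$report$individuals_removed, 0)

  mono <- make_gt(matrix(0L, 6, 3), rep("p1", 6))
  expect_error(apply_qc_filters(mono), "binding filter")
})

test_that("QC report stage counts reconcile input and output dimensions", {
  panel <- small_panel(seed = 5, n_neutral = 300, missing_rate = 0.08)
  rep <- apply_qc_filters(panel$genotypes)$report
  expect_equal(rep$input_dim[2] - rep$loci_removed_missing -
                 rep$loci_removed_maf - rep$loci_removed_maf_repass,
               rep$output_dim[2])
  expect_equal(rep$input_dim[1] - rep$individuals_removed, rep$output_dim[1])
  expect_match(as.character(qc_report_json(rep)), "loci_removed_maf")
})

test_that("LD pruning drops the later locus of correlated pairs", {
  x <- c(0, 1, 2, 0, 1)
  G <- make_gt(cbind(x, x, c(2, 1, 0, 2, 1)), rep("p1", 5))
  # col2 duplicates col1 (r2 = 1); col3 is the mirror of col1 (r2 = 1)
  expect_equal(ld_prune(G, r2_max = 0.7, window_loci = 10, step_loci = 5), 1L)
  expect_error(ld_prune(G, window_loci = 1), "window_loci")
})

test_that("independent loci survive LD pruning", {
  set.seed(7)
  v <- matrix(rbinom(200 * 6, 2, 0.5), 200, 6)
  G <- make_gt(v, rep("p1", 200))
  expect_equal(ld_prune(G, window_loci = 10, step_loci = 5), 1:6)
})

test_that("within-population imputation fills means with global fallback", {
  v <- cbind(c(0, 2, GT_MISSING, 1, 1, 1))
  G <- make_gt(v, c("A", "A", "A", "B", "B", "B"))
  imp <- impute_within_population(G)
  expect_equal(imp[3, 1], 1.0)            # mean of (0, 2)

  # a matrix with no missing cells comes back unchanged
  full <- make_gt(cbind(c(0, 1, 2, 1)), rep("p1", 4))
  expect_equal(impute_within_population(full),
               matrix(c(0, 1, 2, 1), dimnames = list(full$individual_ids,
                                                     "L001")))

  # locus all-missing in pop A falls back to the global locus mean
  v2 <- cbind(c(GT_MISSING, GT_MISSING, 0, 1, 1, 1))
  G2 <- make_gt(v2, c("A", "A", "B", "B", "B", "B"))
  expect_equal(unname(impute_within_population(G2)[1:2, 1]),
               rep(mean(c(0, 1, 1, 1)), 2))

  v3 <- cbind(rep(GT_MISSING, 4))
  expect_error(impute_within_population(make_gt(v3, rep("A", 4))),
               "entirely missing")
})

test_that("population allele frequencies count alleles over non-missing calls", {
  v <- cbind(c(0, 1, 2), c(2, 2, 2), c(1, GT_MISSING, GT_MISSING))
  G <- make_gt(v, rep("p1", 3))
  fr <- population_allele_frequencies(G)
  expect_equal(unname(fr$freq[1, ]), c(0.5, 1.0, 0.5))
  expect_equal(unname(fr$n_alleles[1, ]), c(6L, 6L, 2L))
})

test_that("frequencies lie in [0,1] and recover integer allele counts", {
  panel <- default_panel()
  fr <- population_allele_frequencies(panel$genotypes)
  ok <- !is.na(fr$freq)
  expect_true(all(fr$freq[ok] >= 0 & fr$freq[ok] <= 1))
  counts <- fr$freq * fr$n_alleles
  expect_equal(counts[ok], round(counts[ok]), tolerance = 1e-12)
})
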