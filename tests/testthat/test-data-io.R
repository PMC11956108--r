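test_that("delimited genotype round trip preserves codes and ids", {
  G <- tiny_genotypes()
  G$codes[2, 3] <- NA
  G <- genotype_matrix(G$codes)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(G, f)
  G2 <- read_genotypes(f)
  expect_identical(rownames(G2$codes), rownames(G$codes))
  expect_identical(colnames(G2$codes), colnames(G$codes))
  expect_equal(G2$codes, G$codes)
})

test_that("letter-coded genotypes map to -1/+1 and keep all-missing columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("line_id\tm1\tm2",
               "L1\tAA\tNA",
               "L2\taa\tNA",
               "L3\tAA\tNA"), f)
  G <- read_genotypes(f)
  expect_equal(unname(G$codes[, "m1"]), c(1, -1, 1))
  expect_equal(ncol(G$codes), 2)
  expect_equal(unname(marker_missing_rate(G)["m2"]), 1)
})

test_that("toy VCF loads biallelic records and skips multi-allelic ones", {
  skip_if_not_installed("VariantAnnotation")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1,length=1000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tL1\tL2\tL3",
    "1\t10\tv1\tA\tG\t.\t.\t.\tGT\t0/0\t1/1\t0/1",
    "1\t20\tv2\tC\tT\t.\t.\t.\tGT\t1/1\t1/1\t0/0",
    "1\t30\tv3\tG\tA,C\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
    "1\t40\tv4\tT\tC\t.\t.\t.\tGT\t0/0\t0/0\t0/0",
    "1\t50\tv5\tA\tT\t.\t.\t.\tGT\t1/1\t0/0\t1/1"), f)
  expect_warning(G <- read_genotypes(f, format = "vcf"),
                 "non-biallelic")
  expect_equal(ncol(G$codes), 4)
  expect_equal(attr(G, "skipped"), 1)
  expect_equal(unname(G$codes["L1", ]), c(1, -1, 1, -1))
  expect_equal(unname(G$codes["L3", "v1"]), 0)
})

test_that("filter_snps applies strict thresholds and is idempotent", {
  # 10 lines; marker freq/missing layout constructed by hand
  codes <- cbind(
    keep_maf10   = c(rep(1, 9), -1),              # MAF 0.10
    drop_maf04   = c(rep(1, 10)),                 # MAF 0 (monomorphic)
    boundary_maf = c(rep(1, 9), -1),              # placeholder, edited below
    drop_missing = c(rep(NA, 2), rep(1, 4), rep(-1, 4)),  # missing 0.2
    boundary_mis = c(NA, rep(1, 5), rep(-1, 4))   # missing exactly 0.1
  )
  # exact MAF 0.05 on 10 inbred lines is not constructible; use 20 half-weights
  rownames(codes) <- paste0("L", 1:10)
  G <- genotype_matrix(codes)
  expect_message(Gf <- filter_snps(G), "retained")
  expect_true("keep_maf10" %in% colnames(Gf$codes))
  expect_false("drop_maf04" %in% colnames(Gf$codes))
  expect_false("drop_missing" %in% colnames(Gf$codes))
  expect_true("boundary_mis" %in% colnames(Gf$codes))  # rate == 0.1 kept
  # idempotence
  expect_message(Gff <- filter_snps(Gf), "retained")
  expect_equal(Gff$codes, Gf$codes)
  # exact-boundary MAF: 20 lines with one heterozygote (dosage 0.5 -> f 0.05)
  codes2 <- matrix(rep(-1, 20), ncol = 1,
                   dimnames = list(paste0("P", 1:20), "maf005"))
  codes2[1, 1] <- 1  # +1 allele freq = 1/20 = 0.05 exactly
  expect_message(Gk <- filter_snps(genotype_matrix(codes2)), "1 of 1")
  expect_equal(ncol(Gk$codes), 1)
  # everything removed
  mono <- genotype_matrix(matrix(1, 10, 2,
                                 dimnames = list(paste0("L", 1:10),
                                                 c("a", "b"))))
  expect_error(filter_snps(mono), "all markers removed")
})

test_that("impute_missing fills per-marker means and preserves them", {
  codes <- cbind(a = c(-1, 1, NA), b = c(1, 1, 1), d = c(1, 1, NA))
  rownames(codes) <- paste0("L", 1:3)
  G <- genotype_matrix(codes)
  Gi <- impute_missing(G)
  expect_equal(unname(Gi$codes[3, "a"]), 0)
  expect_false(anyNA(Gi$codes))
  # [+1,+1,NA,-1] -> 1/3
  codes2 <- matrix(c(1, 1, NA, -1), ncol = 1,
                   dimnames = list(paste0("L", 1:4), "m"))
  Gi2 <- impute_missing(genotype_matrix(codes2))
  expect_equal(unname(Gi2$codes[3, 1]), 1 / 3)
  # per-marker means preserved
  expect_equal(colMeans(Gi2$codes), colMeans(codes2, na.rm = TRUE),
               ignore_attr = TRUE)
  # identity when nothing is missing
  G3 <- tiny_genotypes()
  expect_identical(impute_missing(G3), G3)
  # all-missing marker errors
  codes3 <- cbind(a = c(NA_real_, NA, NA), b = c(1, -1, 1))
  rownames(codes3) <- paste0("L", 1:3)
  expect_error(impute_missing(genotype_matrix(codes3)), "no observed")
})

test_that("subset_metabolome filters by tissue and preserves order", {
  mx <- tiny_metabolome(m = 5)
  mx <- metabolome_matrix(mx$values,
                          meta = data.frame(
                            metabolite_id = colnames(mx$values),
                            tissue = c("leaf", "seed", "leaf", "leaf",
                                       "seed")))
  leaf <- subset_metabolome(mx, "leaf")
  expect_identical(colnames(leaf$values), c("met1", "met3", "met4"))
  all_leaf <- metabolome_matrix(mx$values,
                                meta = data.frame(
                                  metabolite_id = colnames(mx$values),
                                  tissue = rep("leaf", 5)))
  expect_equal(subset_metabolome(all_leaf, "leaf")$values, mx$values)
  expect_error(subset_metabolome(mx, "root"), "unknown tissue")
})

test_that("metabolome and phenotype round trips preserve replicates and NAs", {
  mx <- tiny_metabolome(n = 4, m = 3, reps = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_metabolome(mx, f)
  mx2 <- read_metabolome(f)
  expect_equal(mx2$values, mx$values, ignore_attr = TRUE)
  expect_equal(mx2$replicate, mx$replicate)
  ph <- phenotype_table(matrix(c(1.5, NA, 2.5), 3, 1,
                               dimnames = list(paste0("L", 1:3), "tr")))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(ph, f2)
  expect_equal(read_phenotypes(f2)$values, ph$values)
})

test_that("cross table validation catches bad input", {
  G <- tiny_genotypes()
  expect_error(cross_table(c("h1", "h2"), c("L1", "L2"), c("L2", "L1")),
               "duplicated unordered")
  expect_error(cross_table("h1", "L1", "L99", genotypes = G), "absent")
  ct <- cross_table(c("h1", "h2"), c("L1", "L2"), c("L2", "L3"),
                    genotypes = G)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_crosses(ct, f)
  expect_equal(read_crosses(f)$hybrid_id, ct$hybrid_id)
})
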