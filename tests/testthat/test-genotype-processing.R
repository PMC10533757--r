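test_that("VCF coding convention and multi-allelic skipping", {
  vcf <- c("##fileformat=VCFv4.2", "##contig=<ID=chr1>",
           paste0('##FORMAT=<ID=GT,Number=1,Type=String,',
                  'Description="Genotype">'),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
           paste(c("chr1", "100", "snp1", "A", "T", ".", ".", ".", "GT",
                   "0/0", "0/1", "1/1"), collapse = "\t"),
           paste(c("chr1", "150", "snp2", "A", "T,G", ".", ".", ".", "GT",
                   "0/0", "0/1", "1/1"), collapse = "\t"),
           paste(c("chr1", "200", "snp3", "A", "T", ".", ".", ".", "GT",
                   "0/0", "./.", "1|1"), collapse = "\t"))
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, p)
  expect_message(m <- read_genotypes(p), "multi-allelic")
  expect_equal(colnames(m$dosage), c("snp1", "snp3"))   # tri-allelic dropped
  expect_equal(unname(m$dosage[, "snp1"]), c(0, 1, 2))
  expect_equal(unname(m$dosage[, "snp3"]), c(0, NA, 2))
})

test_that("simulated genotypes round-trip through VCF and dosage CSV", {
  cfg <- sim_config(n_individuals_A = 15, n_individuals_B = 10,
                    n_checks = 3, n_snps = 40, seed = 2)
  m <- simulate_s0_genotypes(cfg)
  pv <- withr::local_tempfile(fileext = ".vcf")
  pc <- withr::local_tempfile(fileext = ".csv")
  write_genotypes_vcf(m, pv)
  write_dosage_csv(m, pc)
  mv <- read_genotypes(pv)
  mc <- read_genotypes(pc)
  expect_equal(unname(mv$dosage), unname(m$dosage))
  expect_equal(unname(mc$dosage), unname(m$dosage))
  expect_equal(mv$map$position, m$map$position)
  expect_equal(mc$map$chromosome, m$map$chromosome)
})

test_that("marker filters apply missingness then MAF with first-fail attribution", {
  # 10 SNPs: 1 too missing, 2 below the MAF floor, 7 clean
  set.seed(1)
  n <- 40
  d <- sapply(rep(0.3, 10), function(p) rbinom(n, 2, p))
  d[1:12, 1] <- NA                                 # 30% missing
  d[, 2] <- c(1, rep(0, n - 1))                    # MAF 1/80 = 0.0125
  d[, 3] <- c(1, 1, rep(0, n - 2))                 # MAF 2/80 = 0.025 (<= floor)
  m <- toy_markers(d)
  res <- filter_markers(m, max_missing = 0.20, min_maf = 0.025)
  expect_equal(ncol(res$markers$dosage), 7)
  expect_equal(res$report$n[res$report$rule == "missing"], 1)
  expect_equal(res$report$n[res$report$rule == "maf"], 2)
  expect_true(is.na(res$report$n[res$report$rule == "depth"]))
  # threshold semantics: MAF 0.03 kept, 0.02 removed; 25% missing removed
  d2 <- cbind(a = c(rep(1, 3), rep(0, 47)),      # MAF 0.03
              b = c(rep(1, 2), rep(0, 48)),      # MAF 0.02
              c = c(rep(NA, 13), rbinom(37, 2, 0.5)))  # 26% missing
  res2 <- filter_markers(toy_markers(d2))
  expect_equal(colnames(res2$markers$dosage), "a")
  expect_error(filter_markers(toy_markers(d2[, 2, drop = FALSE])),
               "all SNPs removed")
})

test_that("mean imputation fills only missing cells and preserves SNP means", {
  d <- cbind(a = c(0, 2, NA, NA), b = c(1, 1, 1, 1), c = c(0, 1, 2, NA))
  m <- toy_markers(d)
  mi <- impute_mean(m)
  expect_false(anyNA(mi$dosage))
  expect_equal(mi$dosage[3, "a"], 1.0)           # mean of {0,2}
  expect_equal(colMeans(mi$dosage), colMeans(d, na.rm = TRUE))
  obs <- !is.na(d)
  expect_equal(mi$dosage[obs], d[obs])
  expect_identical(impute_mean(mi)$dosage, mi$dosage)   # identity, no missing
  d[, "b"] <- NA
  expect_error(impute_mean(toy_markers(d)), "fully missing")
})

test_that("filtering then imputing commutes with imputing the retained SNPs", {
  set.seed(3)
  d <- sapply(runif(30, 0.05, 0.5), function(p) rbinom(25, 2, p))
  d[sample(length(d), 60)] <- NA
  m <- toy_markers(d)
  f1 <- impute_mean(filter_markers(m)$markers)
  kept <- colnames(f1$dosage)
  f2 <- subset_markers(impute_mean(
    subset_markers(m, snps = kept)), snps = kept)
  expect_equal(f1$dosage, f2$dosage)
})

test_that("MAF and observed heterozygosity follow their definitions", {
  d <- rbind(i1 = c(0, 0, 2), i2 = c(1, 0, 2), i3 = c(1, 1, 1),
             i4 = c(2, 0, 1))
  mh <- maf_and_het(toy_markers(d))
  expect_equal(unname(mh$maf[1]), 0.5)       # dosages (0,1,1,2)
  expect_equal(unname(mh$ho["i1"]), 0)       # fully homozygous
  expect_equal(unname(mh$ho["i3"]), 1)
  expect_true(all(mh$maf >= 0 & mh$maf <= 0.5))
})

test_that("LD r2 is 1 for duplicated SNPs and ~1/n for independent loci", {
  set.seed(6)
  x <- rbinom(60, 2, 0.4)
  d <- cbind(a = x, b = x)
  out <- ld_r2(toy_markers(d), max_dist_bp = 1e6)
  expect_equal(out$mean_r2, 1, tolerance = 1e-12)
  # monomorphic SNP pairs skipped, not NA
  d2 <- cbind(a = x, mono = rep(0, 60))
  out2 <- ld_r2(toy_markers(d2), max_dist_bp = 1e6)
  expect_equal(nrow(out2), 0)
  # null expectation: E[r2] ~ 1/n for independent loci
  n <- 500
  set.seed(7)
  d3 <- sapply(runif(60, 0.1, 0.5), function(p) rbinom(n, 2, p))
  out3 <- ld_r2(toy_markers(d3), max_dist_bp = 1e7)
  mean_r2 <- sum(out3$mean_r2 * out3$n_pairs) / sum(out3$n_pairs)
  se <- sqrt(2) / n / sqrt(sum(out3$n_pairs))   # r2 ~ chisq(1)/n: sd ~ sqrt(2)/n
  expect_lt(abs(mean_r2 - 1 / n), 3 * se + 0.2 / n)
})

test_that("VanRaden G matches the loop-wise oracle and its identities", {
  for (seed in 1:20) {
    set.seed(seed)
    d <- sapply(runif(20, 0.05, 0.95), function(p) rbinom(10, 2, p))
    poly <- apply(d, 2, function(x) length(unique(x)) > 1)
    if (sum(poly) < 2) next
    G <- vanraden_g(toy_markers(d), ridge = FALSE)
    expect_lt(max(abs(G$G - vanraden_oracle(d))), 1e-10)
  }
  # identical individuals produce identical rows
  d <- rbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1), c = c(2, 1, 0, 0))
  G <- vanraden_g(toy_markers(d), ridge = FALSE)
  expect_equal(G$G["a", ], G$G["b", ])
  expect_equal(G$G["a", "a"], G$G["a", "b"])
  # symmetry and centering identity: rows of Z sum to ~0 across individuals
  expect_lt(max(abs(G$G - t(G$G))), 1e-10)
  expect_lt(max(abs(colSums(G$G))), 1e-10)
  expect_error(vanraden_g(toy_markers(matrix(2, 4, 3))), "polymorphic")
})

test_that("G is invariant to SNP order and to duplicating every SNP", {
  set.seed(9)
  d <- sapply(runif(40, 0.1, 0.9), function(p) rbinom(15, 2, p))
  m <- toy_markers(d)
  G1 <- vanraden_g(m, ridge = FALSE)$G
  perm <- sample(ncol(d))
  G2 <- vanraden_g(toy_markers(d[, perm]), ridge = FALSE)$G
  expect_equal(G1, G2, tolerance = 1e-12)
  G3 <- vanraden_g(toy_markers(cbind(d, d)), ridge = FALSE)$G
  expect_equal(G1, G3, tolerance = 1e-12)
  # ridge guarantees positive definiteness
  Gr <- vanraden_g(m)
  expect_gt(min(eigen(Gr$G, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_true(mean(diag(Gr$G)) > 0.5 && mean(diag(Gr$G)) < 2.5)
})

test_that("heterozygote under-call bound matches the closed form", {
  expect_equal(het_undercall_prob(10), 2 * 0.5^10)
  expect_lte(het_undercall_prob(10), 0.002)
  expect_equal(het_undercall_prob(1), 1)
  expect_error(het_undercall_prob(0), ">= 1")
})
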