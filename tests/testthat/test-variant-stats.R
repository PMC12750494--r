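# Variant typing, site filtering, allele summaries, SO impact mapping.

test_that("variant types follow allele lengths and MNPs are rejected", {
  expect_equal(classify_variant_type("A", "G"), "SNP")
  expect_equal(classify_variant_type("A", "AT"), "INS")
  expect_equal(classify_variant_type("ATG", "A"), "DEL")
  expect_equal(classify_variant_type(c("A", "CT"), c("AT", "C")),
               c("INS", "DEL"))
  expect_error(classify_variant_type("AT", "GC"), "unsupported")
})

test_that("site statistics count diploid alleles as stated", {
  # 30 samples, one heterozygote: alt frequency 1/60 fails a 3% MAF floor.
  col <- c(1L, rep(0L, 29))
  s <- site_stats(col)
  expect_equal(s$maf, 1 / 60)
  expect_lt(s$maf, 0.03)
  expect_equal(s$het_frac, 1 / 30)

  # Two homozygous-alternate samples: 4/60 passes 5%.
  col2 <- c(2L, 2L, rep(0L, 28))
  expect_equal(site_stats(col2)$maf, 4 / 60)
  expect_gt(site_stats(col2)$maf, 0.05)

  mono <- rep(0L, 30)
  s3 <- site_stats(mono)
  expect_equal(s3$maf, 0)
  expect_equal(s3$het_frac, 0)
  expect_equal(s3$missing_frac, 0)

  all_missing <- rep(NA_integer_, 10)
  expect_true(is.na(site_stats(all_missing)$maf))
})

test_that("a 5% MAF floor requires two carrier individuals among 30", {
  # Homozygous panel: k carriers contribute 2k/60 allele frequency, so
  # k = 1 (3.33%) must fail and k = 2 (6.67%) must pass at MAF5.
  geno <- sapply(0:3, function(k) c(rep(2L, k), rep(0L, 30 - k)))
  sites <- data.frame(chrom = "1A", pos = 1:4 * 100,
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  gm <- genotype_matrix(sites, t(geno), sprintf("S%02d", 1:30))
  res <- filter_sites(gm, filter_config(maf_min = 0.05))
  expect_equal(res$kept, c(FALSE, FALSE, TRUE, TRUE))
  # At MAF3 the single-carrier site still fails (3.33% > 3% though): passes.
  res3 <- filter_sites(gm, filter_config(maf_min = 0.03))
  expect_equal(res3$kept, c(FALSE, TRUE, TRUE, TRUE))
})

test_that("missingness boundary is inclusive at 10%", {
  mk_col <- function(n_miss) {
    c(rep(NA_integer_, n_miss), rep(2L, 15), rep(0L, 15 - n_miss))
  }
  sites <- data.frame(chrom = "1A", pos = c(100, 200), ref = "A", alt = "G")
  gm <- genotype_matrix(sites, rbind(mk_col(3), mk_col(4)),
                        sprintf("S%02d", 1:30))
  res <- filter_sites(gm, filter_config(maf_min = 0))
  expect_equal(res$kept, c(TRUE, FALSE))  # 3/30 = 10% passes, 4/30 fails
})

test_that("filter_sites matches a brute-force reimplementation", {
  set.seed(77)
  for (rep in 1:8) {
    gm <- random_geno_matrix(50, 30)
    for (maf_min in c(0, 0.03, 0.05)) {
      res <- filter_sites(gm, filter_config(maf_min, 0.10, 0.10))
      expect_identical(res$kept,
                       brute_filter_kept(gm, maf_min, 0.10, 0.10))
    }
  }
})

test_that("filters are monotone in the MAF floor", {
  set.seed(78)
  for (rep in 1:5) {
    gm <- random_geno_matrix(80, 30)
    counts <- vapply(c(0, 0.01, 0.03, 0.05, 0.1), function(m) {
      sum(filter_sites(gm, filter_config(m, 1, 1))$kept)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
  # Identity: no floor and permissive missing/het keeps every site with
  # at least one called genotype.
  gm <- random_geno_matrix(40, 12, probs = c(0.7, 0.1, 0.2, 0))
  expect_true(all(filter_sites(gm, filter_config(0, 1, 1))$kept))
})

test_that("per-sample allele percentages partition 100", {
  sites <- data.frame(chrom = "1A", pos = 1:4 * 10, ref = "A", alt = "G")
  gm <- genotype_matrix(sites, cbind(c(0L, 1L, NA, 2L), rep(0L, 4)),
                        c("mixed", "allref"))
  s <- sample_allele_summary(gm)
  expect_equal(s$pct_ref, c(25, 100))
  expect_equal(s$pct_het, c(25, 0))
  expect_equal(s$pct_missing, c(25, 0))
  expect_equal(s$pct_het + s$pct_missing + s$pct_ref + s$pct_hom_alt,
               c(100, 100))
})

test_that("impact classification takes the most severe SO term", {
  expect_equal(classify_impact("stop_gained"), "HIGH")
  expect_equal(classify_impact("synonymous_variant"), "LOW")
  expect_equal(classify_impact(c("intron_variant", "missense_variant")),
               "MODERATE")
  expect_equal(classify_impact(c("intergenic_variant", "stop_gained",
                                 "synonymous_variant")), "HIGH")
  expect_warning(out <- classify_impact("made_up_term"), "unknown")
  expect_equal(out, "MODIFIER")
})

test_that("functional classes map missense/nonsense/silent", {
  expect_equal(functional_class("missense_variant"), "missense")
  expect_equal(functional_class("stop_gained"), "nonsense")
  expect_equal(functional_class("synonymous_variant"), "silent")
  expect_equal(functional_class("upstream_gene_variant"), "none")
})

test_that("arm binning partitions sites at the centromere", {
  sites <- data.frame(chrom = c("1A", "1A", "1A", "2B"),
                      pos = c(10, 500, 900, 100))
  cen <- c(`1A` = 500, `2B` = 50)
  counts <- bin_by_arm(sites, cen)
  expect_equal(counts[["1A.1"]], 2)  # position 500 sits on the short arm
  expect_equal(counts[["1A.2"]], 1)
  expect_equal(counts[["2B.2"]], 1)
  expect_equal(sum(counts), nrow(sites))
  expect_error(bin_by_arm(data.frame(chrom = "9Z", pos = 1), cen),
               "centromere")
})

test_that("genotype matrices round-trip through GT-only VCF", {
  cfg <- fast_cfg()
  panel <- build_panel(cfg)
  gm <- simulate_genotypes(cfg, panel$truth)$matrix
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path)
  expect_equal(unname(back$geno), unname(gm$geno))
  expect_equal(back$samples, gm$samples)
  expect_equal(back$sites$so_term, gm$sites$so_term)
  expect_equal(back$sites$pos, gm$sites$pos)

  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "S1"), collapse = "\t"),
               "1A\t100\t.\tA\tG,T\t.\tPASS\t.\tGT\t0/1"),
             path)
  expect_error(read_vcf(path), "multiallelic")
})
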