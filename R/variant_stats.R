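# Genotype matrices, site filtering, allele summaries, SO impact mapping.
#
# Genotypes are coded as integers: 0 = homozygous reference, 1 =
# heterozygous, 2 = homozygous alternate, NA = missing. The panel is
# diploid and inbred, so each called genotype contributes two alleles.

GT_HOM_REF <- 0L
GT_HET <- 1L
GT_HOM_ALT <- 2L

#' Construct a genotype matrix
#'
#' @param sites Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` and optionally `so_term` (sequence-ontology annotation).
#' @param geno Integer matrix, sites x samples, values 0/1/2/NA.
#' @param samples Character vector of sample ids (one per column).
#' @return A list of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, geno, samples) {
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(sites)) stopf("sites and genotype rows disagree")
  if (ncol(geno) != length(samples)) {
    stopf("samples and genotype columns disagree")
  }
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stopf("genotype codes must be 0, 1, 2 or NA")
  if (!all(grepl("^[ACGT]+$", sites$ref)) ||
      !all(grepl("^[ACGT]+$", sites$alt))) {
    stopf("alleles must be non-empty strings over A, C, G, T")
  }
  colnames(geno) <- samples
  structure(list(sites = sites, geno = geno, samples = samples),
            class = "genotype_matrix")
}

#' Classify a variant by its allele lengths
#'
#' SNP when both alleles are single bases, insertion when the alternate is
#' longer, deletion when shorter. Equal-length multi-base substitutions
#' (MNPs) are unsupported.
#'
#' @param ref,alt Allele strings (vectorized).
#' @return Character vector over `"SNP"`, `"INS"`, `"DEL"`.
#' @export
classify_variant_type <- function(ref, alt) {
  lr <- nchar(ref)
  la <- nchar(alt)
  if (any(lr == la & lr > 1)) {
    stopf("unsupported variant type: equal-length multi-base substitution")
  }
  ifelse(lr == 1 & la == 1, "SNP", ifelse(la > lr, "INS", "DEL"))
}

#' Per-site filter statistics
#'
#' Allele counts come from the non-missing diploid genotypes (homozygous
#' reference contributes two reference alleles, heterozygous one of each,
#' homozygous alternate two alternates). The minor allele frequency is one
#' minus the major allele frequency; the missing fraction uses all samples
#' as denominator while the heterozygous fraction uses called samples only.
#'
#' @param column Integer genotype codes for one site (0/1/2/NA).
#' @return A list with `maf`, `missing_frac`, `het_frac`; `maf` is `NA`
#'   when every genotype is missing.
#' @export
site_stats <- function(column) {
  n_samp <- length(column)
  if (!n_samp) stopf("site has no samples")
  called <- column[!is.na(column)]
  missing_frac <- (n_samp - length(called)) / n_samp
  if (!length(called)) {
    return(list(maf = NA_real_, missing_frac = missing_frac,
                het_frac = NA_real_))
  }
  alt_alleles <- sum(called)           # codes count alt alleles directly
  n_alleles <- 2 * length(called)
  p_alt <- alt_alleles / n_alleles
  list(maf = 1 - max(p_alt, 1 - p_alt),
       missing_frac = missing_frac,
       het_frac = sum(called == GT_HET) / length(called))
}

#' Site filter configuration
#'
#' @param maf_min Minimum minor allele frequency (0.03 or 0.05 in common
#'   use).
#' @param max_missing Maximum fraction of missing genotypes per site.
#' @param max_het Maximum fraction of heterozygous calls among called
#'   genotypes per site.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(maf_min = 0.05, max_missing = 0.10,
                          max_het = 0.10) {
  vals <- c(maf_min, max_missing, max_het)
  if (any(vals < 0 | vals > 1)) stopf("filter fractions must lie in [0, 1]")
  structure(list(maf_min = maf_min, max_missing = max_missing,
                 max_het = max_het), class = "filter_config")
}

#' Filter sites by MAF, missingness and heterozygosity
#'
#' A site is kept when `maf >= maf_min`, `missing_frac <= max_missing` and
#' `het_frac <= max_het` (all thresholds inclusive). Sites where every
#' genotype is missing are always dropped. Note that in a panel of 30
#' homozygous samples a single alternate-allele carrier contributes at most
#' 2/60 = 3.3% allele frequency, so a 5% MAF floor requires at least two
#' carrier individuals.
#'
#' @param gm A [genotype_matrix()].
#' @param config A [filter_config()].
#' @return A list with `matrix` (the filtered [genotype_matrix()]),
#'   `kept` (logical per input site) and `counts` (surviving sites per
#'   variant type: SNP, INS, DEL).
#' @export
filter_sites <- function(gm, config = filter_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  stats_per_site <- apply(gm$geno, 1, site_stats)
  maf <- vapply(stats_per_site, `[[`, numeric(1), "maf")
  miss <- vapply(stats_per_site, `[[`, numeric(1), "missing_frac")
  het <- vapply(stats_per_site, `[[`, numeric(1), "het_frac")
  kept <- !is.na(maf) & maf >= config$maf_min & miss <= config$max_missing &
    het <= config$max_het
  out <- genotype_matrix(gm$sites[kept, , drop = FALSE],
                         gm$geno[kept, , drop = FALSE], gm$samples)
  types <- classify_variant_type(out$sites$ref, out$sites$alt)
  counts <- c(SNP = sum(types == "SNP"), INS = sum(types == "INS"),
              DEL = sum(types == "DEL"))
  list(matrix = out, kept = kept, counts = counts)
}

#' Per-sample allele-type percentages
#'
#' For each sample, the percentage of sites called heterozygous, missing,
#' homozygous reference and homozygous alternate, each over the total
#' number of sites; the four percentages partition 100.
#'
#' @param gm A [genotype_matrix()].
#' @return Data frame with one row per sample.
#' @export
sample_allele_summary <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- nrow(gm$geno)
  if (!n) stopf("no sites")
  data.frame(
    sample = gm$samples,
    pct_het = 100 * colSums(gm$geno == GT_HET, na.rm = TRUE) / n,
    pct_missing = 100 * colSums(is.na(gm$geno)) / n,
    pct_ref = 100 * colSums(gm$geno == GT_HOM_REF, na.rm = TRUE) / n,
    pct_hom_alt = 100 * colSums(gm$geno == GT_HOM_ALT, na.rm = TRUE) / n,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Default sequence-ontology impact and functional-class table
#'
#' Maps each SO term to an impact tier -- HIGH (stop gained/lost, start
#' lost, frameshifts, splice donor/acceptor), MODERATE (missense, in-frame
#' insertions/deletions and other non-disruptive protein changes), LOW
#' (synonymous, splice region, incomplete terminal codon, start/stop
#' retained) or MODIFIER (intronic, up/downstream, non-coding, intergenic)
#' -- and to a functional class (missense, nonsense, silent or none).
#'
#' @return Data frame with columns `term`, `impact`, `fclass`.
#' @export
default_impact_table <- function() {
  tab <- rbind(
    c("stop_gained", "HIGH", "nonsense"),
    c("stop_lost", "HIGH", "none"),
    c("start_lost", "HIGH", "none"),
    c("frameshift_variant", "HIGH", "none"),
    c("splice_donor_variant", "HIGH", "none"),
    c("splice_acceptor_variant", "HIGH", "none"),
    c("transcript_ablation", "HIGH", "none"),
    c("exon_loss_variant", "HIGH", "none"),
    c("missense_variant", "MODERATE", "missense"),
    c("inframe_insertion", "MODERATE", "none"),
    c("inframe_deletion", "MODERATE", "none"),
    c("disruptive_inframe_insertion", "MODERATE", "none"),
    c("disruptive_inframe_deletion", "MODERATE", "none"),
    c("protein_altering_variant", "MODERATE", "none"),
    c("synonymous_variant", "LOW", "silent"),
    c("splice_region_variant", "LOW", "none"),
    c("incomplete_terminal_codon_variant", "LOW", "none"),
    c("start_retained_variant", "LOW", "silent"),
    c("stop_retained_variant", "LOW", "silent"),
    c("initiator_codon_variant", "LOW", "none"),
    c("intron_variant", "MODIFIER", "none"),
    c("upstream_gene_variant", "MODIFIER", "none"),
    c("downstream_gene_variant", "MODIFIER", "none"),
    c("intergenic_variant", "MODIFIER", "none"),
    c("non_coding_transcript_variant", "MODIFIER", "none"),
    c("non_coding_transcript_exon_variant", "MODIFIER", "none"),
    c("5_prime_UTR_variant", "MODIFIER", "none"),
    c("3_prime_UTR_variant", "MODIFIER", "none")
  )
  data.frame(term = tab[, 1], impact = tab[, 2], fclass = tab[, 3],
             stringsAsFactors = FALSE)
}

impact_order <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

#' Impact of a variant from its SO terms
#'
#' Returns the impact of the most severe term (HIGH > MODERATE > LOW >
#' MODIFIER). Unknown terms map to MODIFIER with a warning.
#'
#' @param so_terms Character vector of SO terms annotating one variant.
#' @param table Impact table (defaults to [default_impact_table()]).
#' @return One of `"HIGH"`, `"MODERATE"`, `"LOW"`, `"MODIFIER"`.
#' @export
classify_impact <- function(so_terms, table = default_impact_table()) {
  idx <- match(so_terms, table$term)
  if (anyNA(idx)) {
    warning(sprintf("unknown SO term(s) %s mapped to MODIFIER",
                    paste(so_terms[is.na(idx)], collapse = ", ")),
            call. = FALSE)
  }
  impacts <- ifelse(is.na(idx), "MODIFIER", table$impact[idx])
  impact_order[min(match(impacts, impact_order))]
}

#' Functional class of an SO term
#'
#' @param so_term A single SO term.
#' @param table Impact table (defaults to [default_impact_table()]).
#' @return One of `"missense"`, `"nonsense"`, `"silent"`, `"none"`.
#' @export
functional_class <- function(so_term, table = default_impact_table()) {
  idx <- match(so_term, table$term)
  if (is.na(idx)) "none" else table$fclass[idx]
}

#' Count sites per chromosome arm
#'
#' Positions at or before the centromere belong to the short arm
#' (`<chrom>.1`), the rest to the long arm (`<chrom>.2`). The two counts
#' partition the sites of each chromosome.
#'
#' @param sites Site data frame with `chrom` and `pos`.
#' @param centromeres Named numeric vector of centromere positions (bp),
#'   one entry per chromosome appearing in `sites`.
#' @return Named integer vector keyed `<chrom>.1` / `<chrom>.2`.
#' @export
bin_by_arm <- function(sites, centromeres) {
  missing_cen <- setdiff(unique(sites$chrom), names(centromeres))
  if (length(missing_cen)) {
    stopf("no centromere position for chromosome(s): %s",
          paste(missing_cen, collapse = ", "))
  }
  arm <- ifelse(sites$pos <= centromeres[sites$chrom], ".1", ".2")
  key <- paste0(sites$chrom, arm)
  chroms <- names(centromeres)
  all_keys <- paste0(rep(chroms, each = 2), c(".1", ".2"))
  counts <- table(factor(key, levels = all_keys))
  out <- as.integer(counts)
  names(out) <- all_keys
  out
}

#' Write a genotype matrix as a GT-only VCF v4.2
#'
#' SO annotations, when present, are carried in the INFO `ANN=` field.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$geno + 1L],
                   nrow(gm$geno), ncol(gm$geno))
  gt_str[is.na(gm$geno)] <- "./."
  info <- if (!is.null(gm$sites$so_term)) {
    paste0("ANN=", gm$sites$so_term)
  } else {
    rep(".", nrow(gm$sites))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"SO term annotation\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(gm$sites)), function(i) {
    paste(c(gm$sites$chrom[i], sprintf("%.10g", gm$sites$pos[i]), ".",
            gm$sites$ref[i], gm$sites$alt[i], ".", "PASS", info[i], "GT",
            gt_str[i, ]), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a GT-only VCF into a genotype matrix
#'
#' Reading goes through `vcfR`. Only biallelic sites are supported:
#' records with more than one alternate allele are rejected, matching the
#' type-partitioned downstream summaries.
#'
#' @param path VCF path (plain text).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE))) {
    stopf("multiallelic site(s) with >1 ALT allele are not supported")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_integer_, length(x))
    out[x %in% "0/0"] <- GT_HOM_REF
    out[x %in% c("0/1", "1/0")] <- GT_HET
    out[x %in% "1/1"] <- GT_HOM_ALT
    out
  }
  geno <- apply(gt, 2, code)
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  info <- vcfR::getINFO(v)
  so <- ifelse(grepl("ANN=", info), sub(".*ANN=([^;]+).*", "\\1", info),
               NA_character_)
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.numeric(fix[, "POS"]),
                      ref = fix[, "REF"], alt = alt,
                      stringsAsFactors = FALSE)
  if (!all(is.na(so))) sites$so_term <- so
  genotype_matrix(sites, geno, colnames(gt))
}
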