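# Shared fixtures and independent brute-force oracles.

# Small, fast panel: 12 lines, five 20-Mb chromosomes, the usual three
# features (carriers L01-L05 / L06-L09 / L10-L12 fit within 12 lines).
fast_cfg <- function(seed = 7, ...) {
  chroms <- stats::setNames(rep(2e7, 5), c("1A", "1B", "2A", "2B", "7D"))
  sim_config(n_lines = 12, chromosomes = chroms, n_sites = 400,
             seed = seed, ...)
}

# One-row coverage record with a consistent covbases/coverage pair.
mk_rec <- function(rname, coverage, span = 1e6, meandepth = 10,
                   meanmapq = 35, line_id = NULL) {
  covbases <- round(coverage / 100 * span)
  rec <- coverage_table(data.frame(
    rname = rname, startpos = 1, endpos = span, numreads = 1000,
    covbases = covbases, coverage = 100 * covbases / span,
    meandepth = meandepth, meanbaseq = 36, meanmapq = meanmapq,
    stringsAsFactors = FALSE
  ))
  if (!is.null(line_id)) attr(rec, "line_id") <- line_id
  rec
}

# Brute-force per-site diversity: average pairwise difference over all
# pairs of called alleles.
brute_pi <- function(column) {
  called <- column[!is.na(column)]
  alleles <- unlist(lapply(called, function(g) {
    switch(as.character(g), "0" = c(0, 0), "1" = c(0, 1), "2" = c(1, 1))
  }))
  n <- length(alleles)
  if (n < 2) {
    return(NA_real_)
  }
  diffs <- 0
  for (i in seq_len(n - 1)) {
    diffs <- diffs + sum(alleles[i] != alleles[(i + 1):n])
  }
  diffs / (n * (n - 1) / 2)
}

# Brute-force site filter: recompute every quantity per site from first
# principles, independently of filter_sites/site_stats.
brute_filter_kept <- function(gm, maf_min, max_missing, max_het) {
  vapply(seq_len(nrow(gm$geno)), function(i) {
    g <- gm$geno[i, ]
    n <- length(g)
    miss <- sum(is.na(g)) / n
    called <- g[!is.na(g)]
    if (!length(called)) {
      return(FALSE)
    }
    het <- sum(called == 1L) / length(called)
    alt <- sum(called)
    tot <- 2 * length(called)
    freq <- alt / tot
    maf <- min(freq, 1 - freq)
    maf >= maf_min && miss <= max_missing && het <= max_het
  }, logical(1))
}

random_geno_matrix <- function(n_sites, n_samples,
                               probs = c(0.62, 0.08, 0.22, 0.08)) {
  geno <- matrix(
    sample(c(0L, 1L, 2L, NA_integer_), n_sites * n_samples, replace = TRUE,
           prob = probs),
    nrow = n_sites
  )
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt_kind <- sample(1:3, n_sites, replace = TRUE)
  alt <- vapply(seq_len(n_sites), function(i) {
    switch(alt_kind[i],
           sample(setdiff(bases, ref[i]), 1),
           paste0(ref[i], sample(bases, 1)),
           ref[i])
  }, "")
  is_del <- alt_kind == 3
  ref[is_del] <- paste0(ref[is_del], "T")
  sites <- data.frame(chrom = "1A", pos = sort(sample.int(1e6, n_sites)),
                      ref = ref, alt = alt, stringsAsFactors = FALSE)
  genotype_matrix(sites, geno, sprintf("S%02d", seq_len(n_samples)))
}

# Random unrooted binary tree with positive branch lengths and its
# (additive) leaf-to-leaf distance matrix.
random_additive_tree <- function(n_taxa) {
  tree <- ape::unroot(ape::rtree(n_taxa, br = NULL))
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.05, 1)
  d <- ape::cophenetic.phylo(tree)
  ord <- sort(rownames(d))
  list(tree = tree, d = d[ord, ord])
}
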