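# Nucleotide diversity and neighbor-joining trees from genotype data.

#' Per-site nucleotide diversity
#'
#' With `n` called alleles and allele frequencies `p_i`,
#' `pi = n/(n-1) * (1 - sum(p_i^2))`: the unbiased average pairwise
#' difference over all pairs of called alleles at the site. Sites with
#' fewer than two called alleles are undefined (`NA`).
#'
#' @param column Integer genotype codes for one site (0/1/2/NA); each
#'   called diploid genotype contributes two alleles.
#' @return A non-negative number, or `NA` if fewer than 2 alleles called.
#' @export
site_pi <- function(column) {
  called <- column[!is.na(column)]
  n <- 2 * length(called)
  if (n < 2) {
    return(NA_real_)
  }
  p_alt <- sum(called) / n
  (n / (n - 1)) * (1 - p_alt^2 - (1 - p_alt)^2)
}

#' Windowed per-base nucleotide diversity track
#'
#' Per window, the sum of [site_pi()] over the variant sites inside it
#' divided by the window width in bp: monomorphic and invariant bases
#' contribute zero to the numerator but their full length to the
#' denominator, giving a per-base value comparable across windows.
#'
#' @param gm A [genotype_matrix()] with sites sorted by position within
#'   chromosome.
#' @param window_bp Window width in bp.
#' @param chrom_lengths Named numeric vector of chromosome lengths; windows
#'   tile each chromosome.
#' @return Data frame with `chrom`, `start`, `end` (1-based inclusive) and
#'   `pi` (per-base) per window.
#' @export
windowed_pi <- function(gm, window_bp, chrom_lengths) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (window_bp <= 0) stopf("window_bp must be > 0")
  pis <- apply(gm$geno, 1, site_pi)
  pis[is.na(pis)] <- 0
  out <- list()
  for (chrom in names(chrom_lengths)) {
    len <- chrom_lengths[[chrom]]
    n_win <- ceiling(len / window_bp)
    on_chrom <- gm$sites$chrom == chrom
    win_idx <- floor((gm$sites$pos[on_chrom] - 1) / window_bp) + 1L
    sums <- vapply(seq_len(n_win), function(w) {
      sum(pis[on_chrom][win_idx == w])
    }, numeric(1))
    starts <- (seq_len(n_win) - 1) * window_bp + 1
    ends <- pmin(seq_len(n_win) * window_bp, len)
    out[[chrom]] <- data.frame(chrom = chrom, start = starts, end = ends,
                               pi = sums / window_bp,
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Identity-by-state distance matrix
#'
#' For a pair of samples, over the sites where both are called, each site
#' contributes the fraction of shared alleles (identical homozygotes share
#' 2/2, a homozygote and a heterozygote share 1/2, opposite homozygotes
#' share 0/2); the distance is one minus the mean shared fraction. A pair
#' with no co-called site has no defined distance and raises an error.
#'
#' @param gm A [genotype_matrix()] with at least two samples.
#' @return A symmetric matrix with zero diagonal, entries in `[0, 1]`,
#'   dimnames the sample ids.
#' @export
ibs_distance_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- length(gm$samples)
  if (n < 2) stopf("need at least two samples")
  d <- matrix(0, n, n, dimnames = list(gm$samples, gm$samples))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      ga <- gm$geno[, a]
      gb <- gm$geno[, b]
      both <- !is.na(ga) & !is.na(gb)
      if (!any(both)) {
        stopf("samples '%s' and '%s' share no called site",
              gm$samples[a], gm$samples[b])
      }
      shared <- 1 - abs(ga[both] - gb[both]) / 2
      d[a, b] <- d[b, a] <- 1 - mean(shared)
    }
  }
  d
}

fmt_bl <- function(x) sprintf("%.10g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j` is joined, with exact ties broken
#' by the lexicographic order of the (sorted) pair labels so the result is
#' deterministic; branch lengths follow the standard formulas and the
#' remaining three nodes resolve to an unrooted star with closed-form
#' lengths. On an additive (tree-like) metric the generating tree is
#' recovered exactly.
#'
#' @param d Symmetric distance matrix with zero diagonal and dimnames.
#' @return The tree in newick format (character scalar, terminated by
#'   `;`).
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-12))) {
    stopf("distance matrix must be symmetric")
  }
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 3) stopf("need at least 3 taxa")
  # Newick fragment per active node; leaf fragments are the labels.
  frags <- labels
  # Sort key used only for deterministic tie-breaking.
  keys <- labels

  while (n > 3) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_key <- apply(cand, 1, function(ij) {
      paste(sort(c(keys[ij[1]], keys[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(pair_key)[1], ]
    i <- pick[1]
    j <- pick[2]

    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    new_frag <- sprintf("(%s:%s,%s:%s)", frags[i], fmt_bl(li),
                        frags[j], fmt_bl(lj))
    new_key <- min(keys[i], keys[j])
    new_d <- (d[i, ] + d[j, ] - d[i, j]) / 2

    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- matrix(0, n - 1, n - 1)
    d2[seq_along(keep), seq_along(keep)] <- d[keep, keep]
    d2[n - 1, seq_along(keep)] <- d2[seq_along(keep), n - 1] <- new_d[keep]
    d <- d2
    frags <- c(frags[keep], new_frag)
    keys <- c(keys[keep], new_key)
    n <- n - 1
  }

  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  sprintf("(%s:%s,%s:%s,%s:%s);", frags[1], fmt_bl(la), frags[2], fmt_bl(lb),
          frags[3], fmt_bl(lc))
}
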