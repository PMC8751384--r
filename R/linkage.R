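#' Normalized linkage disequilibrium D' for one site pair
#'
#' With haplotype counts \code{n11, n10, n01, n00} (allele 1 = the site's
#' major allele), \code{p_A = (n11+n10)/n}, \code{p_B = (n11+n01)/n},
#' \code{D = n11/n - p_A p_B} and D' = |D|/D_max, where D_max is
#' \code{min(p_A (1-p_B), (1-p_A) p_B)} when D > 0 and
#' \code{min(p_A p_B, (1-p_A)(1-p_B))} when D < 0; D = 0 gives D' = 0.
#' D' equals 1 whenever at most three of the four haplotype classes are
#' observed, and is only below 1 when all four combinations occur.
#'
#' @param n11,n10,n01,n00 joint observation counts (vectors allowed)
#' @return D' in [0, 1]; NA when either site is monomorphic among the joint
#'   observations
#' @export
d_prime <- function(n11, n10, n01, n00) {
  # scaled by n^2 so everything stays in exact integer-valued arithmetic:
  # D*n^2 = n11*n00 - n10*n01, and each D_max candidate is a product of the
  # marginal counts
  a1 <- n11 + n10; a0 <- n01 + n00  # site A marginals
  b1 <- n11 + n01; b0 <- n10 + n00  # site B marginals
  mono <- a1 == 0 | a0 == 0 | b1 == 0 | b0 == 0
  d2 <- n11 * n00 - n10 * n01
  dmax2 <- ifelse(d2 > 0, pmin(a1 * b0, a0 * b1), pmin(a1 * b1, a0 * b0))
  out <- ifelse(d2 == 0, 0, abs(d2) / dmax2)
  ifelse(mono, NA_real_, out)
}

#' Collect joint observations for SNP pairs from read fragments
#'
#' Observations come only from fragments physically covering both sites of a
#' pair (single reads or short-insert read pairs). Pairs are restricted to
#' SNPs within \code{max_dist} bp with at least \code{min_pair_cov} joint
#' observations; alleles are restricted to each site's called major/minor,
#' other bases (e.g. sequencing errors) are dropped.
#'
#' @param reads fragment table from \code{\link{emit_reads}} (sample,
#'   population, hap, start, end)
#' @param truth the \code{sim_truth} supplying haplotype alleles
#' @param snps SNP table from \code{\link{call_snps}} (biallelic sites only;
#'   "multi" rows are ignored)
#' @param max_dist maximum pair distance in bp (default 500)
#' @param min_pair_cov minimum joint observations (default 10)
#' @param error_rate per-allele miscall probability applied at extraction
#'   (defaults to the truth config's error_rate)
#' @param max_pairs cap on scanned SNP pairs per population (deterministic
#'   subsample; default 20000)
#' @param by_population if TRUE (default) collect per population, plus "ALL"
#'   pooling every fragment
#' @param seed seed for the miscall stream and pair subsampling
#' @return data.frame: population, site_a, site_b, distance, n11, n10, n01,
#'   n00, d_prime
#' @export
collect_pair_observations <- function(reads, truth, snps, max_dist = 500,
                                      min_pair_cov = 10,
                                      error_rate = truth$config$error_rate,
                                      max_pairs = 20000,
                                      by_population = TRUE, seed = 1) {
  snps <- snps[snps$effect_class != "multi", , drop = FALSE]
  snps <- snps[order(snps$pos), , drop = FALSE]
  if (nrow(snps) < 2) {
    return(data.frame(population = character(), site_a = integer(),
                      site_b = integer(), distance = integer(),
                      n11 = integer(), n10 = integer(), n01 = integer(),
                      n00 = integer(), d_prime = numeric()))
  }
  set.seed(stage_seed(seed, 5L))
  alle <- haplotype_alleles(truth)
  mut_pos <- truth$mutations$pos
  ref_chars <- strsplit(truth$annotation$contigs[[1]], "")[[1]]
  # allele of haplotype h at an arbitrary position: ref unless mutated
  allele_at <- function(p, hap) {
    i <- match(p, mut_pos)
    if (is.na(i)) rep(ref_chars[p], length(hap)) else alle[i, hap]
  }
  # candidate pairs within max_dist
  pos <- snps$pos
  pairs <- list()
  for (i in seq_len(length(pos) - 1)) {
    j <- which(pos > pos[i] & pos <= pos[i] + max_dist)
    if (length(j)) pairs[[length(pairs) + 1]] <- cbind(i, j)
  }
  if (length(pairs) == 0) return(collect_pair_observations(reads, truth,
                                                           snps[0, ], max_dist,
                                                           min_pair_cov))
  pairs <- do.call(rbind, pairs)
  if (nrow(pairs) > max_pairs) {
    pairs <- pairs[sort(sample.int(nrow(pairs), max_pairs)), , drop = FALSE]
    sp_log("linkage", "scanning a deterministic subsample of ", max_pairs,
           " SNP pairs")
  }
  groups <- if (by_population) {
    g <- split(seq_len(nrow(reads)), reads$population)
    g$ALL <- seq_len(nrow(reads))
    g
  } else list(ALL = seq_len(nrow(reads)))

  out <- list()
  for (gname in names(groups)) {
    rd <- reads[groups[[gname]], ]
    o <- order(rd$start)
    rstart <- rd$start[o]
    rhap <- rd$hap[o]
    flen <- rd$end[1] - rd$start[1] + 1L
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      pa <- pos[i]; pb <- pos[j]
      lo <- findInterval(pb - flen, rstart) + 1L  # first start > pb - flen
      hi <- findInterval(pa, rstart)              # last start <= pa
      if (hi < lo) next
      haps <- rhap[lo:hi]
      a <- allele_at(pa, haps)
      b <- allele_at(pb, haps)
      if (error_rate > 0) {
        flip <- stats::runif(length(a)) < error_rate
        a[flip] <- vapply(a[flip], function(x) sample(setdiff(BASES, x), 1), "")
        flip <- stats::runif(length(b)) < error_rate
        b[flip] <- vapply(b[flip], function(x) sample(setdiff(BASES, x), 1), "")
      }
      keep <- a %in% c(snps$major[i], snps$minor[i]) &
        b %in% c(snps$major[j], snps$minor[j])
      a <- a[keep]; b <- b[keep]
      n <- length(a)
      if (n < min_pair_cov) next
      a1 <- a == snps$major[i]
      b1 <- b == snps$major[j]
      n11 <- sum(a1 & b1); n10 <- sum(a1 & !b1)
      n01 <- sum(!a1 & b1); n00 <- sum(!a1 & !b1)
      dp <- d_prime(n11, n10, n01, n00)
      if (is.na(dp)) next  # a site monomorphic among joint observations
      out[[length(out) + 1]] <- data.frame(
        population = gname, site_a = pa, site_b = pb,
        distance = pb - pa, n11 = n11, n10 = n10, n01 = n01, n00 = n00,
        d_prime = dp, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(population = character(), site_a = integer(),
                      site_b = integer(), distance = integer(),
                      n11 = integer(), n10 = integer(), n01 = integer(),
                      n00 = integer(), d_prime = numeric()))
  }
  do.call(rbind, out)
}

#' Aggregate D' over qualifying pairs
#'
#' Unweighted mean D' across pairs within each population (and optionally a
#' per-distance decay table for diagnostics).
#'
#' @param pairs output of \code{\link{collect_pair_observations}}
#' @param decay_bins optional numeric bin width (bp) to also return a
#'   per-distance decay table
#' @return data.frame population, mean_dprime, n_pairs; with attribute
#'   \code{decay} when \code{decay_bins} is given
#' @export
d_prime_aggregate <- function(pairs, decay_bins = NULL) {
  if (nrow(pairs) == 0) {
    return(data.frame(population = character(), mean_dprime = numeric(),
                      n_pairs = integer()))
  }
  dt <- data.table::as.data.table(pairs)
  agg <- dt[, .(mean_dprime = mean(d_prime), n_pairs = .N), by = population]
  out <- as.data.frame(agg)
  if (!is.null(decay_bins)) {
    dec <- dt[, .(mean_dprime = mean(d_prime), n_pairs = .N),
              by = .(population, bin = decay_bins * (distance %/% decay_bins))]
    attr(out, "decay") <- as.data.frame(dec[order(population, bin)])
  }
  out
}
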