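#' Call SNPs from pooled population counts
#'
#' A site is a SNP iff, in the pooled "ALL" population, coverage is at least
#' \code{min_cov} and the second-most-common base has count at least
#' \code{min_minor_count} and frequency at least \code{min_minor_freq}.
#' The effect class is assigned against the reference codon: "S"/"N" inside a
#' CDS, "intergenic" outside, and "multi" when a third allele also clears the
#' minor-allele thresholds (such sites are excluded from the biallelic pN/pS
#' and D' machinery but still contribute to pi).
#'
#' @param pooled population-pooled sitecounts from
#'   \code{\link{pool_populations}} (must contain the "ALL" population)
#' @param annotation the species' \code{genome_annotation}
#' @param min_cov minimum ALL coverage (default 5)
#' @param min_minor_count minimum minor-allele count (default 4)
#' @param min_minor_freq minimum minor-allele frequency (default 0.05)
#' @return data.frame in the \code{snps} schema: species, contig, pos, ref,
#'   major, minor, coverage, major_freq, gene_id, effect_class
#' @export
call_snps <- function(pooled, annotation, min_cov = 5, min_minor_count = 4,
                      min_minor_freq = 0.05) {
  dt <- data.table::as.data.table(pooled)[sample == "ALL"]
  assert_that(nrow(dt) > 0, "pooled table has no ALL population")
  cnt <- as.matrix(dt[, c("nA", "nC", "nG", "nT")])
  cov <- rowSums(cnt)
  ord <- t(apply(cnt, 1, order, decreasing = TRUE))
  top1 <- cnt[cbind(seq_len(nrow(cnt)), ord[, 1])]
  top2 <- cnt[cbind(seq_len(nrow(cnt)), ord[, 2])]
  top3 <- cnt[cbind(seq_len(nrow(cnt)), ord[, 3])]
  is_snp <- cov >= min_cov & top2 >= min_minor_count &
    top2 / cov >= min_minor_freq
  if (!any(is_snp)) {
    sp_log("call", "no SNPs called")
    return(data.frame(species = character(), contig = character(),
                      pos = integer(), ref = character(), major = character(),
                      minor = character(), coverage = integer(),
                      major_freq = numeric(), gene_id = character(),
                      effect_class = character(), stringsAsFactors = FALSE))
  }
  idx <- which(is_snp)
  snps <- data.frame(
    species = dt$species[idx], contig = dt$contig[idx], pos = dt$pos[idx],
    ref = dt$ref[idx],
    major = BASES[ord[idx, 1]], minor = BASES[ord[idx, 2]],
    coverage = as.integer(cov[idx]),
    major_freq = top1[idx] / cov[idx],
    stringsAsFactors = FALSE
  )
  multi <- top3[idx] >= min_minor_count & top3[idx] / cov[idx] >= min_minor_freq
  snps$gene_id <- NA_character_
  snps$effect_class <- "intergenic"
  for (ctg in unique(snps$contig)) {
    ctx <- codon_context(annotation, ctg)
    sel <- snps$contig == ctg
    gi <- ctx$gene_idx[snps$pos[sel]]
    snps$gene_id[sel] <- ifelse(gi > 0,
                                annotation$genes$gene_id[pmax(gi, 1L)],
                                NA_character_)
  }
  coding <- !is.na(snps$gene_id)
  if (any(coding)) {
    # the polymorphism is classified as ref -> top non-reference allele
    alt <- ifelse(snps$major == snps$ref, snps$minor, snps$major)
    cls <- vapply(which(coding), function(i) {
      if (alt[i] == snps$ref[i]) return("S")  # degenerate: ref not among top-2
      classify_snp_effect(annotation, snps$gene_id[i], snps$pos[i],
                          snps$ref[i], alt[i])
    }, character(1))
    snps$effect_class[coding] <- cls
  }
  snps$effect_class[multi] <- "multi"
  sp_log("call", nrow(snps), " SNPs called (", sum(multi), " multiallelic)")
  snps
}

#' Per-site nucleotide diversity from allele counts
#'
#' Unbiased average pairwise difference among the n sampled reads:
#' \code{pi = n/(n-1) * (1 - sum_b p_b^2)}. Sites with fewer than 2 reads are
#' undefined (NA) and excluded from aggregates.
#'
#' @param counts_at_site numeric vector of length 4 (A, C, G, T counts) or a
#'   matrix with 4 columns for many sites
#' @return numeric diversity per site
#' @export
pi_site <- function(counts_at_site) {
  m <- if (is.matrix(counts_at_site)) counts_at_site else
    matrix(counts_at_site, nrow = 1)
  n <- rowSums(m)
  p2 <- rowSums((m / pmax(n, 1))^2)
  out <- ifelse(n >= 2, n / (n - 1) * (1 - p2), NA_real_)
  if (!is.matrix(counts_at_site)) out[1] else out
}

#' Aggregate site diversities to gene or genome level
#'
#' The denominator is the number of gated positions at the level's scope,
#' variant and invariant alike; this is what gives genome-scale magnitudes
#' comparable across populations.
#'
#' @param site_pis per-site diversities (NA sites are dropped from the
#'   numerator only)
#' @param denominator_sites number of gated positions in scope
#' @return mean per-site diversity
#' @export
pi_aggregate <- function(site_pis, denominator_sites) {
  assert_that(denominator_sites > 0, "zero denominator in pi_aggregate")
  sum(site_pis, na.rm = TRUE) / denominator_sites
}

#' Per-population genome diversity and SNP density
#'
#' For each population in a pooled table: gated positions are those with
#' coverage at least \code{min_cov}; pi is the sum of site diversities over
#' the gated denominator; the SNP count restricted to gated positions gives
#' SNPs/Mbp.
#'
#' @param pooled population-pooled sitecounts
#' @param snps SNP table from \code{\link{call_snps}}
#' @param min_cov minimum coverage for a position to enter the denominator
#' @return data.frame: species, population, pi, n_sites, snp_count,
#'   snps_per_mbp, mean_coverage
#' @export
genome_diversity <- function(pooled, snps, min_cov = 5) {
  dt <- data.table::as.data.table(pooled)
  cnt <- as.matrix(dt[, c("nA", "nC", "nG", "nT")])
  cov <- rowSums(cnt)
  pis <- pi_site(cnt)
  dt2 <- data.table::data.table(species = dt$species, population = dt$sample,
                                contig = dt$contig, pos = dt$pos,
                                cov = cov, pi = pis)
  snp_key <- paste(snps$species, snps$contig, snps$pos)
  dt2[, is_snp := paste(species, contig, pos) %in% snp_key]
  out <- dt2[cov >= min_cov,
             .(pi = sum(pi, na.rm = TRUE) / .N, n_sites = .N,
               snp_count = sum(is_snp), mean_coverage = mean(cov)),
             by = .(species, population)]
  out[, snps_per_mbp := snp_count / (n_sites / 1e6)]
  as.data.frame(out[, .(species, population, pi, n_sites, snp_count,
                        snps_per_mbp, mean_coverage)])
}

#' Major-allele frequency matrix for common SNPs
#'
#' Rows are "common" SNPs: called in the pooled ALL population and covered
#' strictly above \code{min_cov} reads in every included population; entries
#' are the frequency of the ALL-major allele in that population. Any SNP not
#' clearing the coverage bar in some population is dropped entirely.
#'
#' @param pooled population-pooled sitecounts
#' @param snps SNP table from \code{\link{call_snps}}
#' @param min_cov coverage that must be exceeded (strictly) in every
#'   population (default 5)
#' @return numeric matrix (common SNPs x populations), rownames
#'   "contig:pos"
#' @export
major_allele_matrix <- function(pooled, snps, min_cov = 5) {
  dt <- data.table::as.data.table(pooled)[sample != "ALL"]
  pops <- sort(unique(dt$sample))
  key <- paste(dt$contig, dt$pos)
  snp_key <- paste(snps$contig, snps$pos)
  dt <- dt[key %in% snp_key]
  cnt <- as.matrix(dt[, c("nA", "nC", "nG", "nT")])
  cov <- rowSums(cnt)
  maj <- snps$major[match(paste(dt$contig, dt$pos), snp_key)]
  freq <- cnt[cbind(seq_len(nrow(cnt)), match(maj, BASES))] / pmax(cov, 1)
  wide_f <- data.table::dcast(
    data.table::data.table(snp_id = paste(dt$contig, dt$pos, sep = ":"),
                           pop = dt$sample, f = freq, cov = cov),
    snp_id ~ pop, value.var = c("f", "cov")
  )
  fcols <- paste0("f_", pops)
  ccols <- paste0("cov_", pops)
  covm <- as.matrix(wide_f[, ccols, with = FALSE])
  covm[is.na(covm)] <- 0
  keep <- rowSums(covm > min_cov) == length(pops)
  m <- as.matrix(wide_f[keep, fcols, with = FALSE])
  colnames(m) <- pops
  rownames(m) <- wide_f$snp_id[keep]
  sp_log("matrix", sum(keep), " common SNPs retained of ", nrow(wide_f),
         " called")
  m
}

#' Flag local clonal expansions
#'
#' A population is flagged when it is well covered (mean coverage at least
#' \code{min_cov}) yet nearly monomorphic relative to the species: local pi
#' at most \code{pi_ratio} times the species-wide (ALL) pi.
#'
#' @param genome_stats output of \code{\link{genome_diversity}}
#' @param pi_ratio maximum local/ALL diversity ratio (default 0.1)
#' @param min_cov minimum mean coverage guard (default 10)
#' @return input with a logical \code{clonal_expansion} column
#' @export
flag_clonal_expansion <- function(genome_stats, pi_ratio = 0.1, min_cov = 10) {
  out <- genome_stats
  out$clonal_expansion <- FALSE
  for (sp in unique(out$species)) {
    sel <- out$species == sp
    all_pi <- out$pi[sel & out$population == "ALL"]
    if (length(all_pi) != 1 || is.na(all_pi) || all_pi == 0) {
      sp_log("clonal", "species-wide pi unavailable or zero for ", sp,
             "; no flags")
      next
    }
    here <- sel & out$population != "ALL"
    out$clonal_expansion[here] <- out$mean_coverage[here] >= min_cov &
      out$pi[here] <= pi_ratio * all_pi
  }
  out
}
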