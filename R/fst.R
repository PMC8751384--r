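#' Hudson F_ST for one biallelic site
#'
#' Hudson-style estimator with small-sample heterozygosity correction:
#' \code{F_ST = 1 - Hw/Hb} with
#' \code{Hw = [2 p1 (1-p1) n1/(n1-1) + 2 p2 (1-p2) n2/(n2-1)] / 2} and
#' \code{Hb = p1 (1-p2) + p2 (1-p1)}. Sites with \code{Hb = 0} or coverage
#' below \code{min_cov} in either population are skipped (NA). The reported
#' value is clamped to [0, 1]; the unclamped Hw and Hb components are also
#' returned for ratio-of-averages aggregation.
#'
#' @param p1,p2 allele frequencies of the same allele in the two populations
#' @param n1,n2 read depths in the two populations
#' @param min_cov minimum depth per population (default 20)
#' @return data.frame fst (clamped), hw, hb; vector inputs allowed
#' @export
site_fst <- function(p1, n1, p2, n2, min_cov = 20) {
  ok <- n1 >= min_cov & n2 >= min_cov
  hw <- (2 * p1 * (1 - p1) * n1 / (n1 - 1) +
           2 * p2 * (1 - p2) * n2 / (n2 - 1)) / 2
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- ifelse(!ok | hb == 0, NA_real_, 1 - hw / hb)
  n_skip <- sum(!ok)
  if (n_skip > 0) sp_log("fst", n_skip, " sites below ", min_cov,
                         "x in one population skipped")
  data.frame(fst = pmin(pmax(fst, 0), 1), hw = ifelse(ok, hw, NA_real_),
             hb = ifelse(ok, hb, NA_real_))
}

#' Per-site F_ST table for one population pair
#'
#' Sites segregating across the two populations (pooled top-2 alleles) with
#' coverage at least \code{min_cov} in both. Frequencies refer to the pooled
#' pair's most common allele.
#'
#' @param pooled population-pooled sitecounts
#' @param pop_a,pop_b population ids
#' @param min_cov minimum depth in each population (default 20)
#' @return data.frame: contig, pos, p1, n1, p2, n2, fst, hw, hb
#' @export
fst_sites <- function(pooled, pop_a, pop_b, min_cov = 20) {
  dt <- data.table::as.data.table(pooled)[sample %in% c(pop_a, pop_b)]
  w <- data.table::dcast(dt, contig + pos ~ sample,
                         value.var = c("nA", "nC", "nG", "nT"), fill = 0L)
  c1 <- as.matrix(w[, paste0(c("nA_", "nC_", "nG_", "nT_"), pop_a),
                    with = FALSE])
  c2 <- as.matrix(w[, paste0(c("nA_", "nC_", "nG_", "nT_"), pop_b),
                    with = FALSE])
  tot <- c1 + c2
  ord <- t(apply(tot, 1, order, decreasing = TRUE))
  a1 <- ord[, 1]; a2 <- ord[, 2]
  n1 <- rowSums(c1); n2 <- rowSums(c2)
  i <- seq_len(nrow(w))
  # restrict to the pooled pair's top-2 alleles
  x1 <- c1[cbind(i, a1)]; y1 <- c1[cbind(i, a2)]
  x2 <- c2[cbind(i, a1)]; y2 <- c2[cbind(i, a2)]
  seg <- tot[cbind(i, a2)] > 0  # segregating across the pair
  p1 <- x1 / pmax(x1 + y1, 1)
  p2 <- x2 / pmax(x2 + y2, 1)
  res <- site_fst(p1, x1 + y1, p2, x2 + y2, min_cov = min_cov)
  out <- data.frame(contig = w$contig, pos = w$pos, p1 = p1, n1 = x1 + y1,
                    p2 = p2, n2 = x2 + y2, res, stringsAsFactors = FALSE)
  out[seg & !is.na(res$fst), , drop = FALSE]
}

#' Gene-level F_ST by ratio of averages
#'
#' \code{1 - sum(Hw)/sum(Hb)} over the gene's qualifying segregating sites
#' (the variance-stabilizing ratio-of-averages form), clamped to [0, 1] with
#' clamp events logged. Reduces to the site estimator for a single site.
#'
#' @param site_records output of \code{\link{fst_sites}}, already subset to
#'   one gene
#' @return numeric F_ST, or NA when no qualifying site
#' @export
gene_fst <- function(site_records) {
  if (nrow(site_records) == 0) return(NA_real_)
  raw <- 1 - sum(site_records$hw) / sum(site_records$hb)
  if (raw < 0 || raw > 1) sp_log("fst", "gene F_ST clamped from ",
                                 format(raw, digits = 4))
  min(max(raw, 0), 1)
}

#' Gene F_ST table for one or all population pairs
#'
#' @param pooled population-pooled sitecounts
#' @param annotation the species' \code{genome_annotation}
#' @param pairs optional 2-column matrix/data.frame of population pairs;
#'   default all unordered pairs excluding "ALL"
#' @param min_cov minimum depth per population per site (default 20)
#' @param retained optional data.frame (population-pair agnostic) from
#'   \code{\link{gate_gene_coverage}} restricting genes per population
#' @return data.frame in the \code{fst_pairs} schema plus n_sites
#' @export
fst_genes <- function(pooled, annotation, pairs = NULL, min_cov = 20,
                      retained = NULL) {
  pops <- setdiff(unique(pooled$sample), "ALL")
  if (is.null(pairs)) {
    pairs <- t(utils::combn(sort(pops), 2))
  }
  g <- annotation$genes
  species <- unique(pooled$species)
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    pa <- pairs[k, 1]; pb <- pairs[k, 2]
    sites <- fst_sites(pooled, pa, pb, min_cov = min_cov)
    for (gi in seq_len(nrow(g))) {
      if (!is.null(retained)) {
        ok_a <- retained$retained[retained$population == pa &
                                    retained$gene_id == g$gene_id[gi]]
        ok_b <- retained$retained[retained$population == pb &
                                    retained$gene_id == g$gene_id[gi]]
        if (length(ok_a) == 1 && !ok_a || length(ok_b) == 1 && !ok_b) next
      }
      sel <- sites$contig == g$contig_id[gi] & sites$pos >= g$start[gi] &
        sites$pos <= g$end[gi]
      out[[length(out) + 1]] <- data.frame(
        species = species, pop_a = pa, pop_b = pb, gene_id = g$gene_id[gi],
        fst = gene_fst(sites[sel, , drop = FALSE]), n_sites = sum(sel),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Detect runs of highly differentiated genes and test them
#'
#' A locus is a run of at least \code{window} consecutive genes (genome
#' order within a contig) whose gene F_ST z-score against the genome-wide
#' gene F_ST distribution is at least \code{z_thresh}. For each locus a
#' two-sample Wilcoxon test compares the locus' site-level D' with the rest
#' of the genome, and a two-sample t test compares its site-level pi with the
#' rest; each p-value family is Benjamini-Hochberg adjusted across loci.
#'
#' @param gene_table data.frame with gene_id, contig, start, fst (one
#'   population pair)
#' @param site_pi data.frame gene_id, pi: site-level diversities mapped to
#'   genes
#' @param site_dprime data.frame gene_id, d_prime: pair-level D' mapped to
#'   genes
#' @param window minimum run length in genes (default 3)
#' @param z_thresh z-score threshold (default 2)
#' @return data.frame, one row per locus: contig, first_gene, last_gene,
#'   n_genes, mean_fst, mean_pi, mean_dprime, linkage_p, diversity_p
#' @export
high_fst_loci <- function(gene_table, site_pi, site_dprime, window = 3,
                          z_thresh = 2) {
  ok <- !is.na(gene_table$fst)
  assert_that(sum(ok) >= 30,
              "locus scan refused: fewer than 30 genes with defined F_ST")
  mu <- mean(gene_table$fst[ok]); s <- stats::sd(gene_table$fst[ok])
  if (s == 0) return(empty_loci())
  gene_table$z <- (gene_table$fst - mu) / s
  gene_table <- gene_table[order(gene_table$contig, gene_table$start), ]
  loci <- list()
  for (ctg in unique(gene_table$contig)) {
    gt <- gene_table[gene_table$contig == ctg, ]
    hot <- !is.na(gt$z) & gt$z >= z_thresh
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (ri in which(r$values & r$lengths >= window)) {
      gid <- gt$gene_id[starts[ri]:ends[ri]]
      loci[[length(loci) + 1]] <- list(contig = ctg, genes = gid,
                                       mean_fst = mean(gt$fst[starts[ri]:ends[ri]]))
    }
  }
  if (length(loci) == 0) return(empty_loci())
  rows <- lapply(loci, function(lc) {
    in_pi <- site_pi$pi[site_pi$gene_id %in% lc$genes]
    out_pi <- site_pi$pi[!(site_pi$gene_id %in% lc$genes)]
    in_d <- site_dprime$d_prime[site_dprime$gene_id %in% lc$genes]
    out_d <- site_dprime$d_prime[!(site_dprime$gene_id %in% lc$genes)]
    lp <- if (length(in_d) >= 2 && length(out_d) >= 2) {
      stats::wilcox.test(in_d, out_d, exact = FALSE)$p.value
    } else NA_real_
    dp <- if (length(in_pi) >= 2 && length(out_pi) >= 2) {
      stats::t.test(in_pi, out_pi)$p.value
    } else NA_real_
    data.frame(contig = lc$contig, first_gene = lc$genes[1],
               last_gene = lc$genes[length(lc$genes)],
               n_genes = length(lc$genes), mean_fst = lc$mean_fst,
               mean_pi = mean(in_pi), mean_dprime = mean(in_d),
               linkage_p = lp, diversity_p = dp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$linkage_p <- stats::p.adjust(out$linkage_p, method = "BH")
  out$diversity_p <- stats::p.adjust(out$diversity_p, method = "BH")
  out
}

empty_loci <- function() {
  data.frame(contig = character(), first_gene = character(),
             last_gene = character(), n_genes = integer(),
             mean_fst = numeric(), mean_pi = numeric(),
             mean_dprime = numeric(), linkage_p = numeric(),
             diversity_p = numeric(), stringsAsFactors = FALSE)
}

#' Flag selective-sweep candidate loci
#'
#' A high-F_ST locus is a sweep candidate iff its diversity test is
#' significant with locus mean pi below the genome mean (diversity lost) and
#' its linkage test is significant with locus mean D' above the genome mean
#' (few recombinant haplotypes) — high F_ST, low pi, high D'.
#'
#' @param loci output of \code{\link{high_fst_loci}} (BH-adjusted p-values)
#' @param genome_mean_pi genome-wide mean site pi
#' @param genome_mean_dprime genome-wide mean pair D'
#' @param alpha adjusted-p threshold (default 0.05)
#' @return loci with a logical \code{sweep_flag} column
#' @export
sweep_candidates <- function(loci, genome_mean_pi, genome_mean_dprime,
                             alpha = 0.05) {
  if (nrow(loci) == 0) {
    loci$sweep_flag <- logical(0)
    return(loci)
  }
  loci$sweep_flag <- !is.na(loci$diversity_p) & loci$diversity_p < alpha &
    loci$mean_pi < genome_mean_pi &
    !is.na(loci$linkage_p) & loci$linkage_p < alpha &
    loci$mean_dprime > genome_mean_dprime
  loci
}

#' Jaccard dissimilarity between population allele profiles
#'
#' Binarizes the major-allele frequency matrix — an entry is "present" iff
#' the population's major allele at that SNP equals the ALL-population major
#' allele (frequency >= 0.5) — then computes the pairwise Jaccard
#' dissimilarity (\code{vegan::vegdist}, binary): 0 means identical allele
#' profiles.
#'
#' @param mat common-SNP x population matrix from
#'   \code{\link{major_allele_matrix}}
#' @return population x population dissimilarity matrix
#' @export
allele_profile_dissimilarity <- function(mat) {
  assert_that(nrow(mat) > 0, "empty major-allele matrix")
  bin <- t(mat >= 0.5) * 1
  as.matrix(vegan::vegdist(bin, method = "jaccard", binary = TRUE))
}

#' Mantel test between two distance matrices
#'
#' Statistic r is the Pearson correlation of the lower-triangle entries;
#' significance comes from random row/column permutations of the second
#' matrix with the observed value included in the null set:
#' \code{p = (1 + #(r_perm >= r_obs)) / (n_perm + 1)} (identity permutations
#' are resampled).
#'
#' @param m_a,m_b square symmetric matrices over the same objects
#' @param n_perm number of permutations (default 100000, as used for the
#'   geographic-distance correlations)
#' @param seed random seed
#' @return list with r and p
#' @export
mantel_test <- function(m_a, m_b, n_perm = 100000, seed = 1) {
  assert_that(is.matrix(m_a) && is.matrix(m_b) &&
                nrow(m_a) == ncol(m_a) && identical(dim(m_a), dim(m_b)),
              "mantel_test needs two square matrices of the same size")
  n <- nrow(m_a)
  lt <- lower.tri(m_a)
  r_obs <- stats::cor(m_a[lt], m_b[lt])
  set.seed(stage_seed(seed, 6L))
  hits <- 0L
  for (k in seq_len(n_perm)) {
    repeat {
      perm <- sample.int(n)
      if (!all(perm == seq_len(n))) break
    }
    r_p <- stats::cor(m_a[lt], m_b[perm, perm][lt])
    if (r_p >= r_obs) hits <- hits + 1L
  }
  list(r = r_obs, p = (1 + hits) / (n_perm + 1))
}
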