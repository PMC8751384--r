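#' Ratio of nonsynonymous to synonymous polymorphism
#'
#' \code{pN/pS = (nN/NN) / (nS/NS)} with nN, nS observed polymorphism counts
#' and NN, NS Nei-Gojobori potential-site counts. \code{nS = 0} with
#' \code{nN > 0} is reported as \code{Inf} (the "no synonymous polymorphism"
#' flag); \code{nN = nS = 0} is undefined (NA). Genome-level values should sum
#' raw counts over retained genes before calling this.
#'
#' @param n_nonsyn,n_syn observed nonsynonymous / synonymous SNP counts
#' @param nonsyn_sites,syn_sites potential-site counts
#' @return numeric ratio, possibly Inf or NA
#' @export
pnps <- function(n_nonsyn, n_syn, nonsyn_sites, syn_sites) {
  ifelse(n_nonsyn == 0 & n_syn == 0, NA_real_,
         ifelse(n_syn == 0, Inf,
                (n_nonsyn / nonsyn_sites) / (n_syn / syn_sites)))
}

#' Per-gene selection statistics
#'
#' Counts classified S/N SNPs per gene, adds Nei-Gojobori potential sites for
#' each gene's CDS and the per-gene pN, pS and pN/pS. Multiallelic and
#' intergenic SNPs are excluded.
#'
#' @param snps SNP table from \code{\link{call_snps}}
#' @param annotation the species' \code{genome_annotation}
#' @param genes optional character vector restricting the gene set (defaults
#'   to every annotated gene)
#' @return data.frame: gene_id, n_codons, nonsyn_sites, syn_sites, n_nonsyn,
#'   n_syn, pn, ps, pnps
#' @export
gene_selection_stats <- function(snps, annotation, genes = NULL) {
  genes <- genes %||% annotation$genes$gene_id
  sites <- t(vapply(genes, function(g) {
    count_potential_sites(gene_cds_seq(annotation, g), g)
  }, numeric(2)))
  coding <- snps[snps$effect_class %in% c("S", "N") & !is.na(snps$gene_id), ]
  nN <- vapply(genes, function(g) {
    sum(coding$gene_id == g & coding$effect_class == "N")
  }, integer(1))
  nS <- vapply(genes, function(g) {
    sum(coding$gene_id == g & coding$effect_class == "S")
  }, integer(1))
  out <- data.frame(
    gene_id = genes,
    n_codons = (annotation$genes$end - annotation$genes$start + 1)[
      match(genes, annotation$genes$gene_id)] / 3,
    nonsyn_sites = sites[, "nonsyn_sites"], syn_sites = sites[, "syn_sites"],
    n_nonsyn = nN, n_syn = nS,
    pn = nN / sites[, "nonsyn_sites"], ps = nS / sites[, "syn_sites"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$pnps <- pnps(out$n_nonsyn, out$n_syn, out$nonsyn_sites, out$syn_sites)
  out
}

#' Genome-level pN/pS
#'
#' Sums raw S/N SNP and potential-site counts over the retained genes, then
#' takes the ratio.
#'
#' @param gene_stats output of \code{\link{gene_selection_stats}}, already
#'   restricted to retained genes
#' @return list with n_nonsyn, n_syn, nonsyn_sites, syn_sites and pnps
#' @export
genome_pnps <- function(gene_stats) {
  nN <- sum(gene_stats$n_nonsyn); nS <- sum(gene_stats$n_syn)
  NN <- sum(gene_stats$nonsyn_sites); NS <- sum(gene_stats$syn_sites)
  list(n_nonsyn = nN, n_syn = nS, nonsyn_sites = NN, syn_sites = NS,
       pnps = pnps(nN, nS, NN, NS))
}

#' Scan for genes under positive selection
#'
#' Each gene's (nN, nS) counts are compared with the genome-minus-gene
#' background by a one-sided Fisher exact test toward an excess of
#' nonsynonymous polymorphism; p-values are Benjamini-Hochberg adjusted
#' across genes. Outliers are genes with adjusted p below \code{alpha} and
#' pN/pS above 1 — the "above 1 and significantly higher than the genomic
#' average" rule. A gene with nonsynonymous polymorphism but \code{pS = 0}
#' (infinite ratio) satisfies the above-1 condition.
#'
#' @param gene_stats output of \code{\link{gene_selection_stats}} (at least
#'   20 genes with defined counts)
#' @param alpha adjusted-p cutoff (default 0.05)
#' @return gene_stats with columns outlier_p (adjusted) and outlier (flag)
#' @export
positive_selection_scan <- function(gene_stats, alpha = 0.05) {
  assert_that(nrow(gene_stats) >= 20,
              "positive-selection scan needs at least 20 genes")
  tot_n <- sum(gene_stats$n_nonsyn); tot_s <- sum(gene_stats$n_syn)
  if (tot_n + tot_s == 0) {
    warning("degenerate background: no classified polymorphisms")
    gene_stats$outlier_p <- NA_real_
    gene_stats$outlier <- FALSE
    return(gene_stats)
  }
  p <- vapply(seq_len(nrow(gene_stats)), function(i) {
    m <- matrix(c(gene_stats$n_nonsyn[i], gene_stats$n_syn[i],
                  tot_n - gene_stats$n_nonsyn[i], tot_s - gene_stats$n_syn[i]),
                nrow = 2, byrow = TRUE)
    stats::fisher.test(m, alternative = "greater")$p.value
  }, numeric(1))
  gene_stats$outlier_p <- stats::p.adjust(p, method = "BH")
  gene_stats$outlier <- gene_stats$outlier_p < alpha &
    !is.na(gene_stats$pnps) & gene_stats$pnps > 1
  sp_log("selection", sum(gene_stats$outlier), " positive-selection outlier genes")
  gene_stats
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with the tie-corrected variance,
#' two-sided p-values, Holm-adjusted.
#'
#' @param values numeric response
#' @param groups group labels
#' @return data.frame group_a, group_b, z, p, p_adj
#' @export
dunn_test <- function(values, groups) {
  groups <- as.character(groups)
  ok <- !is.na(values)
  values <- values[ok]; groups <- groups[ok]
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- sort(unique(groups))
  mean_rank <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  out <- list()
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (j <= i) next
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                 (1 / n[[lev[i]]] + 1 / n[[lev[j]]]))
    z <- (mean_rank[[lev[i]]] - mean_rank[[lev[j]]]) / se
    out[[length(out) + 1]] <- data.frame(
      group_a = lev[i], group_b = lev[j], z = z,
      p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res$p_adj <- stats::p.adjust(res$p, method = "holm")
  res
}

# compact letter display by insert-and-absorb: groups not significantly
# different share at least one letter, significantly different groups share
# none
letter_groups <- function(levels, sig_pairs) {
  sets <- list(levels)
  for (k in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$group_a[k]; b <- sig_pairs$group_b[k]
    repeat {
      hit <- which(vapply(sets, function(s) all(c(a, b) %in% s), logical(1)))
      if (length(hit) == 0) break
      s <- hit[1]
      sets <- c(sets, list(setdiff(sets[[s]], a)), list(setdiff(sets[[s]], b)))
      sets[s] <- NULL
    }
    # absorb subsumed sets
    keep <- rep(TRUE, length(sets))
    for (s in seq_along(sets)) {
      for (t in seq_along(sets)) {
        if (s != t && keep[t] && all(sets[[s]] %in% sets[[t]]) &&
            length(sets[[s]]) < length(sets[[t]])) keep[s] <- FALSE
      }
    }
    sets <- sets[keep]
  }
  labs <- vapply(levels, function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = "")
  }, character(1))
  labs
}

#' Compare a per-gene metric across gene classes
#'
#' Kruskal-Wallis across classes followed by Dunn's test with Holm
#' correction and a compact letter display: classes sharing a letter are not
#' significantly different.
#'
#' @param values per-gene metric (e.g. pi, D', pN/pS)
#' @param classes gene class labels (e.g. amoA, nxrB, other)
#' @param min_per_class classes with fewer members are excluded with a
#'   warning (default 3)
#' @param alpha significance level for the letter display (default 0.05)
#' @return list with kruskal (htest), dunn (data.frame), letters (named
#'   character)
#' @export
compare_gene_classes <- function(values, classes, min_per_class = 3,
                                 alpha = 0.05) {
  classes <- as.character(classes)
  ok <- !is.na(values)
  values <- values[ok]; classes <- classes[ok]
  tab <- table(classes)
  small <- names(tab)[tab < min_per_class]
  if (length(small) > 0) {
    warning("classes excluded (fewer than ", min_per_class, " genes): ",
            paste(small, collapse = ", "))
    keep <- !(classes %in% small)
    values <- values[keep]; classes <- classes[keep]
  }
  assert_that(length(unique(classes)) >= 2,
              "need at least 2 classes with enough genes")
  kw <- stats::kruskal.test(values, factor(classes))
  dn <- dunn_test(values, classes)
  lev <- sort(unique(classes))
  sig <- dn[dn$p_adj < alpha, , drop = FALSE]
  list(kruskal = kw, dunn = dn, letters = letter_groups(lev, sig))
}
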