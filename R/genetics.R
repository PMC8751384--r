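# Codon-level machinery: synonymous/nonsynonymous classification of observed
# polymorphisms and Nei-Gojobori potential-site counting. Internal codons use
# the standard genetic code (stop read-through is nonsynonymous); alternative
# start-codon handling is deliberately not applied to internal codons.

.genetics_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(.genetics_env$aa)) return(.genetics_env)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- stats::setNames(as.character(gc), codons)
  # syn_frac[codon, pos]: fraction of the 3 possible substitutions at that
  # codon position that leave the amino acid unchanged (stop counts as "aa")
  syn_frac <- matrix(0, nrow = length(codons), ncol = 3,
                     dimnames = list(codons, NULL))
  syn_alts <- list()
  nonsyn_alts <- list()
  for (cdn in codons) {
    ref_aa <- aa[[cdn]]
    for (p in 1:3) {
      alts <- setdiff(BASES, substr(cdn, p, p))
      mut <- vapply(alts, function(b) {
        x <- cdn
        substr(x, p, p) <- b
        aa[[x]]
      }, character(1))
      syn <- alts[mut == ref_aa]
      syn_frac[cdn, p] <- length(syn) / 3
      key <- paste0(cdn, p)
      syn_alts[[key]] <- syn
      nonsyn_alts[[key]] <- setdiff(alts, syn)
    }
  }
  .genetics_env$aa <- aa
  .genetics_env$syn_frac <- syn_frac
  .genetics_env$syn_alts <- syn_alts
  .genetics_env$nonsyn_alts <- nonsyn_alts
  .genetics_env
}

#' Classify a single-base substitution within a codon
#'
#' @param codon reference codon (coding strand, upper case)
#' @param pos_in_codon 1, 2 or 3
#' @param alt_base substituted base on the coding strand
#' @return "S" if the substituted codon encodes the same amino acid, else "N"
#' @export
classify_substitution <- function(codon, pos_in_codon, alt_base) {
  tb <- codon_tables()
  mut <- codon
  substr(mut, pos_in_codon, pos_in_codon) <- alt_base
  if (identical(tb$aa[[mut]], tb$aa[[codon]])) "S" else "N"
}

#' Classify a SNP inside a gene as synonymous or nonsynonymous
#'
#' The codon is derived on the coding strand using the gene's frame; on
#' minus-strand genes the genomic alleles are complemented first, so a genomic
#' G->A at codon position 1 of a minus-strand gene is classified as coding
#' C->T. Each SNP is classified against the reference codon independently of
#' other polymorphisms in the same codon.
#'
#' @param ann a \code{genome_annotation}
#' @param gene_id gene containing the SNP
#' @param pos genomic 1-based position of the SNP
#' @param ref_base,alt_base genomic-strand alleles
#' @return "S" or "N"
#' @export
classify_snp_effect <- function(ann, gene_id, pos, ref_base, alt_base) {
  g <- ann$genes[ann$genes$gene_id == gene_id, ]
  assert_that(nrow(g) == 1, paste("unknown gene:", gene_id))
  assert_that(pos >= g$start && pos <= g$end, "SNP outside the CDS")
  cds <- gene_cds_seq(ann, gene_id)
  if (g$strand == "+") {
    cpos <- pos - g$start + 1
    a_ref <- ref_base
    a_alt <- alt_base
  } else {
    cpos <- g$end - pos + 1
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    a_ref <- comp[[ref_base]]
    a_alt <- comp[[alt_base]]
  }
  codon_i <- (cpos - 1) %/% 3
  off <- cpos - 3 * codon_i
  codon <- substr(cds, 3 * codon_i + 1, 3 * codon_i + 3)
  assert_that(identical(substr(codon, off, off), a_ref),
              sprintf("reference allele mismatch at %s:%d", gene_id, pos))
  classify_substitution(codon, off, a_alt)
}

#' Nei-Gojobori potential synonymous and nonsynonymous site counts
#'
#' Equal-weight site counting: at each codon position the synonymous fraction
#' is (number of the 3 possible substitutions that are synonymous)/3; sites
#' accumulate over codons so that syn + nonsyn = 3 x n_codons exactly.
#'
#' @param cds_seq coding-strand CDS sequence (length a multiple of 3)
#' @param gene_id label used in error messages
#' @return named numeric vector \code{c(nonsyn_sites=, syn_sites=)}
#' @export
count_potential_sites <- function(cds_seq, gene_id = "gene") {
  n <- nchar(cds_seq)
  assert_that(n %% 3 == 0, paste("CDS length not multiple of 3:", gene_id))
  tb <- codon_tables()
  codons <- substring(cds_seq, seq(1, n, 3), seq(3, n, 3))
  internal <- codons[-length(codons)]
  if (any(tb$aa[internal] == "*")) {
    stop("internal stop codon in gene ", gene_id, call. = FALSE)
  }
  syn <- sum(tb$syn_frac[codons, ])
  c(nonsyn_sites = 3 * length(codons) - syn, syn_sites = syn)
}

# Admissible substitution alleles at a genomic position given codon context;
# used by the simulator to realize a synonymous or nonsynonymous mutation.
# Returns genomic-strand alternative bases.
admissible_alts <- function(ann, gene_id, pos, ref_base, class) {
  g <- ann$genes[ann$genes$gene_id == gene_id, ]
  cds <- gene_cds_seq(ann, gene_id)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (g$strand == "+") {
    cpos <- pos - g$start + 1
    a_ref <- ref_base
  } else {
    cpos <- g$end - pos + 1
    a_ref <- comp[[ref_base]]
  }
  codon_i <- (cpos - 1) %/% 3
  off <- cpos - 3 * codon_i
  codon <- substr(cds, 3 * codon_i + 1, 3 * codon_i + 3)
  tb <- codon_tables()
  key <- paste0(codon, off)
  alts <- if (class == "S") tb$syn_alts[[key]] else tb$nonsyn_alts[[key]]
  if (g$strand == "-") alts <- unname(comp[alts])
  alts
}
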