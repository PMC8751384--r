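#' @importFrom stats rpois rbinom rgamma rnbinom var cor sd setNames
#'   fisher.test p.adjust kruskal.test wilcox.test t.test pnorm
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".N", ".BY", "coverage", "species", "population", "pos", "contig",
  "ref", "nA", "nC", "nG", "nT", "passed", "fraction_genome_ge_depth",
  "n_covered", "mean_coverage", "retained", "is_snp", "pi", "snp_count",
  "n_sites", "snps_per_mbp", "gene_id", "d_prime", "distance", "bin"
))

BASES <- c("A", "C", "G", "T")

#' Emit a tagged log line
#'
#' Line-oriented logging used across all stages; every filtered or excluded
#' entity (read, site, gene, pair, sample) is reported through this channel.
#'
#' @param stage short stage tag, e.g. "pool" or "fst"
#' @param ... message parts, pasted with no separator
#' @keywords internal
sp_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

# deterministic stage-scoped seed derived from one root seed; offsets keep
# streams independent across stages while staying below .Machine$integer.max
stage_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483647L
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
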