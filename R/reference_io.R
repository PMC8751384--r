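#' Read a reference genome and its coding-gene annotation
#'
#' Loads contig sequences from FASTA and CDS features from a GFF3 file into a
#' validated \code{genome_annotation} object. Only CDS features are consumed;
#' other feature types are counted and logged. Genes on the minus strand are
#' stored with their genomic coordinates, and codon-level logic always operates
#' on the coding-strand sequence obtained through \code{\link{gene_cds_seq}}.
#'
#' @param fasta_path path to the reference FASTA
#' @param gff_path path to a GFF3 file whose CDS records carry \code{ID} and
#'   optionally \code{product} and \code{gene_class} attributes
#' @param species_id label for this species; defaults to the FASTA basename
#' @return a \code{genome_annotation}: list with \code{species_id},
#'   \code{contigs} (named character vector) and \code{genes} (data.frame with
#'   gene_id, contig_id, start, end, strand, product, gene_class)
#' @export
read_reference <- function(fasta_path, gff_path, species_id = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  contigs <- stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  gr <- rtracklayer::import(gff_path)
  n_other <- sum(gr$type != "CDS")
  if (n_other > 0) sp_log("reference", n_other, " non-CDS features ignored")
  gr <- gr[gr$type == "CDS"]
  meta <- S4Vectors::mcols(gr)
  genes <- data.frame(
    gene_id = as.character(meta$ID %||% paste0("gene_", seq_along(gr))),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = as.character(meta$product %||% rep(NA_character_, length(gr))),
    gene_class = as.character(meta$gene_class %||% rep("other", length(gr))),
    stringsAsFactors = FALSE
  )
  genes$gene_class[is.na(genes$gene_class)] <- "other"
  ann <- genome_annotation(species_id %||% sub("\\.[^.]*$", "", basename(fasta_path)),
                           contigs, genes)
  n_amb <- sum(vapply(contigs, function(s) {
    sum(strsplit(s, "")[[1]] %in% c("A", "C", "G", "T") == FALSE)
  }, integer(1)))
  if (n_amb > 0) sp_log("reference", n_amb, " ambiguous reference bases; ",
                        "those sites are excluded from all statistics")
  ann
}

#' Construct and validate a genome annotation
#'
#' @param species_id species label
#' @param contigs named character vector of contig sequences
#' @param genes data.frame of gene models (gene_id, contig_id, start, end,
#'   strand, optional product and gene_class)
#' @export
genome_annotation <- function(species_id, contigs, genes) {
  genes$product <- genes$product %||% rep(NA_character_, nrow(genes))
  genes$gene_class <- genes$gene_class %||% rep("other", nrow(genes))
  ann <- structure(
    list(species_id = species_id, contigs = contigs, genes = genes),
    class = "genome_annotation"
  )
  validate_annotation(ann)
  ann
}

#' Validate a genome annotation
#'
#' Checks the structural invariants: unique gene ids, genes within contig
#' bounds, start <= end, strand in +/- and CDS lengths that are multiples of 3.
#'
#' @param ann a \code{genome_annotation}
#' @return the annotation, invisibly; stops with an informative error naming
#'   the offending gene otherwise
#' @export
validate_annotation <- function(ann) {
  g <- ann$genes
  assert_that(!anyDuplicated(g$gene_id), "duplicate gene_id in annotation")
  assert_that(all(g$contig_id %in% names(ann$contigs)),
              "gene on unknown contig")
  assert_that(all(g$strand %in% c("+", "-")), "gene strand must be + or -")
  bad <- g$gene_id[g$start > g$end | g$start < 1 |
                     g$end > nchar(ann$contigs)[match(g$contig_id, names(ann$contigs))]]
  if (length(bad) > 0) {
    stop("gene coordinates out of contig bounds: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  len <- g$end - g$start + 1
  bad <- g$gene_id[len %% 3 != 0]
  if (length(bad) > 0) {
    stop("CDS length not multiple of 3: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(ann)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation '%s': %d contig(s), %s bp, %d genes\n",
              x$species_id, length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ","), nrow(x$genes)))
  invisible(x)
}

#' Coding-strand sequence of a gene
#'
#' Extracts the CDS from genomic coordinates; minus-strand genes are
#' reverse-complemented so the result always reads 5'->3' on the coding strand.
#'
#' @param ann a \code{genome_annotation}
#' @param gene_id gene identifier
#' @return character scalar, the coding sequence
#' @export
gene_cds_seq <- function(ann, gene_id) {
  g <- ann$genes[ann$genes$gene_id == gene_id, ]
  assert_that(nrow(g) == 1, paste("unknown gene:", gene_id))
  s <- substr(ann$contigs[[g$contig_id]], g$start, g$end)
  if (g$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

#' Read a sitecounts table
#'
#' The sitecounts format is a TSV with header
#' \code{species contig pos ref sample nA nC nG nT}, one row per
#' (species, contig, 1-based position, sample), giving the A/C/G/T counts of
#' filtered reads at that position.
#'
#' @param path TSV path
#' @return data.table with typed columns and no duplicate keys
#' @export
read_site_counts <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("species", "contig", "ref", "sample"),
                                            integer = c("pos", "nA", "nC", "nG", "nT")))
  need <- c("species", "contig", "pos", "ref", "sample", "nA", "nC", "nG", "nT")
  assert_that(identical(names(dt), need),
              paste("sitecounts header must be:", paste(need, collapse = " ")))
  if (nrow(dt) == 0) return(dt)
  assert_that(all(dt$ref %in% BASES), "non-ACGT ref base in sitecounts")
  assert_that(all(dt$pos >= 1), "positions must be 1-based positive")
  cnt <- as.matrix(dt[, c("nA", "nC", "nG", "nT")])
  assert_that(all(cnt >= 0), "negative counts in sitecounts")
  if (anyDuplicated(dt[, c("species", "contig", "pos", "sample")])) {
    stop("duplicate (species, contig, pos, sample) rows in sitecounts",
         call. = FALSE)
  }
  dt
}

#' Read sample metadata
#'
#' TSV with at least \code{sample} and \code{population} columns (the
#' population is the waterworks in the motivating study); any additional
#' numeric columns are kept as chemistry/covariates.
#'
#' @param path TSV path
#' @return data.frame keyed by unique sample
#' @export
read_sample_metadata <- function(path) {
  md <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  assert_that(all(c("sample", "population") %in% names(md)),
              "metadata needs 'sample' and 'population' columns")
  assert_that(!anyDuplicated(md$sample), "duplicate sample ids in metadata")
  md
}

#' Read a species abundance table
#'
#' @param path TSV whose first column is \code{species} and remaining columns
#'   one sample each (non-negative abundances, relative or counts)
#' @return numeric matrix species x samples
#' @export
read_abundance <- function(path) {
  ab <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  assert_that(names(ab)[1] == "species", "first abundance column must be 'species'")
  m <- as.matrix(ab[, -1, drop = FALSE])
  rownames(m) <- ab$species
  assert_that(all(m >= 0), "negative abundances")
  assert_that(nrow(m) >= 2 && ncol(m) >= 2, "need >= 2 species and >= 2 samples")
  m
}

# Fixed column orders for every result schema; writers and readers share them
# so round-trips are identity.
.schemas <- list(
  genome_stats = c("species", "population", "pi", "n_sites", "snp_count",
                   "snps_per_mbp", "mean_dprime", "n_pairs", "pnps",
                   "n_nonsyn", "n_syn", "mean_coverage", "clonal_expansion"),
  gene_stats = c("species", "population", "gene_id", "contig", "start", "end",
                 "gene_class", "mean_coverage", "pi", "n_sites",
                 "n_nonsyn", "n_syn", "pn", "ps", "pnps"),
  snps = c("species", "contig", "pos", "ref", "major", "minor", "coverage",
           "major_freq", "gene_id", "effect_class"),
  fst_pairs = c("species", "pop_a", "pop_b", "gene_id", "fst", "n_sites"),
  loci = c("species", "pop_a", "pop_b", "contig", "first_gene", "last_gene",
           "n_genes", "mean_fst", "mean_pi", "mean_dprime",
           "linkage_p", "diversity_p", "sweep_flag"),
  network_edges = c("source", "target", "rho"),
  truth = c("species", "contig", "pos", "ref", "alt", "class", "derived_count")
)

#' Write a result table in one of the fixed schemas
#'
#' @param rows data.frame with exactly the schema's columns (any order)
#' @param path output TSV path
#' @param schema_name one of genome_stats, gene_stats, snps, fst_pairs, loci,
#'   network_edges, truth
#' @export
write_table <- function(rows, path, schema_name) {
  cols <- .schemas[[schema_name]]
  if (is.null(cols)) stop("unknown schema: ", schema_name, call. = FALSE)
  assert_that(setequal(names(rows), cols),
              paste0("columns for schema '", schema_name, "' must be exactly: ",
                     paste(cols, collapse = ", ")))
  data.table::fwrite(rows[, cols, drop = FALSE], path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' Read back a result table written by \code{\link{write_table}}
#'
#' @inheritParams write_table
#' @export
read_result_table <- function(path, schema_name) {
  cols <- .schemas[[schema_name]]
  if (is.null(cols)) stop("unknown schema: ", schema_name, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = "NA")
  assert_that(identical(names(dt), cols),
              paste("unexpected columns for schema", schema_name))
  dt
}
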