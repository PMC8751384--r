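#' Percent identity of an alignment
#'
#' Identity over aligned columns (soft-clipped bases excluded):
#' \code{(aligned_length - edit_distance) / aligned_length * 100}.
#'
#' @param aligned_length number of aligned columns
#' @param edit_distance edit distance (NM) over those columns
#' @return percent identity in [0, 100]
#' @export
percent_identity <- function(aligned_length, edit_distance) {
  (aligned_length - edit_distance) / aligned_length * 100
}

#' Read-level alignment filter
#'
#' A record is kept iff mapping quality is at least \code{min_mapq}, percent
#' identity is at least \code{min_identity} and the read pair maps uniquely
#' best in the joint reference index. Both thresholds are inclusive.
#'
#' @param rec data.frame of alignment record summaries with columns
#'   \code{mapq}, \code{percent_identity}, \code{pair_uniquely_best}
#' @param min_mapq minimum mapping quality (default 30)
#' @param min_identity minimum percent identity (default 96)
#' @return logical keep flag per record
#' @export
filter_alignment_record <- function(rec, min_mapq = 30, min_identity = 96.0) {
  assert_that(all(rec$percent_identity >= 0 & rec$percent_identity <= 100),
              "percent_identity must be in [0, 100]")
  rec$mapq >= min_mapq & rec$percent_identity >= min_identity &
    as.logical(rec$pair_uniquely_best)
}

#' Sitecounts from a coordinate-sorted SAM/BAM alignment
#'
#' Thin pileup wrapper for users starting from alignments rather than
#' sitecounts: applies the mapping-quality filter at pileup time. The percent
#' identity and unique-best-pair filters act on whole records and should be
#' applied when producing the BAM (or via \code{\link{filter_alignment_record}}
#' on a record summary); the returned attribute \code{entry_point} records
#' that this path was used.
#'
#' @param bam_path SAM/BAM path (SAM is converted in memory)
#' @param species_id species label for the output rows
#' @param sample_id sample label for the output rows
#' @param reference a \code{genome_annotation} supplying reference bases
#' @param min_mapq minimum mapping quality (default 30)
#' @return sitecounts data.table
#' @export
site_counts_from_bam <- function(bam_path, species_id, sample_id, reference,
                                 min_mapq = 30) {
  if (grepl("\\.sam$", bam_path)) {
    bam_path <- Rsamtools::asBam(bam_path,
                                 destination = tempfile(),
                                 overwrite = TRUE, indexDestination = TRUE)
  }
  p <- Rsamtools::pileup(
    bam_path,
    scanBamParam = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
      mapqFilter = min_mapq
    ),
    pileupParam = Rsamtools::PileupParam(
      max_depth = 100000, min_base_quality = 0, min_mapq = min_mapq,
      distinguish_strands = FALSE, include_insertions = FALSE
    )
  )
  p <- p[p$nucleotide %in% BASES, ]
  dt <- data.table::dcast(
    data.table::as.data.table(p),
    seqnames + pos ~ nucleotide, value.var = "count", fun.aggregate = sum,
    fill = 0L
  )
  for (b in BASES) if (!b %in% names(dt)) dt[[b]] <- 0L
  ref_chars <- strsplit(reference$contigs, "")
  out <- data.table::data.table(
    species = species_id, contig = as.character(dt$seqnames), pos = dt$pos,
    ref = mapply(function(ctg, pp) ref_chars[[ctg]][pp],
                 as.character(dt$seqnames), dt$pos),
    sample = sample_id,
    nA = as.integer(dt$A), nC = as.integer(dt$C),
    nG = as.integer(dt$G), nT = as.integer(dt$T)
  )
  attr(out, "entry_point") <- "alignment"
  out
}

#' Genome breadth-of-coverage gate for one (species, sample)
#'
#' A sample passes for a species iff at least \code{min_breadth} of the genome
#' is covered at depth \code{min_depth} or more (both inclusive). Positions
#' absent from the counts are treated as depth 0.
#'
#' @param counts sitecounts table
#' @param genome_lengths named vector, species -> genome length (bp)
#' @param min_breadth minimum covered fraction (default 0.5)
#' @param min_depth minimum depth defining "covered" (default 5)
#' @return gate report data.frame: species, sample, fraction_genome_ge_depth,
#'   passed
#' @export
gate_sample_genome <- function(counts, genome_lengths, min_breadth = 0.5,
                               min_depth = 5) {
  dt <- data.table::copy(data.table::as.data.table(counts))
  dt[, coverage := nA + nC + nG + nT]
  rep_dt <- dt[, .(n_covered = sum(coverage >= min_depth)),
               by = .(species, sample)]
  assert_that(all(rep_dt$species %in% names(genome_lengths)),
              "unknown species genome length")
  rep_dt[, fraction_genome_ge_depth :=
           n_covered / genome_lengths[species]]
  rep_dt[, passed := fraction_genome_ge_depth >= min_breadth]
  failed <- rep_dt[!(passed)]
  if (nrow(failed) > 0) {
    sp_log("gate", nrow(failed), " sample-genome combinations failed the ",
           min_breadth * 100, "% breadth at ", min_depth, "x gate")
  }
  as.data.frame(rep_dt[, .(species, sample, fraction_genome_ge_depth, passed)])
}

#' Pool sample counts into population-level profiles
#'
#' Counts of retained samples are summed per population, plus a synthetic
#' "ALL" population summing every retained sample. Populations left with no
#' retained sample are dropped with a log entry. Pooling conserves counts
#' exactly.
#'
#' @param counts sitecounts table
#' @param metadata sample metadata (columns sample, population)
#' @param gate optional gate report from \code{\link{gate_sample_genome}};
#'   if given, only passing (species, sample) combinations are pooled
#' @return sitecounts table whose \code{sample} column holds population ids
#'   (including "ALL")
#' @export
pool_populations <- function(counts, metadata, gate = NULL) {
  dt <- data.table::copy(data.table::as.data.table(counts))
  assert_that(all(dt$sample %in% metadata$sample),
              "every sitecounts sample must be present in metadata")
  if (!is.null(gate)) {
    keep <- gate[gate$passed, c("species", "sample")]
    before <- length(unique(dt$sample))
    dt <- dt[paste(species, sample) %in% paste(keep$species, keep$sample)]
    sp_log("pool", before - length(unique(dt$sample)),
           " samples removed by the breadth gate")
  }
  dt[, population := metadata$population[match(sample, metadata$sample)]]
  dropped <- setdiff(unique(metadata$population), unique(dt$population))
  if (length(dropped) > 0) {
    sp_log("pool", "populations with no retained samples dropped: ",
           paste(dropped, collapse = ", "))
  }
  pooled <- dt[, .(nA = sum(nA), nC = sum(nC), nG = sum(nG), nT = sum(nT)),
               by = .(species, contig, pos, ref, sample = population)]
  all_pop <- dt[, .(nA = sum(nA), nC = sum(nC), nG = sum(nG), nT = sum(nT),
                    sample = "ALL"),
                by = .(species, contig, pos, ref)]
  out <- rbind(pooled, all_pop[, names(pooled), with = FALSE])
  data.table::setorder(out, species, contig, pos, sample)
  out[]
}

#' Per-population gene coverage gate
#'
#' Within each (species, population), genes whose mean coverage lies outside
#' mean +/- \code{sd_mult} standard deviations of that population's per-gene
#' coverage distribution are excluded. With fewer than 3 genes no exclusion is
#' performed (warning logged).
#'
#' @param gene_cov data.frame with species, population, gene_id,
#'   mean_coverage
#' @param sd_mult exclusion width in standard deviations (default 2)
#' @return input with a logical \code{retained} column
#' @export
gate_gene_coverage <- function(gene_cov, sd_mult = 2) {
  dt <- data.table::copy(data.table::as.data.table(gene_cov))
  dt[, retained := {
    if (.N < 3) {
      sp_log("gene-gate", "fewer than 3 genes for ", .BY$species, "/",
             .BY$population, "; no exclusion applied")
      rep(TRUE, .N)
    } else {
      s <- stats::sd(mean_coverage)
      if (s == 0) rep(TRUE, .N) else
        abs(mean_coverage - mean(mean_coverage)) <= sd_mult * s
    }
  }, by = .(species, population)]
  n_out <- sum(!dt$retained)
  if (n_out > 0) sp_log("gene-gate", n_out, " genes excluded by the ",
                        sd_mult, "-SD coverage gate")
  as.data.frame(dt)
}
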