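test_that("substitution classification matches the genetic code", {
  expect_identical(classify_substitution("TTT", 3, "C"), "S")  # Phe/Phe
  expect_identical(classify_substitution("TTT", 3, "A"), "N")  # Phe->Leu
  # stop read-through is nonsynonymous
  expect_identical(classify_substitution("TAA", 1, "C"), "N")
})

test_that("classification agrees with brute-force translation, all 576 cases", {
  codons <- names(Biostrings::GENETIC_CODE)
  for (cdn in codons) {
    ref_aa <- as.character(Biostrings::translate(Biostrings::DNAString(cdn),
                                                 no.init.codon = TRUE))
    for (p in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(cdn, p, p))) {
        mut <- cdn
        substr(mut, p, p) <- b
        mut_aa <- as.character(Biostrings::translate(Biostrings::DNAString(mut),
                                                     no.init.codon = TRUE))
        expect_identical(classify_substitution(cdn, p, b),
                         if (identical(ref_aa, mut_aa)) "S" else "N")
      }
    }
  }
})

test_that("minus-strand SNPs are classified on the coding strand", {
  ann <- toy_annotation()
  # gminus codes ATG CCC TAA; genomic 16..24 = TTAGGGCAT. Codon 2 (CCC) maps
  # to genomic positions 21,20,19 (all G). Codon position 1 = genomic 21:
  # genomic G->A is coding C->T, CCC(Pro)->TCC(Ser), nonsynonymous.
  expect_identical(classify_snp_effect(ann, "gminus", 21, "G", "A"), "N")
  # codon position 3 = genomic 19: genomic G->C is coding C->G,
  # CCC(Pro)->CCG(Pro), synonymous
  expect_identical(classify_snp_effect(ann, "gminus", 19, "G", "C"), "S")
  expect_error(classify_snp_effect(ann, "gminus", 3, "G", "A"), "outside")
})

test_that("potential-site counting is exact per codon and conserves totals", {
  expect_equal(count_potential_sites("ATG"),
               c(nonsyn_sites = 3, syn_sites = 0))
  expect_equal(count_potential_sites("TTT"),
               c(nonsyn_sites = 8 / 3, syn_sites = 1 / 3))
  set.seed(4)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  for (i in 1:10) {
    cds <- paste(c(sample(sense, 30, replace = TRUE), "TAA"), collapse = "")
    ps <- count_potential_sites(cds)
    expect_equal(unname(sum(ps)), 3 * 31)
  }
  expect_error(count_potential_sites("ATGTAACCC", "gX"), "internal stop.*gX")
})

test_that("pN/pS arithmetic and degenerate cases", {
  expect_equal(pnps(2, 6, 600, 200), (2 / 600) / (6 / 200), tolerance = 1e-12)
  expect_equal(pnps(2, 6, 600, 200), 0.1111, tolerance = 1e-3)
  expect_equal(pnps(0, 5, 600, 200), 0)
  expect_true(is.infinite(pnps(3, 0, 600, 200)))
  expect_true(is.na(pnps(0, 0, 600, 200)))
})

test_that("an all-synonymous simulation yields genome pN/pS of 0", {
  cfg <- sim_config(seed = 6, genome_length = 6000, n_genes = 5,
                    ns_fraction = 0, target_pi = 0.02, error_rate = 0)
  ann <- simulate_reference(cfg)
  truth <- suppressMessages(
    assign_population_frequencies(simulate_haplotypes(ann, cfg)))
  pooled <- suppressMessages(pool_populations(emit_site_counts(truth),
                                              sim_sample_metadata(truth)))
  snps <- suppressMessages(call_snps(pooled, ann))
  gp <- genome_pnps(gene_selection_stats(snps, ann))
  expect_equal(gp$n_nonsyn, 0)
  expect_gt(gp$n_syn, 10)
  expect_equal(gp$pnps, 0)
})

test_that("genome pN/pS orders with the simulated nonsynonymous fraction", {
  run_pnps <- function(seed, nsf) {
    cfg <- sim_config(seed = seed, genome_length = 6000, n_genes = 5,
                      ns_fraction = nsf, target_pi = 0.015, error_rate = 0)
    ann <- simulate_reference(cfg)
    truth <- suppressMessages(
      assign_population_frequencies(simulate_haplotypes(ann, cfg)))
    pooled <- suppressMessages(pool_populations(emit_site_counts(truth),
                                                sim_sample_metadata(truth)))
    snps <- suppressMessages(call_snps(pooled, ann))
    genome_pnps(gene_selection_stats(snps, ann))$pnps
  }
  for (s in 1:5) expect_lt(run_pnps(s, 0.2), run_pnps(s, 0.8))
})

test_that("the positive-selection scan flags constructed outliers only", {
  # 50 genes: background carries mostly synonymous polymorphism; one gene is
  # loaded with nonsynonymous changes
  stats_tbl <- data.frame(
    gene_id = sprintf("g%02d", 1:50), n_codons = 200,
    nonsyn_sites = 450, syn_sites = 150,
    n_nonsyn = c(20L, rep(2L, 49)), n_syn = c(0L, rep(6L, 49))
  )
  stats_tbl$pn <- stats_tbl$n_nonsyn / stats_tbl$nonsyn_sites
  stats_tbl$ps <- stats_tbl$n_syn / stats_tbl$syn_sites
  stats_tbl$pnps <- pnps(stats_tbl$n_nonsyn, stats_tbl$n_syn,
                         stats_tbl$nonsyn_sites, stats_tbl$syn_sites)
  got <- suppressMessages(positive_selection_scan(stats_tbl))
  expect_true(got$outlier[1])  # pS = 0 with many nonsyn: Inf-flag counts as >1
  # give the focal gene one synonymous polymorphism for a finite ratio
  stats_tbl$n_syn[1] <- 1L
  stats_tbl$pnps <- pnps(stats_tbl$n_nonsyn, stats_tbl$n_syn,
                         stats_tbl$nonsyn_sites, stats_tbl$syn_sites)
  got <- suppressMessages(positive_selection_scan(stats_tbl))
  expect_true(got$outlier[1])
  expect_false(any(got$outlier[-1]))
  # a gene identical in composition to the background is never an outlier
  expect_gt(got$outlier_p[2], 0.5)
  expect_error(positive_selection_scan(stats_tbl[1:10, ]), "at least 20")
})

test_that("gene-class comparisons: Kruskal-Wallis, Dunn, letter groups", {
  set.seed(2)
  same <- data.frame(v = rnorm(30), cls = rep(c("a", "b", "c"), each = 10))
  res <- compare_gene_classes(same$v, same$cls)
  expect_gt(res$kruskal$p.value, 0.05)
  expect_true(all(res$dunn$p_adj > 0.05))
  expect_true(length(unique(res$letters)) == 1)

  # disjoint ranges separate cleanly
  two <- data.frame(v = c(1:10, 101:110), cls = rep(c("lo", "hi"), each = 10))
  res2 <- compare_gene_classes(two$v, two$cls)
  expect_lt(res2$dunn$p_adj[1], 0.01)
  expect_false(res2$letters[["lo"]] == res2$letters[["hi"]])

  # letter-sharing contract on a 3-class layout: lo vs hi differ, mid is
  # ambiguous and shares a letter with both
  three <- data.frame(v = c(1:10, 6:15, 101:110),
                      cls = rep(c("lo", "mid", "hi"), each = 10))
  res3 <- compare_gene_classes(three$v, three$cls)
  sig <- res3$dunn[res3$dunn$p_adj < 0.05, ]
  for (k in seq_len(nrow(sig))) {
    la <- strsplit(res3$letters[[sig$group_a[k]]], "")[[1]]
    lb <- strsplit(res3$letters[[sig$group_b[k]]], "")[[1]]
    expect_equal(length(intersect(la, lb)), 0)
  }
  ns <- res3$dunn[res3$dunn$p_adj >= 0.05, ]
  for (k in seq_len(nrow(ns))) {
    la <- strsplit(res3$letters[[ns$group_a[k]]], "")[[1]]
    lb <- strsplit(res3$letters[[ns$group_b[k]]], "")[[1]]
    expect_gt(length(intersect(la, lb)), 0)
  }
  expect_warning(
    compare_gene_classes(c(1:10, 11:20, 5), rep(c("a", "b", "c"), c(10, 10, 1))),
    "excluded")
})
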