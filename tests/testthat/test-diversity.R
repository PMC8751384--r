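test_that("per-site pi equals exhaustive read-pair enumeration", {
  expect_equal(pi_site(c(5, 0, 0, 5)), 25 / 45)   # 0.5556
  expect_equal(pi_site(c(8, 0, 0, 0)), 0)
  expect_equal(pi_site(c(1, 0, 0, 1)), 1)
  expect_true(is.na(pi_site(c(1, 0, 0, 0))))

  set.seed(99)
  for (i in 1:200) {
    counts <- as.vector(stats::rmultinom(1, sample(2:30, 1), runif(4)))
    expect_equal(pi_site(counts), pi_site_oracle(counts), tolerance = 1e-12)
  }
})

make_pooled <- function(rows) {
  # reference bases follow the toy contig (ATGTTTTAA...)
  refs <- strsplit("ATGTTTTAA", "")[[1]][seq_len(nrow(rows))]
  cbind(data.frame(species = "sp", contig = "c1", pos = seq_len(nrow(rows)),
                   ref = refs, sample = "ALL", stringsAsFactors = FALSE),
        stats::setNames(as.data.frame(rows), c("nA", "nC", "nG", "nT")))
}

test_that("SNP calling applies the coverage and minor-allele thresholds", {
  ann <- toy_annotation()
  pooled <- make_pooled(rbind(
    c(96, 0, 4, 0),    # minor freq 0.04 < 0.05 -> no call
    c(90, 0, 10, 0),   # call, major A at 0.9
    c(70, 20, 10, 0),  # triallelic -> multi
    c(3, 2, 0, 0)      # coverage 5, minor count 2 < 4 -> no call
  ))
  snps <- suppressMessages(call_snps(pooled, ann))
  expect_equal(snps$pos, c(2L, 3L))
  expect_equal(snps$major[1], "A")
  expect_equal(snps$major_freq[1], 0.9)
  expect_equal(snps$effect_class[2], "multi")
})

test_that("lowering the minor-allele frequency never removes a call", {
  s <- small_sim()
  strict <- suppressMessages(call_snps(s$pooled, s$ann, min_minor_freq = 0.10))
  loose <- suppressMessages(call_snps(s$pooled, s$ann, min_minor_freq = 0.02))
  expect_true(all(strict$pos %in% loose$pos))
})

test_that("aggregation divides by the gated denominator and ignores order", {
  expect_equal(pi_aggregate(c(0.5, 0.5), 1000), 0.001)
  expect_error(pi_aggregate(0.5, 0), "zero denominator")
  s <- small_sim()
  shuffled <- s$pooled[sample.int(nrow(s$pooled)), ]
  a <- suppressMessages(genome_diversity(s$pooled, s$snps))
  b <- suppressMessages(genome_diversity(shuffled, s$snps))
  expect_equal(a, b[match(paste(a$species, a$population),
                          paste(b$species, b$population)), ],
               ignore_attr = TRUE)
})

test_that("estimated genome pi tracks simulation truth", {
  s <- small_sim()
  gd <- suppressMessages(genome_diversity(s$pooled, s$snps))
  est <- gd$pi[gd$population == "ALL"]
  expect_lt(abs(est - s$truth$realized_pi[["ALL"]]) /
              s$truth$realized_pi[["ALL"]], 0.15)
})

test_that("clonal simulations are monomorphic and error shifts pi by ~2e", {
  mk <- function(e) {
    cfg <- sim_config(seed = 21, genome_length = 6000, n_genes = 5,
                      n_haplotypes = 1, error_rate = e, n_populations = 1,
                      samples_per_population = 1, coverage_mean = 60)
    truth <- suppressMessages(assign_population_frequencies(
      simulate_haplotypes(simulate_reference(cfg), cfg)))
    counts <- emit_site_counts(truth)
    cnt <- as.matrix(counts[, c("nA", "nC", "nG", "nT")])
    mean(pi_site(cnt), na.rm = TRUE)
  }
  expect_equal(mk(0), 0)
  e <- 0.005
  got <- mk(e)
  expect_lt(abs(got - 2 * e) / (2 * e), 0.15)
})

test_that("the major-allele matrix keeps only well-covered common SNPs", {
  ann <- toy_annotation()
  mk_row <- function(pos, sample, counts) {
    ref <- strsplit("ATGTTTTAA", "")[[1]][pos]
    data.frame(species = "sp", contig = "c1", pos = pos, ref = ref,
               sample = sample, nA = counts[1], nC = counts[2],
               nG = counts[3], nT = counts[4], stringsAsFactors = FALSE)
  }
  pooled <- rbind(
    mk_row(2, "ALL", c(60, 0, 40, 0)), mk_row(3, "ALL", c(50, 50, 0, 0)),
    mk_row(2, "w1", c(30, 0, 20, 0)), mk_row(2, "w2", c(30, 0, 20, 0)),
    mk_row(3, "w1", c(25, 25, 0, 0)), mk_row(3, "w2", c(2, 2, 0, 0))
  )
  snps <- suppressMessages(call_snps(pooled, ann))
  m <- suppressMessages(major_allele_matrix(pooled, snps))
  # site 3 is 4x in w2 (not > 5) -> its row is dropped entirely
  expect_identical(rownames(m), "c1:2")
  # identical pooled profiles give identical columns
  expect_equal(m[, "w1"], m[, "w2"])
  expect_true(all(m >= 0 & m <= 1))
})

test_that("clonal-expansion flags need low local pi at high coverage", {
  gs <- data.frame(
    species = "sp", population = c("ALL", "w1", "w2", "w3"),
    pi = c(0.004, 0.0003, 0.004, 0.0001), n_sites = 1000, snp_count = 10,
    snps_per_mbp = 1e4, mean_coverage = c(100, 40, 40, 5)
  )
  got <- flag_clonal_expansion(gs)
  expect_identical(got$clonal_expansion,
                   c(FALSE, TRUE, FALSE, FALSE))  # w3 blocked by coverage
})
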