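test_that("the generator is fully deterministic given the seed", {
  cfg <- sim_config(seed = 11, genome_length = 6000, n_genes = 5,
                    error_rate = 0.01)
  run <- function() {
    ann <- simulate_reference(cfg)
    truth <- assign_population_frequencies(simulate_haplotypes(ann, cfg))
    list(ann = ann, mut = truth$mutations, freqs = truth$freqs,
         counts = emit_site_counts(truth), reads = emit_reads(truth))
  }
  a <- suppressMessages(run()); b <- suppressMessages(run())
  expect_identical(a$ann$contigs, b$ann$contigs)
  expect_identical(a$mut, b$mut)
  expect_identical(a$freqs, b$freqs)
  expect_identical(a$counts, b$counts)
  expect_identical(a$reads, b$reads)
})

test_that("impossible gene packing is rejected", {
  expect_error(simulate_reference(sim_config(genome_length = 3000,
                                             n_genes = 50)),
               "genome too short")
})

test_that("mutation classes follow ns_fraction at its extremes", {
  cfg <- sim_config(seed = 5, genome_length = 6000, n_genes = 5,
                    ns_fraction = 0, target_pi = 0.02)
  ann <- simulate_reference(cfg)
  truth <- suppressMessages(simulate_haplotypes(ann, cfg))
  coding <- truth$mutations$class[truth$mutations$class != "noncoding"]
  expect_true(length(coding) > 50)
  expect_true(all(coding == "S"))

  cfg2 <- sim_config(seed = 5, genome_length = 6000, n_genes = 5,
                     ns_fraction = 1, target_pi = 0.02)
  truth2 <- suppressMessages(simulate_haplotypes(simulate_reference(cfg2), cfg2))
  coding2 <- truth2$mutations$class[truth2$mutations$class != "noncoding"]
  expect_true(all(coding2 == "N"))
})

test_that("two clonal haplotypes carry every derived allele together", {
  cfg <- sim_config(seed = 3, genome_length = 6000, n_genes = 5,
                    n_haplotypes = 2, recomb_rate = 0)
  truth <- suppressMessages(simulate_haplotypes(simulate_reference(cfg), cfg))
  # every mutation sits on the single branch above haplotype 2
  expect_true(all(!truth$carriers[, 1] & truth$carriers[, 2]))
})

test_that("realized diversity matches the target over seeds (direct oracle)", {
  pis <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = s, genome_length = 10000, n_genes = 8,
                      n_haplotypes = 20, target_pi = 0.01)
    truth <- suppressMessages(simulate_haplotypes(simulate_reference(cfg), cfg))
    pairwise_pi_oracle(haplotype_seqs(truth))
  }, numeric(1))
  expect_lt(abs(mean(pis) - 0.01) / 0.01, 0.15)
  # the stored uniform-weight summary is the same quantity up to the
  # distinct-pair vs with-replacement convention
  cfg <- sim_config(seed = 1, genome_length = 10000, n_genes = 8)
  truth <- suppressMessages(simulate_haplotypes(simulate_reference(cfg), cfg))
  expect_equal(pairwise_pi_oracle(haplotype_seqs(truth)), truth$pi_uniform,
               tolerance = 1e-10)
})

test_that("population frequencies behave across the alpha range", {
  base <- small_sim()
  # identical vectors (alpha = Inf) make every site's true F_ST 0
  cfg <- sim_config(seed = 8, genome_length = 6000, n_genes = 5,
                    dirichlet_alpha = Inf, n_populations = 3)
  truth <- suppressMessages(
    assign_population_frequencies(simulate_haplotypes(simulate_reference(cfg),
                                                      cfg)))
  expect_true(all(abs(truth$true_fst$fst) < 1e-12, na.rm = TRUE))

  # two populations fixed for haplotypes that differ at a site -> F_ST 1
  t2 <- base$truth
  H <- t2$config$n_haplotypes
  f <- matrix(0, nrow = H, ncol = 2, dimnames = list(NULL, c("pop_1", "pop_2")))
  f[1, 1] <- 1; f[2, 2] <- 1
  t2$freqs <- f
  tf <- truth_fst(t2)
  differing <- xor(t2$carriers[, 1], t2$carriers[, 2])
  expect_true(all(tf$fst[differing] == 1))

  # smaller alpha means larger mean true F_ST
  mean_fst <- function(alpha, s) {
    cfg <- sim_config(seed = s, genome_length = 6000, n_genes = 5,
                      dirichlet_alpha = alpha, n_populations = 4)
    truth <- suppressMessages(assign_population_frequencies(
      simulate_haplotypes(simulate_reference(cfg), cfg)))
    mean(truth$true_fst$fst, na.rm = TRUE)
  }
  lo <- vapply(1:10, function(s) mean_fst(0.1, s), numeric(1))
  hi <- vapply(1:10, function(s) mean_fst(10, s), numeric(1))
  expect_gt(mean(lo), mean(hi))
})

test_that("stored realized pi and F_ST are exactly recomputable", {
  s <- small_sim()
  expect_identical(truth_pi(s$truth), s$truth$realized_pi)
  expect_identical(truth_fst(s$truth), s$truth$true_fst)
})

test_that("site count emission matches its sampling model", {
  # one haplotype without error: every site monomorphic for that haplotype
  cfg <- sim_config(seed = 9, genome_length = 4002, n_genes = 3,
                    n_haplotypes = 1, error_rate = 0, n_populations = 1,
                    samples_per_population = 1, coverage_mean = 20)
  truth <- suppressMessages(assign_population_frequencies(
    simulate_haplotypes(simulate_reference(cfg), cfg)))
  counts <- emit_site_counts(truth)
  cnt <- as.matrix(counts[, c("nA", "nC", "nG", "nT")])
  nonzero <- cnt > 0
  expect_true(all(rowSums(nonzero) <= 1))
  hit <- rowSums(nonzero) == 1
  expect_identical(c("A", "C", "G", "T")[apply(cnt[hit, ], 1, which.max)],
                   counts$ref[hit])

  # Poisson depth: mean site coverage within 5% of coverage_mean
  s <- small_sim()
  cov <- with(s$counts, nA + nC + nG + nT)
  expect_lt(abs(mean(cov) - s$cfg$coverage_mean) / s$cfg$coverage_mean, 0.05)
})
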