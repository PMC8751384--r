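---
title: "Strain-level population genomics from metagenome pileups: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-level population genomics from metagenome pileups: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainpop)
```

## The problem

Shotgun metagenomes of stable, species-rich communities — the motivating
system is comammox *Nitrospira* in groundwater-fed rapid sand filters, where
each waterworks hosts an effectively allopatric population of every species —
contain strain-level information in the read pileups mapped to a species'
reference genome. From per-site allele counts pooled per population this
package estimates the classic evolutionary summaries: nucleotide diversity
(π), linkage disequilibrium (D′) as a proxy for homologous recombination,
pN/pS as a measure of selective constraint, Hudson's F~ST~ between
populations with a scan for highly differentiated loci and selective sweeps,
and a compositional co-occurrence layer over the species abundance table.
A synthetic haplotype-community generator with complete ground truth stands
in for raw sequencing data, so every estimator can be tested for parameter
recovery.

## Data model and gating

The unit of input is the *sitecounts* table: per (species, contig, 1-based
position, sample) the A/C/G/T counts of filtered reads. When alignments are
the entry point, reads are expected to be filtered at mapping quality ≥ 30,
percent identity ≥ 96 (identity is computed over aligned columns, excluding
soft clips — the convention of the read-filtering scripts this mirrors), and
uniquely best-mapping pairs; `filter_alignment_record()` implements exactly
those inclusive thresholds, and `site_counts_from_bam()` applies the MAPQ
filter at pileup time. Starting from sitecounts, the read filters are assumed
pre-applied; the pipeline manifest records which entry point was used.

Gates, in the order applied:

* **Sample/genome breadth** — a sample enters a species' analysis only if at
  least 50% of the genome is covered at ≥ 5×, both margins inclusive.
  Positions absent from the table count as uncovered.
* **Pooling** — retained samples are summed per population, plus a synthetic
  "ALL" population over every retained sample. Pooling conserves counts
  exactly.
* **Gene coverage** — within each population, genes whose mean coverage falls
  outside mean ± 2 SD of that population's per-gene coverage distribution are
  excluded (recomputed independently per population; with fewer than 3 genes
  no exclusion is attempted).
* **F~ST~ site coverage** — only sites with ≥ 20× in *both* populations of a
  pair enter F~ST~.

## Estimators

**SNP calling.** A site is a SNP if, in ALL, coverage ≥ 5 and the
second-most-common base has count ≥ 4 and frequency ≥ 0.05. These thresholds
are not dictated by any analytic result; they follow common strain-resolved
metagenomics practice and are exposed as configuration. Effect classes are
assigned against the reference codon on the coding strand; a third allele
clearing the minor thresholds marks the site "multi", which keeps it in π but
removes it from the biallelic pN/pS and D′ machinery.

**π.** Per site, the unbiased average pairwise difference among the n reads:
π = n/(n−1)·(1 − Σ~b~ p~b~²). Aggregates divide the summed site values by the
number of *gated* positions, variant and invariant alike — without the
invariant denominator, genome-level magnitudes would be meaningless. Sites
with n < 2 are excluded from numerator and denominator. Sequencing error
inflates π by ≈ 2e (a miscalled read disagrees with every correct read), a
relation the test suite verifies by simulation.

**D′.** Joint haplotype observations come only from physical linkage: single
reads or short-insert read pairs (one simulated fragment, default 300 bp)
covering both sites, with pairs restricted to ≤ 500 bp separation and ≥ 10
joint observations. D′ is computed in integer count products
(D·n² = n~11~n~00~ − n~10~n~01~, D~max~·n² the appropriate marginal product),
which keeps the "≤ 3 observed haplotype classes ⇒ D′ = 1" law exact in
floating point. The aggregate is the unweighted mean over qualifying pairs —
the weighting is not standardized anywhere, so the simplest convention is
used and a per-distance decay table is emitted for diagnostics.

**pN/pS.** Potential sites are counted by the equal-weight Nei–Gojobori
scheme (per codon position, the fraction of the 3 substitutions that are
synonymous; S + N = 3 × codons exactly), with the standard bacterial code and
no special start-codon handling inside genes. Observed polymorphisms are each
classified against the reference codon independently, matching polymorphism
(not substitution) counting in codons carrying several SNPs. Genome-level
pN/pS sums raw counts over retained genes before taking the ratio. A gene
with nS = 0 but nN > 0 carries an infinite ratio: it is excluded from
gene-level means (with an exclusion count reported) but satisfies the
"pN/pS > 1" arm of the outlier rule.

**Positive-selection scan.** The source analysis reports genes "significantly
higher than the genomic average" without naming a test; here each gene's
(nN, nS) is compared with the genome-minus-gene background by a one-sided
Fisher exact test toward nonsynonymous excess, Benjamini–Hochberg adjusted
across genes, and outliers additionally require pN/pS > 1. The test is
deliberately swappable behind the function boundary.

**F~ST~.** Hudson's two-population estimator with small-sample
heterozygosity correction: F~ST~ = 1 − H~w~/H~b~ with
H~w~ = [2p₁(1−p₁)n₁/(n₁−1) + 2p₂(1−p₂)n₂/(n₂−1)]/2 and
H~b~ = p₁(1−p₂) + p₂(1−p₁). No estimator is named in the source; Hudson's is
the standard recommendation for two-population sequence data and is robust to
unequal depth. Gene values use the ratio-of-averages (ΣH~w~/ΣH~b~) form and
are clamped to [0, 1] with clamp events logged.

**Locus and sweep scan.** A high-F~ST~ locus is a run of ≥ 3 consecutive
genes (genome order) each ≥ 2 SD above the genome's gene-F~ST~ mean for the
pair — a window rule of this artifact, since the source reports loci without
printing its rule; both knobs are configuration. Per locus, a two-sample
Wilcoxon test compares locus site-level D′ with the rest of the genome and a
two-sample t test does the same for site-level π, each family BH-adjusted
across loci. A sweep candidate must be significant in both with the correct
directions: π below and D′ above the genome mean. The scan refuses to run on
fewer than 30 genes of background.

**Allele-profile structure.** The major-allele matrix holds, for SNPs covered
> 5× in every retained population, the frequency of the ALL-major allele.
For Jaccard dissimilarities the matrix is binarized at frequency ≥ 0.5
("the population's major allele equals the species-wide major allele") — the
binarization is unstated in the source and this is the simplest faithful
reading. Mantel tests use Pearson correlation on lower triangles with random
permutations, the observed value included in the null set
(p = (1 + hits)/(n~perm~ + 1), so p is never 0); identity permutations are
resampled so that self-comparison yields exactly p = 1/(n~perm~ + 1).

**Compositional layer.** Zeros are replaced by the count-zero multiplicative
rule — 0.65 × the sample's smallest nonzero value, nonzero entries
multiplicatively rescaled so totals are preserved (0.65 is that method
family's conventional default, exposed as a parameter) — followed by the
centered log-ratio transform and proportionality
ρ = 1 − var(clr~i~ − clr~j~)/(var(clr~i~) + var(clr~j~)). Network edges
retain ρ > 0.56 with an FDR estimated by permuting each species' sample
labels independently; the companion figure caption in the source says
ρ > 0.55 while its methods say 0.56 — the methods value is the default here.
Richness counts species strictly above 0.5% relative abundance.

## The synthetic community

The generator is the package's replacement for raw metagenomes, and its
defaults are the calibration conditions used throughout the tests: 60 kb
coding genome (50 genes, ≥ 60% coding), 20 haplotypes at target π = 0.01,
nonsynonymous mutation fraction 0.2, four populations with two samples each,
50× mean Poisson depth, 0.1% miscall rate.

* **Reference**: random non-overlapping CDS (start codon, stop-free interior,
  terminal stop) on random strands; the first six genes carry the
  nitrification gene-class labels so class comparisons can be exercised.
* **Haplotypes**: descend from the reference through a random increasing
  genealogy (each new haplotype copies a random earlier one); each mutation
  lands on a branch and is carried by the clade below it. This clade nesting
  is what makes D′ ≈ 1 in the clonal limit and lets recombination degrade it.
  It is not a coalescent: branch lengths carry no time scale and the clade
  size distribution is that of random increasing trees.
* **Mutation count**: infinite-sites placement (collisions resampled), with
  M = round(target_π · L / mean h), where h = 2k(H−k)/(H(H−1)) is the
  per-mutation expected pairwise heterozygosity at the realized clade sizes —
  an analytic mapping from the diversity target to a mutation budget. Within
  CDS each mutation is nonsynonymous with probability `ns_fraction`, realized
  by drawing an admissible substitution for the codon; positions whose codon
  admits no substitution of the drawn class are resampled and counted.
* **Recombination**: `recomb_rate` expected reassortment events per
  haplotype; each event swaps a uniform 0.5–5 kb segment between two random
  haplotypes. The tract length is of the order of bacterial homologous
  recombination tracts; at the 500 bp pair distances where D′ is measured,
  LD decay is therefore gradual in the rate.
* **Populations**: per-population haplotype frequencies from a symmetric
  Dirichlet(α); smaller α means stronger between-population differentiation,
  α = ∞ gives identical populations. The Dirichlet construction is an
  artifact choice — the source states no within-species demographic model.
* **Observation**: depth ~ Poisson(coverage) per site and sample (negative
  binomial under the overdispersion switch), reads drawn from the
  population's haplotype mixture, miscalls uniform over the other three
  bases. Count-level emission is the contract; read-level fragments
  (`emit_reads()`) exist because D′ requires physical linkage.

Stored truth (mutation classes, carrier matrix, frequency vectors, realized
π per population as Σ2p(1−p)/L, per-site Hudson F~ST~ from true frequencies)
is exactly recomputable from the object, and the tests assert this identity.
Two diversity conventions coexist deliberately: the calibration target uses
distinct-pair weighting (H−1 denominator) while realized per-population
truth uses with-replacement sampling, matching what read pileups estimate;
at H = 20 they differ by 5%, inside every tolerance used.

What the generator does *not* emulate: gene content variation between strains
(no pangenome), indels and rearrangements, coalescent genealogies with a time
scale, mapping artifacts between related species, and spatially structured
population frequencies. Passing recovery tests therefore shows the estimators
are correct for well-mapped, SNP-only strain variation — not that real
cross-mapping or pangenome effects are handled.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere; minus-strand codon logic
  complements alleles onto the coding strand at classification time.
* Reference ambiguity characters are excluded from all statistics and
  counted in the log.
* D′ in integer count products (exact boundary law); π and F~ST~ in double
  precision with F~ST~ clamped to [0, 1] after estimation.
* Monomorphic sites among joint observations make a pair undefined and it is
  skipped; zero-variance species make ρ undefined for their pairs.
* Dunn's post-hoc test (after Kruskal–Wallis) uses tie-corrected rank
  variances with Holm adjustment and a compact letter display computed by
  insert-and-absorb, so classes share a letter exactly when not significantly
  different.
* All randomness flows from one root seed through fixed stage offsets, so
  partial reruns reproduce byte-identical tables.

## Problem sizes

The test suite and the analysis scripts run desk-scale versions of the study
design: 6–60 kb genomes, 5–50 genes, 12–20 haplotypes, 2–4 populations,
40–50× depth, 5–10 seeds per stochastic property. The parameter-recovery
suite checks genome π within ±15% of per-seed truth at the full 60 kb
calibration size, F~ST~ monotone over Dirichlet α ∈ {0.1, 1, 10}, and
aggregate D′ strictly decreasing from recombination rate 0 to 20, seed by
seed. The headline numbers of the motivating study (per-species π, D′, pN/pS
tables, SNPs/Mbp ranges, twelve high-F~ST~ loci) derive from deep multi-site
metagenomes and are not reproducible at these sizes; the package's claims
are the analytic facts and recovery properties above.

## Known limitations

* D′ requires read-level (or fragment-level) input; from sitecounts alone the
  linkage stage is unavailable and the pipeline reports it as absent.
* The locus scan assumes a gene-dense single reference ordering; scattered
  contigs shorten runs and make the 3-gene window conservative.
* The sweep battery is strict by construction — in a weakly recombining
  background the locus-vs-genome D′ contrast has little room, so false
  negatives are expected (the motivating analysis itself retained only 2 of
  12 high-F~ST~ loci as sweeps).
* pN/pS compares polymorphism within one species; it says nothing about
  fixed differences between species (no dN/dS, no codon models).
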