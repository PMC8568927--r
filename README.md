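# mfclone

Multi-sample somatic-evolution analysis for **multifocal tumors** — several
spatially distinct primary lesions plus metastases from one patient, each
sequenced against a matched blood normal. The motivating setting is
multifocal small-intestine neuroendocrine tumors (SI-NETs), a
low-mutation-burden cancer where the central question is whether the many
synchronous primaries share a clonal origin, and which primary seeded the
metastases.

The package answers that question from per-sample somatic call tables:

* **Strict somatic filtering** with the tumor–normal contract used for
  phylogenetics (normal coverage ≥ 20 reads, absence in the normal, alt
  support on both strands with a two-read floor, VAF ≥ 0.01, two-caller
  intersection, population-variant blacklist), plus **whitelist relaxed
  recall** — re-querying unfiltered calls at positions confidently called in
  a paired sample — to sensitively detect shared subclonal variants.
* **Pairwise shared-SNV matrices** and a decision rule classifying small
  overlaps as clonal trunk, contamination trace (low VAF in exactly one
  sample), or early-developmental (embryonic) variants.
* **Maximum-parsimony phylogenies** on the binary sample × variant matrix
  with an all-absent germline outgroup: Fitch small parsimony, exhaustive
  search up to 9 leaves (global optimum; lexicographic tie-break), stepwise
  addition + NNI with deterministic restarts above, per-branch SNV counts by
  Fitch backtrace, and column-resampling **bootstrap supports**
  (500 replicates by default).
* **Mutational-signature refitting**: 96-channel pyrimidine-strand
  trinucleotide profiles refit against a COSMIC-v3-format signature matrix
  by greedy forward selection with non-negative least squares, at most 4
  signatures per sample, weights < 0.06 zeroed.
* **Copy-number analysis and homolog phasing**: log2 tumor/normal read-count
  ratios in 2-kb windows, recursive binary segmentation, whole-chromosome
  loss/gain calls (≥ 90 % of the chromosome in one state), phasing of those
  events to parental homologs via germline heterozygous SNP allele
  imbalance (normal VAF 0.25–0.75), an exact one-sided **binomial
  concordance test** for "related tumors lose the same homolog",
  **chromothripsis** detection (clustered two-state oscillation), a
  fusion reading-frame check, and a VAF-based purity estimate (2 × median,
  flagged below 30 %).
* A **synthetic multifocal-cohort generator** (`sim_config()` /
  `simulate_cohort()`) producing call tables, het-SNP tables, window counts
  and full ground truth for clonally independent primaries with a shared
  metastatic trunk — the test bed for every stage.

The expected allele fractions behind the phasing and purity logic: a clonal
heterozygous diploid variant at purity *p* has VAF *p*/2; on a chromosome
with monoallelic loss, het SNP VAFs concentrate at 1/(2−p) (retained
homolog) and (1−p)/(2−p) (lost homolog); a hemizygous loss gives a window
log-ratio of log2((2(1−p)+p)/2).

## Worked example

Simulate a patient with three independent primaries (A–C) where C seeded two
metastases (D, E) through an 80-variant trunk and all three related samples
lost the same homolog of chr18; then run the analysis:

```r
library(mfclone)

cfg <- sim_config(
  n_primaries = 3, metastatic_primary_ids = "C", n_mets_per_seed = 2,
  trunk_sizes = 80, private_range = c(30, 60),
  genome = genome_model(chroms = c("chr1", "chr17", "chr18")),
  cna_events = list(truth_cna("chr18", "loss", "A", carriers = c("C", "D", "E"))),
  noise = FALSE, seed = 1
)
cohort <- simulate_cohort(cfg)
calls  <- apply_strict_filters(cohort$calls)

pairwise_shared(calls)$counts
#>    A  B   C   D   E
#> A 38  0   0   0   0
#> B  0 41   0   0   0
#> C  0  0 127  80  80
#> D  0  0  80 137  80
#> E  0  0  80  80 116

mat  <- build_character_matrix(calls)
tree <- bootstrap_support(mat, n_reps = 200, seed = 1,
                          tree = assign_branch_counts(search_mp_tree(mat), mat))
export_newick(tree)
#> (normal:0,((((C:47,D:57)31:0,E:36)100:80,A:38)38:0,B:41):0);
```

The shared matrix shows exactly the 80-variant trunk between C and each
metastasis and zero overlap between unrelated primaries. In the newick,
branch lengths are assigned SNV counts and internal labels are bootstrap
supports: the metastatic clade {C, D, E} carries the 80 trunk SNVs at 100 %
support, while the zero-length resolutions inside it have no signal and low
support. Phasing confirms the copy-number relationship:

```r
phase_event(dplyr::filter(cohort$het_snps, chrom == "chr18"), "C", "D")
#> <phase_call> C vs D: same_as_reference (concordance 1, 390 SNPs)

concordance_binomial_test(13, 13)
#> <concordance_test> 13/13 concordant; one-sided P = 0.000122
```

`run_patient(patient_bundle("P1", cohort))` chains all stages and returns
tables for every figure-style artifact (shared matrix, tree, overlap
classes, signature loadings, segments, whole-chromosome events, phasing,
chromothripsis, the concordance test); `run_cohort()` pools the
homolog-concordance test across patients.

A deterministic synthetic signature catalogue
(`synthetic_signature_matrix()`, also shipped as
`inst/extdata/signatures_synthetic.tsv` in the COSMIC v3 dialect) supports
the signature stage; it is not COSMIC data, but emulates the flat clock-like
SBS5/SBS40 pair (cosine > 0.95, hence their well-known confusability) and
well-separated SBS1/SBS2/SBS18 shapes.

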