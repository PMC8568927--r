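---
title: "Methods: clonality, phylogeny and homolog phasing in multifocal tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonality, phylogeny and homolog phasing in multifocal tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfclone)
```

# The analysis problem

A patient with multifocal disease contributes several spatially distinct
primary tumors, one or more metastases, and a blood normal, all whole-genome
sequenced at moderate depth (~30–45×). Two genetically related tumor samples
share the somatic mutations acquired before their lineages split; in a
late-onset cancer a common clonal origin therefore implies hundreds to
thousands of shared SNVs genome-wide. Conversely, clonally independent
primaries share essentially none. `mfclone` operationalises that logic:
exact pairwise intersections of filtered variant keys, a parsimony tree over
the binary presence matrix, and two orthogonal confirmations from copy
number — which parental homolog a shared whole-chromosome loss affected, and
whether complex rearrangement patterns (chromothripsis) are mirrored across
samples.

Small overlaps need care, and the package classifies them by a fixed rule
(`classify_overlap()`): trunks are large (hundreds of variants) and clonal
in every carrier; cross-contamination during sample handling appears as
low-VAF traces in exactly one sample; early-developmental (embryonic)
mutations are few but clonal in all carriers. Defaults — `min_trunk = 50`
variants, `clonal_floor = 0.10` VAF, `trace_ceiling = 0.10` VAF,
`embryonic_max = 20` variants — put wide margins around the three regimes
these data exhibit (trunks of ~10^2–10^3, traces of ~10^1–10^2 at VAF
0.02–0.05, embryonic sets of ~10^1); all are configurable.

# Strict filtering and whitelist recall

`apply_strict_filters()` implements the tumor–normal contract used for tree
building: normal coverage ≥ 20 reads, absence from the normal, alt reads on
both strands with a ≥ 2-read floor, VAF ≥ 0.01, the intersection of two
callers, and position+allele blacklist removal of population variants.
Rules run in a fixed order and each rejected call is annotated with its
first failing rule, which makes rejection accounting testable. Records
without caller provenance are treated as intersection-passing with a
warning, because third-party tables often lack it. Two blacklist stringency
tiers are conventional — aggressive for phylogeny, lenient for
signature/driver work (aggressive SNP filtering biases signature fits) —
and are selected simply by which key set is passed.

`whitelist_recall()` implements the high-sensitivity second pass for a
sample pair: variants strictly called in either sample are re-queried in
both samples' *unfiltered* call sets, and count as recalled with ≥ 2
supporting reads regardless of strand, VAF or caller status. This recovers
shared subclonal variants — the contamination-trace scenario — that strict
filtering removes. Strict calls are by construction a subset of their own
sample's recall.

The exact relaxed-calling VAF floor is not fixed by convention, so it is
exposed as configuration; the default is "any VAF with ≥ 2 alt reads".

# Maximum parsimony with a germline root

`build_character_matrix()` produces the samples × variants 0/1 matrix (SNVs
only; indels carry a higher artifact fraction and are excluded) plus an
all-absent outgroup row. Trees are displayed rooted at that outgroup: the
germline is a biologically known root, so midpoint or arbitrary rooting
would discard information.

Scoring is Fitch small parsimony on unique column patterns with weights
(`fitch_score()`). The search (`search_mp_tree()`) is exhaustive for ≤ 9
leaves — every unrooted topology is enumerated, guaranteeing the global
optimum, with ties broken by the lexicographically smallest canonical
newick — and heuristic above: deterministic stepwise addition in row order
plus four fixed-seed shuffled restarts, each followed by best-improvement
NNI hill climbing to a local optimum. The scheme is a documented search
procedure of this package, not a claim about any particular phylogenetics
program's internals. Enumeration grows as (2n−5)!!, so the exhaustive path
is practical to ~9 leaves; the heuristic path matched the exhaustive
optimum in every randomized 6-leaf check in the test suite.

Per-branch SNV counts (`assign_branch_counts()`) come from a deterministic
Fitch backtrace: the root prefers the absent state (germline), and an
ambiguous child inherits its parent's state when its state set allows. For
homoplasy-free columns the placement is unique and branch counts sum to the
column count; homoplastic columns contribute one count per reconstructed
change under that fixed tie rule.

`bootstrap_support()` resamples matrix columns with replacement (default
500 replicates), re-infers a tree per replicate, and reports for each
internal branch the percentage of replicates containing its unrooted
bipartition. Replicate searches use a random addition order: in regions
with no grouping signal (star-like parts of the tree) a fixed tie-break
would otherwise reproduce the same arbitrary resolution every time and
manufacture 100 % support for it. "Major" branches are defined here as
internal branches with ≥ 10 assigned SNVs, since zero-length resolutions
inside star regions are display artifacts, not claims.

# Mutational signatures

`count_96()` builds the 96-channel profile (pyrimidine-strand substitution ×
flanking bases, purine-reference records reverse-complemented, autosomes
only). `fit_signatures()` refits it against a signature matrix in the
COSMIC v3 file dialect by greedy forward selection: starting empty, add the
signature whose inclusion most reduces the sum of squared errors of the
non-negative least-squares reconstruction of the sum-normalised profile;
stop at `max_k = 4` signatures or when the improvement drops below
`tol = 1e-4`; zero weights below `min_weight = 0.06` and refit the rest.
These defaults mirror the common refitting convention ("default parameters,
at most 4 signatures per sample"); profiles are not corrected by genome
trinucleotide frequencies (the question of whether to normalise is left as
a flag, default off, since refitting against genome-derived signatures on
whole-genome data needs no correction).

The package ships a deterministic *synthetic* signature catalogue
(`synthetic_signature_matrix()`); it is constructed from closed-form
channel weights, not COSMIC data. Its SBS5/SBS40 pair is built highly
collinear (cosine ≈ 0.997) on purpose: the two clock-like processes are
practically confusable, so tests assert on their combined loading rather
than either alone — the honest statement for real data too.

# Copy number, homolog phasing and chromothripsis

`segment_logratio()` computes log2 tumor/normal ratios of read counts in
uniform windows (default 2,000 bp), normalised by library size and
recentred on the genome-wide median so the copy-neutral state sits at 0
(this assumes most of the genome is neutral — true in these
low-complexity genomes). Segmentation is recursive binary splitting on the
mean difference, accepting a split when the two sides differ by
≥ `min_delta = 0.25` with ≥ `min_windows = 5` windows each, followed by
merging of adjacent sub-threshold fragments; segments tile each chromosome
exactly. State thresholds (loss < −0.25, gain > 0.2) give symmetric
detection of hemizygous events down to ~30 % purity, matching the cohort's
inclusion rule; a hemizygous loss at purity p has expected log-ratio
log2((2(1−p)+p)/2), i.e. −0.51 at p = 0.6. A ≥ 25 kb reporting filter
(`filter_small_segments()`) mirrors the conventional visualization cut;
the analysis itself keeps the tiling. This simple segmenter replaces a
dedicated HMM-style caller because the downstream logic needs only states
and breakpoints.

`call_whole_chrom()` emits a whole-chromosome event when ≥ 90 % of the
chromosome length shares one non-neutral state. `phase_event()` then asks
which homolog: each germline het SNP (normal VAF within 0.25–0.75) is
oriented by which allele exceeds 0.5 + δ (δ = 0.05) in a reference sample —
typically the metastatic primary — and the concordance fraction is the share
of those informative SNPs whose same allele is elevated in the test sample.
≥ 0.9 concordance calls `same_as_reference`, ≤ 0.1 `different_from_reference`;
test VAFs pinned at 0.5 despite copy loss indicate a biallelic event
(both homologs affected, allele balance preserved); anything else, or fewer
than 20 informative SNPs, is indeterminate.

The homolog-concordance test (`concordance_binomial_test()`) is the exact
one-sided binomial tail P(X ≥ k | n, 0.5). The counting unit is sample
pairs related by the SNV phylogeny in which both members carry a
monoallelic whole-chromosome loss of the same chromosome; biallelic and
indeterminate calls are excluded. This is the most direct reading of
"binomial test on related monoallelic cases"; 13 concordant pairs of 13
give 0.5^13 ≈ 1.2 × 10⁻⁴.

`detect_chromothripsis()` is a rule, not a model: ≥ 10 segments on the
chromosome, ≥ 90 % of them in the two dominant copy states, and ≥ 80 % of
adjacent transitions alternating between exactly those two states.
`fusion_frame_check()` evaluates a two-breakpoint junction: partners must
be joined on one transcriptional strand (both in sense, or both inverted),
and the fused product is in frame when the cumulative CDS lengths upstream
of the two breakpoints are congruent modulo 3 — equivalently, the
downstream partner resumes at its own codon phase.

`estimate_purity()` uses the diploid-clonal expectation VAF = p/2: purity
is 2 × median VAF over ≥ 20 copy-neutral clonal candidates, clipped to
(0, 1], flagged below 0.30.

# The synthetic cohort generator

`simulate_cohort()` is first-class, tested code, and the test bed for every
stage. It emulates:

* clonally independent primaries, one or more of which seed metastases that
  inherit the seed's trunk variants (default architecture: six primaries,
  one seeding five metastases through a 667-variant trunk, 300–1,700
  private SNVs per sample — the burden range observed in this tumor type);
* clock-like SBS5-dominated spectra via signature-mixture sampling of
  96-channel classes (contexts are drawn from the signature probabilities
  directly, matching the refitting convention; genome trinucleotide
  frequencies are uniform by default with a hook for genome-derived ones);
* embryonic variant sets (clonal VAF in all carriers) and cross-
  contamination (donor-clonal variants at trace VAF 0.02–0.05 in the
  recipient only) — the two small-overlap signatures;
* homolog-labelled whole-chromosome CNAs, purity dilution and binomial
  read sampling: site depth ~ Poisson(mean depth, default 40×), alt reads
  ~ Binomial(depth, expected VAF) with expected VAF = p·m / (2(1−p) + p·CN),
  and a two-read detection floor (dropout below it), mimicking the caller
  support floor. Het-SNP VAFs on altered chromosomes follow the closed
  forms above, which the tests verify. Default purity is 0.6, a typical
  mid-range value for included samples;
* caller provenance: the sensitive caller reports every emitted record,
  while the second caller misses weakly supported sites (alt < 3 reads or
  VAF < 0.05), so strict caller-intersection behaves realistically on
  subclonal variants.

Contamination variants in the recipient are drawn conditional on the
two-read floor: a reported trace variant is, by definition, one the relaxed
caller detected, and the configured count states how many such variants
exist in the relaxed output. Indels are a labelled minority class (default
2 % of private calls) with no sequence realism, present only so that
SNV-only stages demonstrably exclude them.

The default genome is a miniature: the 22 autosomes at 1/100 of their hg19
lengths. The analysis depends on counts and ratios, not absolute
coordinates, so this preserves structure while keeping desk-scale runs
fast; real lengths are available via `genome_model(scale = 1)`. The
generator does **not** emulate read-level artifacts (mapping error,
strand bias beyond binomial splitting, GC waves in coverage), subclonal
copy-number mosaics, or sequence-realistic indels — passing tests show the
algorithms are correct under the stated noise model, not that upstream
calling on real reads is solved.

Determinism: every cohort is generated under its config seed with the
caller's RNG state saved and restored, so identical configs give identical
tables byte for byte.

# Problem sizes and numerical choices

The test and acceptance workloads use the miniature genome: a full
11-sample patient at the default architecture yields ~12,000 somatic
variants, ~14,000 het SNPs and ~14,000 windows, which simulates in seconds;
bootstrap with 500 replicates on the resulting 12-leaf matrix runs in well
under a minute because columns collapse to a handful of unique patterns.
Property suites run 1,000 random matrices against a brute-force
assignment-enumeration oracle at 5 leaves and 100 full-search comparisons
against exhaustive topology enumeration at ≤ 6 leaves, plus 100 simulated
phasing patients at purity 0.4–0.9 and depth 40.

Ties and degeneracies are handled deterministically throughout:
lexicographic newick tie-breaks in exhaustive search; first-encountered
winners in stepwise addition; the ancestral-state preference in the branch
backtrace; stable column order (chrom, pos, alt) in the character matrix.
Degenerate inputs refuse loudly (fewer than 3 leaves, all-zero profiles,
zero-trial binomial tests, too few purity sites) with typed conditions
(`mfclone_input_error`, `mfclone_config_error`).

# Known limitations

* The parsimony search above 9 leaves is heuristic; with the strong trunk
  signal typical of these cohorts this is immaterial, but pathological
  homoplasy could in principle defeat NNI from all restarts.
* Homolog phasing is pairwise against one reference sample and assumes a
  whole-chromosome event in both samples; focal events and subclonal CNAs
  are out of scope, as is allele-specific integer copy-number fitting.
* The purity estimator assumes the median clonal VAF comes from diploid
  regions; heavily rearranged genomes would bias it (the flag threshold,
  not the estimator, is doing the gatekeeping here).
* Signature refitting is deliberately a refit, not de novo extraction, and
  inherits the usual collinearity caveats (reported as combined loadings
  for near-collinear pairs).
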