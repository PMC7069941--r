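---
title: "Stage-wise small RNA analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-wise small RNA analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sRNAstage)
```

# The analysis

sRNAstage implements the small-RNA profiling workflow used to compare four
stages of plant somatic embryogenesis — embryogenic callus (EC), incomplete
pro-embryogenic culture (ICpEC), globular embryo (GE) and non-embryogenic
callus (NEC) — from raw sequencing reads to stage-presence expression
patterns. The pipeline has five stages, each exposed as ordinary functions
over tibbles:

1. **Structural cleaning** (`filter_and_trim()`, `collapse_unique()`):
   raw reads are removed for poly-N content, 5' adapter contamination, a
   missing 3' adapter or insert, homopolymer content, or an out-of-range
   insert length; survivors are trimmed and collapsed into unique 18–30 nt
   tags with per-library counts.
2. **Priority-cascade annotation** (`map_exact()`, `annotate_tags()`,
   `summarize_categories()`): each unique tag is mapped exactly to the
   reference on both strands and given a *single* category by fixed
   precedence — rRNA > known miRNA > piRNA > repeat > exon > intron — so
   overlapping annotations never double-count a tag.
3. **Composition profiling** (`length_distribution()`,
   `base_composition()`): length spectra (plant sRNA libraries peak at 21
   and 24 nt) and positional base frequencies, including the 5' first-base
   bias that distinguishes miRNA classes.
4. **Differential expression** (`rpm()`, `ac_pvalue()`, `call_de()`):
   reads-per-million normalisation and the Audic–Claverie exact test for a
   count observed once in each of two libraries.
5. **Pattern classification** (`classify_patterns()`, `flag_abundance()`,
   `venn_sets()`): presence/absence profiles across the four stages with
   abundance highlights and four-set Venn partitions.

A synthetic-data generator (`sim_config()`, `simulate_reference()`,
`simulate_counts()`, `simulate_reads()`) produces inputs with known ground
truth so every stage is testable end to end without any external download.
`run_pipeline()` composes all stages from one configuration with a hashed
run manifest; there is deliberately no shell entry point — the functions,
scripts and this vignette are the interface, as the package targets
interactive R analysis.

# Cleaning rules

The removal rules are structural (no base-quality model) and are applied in
a fixed order so each read has exactly one removal cause:

| order | rule | definition | parameter defaults |
|---|---|---|---|
| 1 | `poly_n` | read contains any N | — |
| 2 | `five_prime_adapter` | first 8 nt match the 3' end of the 5' adapter with ≤ 1 mismatch | seed 8 nt |
| 3 | `homopolymer` (raw) | one base ≥ 80% of the read, or a run ≥ 15 nt | 0.8, 15 nt |
| 4 | `no_3prime_adapter` | the first 8 nt of the 3' adapter are not found | seed 8 nt |
| 5 | `no_insert` | the adapter match starts at position 1 | — |
| 6 | `homopolymer` (insert) | as rule 3, on the trimmed insert | 0.8, 15 nt |
| 7 | `length_range` | trimmed insert outside 18–30 nt | 18, 30 |

Two deliberate choices: the homopolymer rule is checked on the raw read
*before* the adapter search, because an adapter-less homopolymer artifact is
a homopolymer problem, not an adapter problem — attributing it to the
missing adapter would misstate the failure mode; and "poly-base" content is
operationalised as a dominant-base fraction (≥ 80%) *or* a long run
(≥ 15 nt), both configurable, since no numeric definition is standard.
Adapters default to the Illumina TruSeq small-RNA sequences and are
configuration constants. T and U are equivalent on input; tags are stored
with T and composition profiles are reported in the RNA alphabet.

# Annotation cascade

Mapping is exact and full-length (both strands via reverse complement). The
package targets desk-scale references where exact matching is sufficient and
dependency-free; there is no mismatch-tolerant alignment, multi-mapping
rescue, or novel-miRNA hairpin prediction. Placements feed a strand-aware
interval overlap (GenomicRanges); a feature claims a placement when the
overlap covers at least `min_overlap` of the tag (default 1.0 — the tag must
lie inside the feature). A tag's category is the highest-priority category
over *all* its placements (no fractional assignment), which preserves the
single-annotation-per-tag contract; within the exon/intron tiers, sense
precedes antisense as a deterministic tie-break, and the final label is
split into `_sense`/`_antisense` by comparing tag and feature strands.

The six-class precedence above orders only the classes it names; tRNA,
snRNA and snoRNA (reported in the category table but absent from the stated
order) are slotted immediately after rRNA, i.e. the structural-ncRNA tier
outranks everything else. That placement is a package decision, exposed via
the `cascade` argument. Matches against the mature-miRNA catalog are
5'-anchored and tolerate up to 2 nt of 3'-end length difference
(`mirna_3p_tolerance`), reflecting the 3' heterogeneity of mature miRNA
isoforms; a catalog match is assigned `known_miRNA` unless a
structural-ncRNA feature claims the tag. Mapped tags overlapping nothing
are `unannotated`, as are unmapped tags.

Percentages in the category summary are formatted as in published summary
tables: round half up to two decimals, trailing zeros stripped (0.70 →
"0.7"), recomputed from raw counts. `format_category_counts()` applies the
same arithmetic to an externally supplied count table and enforces the
row-sum identity (categories + unannotated = total, per library).

# The exact two-library test

With counts \(x\) and \(y\) for one tag in libraries of \(N_1\) and \(N_2\)
total clean reads, the probability of \(y\) given \(x\) is

\[
p(y \mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!\,\bigl(1+\tfrac{N_2}{N_1}\bigr)^{x+y+1}},
\]

the lower and upper tails are \(C(y) = \sum_{k \le y} p(k \mid x)\) and
\(D(y) = \sum_{k \ge y} p(k \mid x)\), and the reported two-sided p-value is
the doubled smaller tail, \(p = \min(1,\, 2\min(C, D))\). Normalised
expression is \(\mathrm{RPM} = 10^6 \, x / N\), the fold change is
\(\log_2(\mathrm{RPM_B} / \mathrm{RPM_A})\), and a tag is called up
(down) when the normalised ratio exceeds 2 (falls below 1/2) with
\(p < 0.01\); \(p < 0.05\) is recorded as a secondary significance tier.
Tags detected in exactly one library of a pair keep their infinite fold
change and carry a specificity flag (`A_only`/`B_only`) instead of a
pseudocounted finite value — stage-specific expression is a first-class
outcome here, not a numerical nuisance. Raw p-values are the default (the
classical two-library workflow applies no correction); Benjamini–Hochberg
is available via `adjust = "BH"`.

Numerical notes:

* `ac_probability()` is evaluated in log space via `lgamma`, so counts far
  beyond any realistic library cannot overflow; for \(N_1 = N_2\) it reduces
  exactly to \(\binom{x+y}{x} / 2^{x+y+1}\).
* Tail sums run until the increment falls below \(10^{-16}\) of the running
  sum, with a hard cap of \(x + y + 10\sqrt{x+y} + 1000\) terms; the upper
  tail is summed directly from \(y\) upwards (never via \(1 - C\)), so tiny
  tails retain full relative precision.
* Because \(p(\cdot \mid x)\) conditions on \(x\), the doubled-tail p-value
  is **not** exactly symmetric under swapping the libraries; the exact
  relationship is the complement identity
  \(C(x, y; N_1, N_2) + C(y, x; N_2, N_1) = 1\), and the two orientations
  differ by at most the boundary probability mass. `call_de()` therefore
  evaluates the test in a canonical orientation (alphabetical library
  order), making calls invariant to how a pair is written. The test suite
  checks the exact complement identity, the closed form at equal library
  sizes, frozen values from an arbitrary-precision rational evaluation, and
  full-grid agreement (counts up to 200, size ratios 0.5/1/2) with the
  negative-binomial representation
  \(p(k \mid x) = \mathrm{NB}(k;\, x+1,\, N_1/(N_1+N_2))\), which is an
  independent closed-form route to both tails.
* Under a null of equal Poisson rates the test holds its size at the 0.01
  working threshold (measured on 10,000 simulated pairs in the acceptance
  script); with overdispersed (negative-binomial) data and large counts it
  is anticonservative, like any Poisson-exact test — a known limitation of
  per-library testing without replicates.

# Pattern classes

Presence in a stage means count ≥ `presence_min` (default 1: any detection
counts as expression; raise it for noise-robust use). The presence vector
over (EC, ICpEC, GE, NEC) maps onto a closed vocabulary:

| label | vector | abundance threshold |
|---|---|---|
| `ALL_STAGES` | 1111 | > 10,000 |
| `EARLY_SE_ONLY` | 1110 | > 500 |
| `EC_ONLY` | 1000 | > 100 |
| `ICPEC_ONLY` | 0100 | > 100 |
| `GE_ONLY` | 0010 | > 100 |
| `NEC_ONLY` | 0001 | > 100 |
| `OTHER` | any other non-zero | > 100 (package default) |

The named classes are the six enumerated stage-presence patterns of the
four-stage design (all-stage, early-SE-only and the four single-stage
classes); the remaining nine non-zero vectors are grouped as `OTHER` rather
than silently dropped, and all-zero rows are rejected with an explicit
reason. Abundance flags are strict inequalities on the maximum count over
*present* stages; `OTHER` reuses the 100-read threshold as a documented
default since no threshold is defined for unnamed patterns.
`venn_sets()` partitions ids into the 15 disjoint regions of the four stage
sets, optionally after filtering to a length class (e.g. 24-nt tags).

# The synthetic-data generator

`sim_config()` encodes the study conditions the generator emulates:

* four libraries (EC, ICpEC, GE, NEC), default 10^6 clean reads each;
* tag lengths 18–30 nt with modes at 21 and 24 nt;
* a unique-tag composition dominated by unannotated tags (~70%) with
  rRNA/repeat/exon/intron minorities, and a separate total-read composition
  (rRNA and miRNA mass far exceed their unique-tag shares), both patterned
  on the published four-stage category table;
* 237 planted miRNAs split across the six presence patterns in the
  published census (52/40/43/19/42/41), rescaled when `n_mirnas` differs;
* abundance tiers (high 20,000 / mid 800 / low 150 mean reads, sampled
  10%/40%/50%) anchored to the study's 10,000/500/100 highlight thresholds;
  tier means are planted counts directly, and background mass fills the
  remainder of the library;
* a planted 8-fold change in one stage for 30% of all-stage miRNAs — large
  fold changes are what the four-stage comparisons report, and absent-stage
  counts are hard zeros because the patterns are presence/absence classes;
* negative-binomial count noise with `variance = mu + dispersion * mu^2`
  (default `dispersion = 0.1`, a typical small-RNA overdispersion;
  `dispersion = 0` gives deterministic rounded means). No overdispersion
  value is reported for the original libraries, so this is an exposed
  assumption, not a fact;
* a 5'-U first-base bias (U = 1.0 at 23 nt, reflecting the reported
  all-U bias of 23-nt miRNAs; U = 0.6 elsewhere);
* structural contaminants at configurable rates (defaults total 7%,
  keeping clean fractions above 90%): poly-N reads, full-length
  homopolymers, adapter-less reads and 5'-adapter carry-over.

Ground truth records every planted category, pattern, tier, first base and
per-pair differential status (defined on expected RPMs: ratio > 2, < 1/2,
or presence-xor-absence). Determinism is per-seed with per-library
sub-seeds; identical configurations give byte-identical outputs.

What the generator does *not* emulate: sequencing errors beyond the
structural contaminants, base-quality values (a constant is written),
multi-mapping repeat structure, miRNA families/isoform ladders, and any
genome-scale sequence realism — the reference is random DNA with planted
features. Passing round-trip tests therefore demonstrate that the
*algorithms* recover planted structure under realistic count noise, not
that the pipeline is robust to alignment artifacts in real genomes.

# Problem sizes and test design

The default configuration (10^6 reads, 237 miRNAs, 100 kb reference) is the
emulated study scale. The test suite and the acceptance script run a scaled
study: 10^5 clean reads per library, 100 miRNAs, a 60 kb reference, with
abundance tiers scaled by the same factor (high 2,000 / mid 80 / low 15) so
counts per million are preserved. At that scale the round-trip benchmark
(simulate → classify → test) recovers ≥ 95% of planted pattern labels and
planted differential calls, and the whole suite runs in about a minute.
Recovery is measured as sensitivity: the fraction of planted labels (or
planted up/down calls) reproduced exactly; false positives among non-DE
pairs are tracked separately in the tests because the per-library exact
test is anticonservative under overdispersion. The residual missed calls
are almost entirely stage-specific low-tier tags whose count draw lands
below about seven reads — at x = 0 the doubled-tail p-value is
\(2^{1-y}\), which cannot reach 0.01 until \(y \ge 9\) — a sensitivity
floor of the exact test itself, not of the implementation. The acceptance
script pools three replicate simulations for a stable recovery estimate.

# Known limitations

* Exact-match mapping only; reads from polymorphic or erroneous positions
  simply fail to map.
* The exact test models no biological replication; with replicates,
  count-model packages (edgeR/DESeq2) are the right tool, and this package
  intentionally reproduces the classical per-library workflow instead.
* The published six-class pattern vocabulary is presence/absence at a
  detection floor of one read; low-count noise can flip presence bits, which
  is why `presence_min` is exposed.
* Percentage formatting reproduces the mixed published style ("0.7%" next
  to "0.26%"); it is a display convention, and all identities are asserted
  on raw counts.
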