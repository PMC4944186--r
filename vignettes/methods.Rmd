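---
title: "Methods: full-length 16S long-read profiling on synthetic communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: full-length 16S long-read profiling on synthetic communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Short-read 16S surveys amplify one or two hypervariable regions (here
V3--V4, a ~469 bp window) and cluster the reads into OTUs; long-read
platforms can span the nearly full-length gene (~1.5 kb, all nine
hypervariable regions V1--V9) but at a per-base error rate around 20%.
`nanotax` implements both analysis arms and the statistics needed to ask
whether the noisy full-length arm recovers the same community, and when
the extra regions genuinely buy species-level resolution that V3--V4
cannot provide.

Because no real sequencing run ships with per-read ground truth, every
analysis here is exercised against a synthetic-data generator whose
outputs carry sidecar truth tables. The generator's defaults are the
study conditions; nothing in the analysis code depends on them.

## The synthetic reference database

`generate_reference_db()` draws a uniform-random root gene (default
1,500 bp), writes both primer pairs' binding sites into it verbatim,
then derives genus ancestors and species by substituting bases *only
inside the V1--V9 intervals*: genus ancestors at
`between_genus_divergence` (default 0.10) against the root, species at
per-region rates (default 0.02 everywhere). Conserved inter-region
backbone and primer sites are identical across all records, which is
what makes in-silico PCR succeed on every record and makes "which
window can separate these two taxa" a question with an exact,
constructed answer. Within-genus 16S species typically differ by a few
percent concentrated in variable regions, and genera by roughly ten;
the defaults mirror that order of magnitude.

The V1--V9 boundaries ship as a plain config table
(`default_region_map()`, conventional *E. coli*-numbering intervals);
every region analysis is relative to whatever map is loaded. The
V3--V4 primer cores are the printed standard pair
(`CCTACGGGNGGCWGCAG` / `GACTACHVGGGTATCTAATCC`), placed so the product
is 469 bp; the near-full-length pair defaults to the Klindworth et al.
standard sequences for S-D-Bact-0008-c-S-20 / S-D-Bact-1391-a-A-17,
placed to flank V1 through V9. Both pairs are configuration, not
constants.

## The long-read error model

`error_profile(p_sub, p_ins, p_del)` is parameterised **per aligned
column**: scanning the true read-to-template alignment, the expected
fraction of substitution, insertion and deletion columns equals the
three probabilities, so expected alignment-estimated accuracy is
`1 - (p_sub + p_ins + p_del)`. The platform default is
`nanopore_error_profile()` = (0.090, 0.064, 0.050), i.e. 79.6%
accuracy.

The subtlety is that error rates are *measured* by optimally realigning
reads, and an optimal affine-gap alignment is not an arbitrary column
sequence. If insertions and deletions were sprinkled independently, the
aligner would pair nearby insertion/deletion columns into single
substitution columns (an I column plus a D column costs 4 under the
(1,1,1,1) scheme; a mismatch costs 1), and the measured rates would
drift systematically off the generative ones — we observed about 1.5
percentage points of drift, comparable to the quantities being
recovered. The generator therefore emits the truth alignment in
*aligner-canonical* form:

* insertion runs are placed only at junctions with no deletion within 4
  template columns on either side;
* inserted bases differ from both flanking template bases;
* substituted bases differ from the true base and from any adjacent
  deleted template base.

Run-length means are calibrated analytically so expected column-type
fractions still equal the profile exactly. The cost of canonical form
is mild context dependence in the error process (about 1% of error
bases are drawn from 2 instead of 3 alternatives); homopolymer-aware or
quality-dependent error structure is deliberately out of scope, since
only aggregate rates are being modelled. Expected read length is
`L(1 - p_del/(1 - p_ins))` plus the insertion contribution —
`expected_read_length()` gives the exact value; the familiar
first-order form `L(1 - p_del + p_ins)` differs by ~0.1% at the default
rates.

Concatemer artifacts (hairpin-adapter products carrying two amplicons)
are simulated by concatenating two independently drawn, independently
corrupted amplicons with probability `p_concat`; truth tables record
both sources. Long reads carry a constant placeholder quality: pass
filtering by basecaller quality happens upstream of everything this
package models.

## Alignment

`align_local()` / `align_global()` are exact affine-gap
(Smith-Waterman / Needleman-Wunsch) DPs written in C++, scoring match
+1 and costing mismatch 1, gap open 1, gap extend 1 by default — the
LAST parameter set `-q 1 -a 1 -b 1`, reading `-q` as the mismatch cost
(its actual meaning in LAST, despite occasionally being glossed as a
match score). They return exact per-column counts of matches,
mismatches, insertions (query base absent from the reference) and
deletions. Equal-scoring tracebacks resolve deterministically: diagonal
over deletion over insertion; gap states prefer closing over extending.
`N` never matches anything, including `N` — a documented choice, since
aligners differ here. The full DP is the implementation *and* the
reference; tests cross-check scores against an independent brute-force
DP and against `Biostrings::pairwiseAlignment`.

## Classification and accuracy assessment

`classify_reads()` is taxonomy-supervised phylotyping: each read is
locally aligned against every reference and the best score wins. Ties
are truncated to the lowest common ancestor of the tied references
rather than broken arbitrarily — reproducible and conservative (a read
equidistant from two congeneric species is genus-level information, not
a coin flip). Reads whose best alignment covers less than
`min_query_cover` (default 0.5, permissive) of the read are unassigned.
`filter_low_abundance()` then discards taxa supported by fewer than 2
reads, keyed by the deepest assigned lineage.

`assess_accuracy()` pools matches/mismatches/insertions/deletions over
control-read alignments and reports micro-averaged rates on the shared
denominator, so accuracy plus the three error rates sum to exactly 1.
The span filter keeps reads whose alignment covers at least 80% of the
**reference** by default (`coverage_on = "query"` is available); with
near-full-length reads the two coverages rarely disagree. The control
is a packaged synthetic 1,400 bp sequence (`control_sequence()`)
standing in for a lambda-derived spike-in; it is labelled synthetic and
is built from a hard-coded seed so every installation agrees on it.

## The short-read arm

`join_pairs()` merges a 2x250 pair over the overlap maximizing matched
bases subject to a mismatch-fraction cap, takes the higher-quality base
at disagreements, and rejects joined reads shorter than 75% of the
summed pair length (for the 469 bp amplicon the overlap is
2x250 - 469 = 31 bases). `quality_filter()` truncates at the first base
below Q20 and requires 75% retention — the truncate-plus-retain reading
of a bare ">= Q20" rule. `cluster_otus()` is greedy centroid clustering
at 97% identity on dereplicated reads in decreasing abundance (ties:
longer, then lexicographic id), with identity defined as matches over
*all* alignment columns, so gaps count against identity — stated
explicitly because popular tools differ subtly here. Chimera removal
and reference-first clustering are omitted: the simulator generates no
chimeras beyond concatemers, which never enter the short-read arm.

`rarefy()` subsamples to an even depth without replacement;
`rarefaction_curve()` draws one permutation per replicate and reads
every depth as a prefix, so subsamples are nested and every replicate's
curve is monotone non-decreasing by construction, not merely in
expectation.

## Cross-platform comparison

`profile_abundance()` collapses assignments (or count-weighted OTUs) to
one rank; unlabeled reads stay in the coverage denominator, making
`rank_coverage` comparable across ranks. `compare_platforms()`
partitions the taxon union into group I (both platforms), II
(long-read only) and III (short-read only), computes
`log2(B/A)` on relative abundances for group I only — no pseudocounts,
and depth differences cancel — and flags `|log2fc| > 1`.
`spearman_r2()` reports rho² with an exact permutation p-value for
n <= 9 and the t approximation beyond. `venn_counts()` gives
shared/specific counts plus the fraction of reads carried by shared
taxa.

## Region variant analysis

`align_references()` aligns two sequences optimally; for more it uses
star-progressive alignment anchored on the first sequence (pairwise
global alignments whose gap runs are merged per junction). For the
handful of closely related references this analysis sees, the star
method is adequate, dependency-free and deterministic; it is not a
general-purpose MSA. `detect_variants()` flags every column whose
residues are not all identical — gaps count as alleles, flagged
`has_gap` so gap-free counts remain recoverable — and reports the
frequency of the second-most-common allele as the minor allele
frequency, which keeps it in (0, 0.5] even at columns with three or
four alleles (a strict "less than 50%" reading would exclude the
pairwise case where both alleles sit at exactly 50%, which is plainly
counted in practice). Sites inherit an anchor coordinate (gap columns
inherit the previous anchored position, exact to within one column at
region boundaries when indels are present) and a V-region label.
`discriminability()` asks whether any variant falls inside an amplicon
window located by in-silico PCR on the anchor — the operational version
of "can V3--V4 separate these species, or does it take the full-length
gene". Building phylogenetic trees from the references is out of scope.

## Pipeline, determinism and problem sizes

`run_pipeline()` executes reference generation, both simulation arms,
classification, clustering, rarefying, comparison and region analysis
from one `run_config()`, writing every intermediate to disk (FASTA,
FASTQ, TSV, JSON summary). All thresholds default to the study values
(97% identity, Q20, 75% retention, 80% span, singleton discard,
|log2fc| > 1). Every stochastic step derives its seed deterministically
from the master seed, so a config determines all outputs byte for byte;
truth tables are sidecar files so classification can never read its own
answers.

Default problem sizes are chosen to exercise the statistics at
laptop scale: a 4-genera x 3-species database, hundreds of reads per
arm, and 1,000 control reads for error-rate recovery, at which size the
recovered rates are stable to a few tenths of a percentage point. The
test suite runs the same analyses at these or smaller sizes.

## What passing tests do and do not show

The generator emulates amplicon structure, per-column long-read error,
Phred-governed short-read error and concatemer artifacts. It does not
emulate chimeras, host contamination, primer-binding failures,
abundance-dependent amplification bias, homopolymer error clustering,
or the unalignable read fraction real runs contain. Recovery results on
synthetic data therefore validate the *computations* — alignment
counting, the estimator identities, threshold logic, group partitions —
not the field performance of any sequencing platform. Printed
real-data quantities that depend on unreleased reads or an external
reference database (total OTU counts, per-rank coverage of a real
mouse community, variant counts against a curated 16S database) are
structurally reproduced but not numerically asserted.
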