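---
title: "Split-read Alu insertion calling and cross-genus sharing statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-read Alu insertion calling and cross-genus sharing statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alushare)
```

## The problem

Alu elements are ~300 bp primate-specific retrotransposons that spread by
target-primed reverse transcription (TPRT). An insertion at a given locus is
effectively a unique, irreversible event whose ancestral state is *absence*,
which makes the presence/absence pattern of recent insertions across
individuals a nearly homoplasy-free genealogical marker. When two long-diverged
lineages — say, a baboon-like ingroup radiation and an intergeneric relative —
*share* polymorphic insertions, the sharing pattern carries information about
incomplete lineage sorting, ancient admixture and ongoing gene flow.

`alushare` implements, at desk scale and fully testable, the computational
machinery such a study needs:

1. a **synthetic WGS cohort generator** with planted insertions under a
   configurable sharing design (the ground truth every downstream claim is
   tested against);
2. a **split-read caller**: reads that straddle an insertion junction are
   recognized by their partial match to an Alu consensus, the Alu segment is
   cleaved, and the residual flank is mapped uniquely back to the reference;
3. a **cohort genotype matrix** with outgroup and second-reference screens;
4. the **sharing statistics**: per-bin carrier tallies with one-way ANOVA and
   Bonferroni post-hoc t-tests, species-indicative sets cross-referenced with
   the intergeneric individual and z-scored, and PCR-style validation
   accounting;
5. a **5' flank-length read filter** with a before/after comparison,
   including the subtle failure mode where filtering *adds* loci to
   species-indicative sets;
6. **subfamily assignment** by percent divergence against a consensus library.

## The synthetic cohort

The default study design mirrors the sampling structure the statistics
assume: six ingroup species with two sampled individuals each, split into a
northern and a southern clade; one intergeneric individual in whose genome
candidate loci are ascertained; one outgroup individual used as the
recentness screen. The default reference is a single 100 kb i.i.d. random
chromosome at GC 0.40 — deliberately repeat-free, so that "unique flank
mapping" is a clean contract rather than a statistical hope. Insertions are
planted as `[TSD][element][TSD]` with TSD lengths drawn uniformly from 6–20 bp
(typical of TPRT target-site duplications), optional 5' truncation, and
carrier sets drawn per sharing class:

* `fixed_ingroup` — all ingroup individuals plus the intergeneric individual;
* `intergeneric_shared` — the intergeneric individual plus 2–11 ingroup
  carriers (the bins the sharing statistics live on);
* `species_indicative` — both individuals of exactly one species, nobody else;
* `polymorphic_ingroup` — an ingroup-only pattern that is not species-bound;
* `intergeneric_private` — the intergeneric individual alone.

The outgroup never carries an insertion; the sharing class is a pure function
of the carrier genotypes and is re-derived (and asserted) at planting time.
Heterozygous carriers place the element on haplotype A only; the simulator
samples both haplotypes equally, so a heterozygous junction sees half the
nominal coverage.

Reads are paired-end FR, 100 bp, fragment size 450 ± 50 (the WGS this design
emulates does not pin these; they are ordinary short-insert Illumina
values), with i.i.d. substitution errors at rate 10⁻³ and no indel errors.
The fragment-count contract is `pairs = coverage × haploid_length / (2 ×
read_len)`. What the generator does *not* model — repeat-rich backgrounds,
quality-score structure, PCR duplicates, indels, reference gaps — bounds what
green tests mean: they certify the pipeline's logic, not its robustness to
real-genome mapping ambiguity.

## The split-read caller

A read is a candidate split read if it shares an 11-mer seed with the
consensus (either orientation). Candidates are locally aligned to the
consensus (match +1, mismatch −1, gap −2); a qualifying Alu segment needs
≥ 20 matched bases at ≥ 0.90 identity. The alignment engine is
`Biostrings::pairwiseAlignment`; the package's own contribution is the
calling logic around it, and the test suite checks the scan against an
independent brute-force Smith–Waterman oracle so the engine is never trusted
blindly. Reads provably internal to an element (too many seed hits to retain
a mappable flank) are skipped wholesale — an exact bound, not a heuristic:
a read keeping a clean flank of `f` bases can match at most
`read_len − k + 1 − f` distinct consensus k-mers.

The non-Alu residue is mapped to the reference with a mismatch budget of 5%
and accepted only if (a) it is at least 20 bp long, (b) the best placement
beats the second best by ≥ 4 score units ("uniquely mapped"; 4 units = 2
mismatches under the scoring above), and (c) identity ≥ 0.95. The junction is
the reference coordinate abutting the cleaved end. Geometry fixes the flank
side: a flank left of the element head (in element orientation) is 5', right
of the tail is 3'. A read whose element segment is internal yields two
evidence records. Per individual, accepted junctions within 25 bp merge into
one call: TSDs shift the 5' and 3' cleave points apart by the TSD length
(6–20 bp here), so a window below ~20 bp would split every insertion in two,
while the planting guard distance (≥ 2 fragment lengths) makes windows up to
a few hundred bp safe. The call coordinate is the modal 5'-side cleave point
when 5' evidence exists (ties to the smaller coordinate), else the modal
3'-side point. Recovery of planted loci is scored against the duplicated
target site `[pos, pos + tsd_len]` rather than a single base: the cleave
point of a TPRT insertion is only defined up to the TSD, and at 5'-truncated
loci whose TSD happens to extend the consensus match, a coordinate inside
the TSD is a score-optimal — and equally correct — description of the same
insertion event. A single
supporting read suffices by default (`min_support = 1`): the downstream
validation accounting is exactly the machinery that quantifies what that
permissiveness costs, and the 5' flank filter is the corrective lens.

All planted elements sit on the + strand of the reference — a generator
simplification, not a caller one: fragments are sampled from both strands,
so half of all junction reads reach the caller as reverse complements and
the orientation logic is exercised throughout.

## Matrix, classification, statistics

Per-individual calls are clustered across the cohort (single linkage along
each chromosome, joining a cluster when within 25 bp of the running median).
The matrix records `detected`/`not_detected` plus a per-cell support count:
absence of a call means *no acceptable reads*, not *predicted absence*, and
downstream users deserve to see the difference even though the statistics
use the binary state. Loci detected in the outgroup are excluded from all
statistics. Among loci detected in the intergeneric individual, the ingroup
carrier count `k` classifies the locus: `k = 12` fixed, `2 ≤ k ≤ 11`
polymorphic (the retained bins), `k = 1` singleton — reported but outside
the bins, which begin at 2 by the "shared by two to twelve" convention.

The per-bin table counts, for every polymorphic shared locus of bin `b`, one
unit for each of its `b` carriers; hence the conservation identity
`Σ_individuals count[b, ·] = b × total[b]`, which the tests assert both on
synthetic cohorts and on the published tallies shipped as a fixture. Each
bin gets a classical one-way fixed-effects ANOVA (`lm`/`anova`) across
species (6 × 2) or clades (2 × 6), followed — when p ≤ 0.05 — by all
pairwise pooled-variance two-tailed t-tests (`t.test(var.equal = TRUE)`)
under a Bonferroni threshold of α/15 for species (α/1 for clades). Two
degenerate cases are fixed by convention: zero between-group variance
reports F = 0, p = 1; zero within-group variance with distinct means reports
F = ∞, p = 0.

The species-indicative z-test standardizes the six per-species shared counts
against their own mean and **sample** (n−1) standard deviation, with a
one-tailed normal p-value taken as the tail beyond the observed deviation
(`1 − Φ(|z|)`). Both choices are deliberate: they are the conventions under
which the published statistic this module regression-tests against is
reproducible for every sign of z (mean 87, sd 77.7, z = 1.9176 for the
largest count; the below-average counts' printed p-values are lower-tail
probabilities). Whether a normal z-test on six counts is a sound test is a separate
question; the package replicates the convention rather than endorsing it.
Treating the two individuals of a species as independent ANOVA replicates is
likewise inherited, not endorsed.

## The flank filter and its pathology

Re-screening calls to require ≥ 30 bp of unique 5' flanking sequence
removes weakly anchored calls (a call survives if *any one* of its reads
qualifies — the alternative of requiring all reads would conflate support
depth with anchor quality). The filter is idempotent and monotone, and the
package reports what it changes: per-bin shifts, per-individual call losses,
and — the interesting part — loci that *enter* a species-indicative set only
because another individual's call was filtered away. The high-confidence
rule intersects post-filter indicative sets with the pre-filter ones
(matching loci by junction proximity, since re-clustering may shift
representatives) and removes loci found in the second reference.

## Validation accounting

Predictions are scored against an external genotype table in PCR band
coding — `(1,1)`, `(1,0)`, `(0,0)`, `(−9,−9)` for missing. A predicted cell
with at least one insertion allele in truth is confirmed (heterozygous bands
confirm); missing truth is a no-amplification exclusion; homozygous-absent
truth is a false prediction. Rates divide by evaluable predictions. A locus
is a false negative when the computational classification says polymorphic
but truth is filled in every panel individual; its rate divides by loci
assessed. The published marginal counts are shipped as a fixture together
with a synthetic per-cell realization (the real per-locus table is not
reproducible from the printed record); the realization is labelled synthetic
and exists so the accounting runs end to end against the printed totals.

## Subfamily assignment

Each element is globally aligned (match +1, mismatch −1, gap open 5, extend
1) to every consensus in a user-supplied library; divergence is mismatch
plus interior-indel columns over aligned consensus columns after trimming
terminal gap runs (a 5'-truncated element is not penalized for its missing
head). Elements at ≤ 2% divergence are flagged young. Two simplifications
are documented rather than hidden: CpG positions are not down-weighted
(inflating divergence slightly relative to RepeatMasker-style scoring), and
no Kimura correction is applied. The built-in library is synthetic — a fixed
AluY-like consensus plus per-subfamily diagnostic substitutions recorded in
the FASTA headers — so no third-party repeat library ships with the package;
a user-supplied library drops in unchanged.

## Numerical and design choices

* Coordinates are 0-based half-open internally and in BED-like outputs;
  1-based only in printed reports.
* One master seed fans out into named per-stage substreams
  (reference/planting/reads/library), so stages are independently
  reproducible and byte-identical under a fixed seed.
* Insertion points keep a pairwise guard distance of at least two fragment
  lengths (slotted placement with bounded jitter), so no read pair straddles
  two planted loci and locus clustering is unambiguous by construction.
* Ties in subfamily assignment break by library order; ties in junction
  position break to the smaller coordinate.
* The default problem sizes (100 kb reference, 62 planted loci, 30×,
  14 individuals; ~20 kb cohorts in unit tests) were chosen as the smallest
  sizes at which every sharing bin and class is populated and binomial
  counting noise stays well inside the asserted margins.

## Known limitations

The generator's clean background makes flank mapping easier than in a real
primate genome; sensitivity and junction-error numbers from synthetic runs
are upper bounds on real-data performance. The second-reference screen is an
exact 60-mer junction search, a stand-in for in-silico PCR against a second
assembly. Genotype likelihoods, imputation of missing states, non-Alu mobile
elements and discordant-pair-only calling are out of scope.
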