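---
title: "Annotating motif-defined centromeres and simulating centromere transitions"
author: "cenevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating motif-defined centromeres and simulating centromere transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cenevo)
```

## The problem

Budding-yeast point centromeres are short (~100-200 bp), genetically defined
loci with a stereotyped architecture: an ~8-bp CDEI motif bound by Cbf1, an
AT-rich spacer (CDEII, roughly 50-200 bp depending on species) that wraps the
centromeric nucleosome, and an ~26-bp CDEIII motif bound by the CBF3 complex.
Mucoromycota core centromeres lack sequence homology to these but share an
analogous organization: a ~41-bp motif followed by a long AT-rich tract.
`cenevo` provides (i) a motif scanner with exactly calibrated p-values,
(ii) a two-stage annotation pipeline for point centromeres with a rule-based
filter cascade and karyotype inference, (iii) a core-centromere annotator
driven by downstream GC profiling, (iv) stochastic simulators of centromere
type transitions under drift and selection, validated against exact Markov
chains, and (v) a synthetic-genome generator that plants centromeres with
known coordinates so every stage can be verified against ground truth
without downloading assemblies.

## Motif model and scoring

A motif is a position weight matrix (PWM): a `width x 4` matrix of
per-position base probabilities, built from aligned example sites with
additive smoothing,

  probs[i, b] = (count(b at i) + pseudocount * 0.25) / (n_sites + pseudocount),

with pseudocount 0.1 by default (the usual small additive smoothing; it
keeps log-odds finite for consensus-only site sets). An `N` in a site
contributes 0.25 to each base. A window of sequence is scored by the
log-odds sum `sum_i log2(probs[i, b_i] / bg[b_i])` in bits, against a
0-order background. The background defaults to base frequencies estimated
from the scanned assembly (pooled contigs, one pseudo-observation per base);
uniform and user-supplied backgrounds are available. On AT-rich yeast
assemblies the genome-estimated background matters: it makes GC-rich
near-consensus words more surprising, which measurably improves the
sensitivity of the permissive CDEI rescan (see below).

### Exact p-value calibration

Score thresholds are expressed as p-values: the probability that a random
word drawn from the background scores at least as high. `cenevo` computes
this null distribution exactly by dynamic programming: each position's
log-odds entries are mapped to integers on a grid of step
`delta = max(per-position range) / granularity` (granularity 1000 by
default), and the distribution of the integer total is obtained by
per-position convolution. The full support sums to 1 to machine precision,
and the discretization error is bounded by `width * delta` bits of score
(2.6% of a position range per position at the default). P-values are
reported on the integer grid; windows are selected by their integer score,
so scanner results and the DP distribution are mutually consistent by
construction, which the tests exploit by comparing both against exhaustive
enumeration of all `4^w` words for widths up to 8.

Scanning is strand-aware: minus-strand hits are reported in forward-strand
coordinates (0-based, half-open; GFF3 output converts to 1-based inclusive)
with the matched sequence reverse-complemented into motif orientation.
Windows containing non-ACGT characters are skipped, never scored, because
fragmented assemblies contain gap runs. All hits at or below the threshold
are reported, including overlapping ones; resolution belongs to the
annotation layer, keeping the scanner a pure function.

## The point-centromere pipeline

1. **CDEIII scan.** Both strands of every contig are scanned with the
   CDEIII PWM. Practical thresholds range from 1e-3 (sensitive, small
   search space) to 1e-7 (strict, whole-assembly scans); the package
   default is 1e-5, the midpoint of that range on a log scale. For a 12-Mb
   assembly (~24 million windows over both strands) the expected number of
   chance hits is the threshold times the window count, so whole-genome
   runs that must not pass false positives should sit at the strict end;
   the bundled acceptance analysis uses 1e-7, for an expected ~2.4 chance
   hits genome-wide before the cascade.
2. **Window extraction.** Every hit with at least 224 bp available on its
   5' (CDEI) side yields a 250-bp candidate window: 224 bp upstream plus
   the 26-bp motif, in centromere orientation (minus-strand hits are
   reverse-complemented; "upstream" is then forward-strand downstream).
   Edge-adjacent hits are dropped and counted.
3. **CDEI rescan.** Each window is rescanned, forward orientation only,
   with the CDEI PWM at a deliberately permissive 1e-2. Only placements
   entirely within the 224-bp upstream stretch qualify. Among qualifying
   hits the pipeline keeps the one maximizing the call's combined-score
   contribution, `w2 * score / max_score + w3 * implied_CDEII_AT / 100`
   (ties towards the window 5' end). Selecting on motif score alone is
   fragile here: at a permissive threshold, windows regularly contain
   chance CDEI-like words in their AT-poor upstream stretch, and a chance
   hit that ties or slightly beats a degenerate true site would otherwise
   displace it and corrupt the implied CDEII length. The AT term breaks
   exactly those ties in favour of the placement that leaves an AT-rich
   spacer, which is the biological structure being annotated; when the AT
   term does not discriminate, the rule reduces to best-score.
4. **CDEII measurement.** CDEII is the subsequence strictly between the
   CDEI end and the CDEIII start; its length and AT percentage (ambiguous
   bases excluded from numerator and denominator) are computed per call.
5. **Combined score.** Each call receives
   `w1 * score_CDEIII / max_CDEIII + w2 * score_CDEI / max_CDEI + w3 * AT / 100`
   with default weights (1, 1, 1). The functional form is a design choice:
   it is scale-free (each component normalized to [~0, 1]), strictly
   increasing in each component, and a perfect-consensus call with 100% AT
   CDEII scores exactly `w1 + w2 + w3`. Weights are exposed for tuning.
6. **Filter cascade**, applied sequentially, each rule marking its
   removals: (1) keep the top 50 calls by combined score; (2) remove calls
   whose CDEII length differs by more than 30 bp from the median of the
   top-5 survivors (with fewer than 5 survivors, the median of all); (3)
   remove calls with CDEII AT below 70%; (4) remove duplicates -- identical
   full sequences anywhere, or more than 50% span overlap on the same
   contig and orientation (fragmented assemblies duplicate centromeric
   contigs), keeping the higher combined score, ties to the
   lexicographically smaller (contig, start); (5) recompute the survivor
   medians and remove calls for which BOTH the length lies outside
   median +/- 10 bp AND the AT content is below median - 7 points. The
   joint rule is a strict conjunction, so a call deviating in length alone
   or AT alone survives it. All parameters are exposed.

The number of retained calls is the inferred karyotype. On synthetic
16-chromosome genomes with one planted centromere per chromosome and 40
decoy loci, the pipeline recovers all 16 at precision 1.0 for typical
seeds; the residual failure modes are quantified below.

### Sensitivity and specificity at the study conditions

Two stochastic failure modes remain at the default study conditions (5%
per-position motif noise, 38% GC background, 95% AT CDEII):

* A planted 8-bp CDEI can receive 3 or more substitutions
  (P about 0.6% per site); roughly half of such words still pass 1e-2
  under the genome-estimated background, and some of the rest are rescued
  by a nearby chance hit whose call survives the cascade (its CDEII
  contains the AT-rich core), leaving an effective per-site miss rate of
  about 0.3% -- measured as 8 misses in 3,000 simulated candidate windows.
* A CDEIII-only decoy can acquire a chance CDEI whose implied CDEII
  happens to fall in the retained length band with AT at or above 70%;
  the measured cascade-survival rate is 0.56% per decoy window (56 of
  10,000 simulated), i.e. an expectation of roughly 0.08 false retained
  calls per default genome, so about 8% of seeds yield one such call.

Both rates are properties of the annotation problem at a permissive CDEI
threshold, not of the implementation; the published pipeline addresses the
second with per-clade threshold tuning and external synteny checks, for
which `extract_flanks()` provides the hand-off (±10 kb around each call)
without bundling a homology engine.

## Mucoromycota core centromeres

The adaptation performs a single motif search (41-bp motif by default),
extracts up to 750 bp downstream of each hit in motif orientation
(truncated and flagged at contig edges -- core-centromere contigs are often
short), and profiles GC content in a 100-bp moving window at 1-bp steps
(`gc_percent = 100 (G+C) / (window - ambiguous)`, windows more than half
ambiguous omitted). The AT-rich region length is estimated as the maximal
run of windows from offset 0 at or below a 25% GC cutoff, reported as
`run + window - 1` bp and capped at the available downstream length. The
cutoff rule is an explicit, testable stand-in for identifying bona fide
cores by visual inspection of GC profiles; a call whose estimated AT region
is shorter than one window (100 bp) is flagged as not bona fide, which
rejects chance motif hits in ordinary sequence. On planted AT runs the
estimate lands within one window width of truth: the window straddling the
run's 3' boundary still averages below the cutoff until roughly two thirds
of it is background, giving a systematic overshoot of 40-70 bp -- within
the stated one-window tolerance, and immaterial for separating length
classes that differ by ~2-fold between genomes. Iterative motif refinement
(`refine_core_motif()`) rebuilds the PWM from the matched sites of the
current hit set and rescans until the hit set is stable (at most 10
rounds), mirroring the practice of updating search motifs with newly
discovered centromeres until no additional loci appear.

## Transition simulations

The transition model tracks centromere types A (ancestral) and B (new)
across `n` centromeres. Each step picks one centromere uniformly and sets
it to A with the retention probability `p`, otherwise to B; `p = 0.5` is
pure drift, smaller values favour the new type. Draws use a real
`u ~ Uniform[0,1)`; the historical integer scheme (0-999 against
`round(1000 p)`) is available behind `integer_scheme = TRUE` and is
distributionally identical at 3-digit granularity. Haploid lineages carry
16 centromeres, diploids 32 chromatids; both start all-A.

Because each step's assignment does not depend on the current state, a
replicate's final state is determined by the last draw touching each
centromere; `run_lineage()` exploits this for vectorized replicates, and a
property test checks the shortcut against a literal step-by-step fold over
identical draws. The exact final-state distribution is available from
`markov_oracle()`: the B-count is a birth-death chain on `{0..n}` with
up-rate `(n-k)/n (1-p)` and down-rate `k/n p`; simulations at 10,000
replicates sit within 4 standard errors of the matrix-power probabilities
across a grid of `(n, p, steps)`. Two closed-form anchors: at `p = 0` the
time to the all-B state is the coupon-collector time with mean
`n H_n` (about 54.09 steps for n = 16), and at `p = 0.5` the chain
equilibrates to Binomial(n, 1/2), making the full-transition probability
`2^-16` (about 1.5e-5) for a haploid and `2^-32` for a diploid -- full
transitions effectively require selection, while at `p <= 0.01` the
1000-step full-transition probability rises above 0.85.

### Populations and meiosis

The population model holds 100 diploid individuals (16 chromosome pairs,
2 chromatids each), all-A at start. Each iteration mutates exactly one
uniformly chosen chromatid of one chromosome of one individual under the
retention rule, then (in the meiosis condition) synchronously reassorts:
every individual, at every chromosome, keeps one of its own chromatids
uniformly and draws the other uniformly with replacement from the
population-wide pool of 2N chromatids at that chromosome, in the
post-mutation state. Two readings were genuinely open and are settled
here as configuration: the donor pool includes the focal individual's own
chromatids, and the update is synchronous.

A counting argument fixes what this model can and cannot show in 500
iterations. The mutation step introduces at most one B chromatid per
iteration into a pool of 3,200, so the expected final B frequency is about
0.14, and reassortment -- a neutral copying process -- preserves expected
frequency while adding drift. An individual with all 32 chromatids of type
B therefore has vanishing probability within 500 steps under either
condition, and the per-replicate count of fully transitioned individuals
is almost surely 0 with and without meiosis; the corresponding
stochastic-dominance check in the test suite documents this as a negative
result rather than being weakened. The meiosis effect is nonetheless real
and visible one level down: with reassortment, drift fixes the new type
population-wide at individual chromosomes (about 0.5 chromosomes per
500-step replicate at `p = 0.01`), which is impossible without meiosis
inside the mutation budget (fixation of one chromosome would need at least
200 of the ~31 expected hits on it). `run_population()` therefore reports
fully transitioned individuals, fixed chromosomes, and the total B count
per replicate.

## The synthetic-genome generator

`make_point_centromere_genome()` plants exactly one centromere
(CDEI + CDEII + CDEIII, uniformly random interior position and strand) per
chromosome in i.i.d. background sequence, plus CDEIII-only decoys and
full-structure decoys with AT-poor CDEII, and emits an exact truth table.
Defaults, chosen once as field-realistic study conditions: 16 chromosomes
of 750 kb (a 12-Mb yeast-scale assembly); background GC 38%; planted CDEII
85 bp at 95% AT (the yeast-like regime); per-position motif substitution
rate 5%; 20 + 20 decoys with decoy CDEII at 50% AT, placed at least 300 bp
from any other locus. CDEII length classes with mixture weights (for
example `c("50" = 0.5, "61" = 0.5)`) emulate genomes caught mid-transition
with two coexisting centromere types. The default consensus strings are
synthetic stand-ins with the field's hallmark features (the CDEI E-box
CACGTG, the CDEIII CCGAA core, a mixed-composition 41-bp core motif); they
are not sequences of any particular genome, and the 41-bp motif was
screened to be free of internal reverse-complement repeats that would
produce shifted antisense self-hits.

`make_mucor_genome()` plants one motif + AT-run locus per contig (92% AT
run; one or two length classes), optionally ending a contig inside the run
to exercise truncation handling. `make_strain_population()` emits per-strain
genomes in which a chosen fraction of strains carry 1-2 centromeres whose
CDEII was lengthened or shortened by 10 bp through a microhomology-style
event: a lengthening inserts an exact copy of the immediately preceding
internal stretch (so the product contains a tandem duplication), a
shortening deletes a stretch. `classify_strain_variants()` flags strains
with any retained CDEII outside 80-90 bp.

What the generator does not model -- repeat families, realistic assembly
fragmentation, phylogenetic correlation between strains, centromere-
proximal retrotransposons -- bounds what passing tests show: they verify
the scanner, the cascade logic, coordinate bookkeeping and the estimators
against planted truth, not robustness to repeat-rich real assemblies.

## Numerical and interface choices

* Coordinates are 0-based half-open internally and in BED; GFF3 is 1-based
  inclusive, with `centromere` parents and CDEI/CDEII/CDEIII children.
* Score discretization at 1000 bins per position range; p-values exact on
  the integer grid, conservative floor lookup for arbitrary real scores.
* Degenerate inputs: empty sequences and motif-free genomes yield empty
  results, not errors; fewer than 5 cascade survivors fall back to the
  median of all survivors; zero-length CDEII gives `NA` AT, which the AT
  rule treats as failing.
* All randomness is seeded through configuration objects; outputs are
  byte-identical across runs at fixed inputs and seeds.
* Problem sizes in the test and acceptance runs: the full 12-Mb genome for
  the main recovery analysis; a 3.2-Mb genome for the mixed-class
  analysis; 10,000 replicates for lineage simulations; 200 replicates of
  500 steps per population condition; 30 strains for variant
  classification. These sizes make each analysis reproducible in minutes
  on one core while keeping Monte-Carlo error well inside the stated
  tolerances.

## Known limitations

Synteny verification against external proteome databases is out of scope
(`extract_flanks()` exports the regions a homology pipeline would need).
The scanner uses 0-order backgrounds only, and hit lists are thresholded on
p-values without multiple-testing correction, matching the fixed-threshold
practice the pipeline reproduces. The population simulator implements the
literal one-mutation-per-iteration reading discussed above; richer
Wright-Fisher or centromere-drive dynamics are deliberately not modelled.
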