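---
title: "Fitness and pairwise epistasis from combinatorial library enrichment sequencing"
author: "combEpi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitness and pairwise epistasis from combinatorial library enrichment sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combEpi)
```

## The experiment this package models

A combinatorial mutant library of the integron integrase IntI1 combines 13
focal amino-acid substitutions (E103K, T118S, D161G, H162Q, S173R, K219R,
Y220N, D299E, V315A, G319E, G320D/N, A321G, A329T) in all possible
combinations.  At the two most variable positions the library primers used
degenerate codons: `GRM` at 319 (glycine, glutamate, plus the unintended
aspartate) and `RRT` at 320 (glycine, aspartate, asparagine, plus the
unintended serine).  The designed allele space therefore holds
2^11 x 3 x 4 = 24,576 alleles.  The library goes through enrichment cycles
selecting for double-strand (attI x attI) recombination activity, and long
consensus amplicon reads are taken before selection (t0) and after cycles
1, 3 and 6.

Each curated read is reduced to its *allele-ID*: the string of residues at
the 13 focal positions.  Everything downstream — fitness, epistasis, the
null model — operates on the allele-ID x time-point count table
(`AlleleCounts`, a `SummarizedExperiment`).

## Read curation

Consensus long reads still carry roughly 0.3% per-base errors and a
surprising number of indels; on a 1014-bp ORF that is about three errors
per read.  Indels observed even in late cycles (where frame-shifted,
inactive integrases cannot survive selection) are technical artifacts, so
the pipeline repairs them rather than discarding the reads:

1. reads too short to span the first through last focal codon (ORF
   positions 307-987) are discarded;
2. the read, or its reverse complement, is aligned to the reference with a
   free-end-gap global alignment (match +1, mismatch -1, gap open -2, gap
   extend -1); best-alignment identity below 80% marks the read
   unalignable (this removes chimeras and junk without touching real
   alleles at 0.3% error);
3. read insertions are removed and read deletions are filled back with the
   reference base (`correctIndels()`); focal codons containing repaired
   bases are accepted as reference-residue calls and counted in the
   report;
4. focal codons are translated into the allele-ID; codons with `N` give
   `X` and stops give `*`, both flagged `unexpected`; all other codons are
   compared with the reference to build the off-target mutation spectrum.

The aligner and its parameters are a package choice — any scoring scheme
that is robust at sub-percent error rates gives identical allele-IDs,
because almost all reads are one substitution-only edit away from a
template.  Reads of exactly reference length whose direct mismatch
fraction is below 5% skip the alignment; no indel placement can beat the
substitution-only interpretation under the scoring above at that identity.

`detectOfftargetHotspots()` scans the spectrum for positions standing a
configurable multiple (default 10x) above the median per-position
substitution frequency — the pattern by which the A234V hotspot was
noticed in the real data.  A 14th tracked locus (A234V) can be appended to
the panel (`defaultPanel(hotspot = TRUE)`) when that substitution should
be carried in the allele-ID itself.

## Fitness and pairwise epistasis

Before estimation the table is filtered: alleles must be wild type at the
degenerate loci 319 and 320 and wild type or the expected mutant
everywhere else.  That leaves 11 focal mutations and 55 unordered pairs.
Coverage only supports *background-averaged* estimates: the fitness of a
mutation is the collective enrichment of every allele carrying it,
relative to every allele wild type at that locus,

    W_i = ln[ (mut_i^t1 / wt_i^t1) / (mut_i^t0 / wt_i^t0) ],

with counts aggregated over genetic backgrounds.  Pairs use carriers of
both mutations versus alleles wild type at both loci; mixed alleles belong
to neither group.  Pairwise epistasis is

    eps_ij = W_ij - (W_i + W_j).

Only the t0 -> cycle-1 interval is used by default: the genetic-background
profile of each focal mutation is common at t0 (verifiable with
`backgroundProfile()`) but drifts differentially afterwards, which is
exactly what makes later intervals incomparable; the package computes them
if asked, with a warning.

**Pseudocounts.**  Zero aggregates make the log ratio undefined.  The
default adds 0.5 to each of the four aggregates; `pseudocount = 0` returns
flagged `NA` estimates instead of silently dropping them.  The null model
always uses the same policy as the real-data estimator, otherwise the
confidences would be biased.  Because estimates are background-averaged,
an injected interaction appears diluted relative to its per-genotype
value (carriers of one mutation average over both states of its partner);
signs and significance are preserved, which is what the detection
machinery needs.

## The Poisson-resampling null model

Counting noise alone can fake epistasis.  To calibrate, the experiment is
re-simulated under explicit *no epistasis*: each replicate

1. resamples the observed t0 counts with Poisson draws (mean = observed
   count) to represent uncertainty in the true t0 frequencies;
2. propagates one selection cycle, `f1 = f0 w / wbar`, with genotype
   fitness `w_a = prod exp(W_i)` built from the *real* single-mutation
   estimates;
3. draws simulated t1 counts Poisson at the real t1 total;
4. re-estimates all 11 single and 55 pair W, hence all 55 epsilon,
   exactly as for the real data (same pseudocount, using the real t0
   counts alongside the simulated t1 counts).

1000 replicates per run is the default.  Confidence of a real estimate is
one-sided in the direction of its sign: the fraction of simulated epsilon
below (positive case) or above (negative case) the real value, with ties
counted one half.  A confidence of exactly 1 is reported as a bound,
`> 1 - 1/n_sims`.  Flags are set at 95% and 99%; no multiple-testing
correction is applied by default (matching how per-pair confidences are
conventionally reported for this design), and users who want it can adjust
the exceedance column themselves.

**What "calibrated" means here.**  Because the test direction is chosen by
the observed sign, the 95% flag is a pair of one-sided tests: under a true
null each tail fires for about 5% of pairs, so about 10% of pairs carry
the flag overall.  The quantity that is uniform on (0,1) under the null is
the null-CDF position `F_null(eps_real)` (the `null_exceedance` column);
calibration tests in this package check that uniformity and the per-tail
5% rates.  Reproducibility: one seed governs a run, and each replicate
draws from a sub-stream derived from it, so results do not depend on
execution order.  Per-replicate undefined estimates (possible at
pseudocount 0) are excluded and counted, with a warning above 5%
exclusions.

## The recombination-assay arm

Plate/conjugation assays measure recombination frequency as recombinant
over total colony counts; activity of an allele is its fold change versus
a reference allele (delta-method quotient SE over replicate means).  Under
independent loci the expected fold increase of a combination mutant is the
product of its members' fold increases, e.g. 7.6 x 5.4 x 7.2 = 295.5 — a
roughly 300-fold prediction against an observed ~10-fold gain for that
triple mutant.  Significance of the deviation uses first-order error
propagation: `sigma_E = E sqrt(sum (s_i/x_i)^2)` for the product,
`sigma_eps = sqrt(sigma_E^2 + s_O^2)` for `eps = E - O`, and a default
`k = 2` one-sided criterion (`eps > k sigma_eps`), chosen as the usual
approximately-95% cutoff; first-order propagation is accurate to within
10% of Monte-Carlo propagation whenever relative errors stay below ~20%,
which triplicate assays comfortably satisfy.  On shared truth the two
scales agree identically: `ln E - ln O = -eps_count` when fold changes are
the linear-scale fitnesses of the count view (tested).

## The synthetic-data generator

`makeBenchmark()` produces ground-truthed experiments so every stage is
testable without any external download.  What it emulates, with the
defaults chosen once as the study conditions:

* **Library** — clones drawn locus-independently from the design
  frequencies (binary loci 0.5/0.5; 319 G:1/2 E:1/4 D:1/4; 320 each 1/4,
  from uniform draws over the degenerate codon expansions); library size
  5x the 24,576-allele space, the oversampling used when the real library
  was built.  40% of clones carry one unintended coding mutation placed
  uniformly over non-focal sense codons (clone-level, so a clone's
  off-target identity is consistent across cycles); one mutation per
  affected clone is the simplest reading of "about 40% of alleles
  affected".
* **Selection** — deterministic replicator updates under per-mutation
  selection coefficients (ln scale, per cycle).  The default coefficients
  span roughly -0.35 to +1.1 with most mutations beneficial — the
  signature of mutations that were themselves discovered by selection for
  this activity — giving cycle-1 enrichment signals of the same order as
  the real single-mutation estimates.  Noise in the selection step itself
  is neglected (recombinant pools are vastly deeper than the sequencing),
  matching the modelling assumption of the null simulation; an optional
  bottleneck is deliberately not a default.
* **Epistasis presets** — `"null"` (multiplicative truth), `"full-course"`
  (six cycles, four time points) and `"sign-epistasis"`, which injects
  eps = -0.9 on V315A x A321G so that V315A is beneficial alone
  (+0.10) but the double mutant is worse than the A321G single — the
  qualitative sign-epistasis pattern of that pair.
* **Sequencing** — reads sampled from the clone frequencies at the usable
  read totals of the real runs (t0 67,179; cycles 1/3/6: 21,622 / 31,694 /
  18,907), with 0.3% uniform per-base substitutions, 5e-4 per-base
  single-base indels (consensus reads leave indels rarer than
  mismatches), constant base quality, and random orientation.

What it does **not** emulate: 5'-UTR variation (hitchhiking, invisible to
the protein), quality-score structure, chimeras, PCR jackpotting and
context-dependent error profiles.  Passing tests on synthetic data
therefore demonstrate the correctness and calibration of the estimators
under the stated noise model, not robustness to every artifact of a real
sequencing run.

## Problem sizes in the test suite

The statistical tests run at the study's scale where it matters and at
reduced scale elsewhere: calibration and power checks use 20 replicate
experiments at the real read totals with 1000-replicate nulls; read-level
round trips use a few hundred full-length reads (curation is exact at zero
error, so depth adds nothing to that check); oracle-equivalence tests use
3-locus toy tables where brute-force per-allele aggregation is feasible.

## Known limitations

* Fitness and epistasis are background-averaged; they are not
  single-background effects, and full-haplotype fitness regression is out
  of scope (coverage per complete allele is far too low).
* Higher-order (3+-way) epistasis is not decomposed.
* The null model calibrates counting noise only; off-target load and
  selection-step stochasticity widen real nulls by an unknown amount, so
  real-data confidences are upper bounds of enthusiasm, not guarantees.
* The synthetic reference ORF is an arbitrary stop-free sequence with the
  correct focal codons; analyses that depend on the true IntI1 sequence
  context (e.g. real off-target spectra) need the real reference FASTA,
  which every curation entry point accepts.
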