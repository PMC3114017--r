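---
title: "Strand-aware ChIP-seq peak detection with permutation FDR control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-aware ChIP-seq peak detection with permutation FDR control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permpeaks)
```

## The problem

A ChIP-seq experiment sequences short reads from DNA fragments enriched by
chromatin immunoprecipitation (the IP sample) and from a background library
(the control). Genomic regions where IP coverage exceeds control coverage
beyond what chance allows are candidate protein-binding sites. Two practical
obstacles dominate the analysis:

1. **PCR duplicate artifacts.** Libraries built from small amounts of
   chromatin (typical for plant tissue) need many PCR cycles, and individual
   fragments can be amplified to very high copy numbers. A duplicate stack
   inflates coverage at one position *on one strand*. Discarding all
   duplicate reads is the blunt fix, but in libraries where 30--50% of reads
   are legitimate duplicates it throws away a third of the data and distorts
   the ranking of genuinely deep regions.
2. **Non-exchangeable coverage distributions.** IP and control differ not
   only in depth but in shape: IP reads concentrate in (true and false
   positive) enriched regions. A scaling factor alone does not make the two
   samples comparable.

`permpeaks` addresses the first with a strand-minimum counting rule and the
second with moment matching, and calibrates significance by label
permutation rather than a parametric null.

## The procedure

**1. Extension and strand-minimum counting.** Each uniquely mapped read is
virtually extended from its 5' end to the average fragment length $w$
(user-supplied, a property of the library; there is deliberately no
default). With $f_i$ and $r_i$ the number of extended forward- and
reverse-strand reads overlapping position $i$, the default per-position hit
count is $x_i = \min(f_i, r_i)$. Fragments from a real binding site are
sequenced from either end with equal probability, so genuine sites gain
support on both strands, while a one-strand duplicate stack cannot raise
$\min(f_i, r_i)$ above the opposite strand's level --- the artifact is
neutralized without deleting any reads. `forward`, `reverse` and `sum`
modes are available; `sum` is our reading of "merge the information of both
strands", for which no formula is fixed by convention.

**2. Depth scaling.** Counts become hits per $\theta$ million reads,
$y_i = x_i\,\theta\,10^6 / T$, with $T$ the sample's mapped-read total
($\theta = 1$ by default).

**3. Moment matching.** The scaled IP track is mapped affinely onto the
control's first two moments:
$y'_i = (y_i - \bar y_{IP})\,\sigma_C/\sigma_{IP} + \bar y_C$.
Moments are population (n-denominator) statistics over *every* position of
every analyzed chromosome, zeros included, computed jointly across
chromosomes --- one global normalization per sample. The n- versus
(n−1)-denominator choice is immaterial at genome scale but is fixed so that
results are exactly reproducible.

**4. Background floor.** Control coverage is not uniform; in its deserts no
coverage estimate exists and ratios would explode. The floor is
$\beta$: the raw IP background level $c$ (by default the mean IP count over
the $n_0$ positions with nonzero IP coverage, $c = \sum_i x_i / n_0$;
settable by the user) passed through the same scaling and moment-matching
transforms as any other IP value. Control values below $\beta$ are raised
to $\beta$. We apply the floor to the control track, which is where a floor
is mathematically needed (it is the test's denominator/rate).

**5. Scoring.** Per nucleotide, either the **ratio** (default)
$t_i = \max(y'_i, 0) / y^{floor}_i$, or the **Poisson** score
$t_i = -\log_{10} P(Y \ge \lceil \max(y'_i,0) \rceil)$ with
$Y \sim \mathrm{Poisson}(y^{floor}_i)$, computed on the log scale so deep
positions do not underflow. Negative moment-matched IP values are
normalization artifacts and clamp to zero. The ceiling (rather than
rounding) of the continuous IP value is conservative: it can only shrink
the tail probability's significance. The ratio score travels better across
experiments because it does not grow with sequencing depth the way a tail
probability does.

**6. Candidate regions.** Maximal runs with $t_i$ strictly above a cutoff
(default 2; ties at the cutoff excluded) become candidate peaks; runs on
one chromosome separated by fewer than 100 bp (exclusive edge-to-edge gap)
are merged transitively. A region's test statistic is its maximum score;
the leftmost maximizing position is kept as the summit. No default cutoff
is canonical --- it trades candidate granularity against permutation cost,
and the FDR step re-calibrates significance afterwards --- so all validation
work here states it explicitly.

**7. Permutation FDR.** Reads are pooled and the control/IP labels randomly
re-dealt (original sample sizes preserved --- permuting labels fixes the
label counts and keeps the depth structure). Each permuted dataset goes
through steps 1--6 with identical parameters, yielding null region
max-scores. For a candidate threshold $t$ among the observed max-scores,
$\widehat{FDR}(t) = \frac{\text{mean}_p\,\#\{\text{null scores} \ge t\}}
{\#\{\text{observed scores} \ge t\}}$, capped at 1 and monotonized by a
cumulative minimum so a higher threshold never has a higher estimated FDR;
the reported threshold is the smallest observed score whose monotonized
estimate meets the requested level. We average exceedance counts per
permutation rather than pooling all null scores; the two are equivalent in
expectation, and averaging keeps each permutation's contribution equal when
permutations yield different region counts. If no threshold qualifies, the
threshold is $+\infty$ and nothing is declared significant --- an honest
outcome on hopeless data.

## What the simulator emulates, and what it does not

`simulate_chipseq()` provides ground truth for every statistical claim the
package makes about itself. Both samples draw `depth` background fragments
uniformly over the genome. The IP sample adds, for each planted region,
fragments whose starts are uniform over the region widened leftwards by one
fragment length, at $(e-1)$ times the background start density, so expected
fragment coverage is uniformly $e$-fold across the region. Every fragment
yields one read from a uniformly chosen end (left end $\to$ `+`, right end
$\to$ `-`), which reproduces the two-strand flanking pattern that the
strand-minimum rule rewards; a uniform-strand model would under-power
minimum-mode analysis and misrepresent real libraries. Peaks are placed one
per equal-width chromosome bin, clear of bin and chromosome edges by a
half-width plus a fragment length, so truth regions are in-bounds and well
separated.

Defaults mirror the validation conditions used throughout:
200 kb genome, 20 peaks of half-width 150 bp, 8-fold enrichment,
50,000 background fragments per sample, 150 bp fragments, 36 bp reads
(36 bp matches the Illumina read length of the libraries that motivated the
method; half-width 150 bp gives binding regions of ~300 bp, typical for a
transcription-factor ChIP). At these settings background fragment coverage
is ~37x, comfortably above the ~20x where minimum-mode counting is
well-behaved.

The simulator does **not** model mappability, sequencing error, GC bias,
fragment-length dispersion, or biological replicate structure. Passing
tests on it demonstrate the statistical machinery (normalization, scoring,
permutation calibration, duplicate robustness) under a clean generative
model --- not performance on any particular organism's chromatin.

`inject_pcr_duplicates()` reproduces the in-silico amplification protocol
used to stress peak callers (2,000 random distinct reads amplified 100-fold
each and appended), and `inject_onesided_stack()` plants the worst-case
single-strand artifact directly.

## Numerical and design choices

* Coordinates are 1-based closed internally; BED output converts to
  0-based half-open; wig output is 1-based `variableStep span=1`.
* `pos` is the leftmost forward-strand coordinate for both strands (the
  convention of SOAP/Bowtie-class mappers); a `-` read's 5' end is
  `pos + read_length - 1`.
* The duplicate key is (chrom, pos, strand, read length): reads of
  different lengths at one position are distinct molecules.
* Multireads (`n_loc > 1`) are dropped by default but retained behind
  `unique_only = FALSE`, since the input format records multiplicity.
* Extension is clipped at chromosome edges (neither wrapped nor
  discarded), keeping telomere-proximal reads at reduced weight.
* Reads longer than the fragment length keep their own footprint, with a
  warning rather than an error.
* Score ties at the region maximum resolve to the leftmost position;
  regions at exactly the cutoff are excluded (strict inequality).
* Degenerate permutations (a constant-coverage pseudo-sample, possible on
  toy inputs) are recorded as zero null regions with a warning rather than
  aborting the null.
* A region-free observed analysis skips permutation entirely: there is
  nothing to test.
* All randomness flows from a single user seed; permutation $p$ uses
  `seed + p`, and the replicate study uses `seed + 10000 i` so replicate
  and permutation streams cannot collide. Re-running any analysis with the
  same inputs and seed is byte-identical.

## Validation summary

The test suite regenerates everything it asserts. The headline check runs
20 independent simulations at the default conditions above (50
permutations, ratio test, cutoff 2, target FDR 0.05), scores a significant
region as a false discovery when no truth region lies within 250 bp, and
requires the mean realized false-discovery proportion to stay within the
target plus two Monte-Carlo standard errors --- while also requiring >90%
of planted peaks recovered, so the control is not vacuous.
`scripts/acceptance.R` recomputes exactly this quantity from scratch at any
seed. Supporting suites check the coverage engine against a per-position
interval-stabbing oracle, the FDR threshold against a double-loop
enumeration, moment matching to 1e-9 relative precision, exact
significant-region invariance under a 1,000-copy one-strand stack, and the
indistinguishability (two-sample KS, $\alpha = 0.01$) of observed and
permuted region scores on signal-free data. Problem sizes (50--200 kb
genomes, 10--50k reads) keep the full suite in the minutes range on one
CPU; all properties tested are size-stable.

## Known limitations

* Single global fragment length; no paired-end fragment inference.
* No local background model (deliberately --- the moment-matched global
  normalization plus the permutation null is the method), no sub-peak
  summit deconvolution, no motif analysis.
* Permutation cost scales linearly in `n_perm` times the full pipeline;
  on mammalian-scale genomes the C-level pileup dominates and `n_perm`
  in the tens is the practical regime.
* The dense per-position representation favors clarity; genomes are held
  as one numeric vector per chromosome per track.
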