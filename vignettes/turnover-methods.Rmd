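---
title: "Quantifying histone turnover from pulse-chase ChIP time courses"
author: "pulseTI package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying histone turnover from pulse-chase ChIP time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulseTI)
```

# The measurement and the model

In a pulse-chase histone labeling experiment a self-labeling enzyme tag on
a histone (for example H3.3) is pulse-biotinylated, and the labeled
nucleosome pool is pulled down and sequenced at successive chase times
(here 0, 3, 6 and 12 hours). Wherever nucleosomes are disrupted and
rebuilt with new, unlabeled histones, the labeled signal decays; the decay
speed is the local histone turnover rate. The deliverable of this package
is the per-bin **turnover index (TI)** and everything the index feeds:
highest-turnover region discovery with a resampling FDR, differential
turnover between two cell states, negative-binomial peak calling for
factor-target definition, and an MNase-titration accessibility score
(MACC) to cross-validate turnover against chromatin openness.

## Turnover index

The genome is partitioned into fixed bins (1 kb by default; 300 bp is
supported). Each library is reduced to fragment midpoints per bin,
normalized to reads per million (RPM; spike-in reads are excluded from the
denominator), and input subtracted with a floor at zero. For a bin with
input-subtracted signal $y_t$ at chase times $t \in \{0,3,6,12\}$ h,

$$\mathrm{TI} = -\,\hat\beta \,\bigl(1 - p_{\mathrm{Kendall}}\bigr),$$

where $\hat\beta$ is the ordinary least-squares slope of $y_t$ on $t$ and
$p_{\mathrm{Kendall}}$ is the two-sided Kendall rank-correlation p-value
of the same four points. The $(1-p)$ factor shrinks poorly supported
slopes toward zero — a deliberately conservative estimate — and the sign
flip makes fast turnover positive. Replicate TI tracks are averaged
bin-wise for downstream use.

Two properties are worth keeping in mind when reading TI tracks:

* **TI is relative, not absolute.** RPM renormalization divides every
  library by its own (decaying) total, so a bin's TI reflects its decay
  relative to the enrichment-weighted average of the whole labeled pool.
  Regions turning over more slowly than the pool average acquire
  *negative* TI; regions near the average sit at zero. TI orders loci
  within a genome; it is not a half-life.
* **The weight is discrete.** With four time points the exact Kendall
  p-value takes one of a small set of values (see below), so the TI of a
  null bin is a mixture over those weights. This matters for the
  differential test (see *Known limitations*).

## Exact Kendall trend p-value

Chase times are strictly increasing and untied, so under the null every
ordering of the observed values is equally likely. For $n \le 8$ time
points the implementation enumerates all $n!$ orderings ($4! = 24$ here)
of the observed values, computes the Kendall numerator
$S=\sum_{i<j}\mathrm{sign}(y_j-y_i)$ for each, and reports
$\Pr(|S| \ge |S_{\mathrm{obs}}|)$. Ties are handled exactly: the tie
multiset is invariant under permutation, so $|S|$ is equivalent to
$|\tau_b|$. Beyond $n = 8$ a tie-corrected normal approximation is used.
An all-tied (constant or all-zero) series gets $p = 1$ and TI $= 0$;
all-zero bins are additionally flagged in a coverage mask rather than
dropped, so genome-wide tracks stay aligned.

## Spike-in consistency scaling

A fixed amount of exogenous 150 bp spike-in DNA per library makes the
genomic:spike read ratio track the amount of labeled material recovered:
`spikeInScaling()` reports each time point's ratio relative to 0 hr and a
monotone-decay QC flag. Following the source procedure, spike scaling is a
*consistency check only*; TI itself is computed on input-subtracted RPM,
not on spike-rescaled values.

# Region discovery and the resampling FDR

`smoothTI()` takes a centered moving average (default three bins) within
each chromosome so an isolated noisy bin cannot rank as a turnover
hotspot; `topRegions()` then removes blacklisted bins (the reproducible
stand-in for manual repeat removal) and keeps the `n = 1000` highest bins,
breaking ties by genomic position. The FDR of that selection is estimated
by resampling: the threshold is the smallest TI in the selected set; 1000
covered bins are drawn at random 100 times; each trial records the
fraction above threshold, and the *maximum* across trials is reported —
again deliberately conservative. On a pure-null genome the expected trial
fraction is the mass above the 1000th order statistic,
$(n-1)/N \approx 0.01$ for $N = 10^5$ bins, and the max statistic inflates
that to roughly 0.02. Note the statistic is pivotal: because the threshold
is itself the $n$-th order statistic, exactly $n-1$ bins exceed it
whatever the signal looks like, so the FDR mainly reflects genome size and
selection size, not signal strength.

Feature overrepresentation is the log2 ratio of the proportion of selected
regions overlapping an annotation against the proportion of all genome
bins overlapping it; zero proportions give a missing ratio, never zero.
Proximity of unannotated regions to genes is tested by permutation:
query regions are re-placed uniformly (lengths preserved), "within 50 kb"
is measured edge-to-edge, and the p-value uses the add-one estimator
$(1+\#\{\mathrm{perm} \ge \mathrm{obs}\})/(1+n_{\mathrm{perm}})$, which can
never be exactly zero. Uniform placement deliberately omits GC/isochore
matching — it is a simplification, stated rather than hidden.

# Differential turnover

For two conditions with replicate TI tracks, `moderatedTest()` computes
the difference of replicate means and a moderated t statistic: the pooled
per-bin variance ($d = n_A + n_B - 2$ df) is shrunk toward a global prior
$s_0^2$ with prior df $d_0$, both estimated by method of moments on
$\log s^2$ (matching its mean and variance under the scaled-F model; the
estimator agrees with the standard limma implementation on well-behaved
data, which the test suite checks). The p-value is two-sided from a t
distribution with $d_0 + d$ df. `selectChanged()` applies the joint rule:
a bin is changed when its |difference| reaches the 0.975 quantile *and*
its p-value is at most 0.01.

Two design points deserve explanation:

* **Quantile pool.** The difference quantile is computed over *all* bins
  by default (uncovered bins contribute their zero difference), while only
  covered bins can be selected and only covered bins enter the
  hyperparameter fit. Restricting the quantile to covered bins would
  shrink the selection budget from 2.5% of the genome to 2.5% of the
  covered subset, which makes the rule needlessly stingy exactly when
  input subtraction masks a large background fraction. A
  `quantilePool = "covered"` switch restores the restricted behavior.
* **Absolute vs signed quantile.** The source procedure is ambiguous
  between a two-tailed quantile of |difference| and separate upper/lower
  quantiles of the signed difference. Absolute-value mode is the default;
  `mode = "signed"` provides the other reading.

# Negative-binomial window peak caller

`windowScan()` tiles each chromosome with 1 kb windows stepped by 200 bp
and tests the ChIP fragment count against a negative binomial whose mean
is the *local* input level: a centered 5-window (5 kb) running mean of
input counts, scaled by the library-size ratio and floored at one read.
The wide background window matters — estimating the null mean from the
single matched input window injects the input's own counting noise into
the mean estimate and breaks calibration (we measured a three-fold
inflation of the nominal significant fraction). The NB size parameter was
a by-eye choice in the source procedure; the reproducible default here
(`nbSize = "auto"`) fits it by method of moments on the chip-minus-scaled-
input residuals in two passes, excluding windows that look enriched at a
loose threshold ($p \le 10^{-3}$) before the final fit so that genuine
peaks cannot inflate the null variance. Significant windows are unioned
(so overlapping stepped windows never double-report) and merged across
gaps of at most 1 kb; joint targets of several factors (the Polycomb
target definition) are the base pairs covered by every supplied peak set.

# MNase accessibility (MACC)

Chromatin digested with a geometric MNase titration (1, 4, 16, 64 U)
releases accessible loci at gentle digestion and protects closed ones.
`computeMacc()` fits, per bin, an OLS line of RPM signal on
$\log_2(\mathrm{units})$ and reports minus the slope, so accessible
regions score positive. The exact formulation is delegated by the source
to its companion method; the linear-in-$\log_2$ definition here is this
package's explicit convention (no GC correction; a hook is left in the
arguments). Bins with fewer than three covered titration points get `NA`.
`correlateTracks()` compares turnover and accessibility by per-region
means — at enhancers the two independent measurements should and do
correlate.

# The synthetic world

`buildGenome()` + the simulators give every stage a no-download test
surface with known truth. Labeled signal in bin $b$ at chase time $t$ is
proportional to $e_b\,\exp(-k_b t)$; counts are negative binomial
(size 10 by default — biological pulldown libraries are strongly
overdispersed); the spike-in contig receives a constant expected read
count so the genomic:spike ratio decays with the pool; the input is flat.
The ESC-like preset (`escLikeSpecs()`) states a world chosen once, on
biological grounds, and then frozen:

* **Decay rates include replication dilution.** Every class rate carries
  a shared floor of about $\ln 2 / 12\ \mathrm{h^{-1}}$ — labeled
  histones are diluted two-fold per ~12 h ESC cell cycle — with
  locus-specific turnover on top: background 0.06, heterochromatin 0.055,
  Polycomb targets 0.09, TTS 0.10, active TSS 0.12, enhancers 0.18,
  super-enhancers 0.30 per hour. Because TI is relative to the pool
  average, the class *ordering* (super-enhancer > enhancer > TSS >
  Polycomb target > background) is only a property of the world when
  rates share this common floor and regulatory classes occupy a
  realistically small genome fraction (~10% here); a world of isolated
  fast islands on an undecaying background would put enriched-but-slow
  classes *below* background.
* **Within-class spread and coupling.** Each region's rate is jittered
  log-normally (mean-preserving, default `rateJitterSd = 0.35` in log
  units) around its class rate, and its accessibility slope scales with
  the realized rate (`coupleAccessibility`), emulating the observed
  coupling of turnover and openness at enhancers. Without within-class
  spread, a within-class turnover–accessibility correlation would be
  undefined noise.
* **Accessibility truth lives on the titration's linear scale.** The
  response of signal to $\log_2$ units is exponential and saturates for
  slopes beyond ~0.4, so class slopes (0–0.15) plus a continuous per-bin
  jitter (sd 0.03) keep the truth inside the range where the linear MACC
  estimator is faithful. MNase libraries are technical re-digestions of
  one chromatin preparation, so their counts are modeled near-Poisson
  (NB size 1000), unlike the biological time-course libraries.
* **Replicates** differ by one mean-preserving lognormal factor per bin
  (sd 0.15), a stand-in for true replicate structure — it reproduces the
  qualitative inter-replicate spread of real data but no batch or
  position-specific effects.

What a green synthetic test does *not* establish: mappability and GC
artifacts, fragment-length effects, copy-number variation, and aligner
behavior are all outside the generator; real data will be noisier in ways
the mask and blacklist arguments exist to absorb.

# Numerical choices

* Coordinates are 0-based half-open in all files (BED convention) and
  1-based closed inside R (GenomicRanges convention); conversions happen
  only at I/O boundaries.
* Fragments are assigned to bins by midpoint — exactly one bin per
  fragment, conserving tag counts.
* Anomalous-position filtering (z > 7 on per-position tag counts)
  computes its statistics over positions carrying at least one tag;
  over all genomic positions the sd would collapse and remove everything.
  Zero variance across positions removes nothing, with a warning.
* Input subtraction floors at zero: regression on negative enrichment is
  meaningless for a decay index.
* Ties in top-region ranking break by (chromosome, start) so selections
  are reproducible; the add-one permutation p-value is never zero; the
  trigamma inversion in the moderated test uses Newton iterations with
  the standard asymptotic fallbacks.
* All simulators are pure functions of (specification, seed), and the
  pipeline fans one user seed out into fixed per-stage child seeds.

# Known limitations

* **Null TI is not Gaussian.** The discrete Kendall weight correlated
  with the slope magnitude makes replicate TI leptokurtic; under a strict
  null the moderated-t p-values are measurably *conservative* (about
  0.0016 of bins at nominal p < 0.01). A genome-wide KS uniformity test
  with tens of thousands of bins will reject this deviation even though
  it can only suppress, never inflate, false positives.
* **The joint selection rule is power-limited at three replicates.**
  The maximal slope difference between conditions is bounded (the 0 hr
  signal can at most fall to zero within the chase), while the
  per-replicate slope noise carries the negative binomial floor
  $\mathrm{CV} \ge 1/\sqrt{\mathrm{size}}$; at the default dispersion the
  attainable moderated t saturates near the p = 0.01 cutoff for 3 vs 3
  replicates, so recall of even dramatic turnover changes is ~0.4-0.5.
  Deeper sequencing does not help (the floor is dispersion, not depth);
  more replicates or tamer libraries would.
* **The resampling FDR is pivotal** (see above): it certifies the
  selection size against the genome size, and should not be read as a
  measure of signal quality.
* TI is a relative index; cross-experiment comparisons need matched
  designs. The spike-in scaling is reported for QC and is intentionally
  not folded into TI.

# A worked example

```{r demo, eval = FALSE}
library(pulseTI)
man <- synthDemo(seed = 7, outDir = "synthdemo")
man$stages$regions$fdr        # resampling FDR of the top-TI selection
man$stages$differential$counts  # changed bins per direction
man$stages$accessibility$tiMaccEnhancerR  # TI-MACC correlation at enhancers
```

The same stages run on user data from BED fragment files through
`runPipeline()` with a `samples` config; see `?runPipeline`.
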