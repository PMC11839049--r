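---
title: "Models and methods behind hpbody"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hpbody}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

hpbody implements four quantitative analyses used to characterize
bacterial ribonucleoprotein condensates (Hfq–polyphosphate bodies formed
in nitrogen-starved *E. coli*) and their consequences for RNA
metabolism:

1. **Condensate partitioning from single-particle tracking** — where do
   tracked molecules live: in condensates, on the nucleoid, or free in
   the cytosol?
2. **Spike-in-anchored transcript half-lives** — how fast does each
   transcript decay after transcription shut-off, and how does a
   genotype change that?
3. **Untemplated poly(A) tail lengths** — how long are the 3′-terminal
   adenosine runs on each gene's transcripts, modelled per gene across
   genotype-by-condition cells?
4. **GO-term-set overlap** — does the condensate's protein inventory
   share functional annotations with eukaryotic P-bodies and stress
   granules beyond chance?

Every analysis comes with a seeded synthetic-data generator that exports
its ground truth, so the full pipeline is testable without any raw
imaging or sequencing data.

## 1. Condensate partitioning

### The squared-displacement CDF model

Trajectories of single molecules imaged at frame interval $\tau$
(default 0.02 s, i.e. 50 Hz) are reduced to per-step squared
displacements $r^2$ between consecutive frames, pooled over all
trajectories with at least 4 frames. For a population mixing $k$
diffusive states, the cumulative distribution is

$$P(r^2, \tau) = 1 - \sum_{i=1}^{k} \alpha_i
  \exp\!\left(-\frac{r^2}{\tfrac{8}{3} D_i \tau}\right),
  \qquad \sum_i \alpha_i = 1 .$$

The $8/3$ factor is the motion-blur correction: when the camera exposes
for the whole frame interval, each localization is an average over the
exposure, and the mean squared displacement between consecutive
*averaged* positions is $(8/3)D\tau$ per two dimensions rather than
$4D\tau$. The simulator's `physical_blur` mode demonstrates this: it
integrates a fine-grained Brownian path, averages positions over each
exposure, and the resulting displacement law converges to the CDF above.
The default `model_exact` mode draws $r^2$ directly from that law,
giving exact oracles for the fitting code.

### Fitting

The fit minimizes the sum of squared deviations between the empirical
CDF (evaluated at all sorted unique $r^2$ values) and the model, using
Levenberg–Marquardt on unconstrained parameters: log diffusion
coefficients and stick-breaking logits for the weights, which keeps the
weights on the simplex without explicit constraints. Eight deterministic
starts are generated from quantiles of the implied single-state
coefficients $r^2/(\tfrac{8}{3}\tau)$; the best final objective wins.
Label switching is resolved by sorting $D$ ascending after fitting.
Degenerate pools (empty, or all values identical) are rejected with an
error rather than fitted.

### From trajectories to partition fractions

Foci are detected on the frame-summed composite image with a
scale-normalized multiscale Laplacian-of-Gaussian detector
(`min_sigma = 3`, `max_sigma = 5` pixels, response threshold 0.1 on the
min–max-normalized image; blob radius $\sqrt{2}\sigma$). The composite
is normalized to $[0,1]$ before filtering so the threshold is
scale-free. Candidate foci are kept only when supported by at least ten
trajectories of at least ten frames, each with at least 70 % of its
localizations inside the focus — all thresholds boundary-inclusive.
Trajectories are then labelled `In` (complete overlap with a focus for
their entire duration), `In/out` (25 % inclusive to anything short of
complete), or `Out` (below 25 %); overlap fractions strictly between
0.99 and 1 are deliberately `In/out`, since `In` requires complete
overlap.

The free fraction is the weight of the fastest state of a three-state
fit to all pooled displacements, sanity-checked against
$D_3 > 1\ \mu m^2/s$ (a warning, not an error — it is an assumption
about the data, not a mathematical constraint). The condensate fraction
scales the non-free weight of a three-state fit restricted to the
`In` + `In/out` subset by that subset's share of pooled steps:

$$F_{\mathrm{condensate}} =
  \frac{N_{In} + N_{In/out}}{N_{\mathrm{total\ steps}}}
  \,(\alpha_1 + \alpha_2),
  \qquad
  F_{\mathrm{nucleoid}} = 1 - F_{\mathrm{free}} - F_{\mathrm{condensate}}.$$

$N_{\mathrm{total\ steps}}$ counts pooled steps from *all* classes
(an interpretation; the subset-share then has a clean step-fraction
meaning). The nucleoid fraction is defined purely by subtraction and is
reported unclamped, with a flag, if negative. FRAP recovery traces are
fitted to the one-phase association curve
$y(t) = y_0 + (\mathrm{plateau} - y_0)(1 - e^{-kt})$ with
$t_{1/2} = \ln 2 / k$ and a residual-bootstrap confidence interval.

### What the trajectory generator does and does not emulate

Each simulated trajectory carries one latent state for its whole life —
the population-level mixture the CDF model assumes. State 1 (slowest)
starts inside the condensate and stays confined; all other states start
outside and are excluded from it. In `model_exact` mode invalid steps
are resolved by redrawing the step *direction*, which leaves the
marginal $r^2$ law untouched; confinement of the slowest state is the
one unavoidable distortion, and it is mild because the per-step
root-mean-square displacement (≈ 0.06 μm at the default
$D_1 = 0.05\ \mu m^2/s$) is small against the condensate radius
(0.35 μm). Track lengths are 1 + Geometric with mean 10 frames,
matching the typical median track length of this kind of experiment;
defaults place ≈ 1500 trajectories in a 3 × 1 μm field, the
per-replicate scale of the real experiments, with state weights
(0.45, 0.30, 0.25) for condensate/nucleoid/free. Localization noise
defaults to zero (so `model_exact` oracles stay exact); it can be
switched on, with the caveat that noise inflates the apparent slow-state
coefficient. The generator does not emulate camera noise, photophysics
(blinking, bleaching), state switching within a track, localization or
tracking errors, or drift — passing tests therefore validate the
estimator under the fitted model's own assumptions, not robustness to
those artifacts.

## 2. Transcript half-lives from rifampicin chases

Counts from a transcription shut-off time course (default sampling 0,
10, 30, 60 minutes) are normalized in two steps: per-sample relative
abundance (count over sample total), then genomic features divided by
the median relative abundance of the ERCC spike-ins in that sample,
considering only spike-ins above a relative abundance of $5\times10^{-4}$.
Because the spike-ins are added per cell, this anchors a *per-cell*
abundance scale in which global decay is visible — unlike
total-count normalization, which would silently renormalize it away.
The construction is exactly invariant to uniform rescaling of any
sample's raw counts.

Each gene's time course is fitted to $y = a\,e^{-t/b}$ by bounded
least squares, both parameters non-negative, initialized at
$a = 0.001$, $b = 20$ minutes. The least-squares surface has a spurious
minimum at $b \to 0$ (fit the $t=0$ point, abandon the rest) that pure
Levenberg–Marquardt can reach from a near-zero baseline start, so the
implementation also tries a max-abundance start and a log-linear-slope
start and keeps the best residual sum — the reported optimum, not the
path to it, is what the model prescribes. Decay constants are
*measurable* when $5 \le b \le 65$ minutes; values above 65 are reported
as-is with the flag unset (clamping is a plotting concern). Replicate
time courses are fitted jointly per genotype by default (all points in
one objective); per-replicate fitting is available.

Genotype comparisons use the four-category scheme: stable in one
genotype and unstable in the other when $\tau > 65$ min on one side and
$\tau < 55$ min on the other; otherwise, when both decay measurably
($\tau < 65$), a directional call requires an increase of at least
10 minutes; everything else — including unconverged fits — is
`no_call`. Gene-set shifts compare per-gene $\Delta\tau = \tau_{WT} -
\tau_{ppk}$ inside versus outside the set: the percent difference of
medians and a two-sided Wilcoxon rank-sum p-value (normal approximation
with tie correction).

The count generator draws Poisson samples around
$\mathrm{scale}\cdot a_g e^{-t/b_g}$ with constant-abundance spike-ins,
at an expected depth of $10^6$ reads per sample at $t=0$. The default
spike-in ladder is placed well above the $5\times10^{-4}$ filter at
every timepoint: a ladder that straddles the filter changes *which*
spike-ins pass as totals fall over the chase, letting the median drift
and biasing every fitted decay constant — a confound a real spike-in
design avoids by construction, and one worth knowing about when
analyzing real data.

## 3. Untemplated poly(A) tails

With the 3′-end library chemistry modelled here, the untemplated tail
is read first, so it appears as a run of `T` bases at the 5′ end of the
read as sequenced, and the read aligns antisense to its gene. The tail
caller counts the maximal terminal run of `T` (the likeliest reading of
a count of "T bases in the read", since the tail is soft-clipped under
local alignment); a total-T mode ships for sensitivity analysis, and the
orientation convention is configurable because chemistry differs between
protocols. A read is assigned to a gene when its tail-anchoring
coordinate — the aligned end adjacent to the terminal run — falls in the
gene's 3′ window, from 50 bp before to 250 bp after the gene end
(0-based half-open, strand-aware, 300 bp wide). Reads matching several
genes' windows are counted for each of them: in operons, a poly(A)
state is genuinely shared between genes, and assignment to all matches
makes that explicit instead of picking a winner.

Per gene, tail lengths $k$ across all samples follow a zero-inflated
negative binomial,

$$P(k) = \pi\,\mathbb{1}[k=0] +
  (1-\pi)\,\mathrm{NB}(k;\, \mu_c,\, \theta),$$

with one log-link mean per genotype-by-condition cell (four degrees of
freedom in the standard 2 × 2 design with four replicates per cell), and
a single zero-inflation rate and a single overdispersion per gene. The
likelihood is maximized by BFGS on (log means, logit $\pi$, log
$\theta$) with a 500-iteration cap. Because the logit map flattens as
$\pi \to 0$, a profile refit with $\pi$ fixed at zero (a plain negative
binomial) is always run too and adopted when it is at least as good —
this guarantees the nested-model property that zero-inflation can never
fit worse than its own special case. All-zero genes are flagged
degenerate ($\pi \to 1$) rather than fitted; genes with reads in fewer
than two cells are flagged unfit. Wald standard errors come from the
inverted observed information.

Summaries report, per gene and condition, the estimated mean tail
length $(1-\hat\pi)\hat\mu_c$, the genotype difference, a Wald test on
the corresponding log-mean contrast, and Benjamini–Hochberg adjustment
across genes within each condition (the adjustment choice is this
package's; a per-contrast Wald test is the natural companion of the
log-link parameterization). Cumulative distributions of estimated means
over genes are emitted per cell.

The read generator places anchors uniformly in each gene's window,
truncates tails so at least 10 template bases remain alignable, and
warns when same-strand windows overlap. It does not emulate adapter/UMI
chemistry, alignment errors, or rRNA contamination.

## 4. GO-term-set overlap

Term sets are plain unions of per-protein GO annotations — no ontology
propagation; the comparison is between flat annotation sets. Overlap
statistics are the pairwise and three-way intersection sizes and the
fraction of condensate-set terms shared with the P-body or
stress-granule sets. Significance comes from a permutation test that
resamples *proteins*: each of the (default 1000) permutations draws an
equally sized protein set uniformly without replacement from the
declared universe, rebuilds the term union, and recomputes all three
overlap counts from the same draw. P-values use the add-one estimator
$p = (1 + \#\{\mathrm{null} \ge \mathrm{observed}\})/(n_{\mathrm{perm}}+1)$,
one-sided for enrichment; it never returns zero and is floor-bounded at
$1/(n_{\mathrm{perm}}+1)$. Universe proteins without annotations remain
drawable and contribute empty term sets.

The universe generator plants a target overlap fraction exactly: the
condensate set's term union is assembled from granule-associated and
granule-free vocabulary in the planted proportion. Two sizing decisions
make the null meaningful: the granule vocabulary is a quarter of the
term space (so random protein sets share about a quarter of their
terms with the granule sets), and the planted union is sized like a
random protein set's expected union, so permutation statistics compare
*composition* rather than set size.

## Numerical choices, at a glance

- CDF fit objective: least squares on the empirical CDF at sorted
  unique values; LM with 8 deterministic multistarts; stick-breaking
  weights; $D$ sorted ascending.
- Decay fit: `nls.lm` bounded below at zero, prescribed start plus two
  fallback starts, best residual sum kept.
- ZINB: BFGS, relative tolerance $10^{-12}$, up to 3 restarts, $\pi=0$
  profile refit for the boundary; 500-iteration cap throughout.
- Ties in the rank-sum test: normal approximation with continuity and
  tie correction (`exact = FALSE`).
- All generators route randomness through an internal seed guard: a
  given seed yields byte-identical output and the caller's RNG stream
  is left untouched.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use one imaging replicate of
1500 trajectories for the partition pipeline, $10^5$ pooled steps for
displacement-law checks, 500 genes at depth $10^6$ for decay recovery,
2000 reads per cell for ZINB recovery, and a 500-protein universe with
1000 permutations for the overlap test — each the scale of one
replicate of the corresponding real experiment.

## Known limitations

- The partition estimate inherits the model's assumption of no
  within-track state switching; real molecules exchanging between
  nucleoid and cytosol on the frame timescale would blur the weights.
- Focus detection runs on the frame-summed composite, so condensates
  must persist across the movie; transient foci are (by design)
  filtered out by the trajectory-support rule.
- Decay constants above the 65-minute window are reported but carry
  little information at the default 0–60-minute sampling; treat them as
  "effectively non-decaying", not as estimates.
- The ZINB Wald tests rely on the observed information at the optimum;
  for genes with few positive counts the adjusted p-values should be
  read with the usual small-sample caution.
- GO overlap compares flat term sets; annotation-depth differences
  between organisms are not modelled.
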