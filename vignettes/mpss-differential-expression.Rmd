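---
title: "MPSS differential expression: model, procedure and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MPSS differential expression: model, procedure and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpssde)
```

# The measurement model

Massively parallel signature sequencing (MPSS) counts, for each transcript,
a short signature: the DpnII fragment (anchored at a `GATC` site) closest to
the poly(A) tail, extended to 21–22 nt. A library is therefore a multinomial
sample over the signature universe, with per-tag probability proportional to
transcript abundance, and expression is reported in tags per million (tpm):

$$\mathrm{tpm} = 10^6 \times \frac{\text{tag count}}{\text{library total}}.$$

Each condition is sequenced in two alternative reaction series ("2-step" and
"3-step" steppers), each with technical replicates. Steppers are treated as
exchangeable replicate groups: per tag, the replicate means of the two
series are compared, the series with the higher mean is selected (ties go
to 2-step, a deterministic choice the original protocol leaves open), and
that series' replicate mean — converted to tpm with that series' mean
library total — represents the tag.

Tags are mapped back to an annotated transcript database by exact string
match and classified:

| class | strand | location |
|---|---|---|
| 1 | sense | 3′-most signature upstream of the annotated end |
| 2 | sense | internal |
| 3 | sense | 3′-flank window (annotated end + `flank_bp`, default 1000) |
| 4 | antisense | transcript body |
| 5 | antisense | 3′-flank window |

plus `unannotated` (unique hit in decoy/background sequence), `multi`
(several distinct loci) and `unmapped`. The 1–5 rule table is this
package's concretisation of a scheme the MPSS literature cites rather than
restates; the exact boundaries should be read as an interpretation. Multi-
mapping is resolved at the locus level: two isoforms of the same gene
sharing a signature still map uniquely to that gene, with the best (lowest)
class winning. Downstream analysis conventionally restricts itself to
classes 1–5, and the expression filter keeps tags with tpm strictly above
3 in at least one condition (whether the published filter was strict is
unstated; `strict = FALSE` gives the inclusive variant).

# The six-step differential-expression procedure

For counts $x_1, x_2$ in libraries of size $n_1, n_2$, the two-library
proportion Z-test uses the pooled statistic

$$z = \frac{\hat p_1 - \hat p_2}
           {\sqrt{\hat p_0 (1-\hat p_0)\left(\tfrac1{n_1}+\tfrac1{n_2}\right)}},
\qquad \hat p_0 = \frac{x_1+x_2}{n_1+n_2},$$

with a two-sided normal p-value; a degenerate pooled proportion (0 or 1)
yields $z=0,\ p=1$. Significance is *not* taken from the normal tail but
from an empirical null:

1. within each condition, technical replicates are compared pairwise with
   the same Z-test (pairs are formed within a stepper series; leftover
   single replicates are paired across series);
2. each p-value is transformed back to a Z value through the upper-tail
   standard-normal quantile $\Phi^{-1}(1-P)$;
3. the Z values of all within-condition comparisons are pooled into the
   null distribution;
4. the observed between-condition Z values are computed from the
   replicate-mean counts and replicate-mean totals (rounded half-up to
   integers — the procedure's description feeds "mean tag counts" to a
   count test without stating a rounding rule);
5. each tag's empirical tail probability is the fraction of null values at
   least as extreme, with a plus-one correction
   $p_{\mathrm{emp}} = (1 + \#\,\text{extreme})/(N_{\mathrm{null}} + 1)$
   so it is never zero;
6. the false discovery rate combines $p_{\mathrm{emp}}$ with the Storey
   null-proportion estimate
   $\hat\pi_0 = \min\!\left(1,\ 2\,\#\{p > 0.5\}/m\right)$,
   and tags with FDR < 0.1 (strict) are called; a gene is called as soon
   as any of its tags is (its direction is the sign of its most significant
   called tag, with opposite-signed called tags reported as `conflict`).

Three points in this chain were genuinely open and are resolved as follows.

**The quantile transform.** The printed description of step 2 composes the
inverse normal CDF in a dimensionally incoherent way; we read it as
$\Phi^{-1}(1-P)$. Applied to the upper-tail p-value of a signed z statistic
this transform recovers that statistic exactly, so the pooled null is
implemented directly as the multiset of signed within-condition z values.
This is the only reading under which exchanging the condition labels negates
every z while leaving $|z|$, $p_{\mathrm{emp}}$, the FDR and the called set
unchanged — an invariant the package tests enforce — and under which
identical replicates give $z = 0$ rather than a divergent transform.

**Sidedness.** Step 5 is written one-sided ($Z > Z_i$), yet the analysis
reports both up- and down-regulated tags. The default is therefore
two-sided on $|Z|$, with `sided = "one"` available for the literal form.

**The FDR formula.** Read literally, step 6 multiplies the expected
false-positive fraction by $\hat\pi_0$ only
(`mode = "literal"`), which omits division by the observed discovery
fraction and is anti-conservative. The default `mode = "storey"` uses the
tail-ratio (q-value) form

$$\mathrm{FDR}_i = \min\!\left(1,\
\frac{\hat\pi_0 \; p_{\mathrm{emp}}(i)\; m}{\#\{j : |z_j| \ge |z_i|\}}\right),$$

i.e. expected false positives over observed discoveries at each threshold.
Both modes are smoothed to be nondecreasing in $p_{\mathrm{emp}}$ (running
minimum from the least significant tag, as for q-values), and ties in
$|z|$ are broken by tag identifier so runs are deterministic.

# What the synthetic generator emulates

`sim_config()` fixes the study conditions; the defaults mirror a two-pool
brain MPSS experiment:

* **Library size** 1,500,000 expected tags (Poisson), matching the
  ~1.48/1.52 million tags of the two sequenced pools, with two technical
  replicates per stepper per condition (8 libraries in all).
* **Abundance law**: per-gene log-normal with `sdlog = 1.7`. The original
  study does not state an abundance law; `sdlog` was chosen once so that at
  this library scale roughly half to two-thirds of expressed tags fall
  below 20 tpm, the shape the study reports, and is exposed in the
  configuration rather than revisited.
* **Transcript structure**: bodies of 500–3000 nt with one guaranteed
  eligible `GATC` site, a terminal poly(A) run of ≥ 15 A's, and a 10%
  chance of a second, truncated 3′ isoform per gene (alternative
  polyadenylation), which is what pushes tags-per-gene above 1.
* **Background**: 5% of each library drawn from poly(A)-free decoy
  sequences, standing in for the unannotated/multi-mapping fraction of
  real libraries and exercising the mapping bookkeeping.
* **Planted signal**: a fraction `frac_de` of genes has its condition-B
  abundance multiplied by $2^{fc}$, $fc \sim N(\mu, \sigma)$ with random
  sign, after which both conditions are renormalised to probability
  vectors.
* **Noise**: technical replicates are pure multinomial resamples, because
  the empirical null of the procedure is built from technical replicates,
  which are sampling-noise dominated; a Dirichlet-multinomial
  `overdispersion` knob exists for sensitivity analyses. Steppers are
  statistically exchangeable (no base-calling error model), and no
  sequencing error is simulated.

Everything is driven by one integer seed; a fixed seed reproduces every
count table, file and report byte for byte (the generator functions
validate their inputs before touching the RNG precisely so that nested
calls cannot interleave seeding).

What passing tests on these simulations do **not** show: robustness to
biological replication (pooled designs measure no biological variance),
to sequencing error or stepper-specific artefacts, or to mapping ambiguity
of real genomes, all of which are absent by construction.

## A note on compositional sensitivity

Because libraries are relative (proportions), planting fold changes on 5%
of genes shifts the total mass, so after renormalisation *every* null
gene's proportion moves slightly between conditions. At realistic tag
universes (~10,000 genes over 1.5M tags) this shift stays well inside the
technical-replicate null and the realised false-discovery proportion at
cutoff 0.1 averages ≈ 0.07. If the same library depth is concentrated on a
few thousand tags, per-tag counts grow and the Z-test begins to detect the
renormalisation itself — a property of all proportion-based DE tests, worth
remembering when simulating at artificially small scale.

# Numerical and degenerate-input choices

* Replicate-mean counts and totals are rounded half away from zero
  (R's `round()` is half-to-even; a fixed rule keeps reruns identical).
* $x_1 = x_2 = 0$, or a pooled proportion of 0 or 1, gives $z=0, p=1$.
* The empirical-null pair universe per comparison is the union of tags
  observed in either member of the pair; a tag absent from both carries no
  information and would only contribute a $p=1$ atom.
* A tag unseen in one condition gets count 0 and, for its library total,
  the 2-step mean total of that condition (the tie rule's stepper).
* $\hat\pi_0$ is clipped to $[0,1]$; FDR values are clipped to $[0,1]$.
* The abundance histogram bins rounded tpm (1–10, 11–20, …); values
  rounding below 1 fall outside the plotted range.
* Fisher's exact test uses the probability-mass two-sided criterion with a
  $10^{-12}$ relative tie tolerance, by direct hypergeometric enumeration —
  this reproduces both published staining p-values (0.0037 and 0.083)
  exactly and is cross-checked against `stats::fisher.test` in the test
  suite. Comparative-Ct relative expression is $2^{-\Delta C_t}$ against an
  endogenous control, with the ΔCt standard error propagated from replicate
  wells; no calibrator sample is assumed unless supplied.
* Network node ratios use a pseudocount of 1:
  $\log_2\!\left((\mathrm{tpm}_T + 1)/(\mathrm{tpm}_N + 1)\right)$, since
  zero-count handling for published ratio overlays is unstated; a gene's
  tpm is the sum over its class 1–5 tags (also a package choice).
* SIF exports carry no header line (the format defines none); the
  node-attribute table does. Exports are canonically sorted and numerics
  printed with `%.10g` so export → import → export is byte-identical.

# Problem sizes used by the test suite

Module tests run on 100–400 simulated genes with libraries of
$10^4$–$10^6$ tags. The calibration check runs the full six-step procedure on
10,000-gene, 1.5M-tag experiments (9,500 null / 500 DE at
$|\log_2 FC| = 2$) over 25 seeds and requires the mean realised
false-discovery proportion at cutoff 0.1 to stay at or below 0.1; the same
experiment reports a sensitivity of ≈ 0.8 for planted DE tags, with a
conservative floor asserted at 0.3. These sizes were chosen as the smallest
at which each property is statistically meaningful.

# Known limitations

* Biological-replicate variance modelling (negative-binomial and friends)
  is out of scope: the design emulated here pools samples, and its null is
  technical.
* Only two-condition designs; no cross-library normalisation beyond
  per-million scaling.
* Exact-match mapping with no mismatch tolerance (the source protocol
  states none).
* The class 1–5 boundaries and the 3′-flank width are interpretations, as
  flagged above.
* Gene-set and edge-list inputs are consumed from files; no live database
  retrieval.

# A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 10000, frac_de = 0.05, log2_fc_sd = 0,
                  library_size = 1.5e6, seed = 1)
txome <- generate_transcriptome(cfg)
truth <- simulate_expression(txome, cfg)
libs  <- simulate_mpss_libraries(txome, truth, cfg)
de    <- mpss_de(libs, conditions = c("gbm", "normal"))
de
```

See the README for the full worked example, including mapping summaries,
gene rollup and the network overlay export.
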