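---
title: "Statistical methods behind connis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind connis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connis)
```

## The problem

Tn5-based transposon insertion sequencing (TraDIS, Tn-Seq) characterizes a
bacterial mutant pool by the genome positions at which transposon
insertions were recovered. Because disrupting an essential gene removes the
mutant from the pool, essential genes stay (largely) insertion-free, and a
long stretch of a gene without any insertion site (IS) is evidence of
essentiality. Tn5 can insert at any position, but realized libraries are
usually far from saturation, so long insertion-free stretches also arise by
chance — the statistical task is to decide, gene by gene, whether the
observed longest insertion-free run is longer than chance allows.

## The exact run test (ConNIS)

Let $b$ be the genome length, $h$ the number of distinct insertion sites,
and $\theta = h/b$ the genome-wide insertion density. For a gene of length
$b_j$ the expected number of sites under non-essentiality is
$\hat h_j = \lfloor b_j \theta \rceil$ (nearest integer). Conditional on
$\hat h_j$ sites placed uniformly without replacement among the $b_j$
positions, the length $L_j$ of a maximal insertion-free run has the exact
probability mass function

$$\mathbb{P}(L_j = i) \;=\;
  \binom{b_j - i - 1}{\,b_j - \hat h_j - i\,} \Big/
  \binom{b_j - 1}{\,b_j - \hat h_j - 1\,},
  \qquad 1 \le i \le b_j - \hat h_j .$$

`gap_pmf()` evaluates this in log space. The test statistic is the observed
longest run $l_j$; its p-value is the upper tail
$\mathbb{P}(L_j \ge l_j)$. The tail sum telescopes through the hockey-stick
identity to a single ratio,

$$\mathbb{P}(L_j \ge l_j) \;=\;
  \binom{b_j - l_j}{\hat h_j} \Big/ \binom{b_j - 1}{\hat h_j},$$

which is what `connis_tail()` computes — an $O(1)$ expression per gene that
is exercised against both the literal partial sum and a brute-force
enumeration oracle in the test suite. The closed form makes the
subsample-heavy tuning procedure below cheap.

Insertion density is rarely uniform along a genome (cold spots,
compositional bias). A gene sitting in a low-density region can look
insertion-free purely because its neighborhood is. The test therefore
down-weights the expected site count to
$\lfloor \hat h_j w \rceil$ with a weight $0 < w \le 1$: smaller $w$ makes
essential calls harder everywhere, which trades recall for precision
exactly in the regions where the genome-wide $\theta$ overstates the local
density. A gene is called essential when its (multiplicity-adjusted)
p-value falls below $\alpha$; `adjust_pvalues()` offers Bonferroni, Holm
and Benjamini–Hochberg, with Holm as the package default.

Degenerate cases follow fixed conventions: $l_j \le 1$ or a weighted
expectation that rounds to zero give $p = 1$ (such a gene can never be
called essential); an observed run exceeding the support maximum
$b_j - \lfloor \hat h_j w\rceil$ gives exactly $p = 0$, reported as 0
because it is an exact statement under the null; a weighted density at or
above 1 is outside the model and yields $p = 0$ with a warning. Rounding
$\lfloor \cdot \rceil$ resolves ties half-up so that results do not depend
on parity. Both $\hat h_j$ and $l_j$ are computed on the same (optionally
truncated) gene interval; mismatched intervals would bias the test.

## Competing callers and the shared weighting

Four established approaches are provided behind the same interface, each
receiving the weight only through $\theta \mapsto \theta w$ (observed
statistics are never rescaled):

* **Binomial** (`binomial_pvalue()`): $P(X \le k_j)$ with
  $X \sim \mathrm{Bin}(b_j, \theta w)$ — essential genes carry fewer sites
  than expected.
* **Geometric** (`geometric_pvalue()`): $(1 - \theta w)^{l_j - 1}$, the
  limit of the exact tail as $b_j \to \infty$ at fixed density; the suite
  verifies that the sup-distance between the two falls below 0.01 at
  $b = 10^5$, $\theta = 0.05$.
* **Tn5Gaps** (`tn5gaps_pvalue()`): a Gumbel (extreme-value) approximation
  to the longest insertion-free gap overlapping the gene, with scale
  $\beta = 1/\ln(1/(1-\theta w))$ and location
  $\mu = \ln(n \theta w)\beta + \gamma\beta - \tfrac12$, where $n$ extends
  the gene's effective length by the non-overlapping part of the gap
  (`longest_overlapping_run()` reports gaps at full genome-wide length).
  Centering the Gumbel on the *expected* longest run makes this
  approximation conservative: Monte-Carlo simulation shows it overstates
  tail probabilities by up to about 0.1 in sparse regimes, and the tests
  assert this envelope rather than tight agreement.
* **Exp-vs-Gamma** (`fit_exp_gamma()`, `exp_gamma_label()`): a two-component
  mixture on gene-wise insertion indices $d_j = k_j / b_j$, exponential for
  the near-zero essential mode and gamma for the non-essential bulk, fitted
  by EM and thresholded on the $\log_2$ likelihood ratio at $\pm t$ with an
  `ambiguous` band in between. Ambiguous counts as non-essential in all
  performance metrics. EM is initialized at the antimode of a kernel
  density estimate of $d$; when no antimode exists the split falls back to
  the 10th percentile with a warning. Zero indices are displaced to half
  the smallest positive index for density evaluation only (gamma densities
  with shape $> 1$ vanish at 0). The gamma M-step solves the weighted
  shape equation $\log a - \psi(a) = s$ by Newton steps on $\log a$.

## Labeling instability for tuning-value selection

The weight $w$ (or threshold $t$) is a genuine tuning parameter. The
package selects it by resampling: draw $m$ subsamples of a fraction
(default one half) of the observed sites without replacement, relabel every
gene within each subsample at each candidate value, and summarize the
labeling randomness by

$$\phi(w_y) = \frac{1}{q(w_y)} \sum_{j=1}^{p}
  \hat\pi_j(w_y)\bigl(1 - \hat\pi_j(w_y)\bigr),$$

where $\hat\pi_j$ is the fraction of subsamples labeling gene $j$
essential and $q$ counts the genes ever labeled essential. $\phi$ is the
mean Bernoulli variance over those genes: $0$ means perfectly reproducible
labels, $0.25$ coin-flip labeling. Very small candidate values drive
$\phi \to 0$ trivially by labeling (almost) nothing; these uninformative
values are excluded by keeping only candidates at or above $w_{\max}$, the
smallest value attaining the maximal instability, and selecting the
$\phi$-minimizer among the rest (`select_tuning()`). Argmin/argmax ties
break toward the smallest value — the conservative direction. When $q = 0$
the criterion is reported as 0 with a degeneracy flag, since a grid value
that never labels anything carries no information.

Implementation choices worth knowing: the same multiple-testing correction
used for final calls is applied inside every subsample, so the resampled
procedure is the deployed procedure; subsampling moves *sites* (their read
counts travel along); the subsample's own density $h_{\mathrm{sub}}/b$
drives the per-gene expectations; the mixture classifier is refitted
within every subsample; and each subsample runs on a stream seed derived
from the master seed, so results are independent of evaluation order.

A caveat observed in testing: on extremely clean libraries (dense, no
noise, uniform intensity) labels are stable at *every* weight and the
residual instability grows monotonically with $w$; the $w_{\max}$ rule
then excludes everything except $w = 1$, i.e. tuning degrades gracefully
to the unweighted test rather than finding an interior optimum. The
criterion earns its keep precisely when the intensity is non-uniform
enough for small weights to destabilize calls.

## The synthetic library generator

`simulate_library()` produces libraries with known truth on an *E. coli*
scale by default: a 4.6 Mb genome, 4,000 genes with log-normal lengths
(median about 900 bp, clamped to 90–9,000 bp), multinomial intergenic
gaps, and 300 essential genes — proportions matching well-studied
enterobacterial genomes. Each essential gene reserves a uniformly placed
contiguous block of at least a fraction $c$ of its length whose insertion
intensity is zeroed; the remainder of the gene stays open, so essential
genes may carry sites away from the block. Sites are drawn without
replacement with probability proportional to an intensity profile —
uniform, sinusoidal ($1 + A\sin(2\pi\kappa x/B)$, defaults $A = 0.5$,
$\kappa = 3$: visibly non-uniform, never near zero), or uniform with
non-overlapping cold-spot windows at reduced intensity. Optional noise
sites are placed uniformly over the whole genome, reserved blocks
included, emulating spurious insertions that contaminate the truth labels.
Read counts per site are shifted-geometric and matter only through
read-count filtering.

The generator emulates positional structure, not sequencing: there is no
read-level error, no mapping ambiguity, no replicate structure, no
GC-dependent insertion bias, and a single linear sequence (circular
genomes are treated as linear; no run wraps the origin). Passing tests on
these libraries therefore demonstrate correctness of the statistical
machinery under controlled violations of uniformity — not robustness to
every artifact of real libraries.

## Benchmarks shipped with the package

The test suite and `scripts/acceptance.R` rerun two benchmark libraries
end to end: a sinusoidal library (400,000 sites, $c = 0.8$, 8,000 noise
sites) and a cold-spot library (200,000 sites, 25 windows of 10 kb at 1/10
intensity, 4,000 noise sites, $c = 0.75$), both tuned with $m = 100$
subsamples of half the sites, 5% distal truncation, Holm correction at
$\alpha = 0.05$ — subsample counts sized so the complete benchmark runs in
well under a minute while leaving the selected weight stable across seeds.
On these conditions instability-tuned ConNIS reaches MCC around 0.97–0.99
(sinusoidal) and 0.75–0.77 (cold spots); the cold-spot setting is
intrinsically harder because genes inside cold spots are near
insertion-free for structural reasons and inflate false positives at large
weights.

## Known limitations

* The exact test conditions on a *rounded* expected site count; for very
  short genes ($b_j\theta w < 0.5$) the expectation rounds to zero and the
  gene is untestable by construction.
* The Tn5Gaps Gumbel approximation is conservative (see above); it is
  included as a faithful reconstruction of the established approach, not
  as a calibrated test.
* Overlapping genes are summarized independently; shared insertion-free
  runs count for every gene that contains them.
* One sequence per run: multi-chromosome or plasmid-bearing organisms must
  be processed per replicon.
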