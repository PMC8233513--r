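---
title: "Models and methods in clockshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in clockshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`clockshift` asks a focused comparative question: did a noncoding regulatory
region evolve faster on one branch of a species tree than neutral reference
sequence from the same locus would predict?  The motivating setting is a
~690 bp promoter whose activity differs sharply between primate clades, with
concatenated introns serving as the within-locus neutral reference and the
stem branch of the Old World monkeys as the focal lineage.  Around that core
test the package provides the supporting analyses such a study needs: a
codon-model check that the protein itself is conserved, ancestral sequence
reconstruction of the promoter, parsimony counting of expression-state
changes across mammals, and phylogenetic regression of a binary expression
state on life-history covariates.

# Substitution models

Nucleotide evolution uses HKY: transition/transversion ratio $\kappa$,
stationary frequencies $\pi$, and the generator scaled so the mean rate at
stationarity is 1 (branch lengths are expected substitutions per site).
Among-site rate variation uses the discrete-gamma approximation with $K$
equal-probability categories represented by their class means (not medians),
mean-normalized to exactly 1; $K = 5$ by default, matching the Γ₅ convention.
Base frequencies are taken from the observed data rather than maximized —
the usual practical default, and the difference is negligible at these data
sizes.  Frequencies of bases absent from a degenerate alignment are floored
at $10^{-6}$ so the reversible-model algebra stays finite.

Codon evolution uses the single-ratio M0 model on the 61 sense codons of
the universal code: single-nucleotide steps only, $\kappa$ on transitions,
$\omega = d_N/d_S$ on amino-acid-changing steps, target-codon frequency
weighting, mean rate 1.  The codon frequency convention is `F3x4` by default
with an `equal` option; the source analysis does not state its convention,
so recovery tests use the coherent simulate-equal/fit-equal pair.

Transition probabilities come from the spectral decomposition of the
$\pi$-symmetrized generator, with a scaling-and-squaring fallback if the
reconstruction is ill-conditioned.  All likelihoods are computed by
Felsenstein pruning over compressed site patterns in a small C++ core, with
per-pattern rescaling triggered only when partials drift below $10^{-100}$.

# Local clocks and the acceleration test

The local-clock model parameterizes a rooted tree by node ages (tips at 0)
and per-class rate multipliers: branch length = multiplier × (parent age −
child age).  Class 0 is the background with multiplier fixed at 1, which
resolves the scale confound between rates and ages; labelled classes (the
focal branch, class 1; the hominoid clade, class 2) get free multipliers.
Optimization works in transformed coordinates — log for ages at the root,
rates, $\kappa$, $\alpha$; logit for nested age proportions — with L-BFGS-B.
We use a forward-difference gradient, a convergence tolerance of
`factr = 1e7` and one random restart by default (none inside bulk
simulation loops).  This is looser than an idealized $|\Delta \ln L| <
10^{-8}$ rule; at 50 kb the induced parameter error is orders of magnitude
below one Monte-Carlo SE, and it keeps the full acceptance run inside a
single-CPU desk budget.

Standard errors come from a central-difference Hessian of $-\ln L$ at the
optimum in the transformed coordinates, inverted and delta-rule
back-transformed.  A non-positive-definite information matrix produces a
warning, a flag, and a pseudo-inverse rather than a silent failure.

The acceleration test fits the same labelled tree independently to the
focal locus and the reference locus and compares the class-1 multipliers
$r_1^{f}$ and $r_1^{r}$.  Because the two fits use disjoint data, the delta
method for the ratio $R = r_1^{f} / r_1^{r}$ drops the covariance term:
$\mathrm{SE}(R) = \sqrt{v_f / (r_1^{r})^2 + (r_1^{f})^2 v_r / (r_1^{r})^4}$.
Three P-values are always reported, none silently "corrected":

* `p_paper`: $\Phi(-(R - 1) / (1.96\,\mathrm{SE}))$ — a historical
  convention with an extra 1.96 divisor inside the CDF.  It is not a
  standard test; we reproduce it verbatim and label it.
* `p_standard`: the conventional one-sided z-test
  $\Phi(-(R - 1)/\mathrm{SE})$.
* `p_difference`: the analogous statistic on $D = r_1^{f} - r_1^{r}$ with
  the same 1.96 convention; its published counterpart cannot be checked
  because the per-locus variances were never printed, and the output flags
  this.

The delta-method normal approximation needs smallish coefficients of
variation (≲ 0.3) on both multipliers; below that the ratio distribution
grows heavy tails and the z-test becomes conservative.  We observed exactly
this at 1 kb per locus (0 rejections in 200 null replicates), which is a
property of the scale, not a defect of the statistic: with 6 kb per locus
and a well-separated focal branch the nominal 5% level falls inside the
200-replicate binomial band.  A related identifiability caveat: under a
reversible model only the sum of the two root-adjacent branch lengths is
observable, so a rate class confined to a root edge is confounded with the
root age; `fit_local_clock()` warns when a labelling does this.
Interpret promoter-length (~690 bp) tests accordingly: wide intervals,
honest but low power.

# Ancestral reconstruction and parsimony

Ancestral states are marginal (empirical-Bayes) posteriors: for each
internal node the downward partial likelihoods are combined with the "flow"
from the rest of the tree, summed over gamma categories weighted by the
per-site category posterior (an equal-weight option exists).  Marginal
rather than joint reconstruction is the standard choice when per-ancestor
sequences are reported.  Under a reversible model the result does not
depend on root placement; the suite checks this numerically.  MAP ties are
broken by fixed state order A<C<G<T and flagged.  Gap and ambiguity
characters contribute flat partials ("missing"), consistent with the
alignment module's default gap policy; a strict mode drops gapped columns
instead, since the reference implementation's cleaning switch is not stated
in the source analysis.

Fitch parsimony counts the minimum number of binary-state changes with the
classic bottom-up set pass and returns one optimal assignment from the
top-down pass.  Children at polytomies are combined sequentially, which is
equivalent to an arbitrary resolution (warned).  Missing tips can be
treated as wildcards.

# Phylogenetic logistic regression

The binary expression state is regressed on covariates by generalized
estimating equations with a logistic mean and a working correlation among
species of $\exp(-\delta\, d_{ij})$ on patristic distances — the
exponential decay matches the covariance structure implied by a two-state
Markov switching process on the tree.  The decay $\delta$ is profiled on a
grid (scaled by the mean pairwise distance, independence included as the
limit) using a Gaussian pseudo-likelihood of the standardized residuals;
$\beta$ solves the estimating equations by damped Fisher scoring with
model-based Wald standard errors.  This estimator is a declared
implementation choice within the family of phylogenetic logistic methods,
selected for transparency and desk-scale robustness rather than as a clone
of any specific published estimator.  When the best decay is the
independence limit the fit coincides with ordinary logistic ML (checked to
1e-4 on star trees).  Complete separation is detected and refit with a
small ridge penalty, flagged.

The plain correlation utilities use Pearson correlations on log10 scales
(mass, heart rate, BMR are strictly positive and span orders of magnitude)
with two-sided t-tests; the genome-wide screen ranks genes by $|R|$ and
adjusts P-values across genes by Benjamini–Hochberg by default — the source
analysis says only "adjusted P", so the method is a parameter.
The expression threshold separating high from low states defaults to
1 FPKM and is likewise a recorded parameter, not an assertion.

# The synthetic world

The simulators define the stated world for every test:

* **Primate fixture** — 13 taxa, ultrametric with depth 0.10 expected
  background substitutions per site, mouse-lemur rooting, one class-1
  Cercopithecidae stem branch and a class-2 hominoid crown clade (stem
  excluded by default; both options exposed because the source analysis
  does not say whether the stem was included).  Branch lengths are
  plausible synthetic values, not estimates from any real alignment.
* **Mammal fixture** — 29 taxa, ultrametric, ages in million years loosely
  following consensus timetrees; synthetic, used for the trait analyses.
* **Sequence simulation** draws root states from $\pi$ and evolves them
  branch by branch; site-wise gamma categories are drawn from the same K
  discrete classes used in inference, so simulation and fitting share one
  model exactly and recovery tests are coherent.  Default parameters for
  promoter-like data: $\kappa = 4$, $\pi = (0.3, 0.2, 0.2, 0.3)$,
  $\alpha = 0.8$, K = 5 — typical mammalian noncoding values.  Rate-class
  multipliers default to the published promoter and intron estimates when
  emulating those loci.
* **Binary traits** follow a latent threshold model: tip liabilities are
  multivariate normal with correlation $\exp(-\mathrm{decay}\, d_{ij})$,
  shifted by $X\beta$, thresholded at zero.

What the synthetic world does **not** emulate: indels and alignment
uncertainty, CpG and other context effects, base-composition drift across
lineages, intron/promoter differences in composition, and real codon usage
bias.  A green recovery test therefore establishes internal consistency of
simulator + estimator at the stated sizes, not correctness on real
genomes.

# Numerical choices and degenerate inputs

Zero-length branches are allowed; negative lengths are parse errors.
Identical sequences drive branch lengths to the lower box bound ($10^{-9}$)
and set a boundary flag; all-synonymous codon data do the same for
$\omega$.  A labelling that leaves no background branch is rejected as
unidentifiable.  Alignment columns are 0-based internally and 1-based in
every report.  Every stochastic routine takes an explicit seed and records
it; fits are deterministic given data.

# Known limitations

Single nucleotide partition per locus (no joint promoter+intron
likelihood — the two loci are fitted separately by design); no NEXUS; no
site-class codon models; no Bayesian dating; the GEE logistic estimator's
decay parameter is profiled on a grid rather than jointly maximized.  At
promoter length the focal-branch information is small and the observed
information matrix can be near-singular; results carry flags rather than
hiding this.
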