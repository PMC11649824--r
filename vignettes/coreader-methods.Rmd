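---
title: "Methods: models, filters and design choices in coreader"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, filters and design choices in coreader}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`coreader` implements the computational machinery used to establish
facilitated m6A reading by pairs of RNA-binding proteins — a cytoplasmic
YTH-domain m6A reader (ECT2-type) and a pyrimidine-element binder
(ALBA4-type) whose sites sit at or slightly 5' of the methylated
adenosines. Five analysis stages are covered: HyperTRIBE-style
differential RNA editing, a hierarchical binomial model correcting
differential editing for unequal ADAR expression between genetic
backgrounds, post-peak-calling iCLIP binding-site definition,
convolutional sequence models for m6A-site curation and dual-reader
binding prediction with de novo motif attribution, and site-geometry
statistics. A synthetic-data generator with complete ground truth makes
every stage testable end to end without external data.

# The ADAR-corrected hierarchical binomial model

The centerpiece estimator addresses a concrete failure mode of
fusion-protein editing assays: when the ADAR fusion is expressed at
different levels in the two genetic backgrounds being compared, a naive
per-position test attributes the dose effect to the genotype. The model is

$$Y_{ijkc} \sim \mathrm{Binomial}(n_{ijkc},\, p_{ijkc}), \qquad
\mathrm{logit}(p_{ijkc}) = \beta_0 + \beta_j + \gamma_k + \delta_{jk} + u_{ic},$$

where $j$ indexes tertiles of per-sample ADAR expression (ADAR_BIN), $k$
quintiles of gene expression (EXPR_BIN), $\delta_{jk}$ their interaction,
and $u_{ic} \sim N(0, \tau_c^{-1})$ is a per-position random effect with a
condition-specific precision. Differential editing is tested through the
posterior of the linear combination $LC_i = u_{iA} - u_{iB}$: its
posterior mean and sd give $Z_i = \mu_{LC_i}/\sigma_{LC_i}$, two-sided
normal p-values, and Benjamini–Hochberg FDR control. Corrected editing
proportions set ADAR to the center bin:
$\mathrm{logit}^{-1}(\beta_0 + \beta_{j^*} + \gamma_k + \delta_{j^*k} + u_{ic})$.

Design choices the displayed model leaves open, and what this package
does:

* **Identifiability.** The model is over-parameterized; treatment coding
  (first level of each factor fixed at zero) is used. Any full-rank
  coding gives identical fitted probabilities, so this choice does not
  affect the tests.
* **Inference engine.** The contract is the likelihood, not a software
  stack. `fit_adar_model()` uses a Laplace approximation: damped joint
  Newton steps on $(\beta, u)$ with the sparse Hessian solved exactly via
  its Schur complement. The joint step matters — when an ADAR bin is
  nearly aligned with condition (exactly the motivating scenario), fixed
  effects and random-effect means trade off along a ridge that
  block-coordinate schemes traverse impractically slowly, leaving the
  dose effect spuriously inside $u$. Posterior sds of $u_{ic}$ come from
  the corresponding diagonal of the inverse Hessian (fixed-effect
  uncertainty included); $\tau_c$ is updated by an EM-type
  approximate-marginal-likelihood step
  $\tau_c = G_c / \sum_i (u_{ic}^2 + \mathrm{var}(u_{ic}))$, capped at
  $10^6$, with a direct jump to the cap when all posterior modes are
  exactly zero (a degenerate, overdispersion-free table whose precision
  MLE lies on the boundary). Tests cross-check the fit against an
  independent `glmmTMB` fit of the same likelihood.
* **$\sigma_{LC}$.** Both posterior sampling (default, 1000 seeded draws)
  and analytic propagation ($\mathrm{Var} = \mathrm{Var}(u_{iA}) +
  \mathrm{Var}(u_{iB})$, exact here because the two posteriors are
  conditionally independent) are implemented; they agree to a few percent
  at 10^4 draws.
* **FDR and sidedness.** Benjamini–Hochberg and two-sided p-values;
  neither is pinned down by the printed description.

# HyperTRIBE differential editing

Candidate positions carry at least one mismatch in at least one sample;
mutation types are filtered to A-to-G on plus-strand genes and T-to-C on
minus-strand genes (the same transition in transcript space); replicate
agreement requires alternative reads in at least two fusion replicates
(the published pipeline leaves the count unquantified; two is the
default and configurable). The per-position test is a likelihood-ratio
test of the condition term in a binomial logistic model on pooled
replicate counts — implemented in closed form as the 2×2 binomial
deviance and verified against `glm()` in the tests. Significance demands
adjusted p < 0.01, log2 fold-change > 1 and a pooled editing proportion
of at least 0.01; fold-changes use a pseudo-proportion floor of
$1/(\text{depth}+2)$ so that zero-editing controls do not produce
infinities. Positions overlapping several representative gene models are
assigned to the one more highly expressed in the control lines.

# iCLIP binding-site cascade

Starting from single-nucleotide called peaks: runs of directly adjacent
peaks (distance exactly 1 nt, same strand) collapse to the
highest-scoring position, ties to the leftmost; summits are extended by
4 nt each side into 9-nt sites; sites with crosslinks at only one of the
nine positions are artifacts and removed; per replicate, the 30% quantile
(linear-interpolation) of per-site crosslink totals is a minimal
threshold and a site must exceed it strictly in at least two of three
replicates; sites overlapping (≥ 1 nt, same strand) a control-channel
site are removed; targets are genes whose representative model overlaps a
surviving site. The quantile is computed per replicate — the published
wording ("above this threshold in at least two out of three replicates")
reads most naturally that way. The control channel is built identically
but never reproducibility-filtered. "Strong" sites are those scoring
strictly above their gene's median site score; single-site genes keep
their site by default, since a strict median rule would silently drop
every single-site target (configurable). Every stage only removes sites,
is idempotent, and is tested against brute-force recount oracles.

# Convolutional sequence models

No deep-learning framework ships with this package's dependency set, so
`coreader` contains a compact, fully tested 1D CNN engine written in
vectorized base R (im2col gathers + BLAS matrix products; exact
backpropagation verified against numerical gradients). The architecture
contract is the published one: blocks of 1D convolution with ReLU,
dropout, batch normalization and max pooling; flattening; a separate
fully connected hidden layer per output head; sigmoid scalar outputs
with binary cross-entropy, trained with Adam. Training is deterministic
given the spec seed.

**m6A classifier and refinement.** The m6A model trains on ±100 bp
windows around true sites versus location-matched background sites and
predicts the presence of m6A at the *center* of the window. Position
refinement evaluates the model at every shift in ±`max_shift` (default
20 nt) and moves each site to the arg-max, ties to the smallest absolute
shift, then the negative one; a refined site's probability never drops
below the unshifted one, and `max_shift = 0` is the identity. Because
center conditioning is what refinement exploits, the trainer can add
displaced copies of positive windows (shifts 3–25 nt) to the negatives;
at the small training scales of the synthetic studies this measurably
sharpens positional resolution and is used there, while held-out AUC is
always reported against the true negatives only.

**Dual-reader model.** 601-nt windows centered on compendium m6A sites,
two sigmoid outputs (ECT2-bound, ALBA4-bound), gene-disjoint 5-fold
cross-validation so overlapping windows never straddle the train/test
split; all downstream predictions are held-out. First-layer filters (8 nt)
are turned into PWMs by scanning training sequences with the filter's
pre-activation cross-correlation, collecting the top-n positions
(default 5000, following the published procedure) and normalizing
nucleotide frequencies; consensus names use a per-column IUPAC rule
(single base at frequency ≥ 0.5, otherwise the degenerate code over
bases ≥ 0.25). Motif attribution fits, per motif,
`logit P(present within 150 bp) = a + b1 p_ECT2 + b2 p_ALBA4`
on held-out predictions; each coefficient's Z-score measures
correspondence with one protein while controlling for the other.
The published architecture section gives 64 first-layer filters while
the motif section uses 32 filters of length 8; the filter-to-PWM path
simply uses whatever the configured first layer contains, since the
motif count is what downstream consumes.

# Site-geometry statistics

Matched backgrounds pair every site with a position of the same feature
type (5'UTR/CDS/3'UTR) at the same relative-position bin (50 bins,
integer bin arithmetic to avoid float boundary artifacts), drawn from
the genes of the set of interest or an expression-matched pool, and
resampled when falling within 100 bp of any true site — so the
feature/bin histogram matches exactly by construction. Distance and
motif-occurrence profiles count signed transcript-oriented offsets
(negative = 5'), normalized per 1000 anchors, and are tested to match
brute-force all-pairs oracles exactly. Metagene profiles histogram
relative positions per feature. The gene-set overlap test draws random
sets stratified over the first set's expression deciles and applies the
folded permutation formula $p = 1 - 2(|hsum - n/2|/n)$ verbatim, with
the "<0.001" sentinel when no random set beats the observed overlap; the
formula's unusual two-sided folding is preserved, not "fixed", and the
direction is reported alongside. Single-cell co-expression greedily
matches each anchor-positive cell to the nearest-total-UMI
anchor-negative cell without replacement and Fisher-tests genes present
in 20–80% of the matched cells.

# The synthetic world

`simulation_spec()` fixes the study conditions; the generators are
deterministic given the seed, and every planted entity is recorded in a
ground-truth object. The world is one synthetic chromosome with genes
tiled at ≥ 200 nt gaps, roughly half on the minus strand,
gamma-distributed feature lengths (defaults 150/900/300 nt for
5'UTR/CDS/3'UTR). m6A sites are Poisson per gene, placed by metagene
weights (default 5/25/70% across 5'UTR/CDS/3'UTR — the 3'UTR enrichment
characteristic of plant m6A), at least 50 nt apart (real single-gene
m6A sites rarely pack tighter, and the spacing keeps shift-refinement
unambiguous within ±20 nt), each carrying a planted DRACH element
(GGACT, site on the central A). Reader binding uses configurable
marginal and joint bound fractions; bound sites get a true crosslink
contact point drawn at N(−10, 5) nt (ECT2-type) or N(−25, 8) nt
(ALBA4-type) transcript-5' of the site — generator choices consistent
with the observed qualitative geometry, not published values — with the
reader's element (UAUUUU for ALBA4; UGUAUA, a URUAY-class element, for
ECT2) written into the genome at the contact point. Offsets are kept at
least 8 nt from the site so planting never destroys the DRACH element,
and at dual-bound sites the two elements avoid overwriting each other.
Per-replicate crosslink counts are negative binomial (mean 6, dispersion
2) scattered multinomially over ±2 nt, as reverse-transcription
truncations scatter around a contact; background crosslinks (0.3/kb,
often with a 1-nt neighbor) and a weaker control channel (0.15/kb)
provide the weak candidate sites a reproducibility quantile needs to cut.
Called peaks are emulated as 3-adjacent-position clusters at contact
points plus singletons at background crosslinks. Editing counts are
drawn exactly from the hierarchical model above; the confounded-design
generator gives condition A high and condition B low ADAR doses with the
editing strength following the same dose tertiles the analysis assigns,
and no true condition difference. The UMI matrix plants co-expressed
genes at a configurable odds ratio over 200 background genes, so that
anchor-coupled genes contribute little to per-cell depth.

What the generator does *not* emulate: splice isoforms, sequencing
error, crosslinking sequence bias (real iCLIP crosslinks prefer
uridines), overlapping genes, chromosome-scale composition, or m6A
stoichiometry. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated generative assumptions, not
performance on real libraries.

# Problem sizes and numerical choices

The packaged property studies run at sizes chosen to exercise each
method's asymptotics while staying desk-scale: 2000 editing positions
for parameter recovery (β0 recovered within ±0.15, correlation of true
and posterior LC ≥ 0.8 at depth 50, τ = 4), 5000 positions for null
calibration, a 100-gene world for the iCLIP cascade, a 150-gene world
for m6A refinement (2-block CNN, 16 filters, pools 2 and 1 so the total
stride of 2 resolves single-nucleotide refinement; 16 epochs), and a
1000-gene, ~3000-site world for the dual model (24/12 filters, 6
epochs, batch 128, learning rate 2e-3; filter-to-PWM extraction with
top-n 300, scaled from the published 5000 because a 3000-site world
contains proportionally fewer motif occurrences). For the dual-model
attribution study the ECT2/ALBA4 labels are drawn independently
(joint fraction = product of marginals): attribution specificity is
only a well-posed question when one protein's element is not planted
near the other's sites through label dependence. Degenerate inputs:
positions with zero depth in a condition are flagged untested; aliased
fixed-effect columns (absent bin combinations) are dropped with a
warning; separation is ridge-stabilized; zero-sd contrasts are excluded
with a warning; single-position binding "sites" are artifacts by rule.

# Known limitations

The Laplace posterior understates uncertainty for positions with very
low depth; the engine is single-threaded R and sized for desk-scale
studies, not genome-scale training; refinement assumes the true site
lies within `max_shift` of the input; and the permutation p-value
formula, implemented verbatim, returns p = 0 when *every* random set
beats the observed overlap (extreme depletion) — the direction field
distinguishes that case.
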