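# coreader

Dual m6A reader binding analysis: ADAR-corrected differential RNA
editing, iCLIP binding-site definition, convolutional sequence models,
and site-geometry statistics.

## The problem

N6-methyladenosine (m6A) on mRNA is read by YTH-domain proteins
(ECT2-type in plants). A second family of RNA binders — the
pyrimidine-element-binding ALBA proteins — occupies sites at or slightly
5' of the methylated adenosines and facilitates reading. Establishing
that model computationally requires several independent lines of
evidence, each with its own statistical machinery:

* **HyperTRIBE differential editing** — fusing a protein to the
  hyperactive ADAR catalytic domain marks its mRNA targets with A-to-G
  edits; targets are positions where editing proportions
  `E.P. = G/(A+G)` exceed the free-ADAR control (per-position binomial
  likelihood-ratio test; adjusted p < 0.01, log2FC > 1, E.P. ≥ 0.01).
* **ADAR-expression correction** — comparing editing between genetic
  backgrounds is confounded when the ADAR fusion is expressed unequally.
  The package's core estimator is the hierarchical binomial model

  ```
  Y_ijkc ~ Binomial(n_ijkc, p_ijkc)
  logit(p_ijkc) = b0 + b_j + g_k + d_jk + u_ic,   u_ic ~ N(0, 1/tau_c)
  ```

  with ADAR-dose tertiles `j`, gene-expression quintiles `k`, their
  interaction, and per-position condition-specific random effects.
  Differential editing is tested on the posterior of
  `LC_i = u_iA - u_iB` via `Z = mu/sigma`, two-sided p-values and BH
  FDR; corrected editing proportions normalize ADAR to the center bin.
* **iCLIP binding sites** — from single-nucleotide called peaks:
  merge directly adjacent peaks to summits, extend ±4 nt, drop
  single-position artifacts, keep sites above the per-replicate 30%
  crosslink quantile in ≥ 2/3 replicates, subtract the control channel,
  assign targets; "strong" sites score above their gene's median.
* **Sequence models** — a CNN distinguishes m6A sites from
  location-matched backgrounds on ±100 bp windows and refines imprecise
  site positions by shift-and-maximize; a dual-output CNN predicts ECT2
  and ALBA4 binding from 601-nt windows with gene-disjoint 5-fold CV,
  and its first-layer filters are converted to PWMs whose
  protein-specific enrichment is scored by logistic regression on the
  held-out binding probabilities.
* **Site geometry** — feature/position-matched backgrounds, distance and
  metagene profiles, expression-matched permutation tests of gene-set
  overlap (`p = 1 - 2|hsum - n/2|/n`, "<0.001" sentinel), and
  single-cell Fisher co-expression with UMI-matched cells.

A synthetic-data generator (`simulation_spec()`, `simulate_study()`)
emulates the full data structure — transcriptome, 3'UTR-enriched m6A
with DRACH elements, planted reader elements (UAUUUU upstream of bound
sites), replicated crosslink counts with a control channel, editing
counts drawn exactly from the hierarchical model, and a UMI matrix with
planted co-expression — with complete ground truth, so every stage is
testable end to end.

## Worked example

```r
library(coreader)

study <- simulate_study(simulation_spec(seed = 8, n_genes = 100))
res <- iclip_pipeline(study$peaks$alba4, study$xlinks$alba4,
                      study$peaks$control, study$xlinks$control,
                      study$annotation)
res$bs
#> 99 binding sites (9 nt), 3 replicates
length(res$targets)
#> [1] 65
mean(study$truth$target_genes_alba4 %in% res$targets)
#> [1] 1
```

All 65 recovered target genes are true planted targets, and every true
target is recovered; running the control channel through the same
cascade yields zero sites.

```r
ed <- simulate_editing_counts(
  simulation_spec(seed = 11, editing = list(beta0 = -1.5,
    beta_j = c(0, 0.5, 1), gamma_k = rep(0, 5), delta_jk = NULL,
    tau_A = 4, tau_B = 4, depth_mean = 50)), n_positions = 2000)
fit <- fit_adar_model(ed$table)
fit
#> ADAR-corrected hierarchical binomial model
#>   12000 observations, 4000 position x condition random effects
#>   converged in 9 iterations (gradient norm 1.43e-10)
#>   precisions tau: A = 4.048, B = 4.046
#>   fixed effects:
#> (Intercept)       adar2       adar3       expr2       expr3       expr4
#>     -1.5110      0.5100      1.0080     -0.0115      0.0121      0.0126
#>   ...
ctr <- contrast_random_effects(fit, seed = 1)
cor(ed$truth$lc, ctr$mu_lc)
#> [1] 0.967
```

The intercept (−1.511 vs. true −1.5), ADAR-dose effects (0.510, 1.008
vs. 0.5, 1.0) and precisions (4.05 vs. 4) are recovered, and the
posterior condition contrasts track the true per-position differences
at r = 0.97. `summary()`, `coef()`, `predict()` and
`corrected_editing_proportions()` operate on the fitted object.

## Vignette

`vignettes/coreader-methods.Rmd` documents the models, the filtering
rules, every tunable with its default, the design decisions taken where
the methods admit choices, what the synthetic generator does and does
not emulate, and known limitations.
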