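---
title: "Genomic prediction under metabolic flux-balance constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction under metabolic flux-balance constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Genomic prediction regresses a quantitative phenotype on genome-wide
relatedness: with a genomic relationship matrix $G$ built from SNP dosages,
GBLUP predicts a new genotype's phenotype from its kinship to the training
genotypes. When the phenotype is the output of a known metabolic network —
the motivating case is shoot biomass as the flux of a biomass-producing
reaction fed by a curated stoichiometry model — the network itself carries
information that plain GBLUP ignores: at steady state every metabolite's
production and consumption balance, so the $J$ reaction fluxes
$V_i \in \mathbb{R}^J$ of genotype $i$ satisfy $M_i V_i^\top = 0$ for its
$K \times J$ stoichiometry matrix $M_i$.

`fluxgp` implements a hierarchical Bayesian model that infers the fluxes of
*all* genotypes jointly, treating the steady-state condition as a soft
constraint inside the likelihood, together with the two classical
baselines it is compared against:

* **GBLUP** on the phenotype alone ($Y = 1\mu + u + e$,
  $u \sim N(0, G\sigma_u^2)$), fitted by single-kernel REML;
* a **predict-then-project** pipeline: estimate per-genotype training
  fluxes by quadratic programming (QP), predict test-genotype fluxes
  reaction-by-reaction with GBLUP, then project the predictions back onto
  the steady-state polytope with a second QP.

## The joint model

Phenotypes enter through the target (biomass) reaction flux,
$Y = 1a + b V_{,J} + e$, $e \sim N(0, I\sigma_e^2)$. The balance condition
is relaxed to $0 = M_{i,k} V_i^\top + \varepsilon_{ik}$ with
$\varepsilon_{ik} \sim N(0, \sigma_\varepsilon^2)$ shared across all
genotype–metabolite pairs. Each reaction's flux splits into a
kinship-structured genetic component and residual:
$V_{,j} \sim N(U_{,j}, I\sigma_{Vj}^2)$ (truncated below at zero for
irreversible reactions) and $U_{,j} \sim N(1\mu_j, G\sigma_{Uj}^2)$.
Because the test genotypes appear in the constraint block even though
their phenotypes are masked, their fluxes — and hence their predicted
phenotypes $\hat Y_i = a + b V_{i,J}$ — are identified through the network
and the kinship structure.

Two reparameterizations make this tractable:

1. **Per-reaction standardization.** Flux scales differ by orders of
   magnitude between reactions. Rough per-reaction estimates
   $(\tilde\mu_j, \tilde\sigma^2_{Uj}, \tilde\sigma^2_{Vj})$ — obtained by
   fitting the single-kernel mixed model to QP-estimated training fluxes,
   never to test data — define $\delta_j$ and
   $\alpha_j = 10 - \tilde\mu_j/\delta_j$, and inference runs on
   $V''_{,j} = V_{,j}/\delta_j + \alpha_j$, which puts every reaction near
   the common location 10 with unit-order spread. We take
   $\delta_j = (\tilde\sigma^2_{Uj} + \tilde\sigma^2_{Vj})^{1/2}$: fluxes
   are divided by $\delta_j$ while variances are divided by $\delta_j^2$,
   which is only dimensionally coherent if $\delta_j$ lives on the
   standard-deviation scale. A `delta_mode = "literal"` switch provides
   the plain variance-sum reading for comparison.
2. **Likelihood weight.** The observation block has $N$ terms and the
   constraint block $N \times K$; combined naively the constraints swamp
   the phenotypes. A weight $W \in (0,1]$ multiplies the constraint
   log-likelihood. $W$ is a tuning parameter: accuracy as a function of
   $W$ is concave, and the package's benchmark scans the grid
   $\{0.16, 0.32, 0.48, 0.64, 0.80, 0.96\}$.

Priors: half-Cauchy(0, 0.1) on $\sigma_e^2$, half-Cauchy$(0, S_\varepsilon)$
on $\sigma_\varepsilon^2$ with $S_\varepsilon \sim$ Gamma(0.1, 1),
half-Cauchy(0, 10) on the standardized flux variances and on $b$, and
half-Cauchy(0, 10000) on the standardized genetic variances.

### The intercept prior

A half-Cauchy prior on both regression parameters would constrain
$a, b > 0$. Positivity is right for $b$ — the phenotype is proportional to
the biomass flux by construction — but not for $a$: after standardization
the implied intercept is $a' = \tilde\mu_J - 10\,\delta_J$, negative for
any target reaction whose coefficient of variation exceeds 0.1. With $a$
forced positive the posterior collapses to $b \approx 0$ and every
prediction equals the intercept (we observed exactly this on simulated
fits). The package therefore gives the intercept a symmetric Cauchy(0, 10)
prior and keeps the half-Cauchy on the slope.

## Inference

The posterior is explored with the package's own No-U-Turn Sampler
(dual-averaging step-size adaptation targeting 0.8 acceptance, diagonal
mass matrix estimated from the middle of warmup), with the density and
gradient compiled via Rcpp/Armadillo. Three numerical choices matter:

* **Truncation.** Irreversible-reaction coordinates are sampled as
  $V'' = \alpha_j + \exp(\theta)$, so every draw respects
  $V''_{ij} > \alpha_j$ exactly; the truncated-normal normalizer
  $-\log\Phi(U'_{ij}/\sigma'_{Vj})$ is part of the density.
* **Non-centered genetic effects.** $U'$ is parameterized as
  $U'_{,j} = m_j + \sigma'_{Uj} G^{1/2} z_j$, $z \sim N(0, I)$, which
  removes the variance/effect funnel; without it the sampler's step size
  collapses by two orders of magnitude.
* **Initialization.** Standardized fluxes start at the transformed
  QP-estimated training fluxes where available and at the location target
  (plus $N(0, 0.1)$ noise) for test genotypes; variances start at their
  prior medians, except $\sigma_\varepsilon^2$, which starts at the mean
  squared initial constraint residual (test-genotype rows are not yet
  balanced, and a tight initial $\sigma_\varepsilon^2$ would put the
  starting energy four orders of magnitude off scale), and the regression
  pair, which starts at the least-squares scale of the training data.

Default chain length is 5000 with 4000 warmup (a single chain, as one run
per fit is standard here); the benchmark uses 1000/500 with tree depth
capped at 8, sizes chosen so a full weight-grid CV runs on a laptop core.
Convergence is summarized by split-half $\widehat R$ with the usual 1.1
flag threshold; high $\widehat R$ is reported, not fatal, since method
comparison is robust to slowly mixing flux coordinates. When fitting
simulated data whose balance is exact, a small jitter
$\psi_{ik} \sim N(0, 10^{-4})$ is added to the constraint left-hand side
(`simulation_jitter = TRUE`) to keep the constraint block from becoming
numerically singular.

## The QP baseline

Training fluxes solve, per genotype, $\min \sum_j (V_j/V_{\mathrm{ref},j}
- 1)^2$ subject to $M_i V^\top = 0$, nonnegativity on irreversible
reactions, and the biomass-ratio condition
$V_{i,J} = V_{\mathrm{ref},J}\, Y_i / Y_{\mathrm{ref}}$ imposed as a hard
equality. The relative-deviation objective mirrors the projection stage;
the reference genotype's fluxes and phenotype are treated as known side
information (the analogue of a curated reference accession), so folds are
unrestricted. Near-zero denominators ($|u_j| < 10^{-6}$) switch that term
to absolute deviation scaled by the median $|u|$. QPs are solved with
`pracma::quadprog`; solutions are accepted only if equality residuals and
sign constraints hold to $10^{-6}$.

Optional "physiological" ratio-pair constraints (carboxylation within
$[0.94, 3.81]\times$ oxygenation; starch within $[0.79, 3.37]\times$
sucrose synthesis) can be switched on. They are off by default: with them
on, the projection becomes so tightly pinned by the genotype-specific
stoichiometry that predictions barely react to the kinship matrix —
permuting $G$ changes them by well under a percent — i.e. apparent
accuracy no longer reflects genomic information. The package reproduces
this pathology qualitatively on synthetic data.

## The simulation engine

`generate_dataset()` emulates the structure of the motivating data:

* SNP dosages (default $P = 2000$, ancestral MAF uniform on
  $[0.05, 0.5]$) follow a Balding–Nichols family model (10 families,
  $F_{ST} = 0.25$ by default) and feed a VanRaden relationship matrix;
  $N$ defaults to 67, the size of the motivating panel. The family
  structure matters: an unrelated panel's relationship matrix is nearly
  the identity, kinship then carries no information, and GBLUP — the
  baseline the joint model borrows its genetic prior from — degenerates
  to the training mean.
* A sparse signed stoichiometry matrix whose per-reaction and
  per-metabolite nonzero counts have configurable medians (defaults 4 and
  2, the medians of the curated 350-metabolite network; the benchmark
  instances use $K = 10$, $J = 12$ with targets (3, 3), since the real
  medians are arithmetically impossible at that size). Every metabolite
  has at least two reactions, one producer and one consumer; the last
  reaction only consumes and is the target.
* Per-reaction genetic parameters drawn log-uniformly: locations over two
  orders of magnitude ($\mu_j \in [10^{0.5}, 10^{2.5}]$), genetic CV in
  $[0.05, 0.5]$, residual CV in $[0.016, 0.16]$. The heterogeneity of
  scales is the point — it is what the standardization step has to undo.
  The real-data parameter fits are not published, so these ranges are the
  package's definition of "realistic": flux heritabilities mostly high,
  truncation mild.
* Fluxes $U_{,j} \sim N(1\mu_j, G\sigma^2_{Uj})$,
  $V_{,j} \sim N(U_{,j}, I\sigma^2_{Vj})$; for irreversible reactions $U$
  is redrawn as a whole vector (it is kinship-correlated) and $V$ per
  genotype (conditionally independent) until nonnegative, with a retry
  budget of 100.
* Exact balance by construction: for each genotype and metabolite, the
  coefficient of the row's last nonzero reaction is overridden to
  $M_{i,\mathrm{last},k} = -\sum_{j \ne \mathrm{last}} M_{k,j} V_{i,j} /
  V_{i,\mathrm{last}}$ (genotypes with $|V_{i,\mathrm{last}}| < 10^{-6}$
  are redrawn). Because the target column is the last, its coefficients
  become genotype-specific — emulating the genotype-specific biomass
  column of the real data, whose availability for test genotypes makes
  the evaluation a CV2-style scheme.
* Phenotypes $Y = V_{,J} + e$ with
  $\mathrm{var}(e) = 0.25\,\mathrm{var}(V_{,J})$.

What the generator does **not** emulate: the real network topology (350
metabolites, 336 reactions), genetic correlations *between* reactions
(fluxes are drawn independently per reaction, so multi-trait methods have
nothing to exploit), measurement structure in the biomass coefficients,
and any population structure finer than discrete families (no admixture,
no isolation by distance). A
passing benchmark therefore shows the machinery works and the qualitative
method ordering is reproducible under the stated conditions — not that
the same margins hold on real data, where network misspecification
compressed the advantage considerably.

## Benchmark design and expected behavior

`run_benchmark()` runs 3-fold cross-validation per simulated replicate
(the benchmark uses 5 replicates at $N = 60$, $K = 10$, $J = 12$, NUTS
1000/500 — sizes the package adopts so the full grid finishes in minutes
per replicate; the acceptance script uses 2 replicates). Per fold it
estimates training fluxes once by QP, recomputes the rough estimates and
scaling from those training fluxes only, and evaluates all methods on the
same held-out genotypes; accuracy is the per-fold Pearson correlation.
Mann–Whitney–Wilcoxon tests (exact for group sizes up to 20) with
Bonferroni correction compare methods, with figure-style significance
letters.

On data generated as above, the expected picture — which the acceptance
suite checks — is: the joint model at its best weight outperforms the QP
pipeline, which outperforms GBLUP; the accuracy-versus-$W$ profile peaks
strictly inside the grid; at every weight, the two sides of the fitted
constraint correlate above 0.99 (the fluxes really are at steady state);
and the ratio-constraint pathology reproduces.

## Known limitations

* The posterior is multimodal in the fluxes (many flux configurations
  satisfy the constraints); a single chain finds *a* good mode, and
  $\widehat R$ on flux coordinates can exceed 1.1 on hard instances.
  Method comparison tolerates this; downstream use of individual flux
  posteriors should not.
* $W$ is not inferred from data; it is scanned.
* The constraint noise shares one variance across all metabolites, so a
  single badly scaled metabolite row can dominate the constraint block.
* Runtime grows as $N^2 J$ per gradient; the full-size real problem
  ($J = 336$) is out of desk-scale reach, as it was for the original
  21-hour fits.
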