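---
title: "Scoring injury-module activation with the AAFC statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring injury-module activation with the AAFC statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(injurymod)
```

## The problem

Toxicogenomic screens ask whether a chemical exposure activates the
transcriptional programme of a specific organ injury — fibrogenesis,
cellular infiltration, bile duct proliferation and so on — and whether
that activation is concordant across species (rat vs. human) and
across systems (cultured cells vs. whole animals). Single-gene
differential expression answers neither question well: with small
cohorts (typically n = 5 treated and 5 control samples) per-gene power
is low, and the particular genes that pass a threshold overlap across
systems little better than chance. Injury *modules* — gene sets each
uniquely associated with a histopathological injury phenotype — pool
evidence over tens of genes and are the unit of analysis in this
package.

`injurymod` implements the module activation analysis end to end:
per-gene fold changes and t-tests, DEG calling, the aggregate absolute
fold-change (AAFC) module score with permutation inference, Fisher's
combined probability as a reliability indicator, and a cross-system
layer (ortholog-mapped DEG overlap, activation-vector correlation,
condition-level PCA). A synthetic-data generator with known ground
truth makes every stage testable without any external data.

## The model

### Per-gene statistics

All statistics operate on log-transformed expression values. The fold
change of gene $g$ is the difference of cohort means on the natural-log
scale,

$$\mathrm{fc}_g = \bar{x}^{\mathrm{trt}}_g - \bar{x}^{\mathrm{ctl}}_g,$$

so a value of $0.41 \approx \ln 1.5$ corresponds to a 1.5-fold change.
Significance per gene comes from a two-sided two-sample t-test —
pooled-variance Student's by default (`compute_fc(var_equal = TRUE)`),
Welch by flag — and q-values from Benjamini–Hochberg adjustment across
all genes. A gene is called differentially expressed when
$q \le 0.05$ and $|\mathrm{fc}| \ge 0.41$ (`deg_criteria()`); both
thresholds are tunable, and `log_base` rescales the effect threshold
when fold changes arrive in another base. The mean-log-difference fold
change is the package's single effect measure; externally computed
effect estimates (for example bootstrap-based regression betas from a
transcript-abundance workflow) can be injected through the `fc_table()`
constructor and flow through scoring unchanged.

### The AAFC score and its permutation null

The activation score of a module $M$ is the aggregate absolute fold
change over its measured member genes,

$$S_M = \sum_{g \in M} |\mathrm{fc}_g|.$$

The score is sign-invariant by construction — a module whose genes move
coherently down scores as highly as one whose genes move up — which is
the behaviour wanted for injury detection, where direction varies by
phenotype. "Aggregate" is read as the *sum* of absolute values; a mean
variant is available (`summarise = "mean"`), and the two give identical
z-scores at fixed module size because standardisation absorbs the
constant factor.

Significance of $S_M$ is assessed against a permutation null: $B$ gene
sets of the same size are drawn uniformly **without replacement** from
all measured genes and scored identically ($B$ = 10,000 by default,
following standard gene-set permutation practice; sampling gene labels
rather than resampling FC values with replacement keeps each draw a
plausible gene set). Writing $\mu_0$ and $\sigma_0$ for the mean and
standard deviation of the null draws,

$$z_M = \frac{S_M - \mu_0}{\sigma_0}, \qquad
  p_M = \frac{\#\{S^{(b)} > S_M\} + 1}{B + 1}.$$

The z-score is the module activation score proper and ranks modules;
the empirical p-value is the add-one-smoothed upper tail, so it is
never exactly zero (its floor is $1/(B+1)$, e.g. $10^{-4}$ at
$B = 10{,}000$). On universes small enough to enumerate,
`permutation_null(exhaustive = TRUE)` replaces sampling with the exact
null over all $\binom{n}{k}$ subsets; the stored $\sigma_0$ is the
population standard deviation in both modes so the two agree in the
limit.

### Fisher's combined probability

A high AAFC score built from noisy fold changes means little. As a
reliability indicator, the member genes' t-test p-values are combined
with Fisher's method,

$$X = -2 \sum_{i=1}^{k} \ln p_i \sim \chi^2_{2k}
  \quad \text{under the joint null},$$

and the combined p-value is the upper tail of that chi-square. Genes
with zero within-cohort variance have no valid t-test; they keep their
fold change (the AAFC needs only fc) but are excluded from the Fisher
combination, and an all-excluded module errors rather than fabricating
a value. A literal zero p-value is clamped to the smallest positive
double with a warning.

### The significance convention

A module is called **significantly activated** when

* its activation p-value is below $\alpha = 0.05$, *and*
* its Fisher combined value is below $0.01$.

Activation is one-sided: only the upper tail counts, so a strongly
*suppressed* module (negative z) is never flagged, however reliable its
member p-values. When only a z-score is available (no stored
permutation draws), `classify_module()` substitutes the normal upper
tail, which places the activation cutoff at $z > 1.645$; this
reproduces published usage in which z = 1.6 with an overwhelming
Fisher value is not called significant while z = 2.1 is. The
correlation layer likewise uses z-scores, not raw AAFC values, as the
module-level quantity compared across systems, because z is the
size-standardised "activation" and raw sums are not comparable across
modules of different size.

## Tunable parameters

| parameter | default | where | meaning |
|---|---|---|---|
| `q_max` | 0.05 | `deg_criteria()` | BH-adjusted p-value ceiling for DEGs |
| `effect_min` | 0.41 | `deg_criteria()` | minimum \|ln fold change\| (= ln 1.5) |
| `B` | 10,000 | `permutation_null()` | permutation draws per module |
| `alpha` | 0.05 | `score_all_modules()` | activation p-value threshold |
| `fisher_max` | 0.01 | `score_all_modules()` | Fisher combined threshold |
| `min_coverage` | 0.3 | `score_all_modules()` | below this measured fraction a module is flagged low-coverage (still scored; the published method states no floor, so the flag warns rather than filters) |
| `var_equal` | TRUE | `compute_fc()` | pooled Student's t vs. Welch |
| `summarise` | "sum" | scoring functions | AAFC aggregate (sum vs. mean) |

## Randomness and reproducibility

Every stochastic function takes an explicit seed and restores the
caller's RNG state afterwards. `score_all_modules()` derives a
deterministic substream per module by hashing the module name into the
root seed, so per-module results are independent of the order of
modules in the collection, and adding a module never changes the
others' results. The pipeline runner records the config hash, every
file's MD5 checksum and the seeds used in `manifest.json`; rerunning
with the same config and seed reproduces every artifact checksum for
checksum, and unchanged stages are skipped on in-place reruns.

## The synthetic-data generator

`generate_experiment()` emulates the study design the scoring stage
expects: two cohorts of `n_per_cohort` samples (default 5, the common
design for this kind of exposure experiment), `n_genes` genes with
independent Gaussian noise of standard deviation `noise_sd` on the log
scale (default 0.5 around a baseline of 5), and a panel of modules of
which some carry an implanted log fold-change effect. Treatment
samples of a gene in a module with effect $e$ have their mean shifted
by $+e$ or $-e$, with `direction_mix` (default 0.5) controlling the
up/down split — a balanced split deliberately exercises the AAFC
score's sign invariance. Gaussian log-scale noise is the right level
of realism here because every downstream statistic consumes
log-transformed values only; a count-level layer would add cost
without touching any code path being tested. Module names and injury
classes ship as fixtures for the canonical 11-module liver and
8-module kidney panels (`injury_module_panel()`), with the liver panel
splitting 4/3/4 and the kidney panel 3/1/4 across
inflammation/proliferation/degeneration.

`generate_multi_system()` creates ortholog-linked experiments for two
or more systems. Per module $j$ and system $s$ the implanted signed
effect is

$$e_{js} = \text{scale}_j \cdot
  \left(\rho\, z_j + \sqrt{1 - \rho^2}\, \varepsilon_{js}\right),$$

with $z_j$ shared across systems and $\varepsilon_{js}$ idiosyncratic
standard-normal loadings, so the implanted effect vectors of any two
systems have expected correlation exactly $\rho$
(`shared_effect_correlation`): $\rho = 1$ gives identical injuries,
$\rho = 0$ independent ones. Gene identity is linked by position under
per-system identifier prefixes (`HS_G000001` vs. `RN_G000001`), which
forces every cross-system operation through an explicit ortholog map —
accidental name collisions cannot silently stand in for orthology. The
emitted map covers `ortholog_fraction` of gene positions for every
unordered system pair.

What the generator does **not** emulate: count-level sampling noise
and library-size variation, correlated co-expression within modules,
many-to-many orthology, batch effects, and dose–time response
structure. Passing tests on synthetic data therefore demonstrate that
the statistics are correct and calibrated under the stated noise
model, not that any particular biological dataset will show
concordance; on real data the within-module correlation the generator
omits widens the permutation null relative to independence, which is
exactly why the method estimates the null from the observed
fold-change universe rather than assuming one.

## Numerical choices and degenerate inputs

* Null `sd` is the population (divide-by-n) standard deviation, so
  exhaustive and sampled nulls estimate the same quantity.
* A degenerate null (set size = universe, sd 0) leaves z as flagged-NA
  but still reports the smoothed p-value.
* Zero-variance genes: fc kept, t-test NA with a `zero_var` flag,
  excluded from Fisher.
* BH adjustment propagates NA p-values untouched and never reorders
  output.
* Ortholog resolution defaults to one-to-one with a lexicographic
  tie-break (deterministic, and reported via `n_collapsed`); `any`
  keeps the full image.
* Expected DEG overlap uses the independence model: pairwise
  $|A||B|/N$ (the hypergeometric mean) and $|A||B||C|/N^2$ for the
  triple region.
* Activation-vector correlation requires at least 3 modules, identical
  module ordering, and non-zero variance; its p-value is one-sided for
  *positive* correlation, since concordance — not anti-concordance —
  is the scientific claim.
* Condition PCA centres features and does not scale by default:
  module z-scores are already standardised, and gene-FC profiles keep
  their natural magnitudes; `standardize = TRUE` is available.
  Rank-deficient input yields trailing zero-variance components.

## Validation problem sizes

The test-suite and the acceptance script validate the statistics at
sizes chosen to give tight Monte-Carlo bands at desk scale: 2,000-gene
experiments with n = 5 per cohort; 20,000 null module scorings (1,000
datasets × 20 modules, one shared permutation null per dataset — valid
because the null depends only on the fold-change universe and set
size) for calibration; 100 simulation seeds for power (implanted
effect 1.0 ln-units, module size 50, noise sd 0.5) and for
cross-system concordance (11 modules, effect scale 1.0, ρ ∈ {0, 1}).
Permutation counts in these simulation studies are reduced to
400–1,000 draws, which changes z-scores negligibly (the null mean's
standard error scales as $\sigma_0/\sqrt{B}$); the package default
stays at 10,000.

## Known limitations

* Module memberships are user-supplied or synthetic; deriving injury
  modules from histopathology-anchored co-expression is outside this
  package's scope.
* The per-gene test is an ordinary two-sample t-test on log values; no
  shrinkage of variances across genes, no count-model dispersion, no
  bootstrap abundance uncertainty.
* Fisher's method assumes independent member p-values; co-expressed
  modules violate this, which is why the Fisher value is used as a
  reliability *indicator* gating the permutation call rather than as
  the activation test itself.
* The expected-overlap model assumes uniform independent sampling of
  DEGs from the universe.
* Condition metadata (dose, time, system) is free-text and not
  validated or harmonised.

## A worked example

```{r example}
panel <- injury_module_panel("liver")
specs <- lapply(seq_len(nrow(panel)), function(i)
  module_spec(panel$module[i], size = 30,
              effect = if (panel$module[i] %in%
                           c("Cellular infiltration",
                             "Bile duct proliferation")) 0.8 else 0,
              class = panel$class[i]))
sim <- generate_experiment(simulation_config(2000, modules = specs,
                                             seed = 101))
fc <- compute_fc(sim$experiment)
degs <- call_degs(fc)
nrow(degs)

coll <- module_collection(lapply(names(sim$truth$members), function(nm)
  list(name = nm, class = panel$class[match(nm, panel$module)],
       genes = sim$truth$members[[nm]])))
scores <- score_all_modules(fc, coll, B = 2000, seed = 7)
scores[, c("module", "class", "z", "p_perm", "fisher_p", "significant")]
```

The two implanted modules top the ranking and are the only significant
calls, while the nine null modules scatter around z = 0 with Fisher
values far above threshold. Note that `nrow(degs)` is 0: at this
effect size and cohort size not a single gene survives FDR correction
on its own, yet the module statistics call both injured programmes at
the smoothing floor $p = 1/2001$. That contrast — per-gene analysis
blind, module analysis decisive — is the reason the module is the unit
of analysis.
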