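---
title: "Weighted summarization of shared peptides in TMT proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted summarization of shared peptides in TMT proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sharedpep)
```

## The problem

Bottom-up proteomics quantifies peptides, not proteins. When a peptide's
sequence occurs in several proteins (homologs, isoforms, proteoforms), its
reporter-ion intensities carry a mixture of signals and the standard
summarization strategies force a bad choice: *exclusion* discards the shared
peptides (losing proteins identified mostly or only by them), *inclusion*
assigns them fully to every match (biasing every summary toward the cluster
average), and *parsimony* groups proteins under composite labels that are
awkward to test downstream. The same structure appears in PTM quantification,
where a peptide carrying several modification sites is "shared" among those
sites.

`sharedpep` instead models the quantitative profile of each shared peptide as
a convex combination of the profiles of its candidate proteins, and estimates
the combination weights together with the protein abundances.

## The model

Proteins connected by shared peptides form *protein clusters*: connected
components of the bipartite peptide-protein graph. For one cluster and one
TMT mixture, let $X_{cf}$ denote the log2 intensity of feature (peptide ion)
$f = 1,\dots,F$ in channel $c = 1,\dots,C$, and let $V(f) \subseteq
\{1,\dots,K\}$ be the proteins whose sequence contains feature $f$. The model
is

$$X_{cf} = \mu + \mathrm{Feature}_f + \sum_{k \in V(f)} w_{fk}
\left(\mathrm{Protein}_k + \mathrm{Channel}_{kc}\right) + \varepsilon_{cf},$$

with the usual sum-to-zero constraints
($\sum_f \mathrm{Feature}_f = 0$, $\sum_k \mathrm{Protein}_k = 0$,
$\sum_c \mathrm{Channel}_{kc} = 0$ for every $k$) and simplex constraints on
the weights: $w_{fk} \ge 0$ and $\sum_{k \in V(f)} w_{fk} = 1$. A unique
feature has $w_{fk} = 1$ for its single protein. Each protein keeps its own
channel profile $\mathrm{Channel}_{kc}$, so profiles within a cluster may be
non-parallel. Setting every $w_{fk} = 1/|V(f)|$ reproduces the inclusion
strategy; the estimated weights instead apportion each shared peptide
according to how well its shape matches each candidate's profile. The
protein-level summary reported for protein $k$ in channel $c$ is
$\hat Y_{kc} = \hat\mu + \widehat{\mathrm{Protein}}_k +
\widehat{\mathrm{Channel}}_{kc}$.

No distributional assumption is placed on $\varepsilon_{cf}$. Parameters are
estimated by minimizing a robust loss of the residuals over all observed
cells; missing intensities are simply omitted (no imputation).

### The loss and the threshold `M`

The default loss is the smooth Huber loss

$$L_H(x, M) = \begin{cases} x^2 & |x| < M \\ 2M|x| - M^2 & |x| \ge M,
\end{cases}$$

quadratic near zero and linear in the tails. `M` (log2 units) controls the
transition: with a small `M` nearly every residual sits in the linear zone
and the fit behaves like a robust L1 fit while remaining differentiable. The
package default is `M = 1e-3`; `1e-6` is a common alternative for data with
heavier contamination. Plain `l2` and `l1` losses are available;
`l1` is exposed for completeness but its non-differentiability can destabilize
the alternating optimization, which is precisely why the smooth Huber loss
with small `M` is the default.

### Identifiability and the attribution convention

Two facts about this model shape the implementation and deserve to be stated
plainly.

First, the split of a feature's *level* between $\mu$, its feature effect and
the weighted protein term is not determined by the loss: the term
$\sum_k w_{fk}\mathrm{Protein}_k$ is a function of $f$ only and can be
absorbed exactly into $\mu + \mathrm{Feature}_f$ even under the sum-to-zero
constraints (for $K$ proteins there are $K - 1$ such flat directions).
Channel *shapes* and therefore all fold changes are unaffected. The package
resolves the split with an explicit convention: the protein effects are the
sum-to-zero-constrained least-squares attribution of the per-feature levels
to the membership-weight columns — equivalently, the decomposition with
minimum feature-effect norm. When a cluster decouples (all weights 0/1) this
reduces to fitting each protein separately, which is the natural answer. The
simulation generator draws its feature effects in the same canonical
position, so generated parameters are exactly recoverable at zero noise.

Second, the weights of a shared feature are informative only insofar as the
candidate proteins' channel *shapes* differ. If two proteins' profiles differ
only by a vertical shift, the objective is flat in the feature's weights; the
fit then keeps the previous iterate (ultimately the uniform initialization)
rather than letting a solver pick an arbitrary vertex. This is a documented
tie rule, not an error: such weights are genuinely unidentifiable.

## Optimization

Given the weights, the model is linear in $(\mu, \mathrm{Feature},
\mathrm{Channel})$; given the profiles, each shared feature's weights solve
an independent small convex problem. The fit alternates the two convex
subproblems (alternating convex search):

1. **Initialization.** Per-protein profiles from a Tukey median polish of
   each protein's unique features. Proteins without unique features fall back
   to the profile of a uniform-weight inclusion fit and are flagged; a
   cluster in which *no* protein has unique features is additionally flagged
   as unidentifiable.
2. **Weight step.** For each shared feature, the simplex-constrained robust
   fit of its residual profile to the candidate profiles. The feature's own
   additive effect is profiled out (re-estimated as the robust location of
   the residuals at each candidate weight). Profiling keeps the per-feature
   problem jointly convex in (weight, feature effect) and lets boundary
   solutions (weights exactly 0 or 1) be reached in one step; holding the
   feature effect fixed instead couples the steps through a stale offset and
   slows convergence to a crawl on realistic clusters. Two-candidate
   features are solved by golden-section search on $[0,1]$ with a boundary
   polish; larger membership sets by a barrier method started from the
   previous iterate. A step is accepted only if it improves the objective,
   which doubles as the tie rule above.
3. **Profile step.** Iteratively reweighted least squares (IRLS) for the
   Huber loss on a reduced (sum-contrast) design, so all sum-to-zero
   constraints hold by construction. IRLS for the Huber loss is a
   majorize-minimize scheme, so each inner iteration decreases the
   objective; the inner loop is capped (30 iterations, warm-started from the
   previous outer iteration) without endangering the monotonicity of the
   outer loop. Proteins whose total incident weight is numerically zero are
   not estimable; their effects are carried over from the initialization and
   flagged.

Both half-steps minimize the same joint objective over a block of
parameters, so the objective is non-increasing along the iterations (this is
asserted in the test suite). The loop stops when the largest absolute weight
change drops below `weight_tol` (default `1e-3`), or — because weights of
shape-indistinguishable features can wander indefinitely in flat directions
— when the relative objective decrease stays below `obj_tol` (default
`1e-6`) for two consecutive iterations, or after `max_iter` (default 100)
iterations. Convergence status, iteration count and the final weight change
are recorded with every fit.

Single-protein ("trivial") clusters bypass the weighted machinery in the
high-level pipeline and are summarized by the median-polish baseline, which
is also what the `unique` and `all` comparison methods use.

## Preprocessing rules

`annotate_peptides()` re-annotates each peptide with every database protein
containing its (modification-stripped) sequence. `merge_indistinguishable()`
collapses proteins identified by identical peptide sets into one unit whose
label is the `;`-joined sorted accessions — such proteins cannot be told
apart by any method. `filter_shared_only()` removes *subset proteins* (no
unique peptide); because a removal can turn another protein's shared peptide
unique, the rule is iterated to a fixed point, after which every retained
protein has at least one unique feature. Retaining subset proteins
(`keep_subset = TRUE`) is appropriate for designs where sharing is pervasive
and removal would discard too much data; a separate, explicit
`min_unique` count filter is also available, since a minimum-evidence rule is
a different decision from the subset rule. By default no normalization is
applied; `normalize_reference_channel()` offers optional median centering
against a designated reference channel for multi-mixture experiments.

## Differential abundance

Summaries feed a per-protein linear model of condition (or condition-time
cell) means; multi-mixture designs add the mixture as a *fixed* additive
blocking effect. This is a deliberate simplification of the conventional
random-mixture-intercept formulation: in the balanced designs this package
targets, contrast estimates coincide, while variance-component estimation
(REML, Satterthwaite degrees of freedom) is avoided; degrees of freedom are
the residual degrees of freedom of the fixed-effects fit. The function
signature keeps the design argument separate so a random-intercept backend
can be slotted in later. Contrasts of condition means give the log2 fold
change, its standard error, and a two-sided t-test; a standard error below
`1e-10` is flagged degenerate (p forced to 0 or 1) rather than producing an
unstable t statistic. P-values are adjusted per contrast across proteins by
Benjamini-Hochberg. Not-estimable (protein, contrast) pairs are absent rows,
never `NaN`s.

## PTM site occupancy

`expand_sites()` maps modified peptides to site units labeled
`<accession>/<site>` (1-based residue coordinates, e.g. `E9Q6J5/S236`), so a
singly-modified peptide is a unique feature of its site and a multi-site
peptide is a shared feature of all its sites; no concatenated multi-site
labels are created, and site clusters cannot span proteins by construction.
The weighted core then runs unchanged with sites in the role of proteins.
`adjusted_test()` compares the site's change to the unmodified protein's
change: the adjusted estimate is the difference of log2 fold changes, the
standard error adds in quadrature, and the degrees of freedom use the
Satterthwaite combination
$(se_1^2+se_2^2)^2 / (se_1^4/df_1 + se_2^4/df_2)$ — the conventional choice
for a difference of two independent estimates.

## The simulation benchmark

`simulate_cluster()` generates the study conditions used throughout the
tests: a cluster of five proteins in which every pair shares peptides
(5 per pair by default), two unique peptides per protein, five conditions
with two biological replicates each (one TMT channel per sample, one
mixture), and i.i.d. normal feature-level noise with sd 0.2 log2 units.
Three of the five proteins are differentially abundant, with effects 0.5,
1.0, 1.5, 2.0 across the non-reference conditions (signs +, −, + so that the
changed proteins do not all move together); the remaining two are null.
Shared peptides belong wholly to one protein of their pair (alternating) by
default, with uniform and random-weight schemes available. Protein-level
channel values are built deterministically from the condition means; an
optional replicate-level error (`biorep_sd`) adds biological variation when
nonzero, but the default keeps the feature-level sd as the single noise
source so that zero-noise configurations are exactly recoverable. Feature
effects are drawn i.i.d. normal (sd 0.5) and placed in the canonical
position described above.

What the generator emulates: the peptide-sharing topology, non-parallel
protein profiles, robust-loss-relevant contamination (via explicit outlier
injection in tests), and the group-comparison design with a reference
condition. What it does not emulate: intensity-dependent (heteroscedastic)
noise, missingness mechanisms correlated with abundance, reporter-ion ratio
compression, co-isolation interference, or between-mixture effects.
Conclusions from passing tests are therefore about the estimation machinery,
not about those instrument-level artifacts.

`run_benchmark()` simulates independent replicates (each method sees
identical data; replicate $i$ uses seed $s + i$), summarizes with the
weighted, unique-only and all-peptides (naive inclusion, per-protein median
polish over all matching features) methods, tests every protein against the
reference condition, and scores: sensitivity and specificity at unadjusted
$p < 0.05$ (unadjusted so that the operating point does not depend on the
differing numbers of tests between methods), and MSE/bias of the estimated
log2 fold changes against the truth. `resample_unique()` supports the
peptide-resampling design (keep a random subset of unique peptides and all
shared ones, optionally forcing one pick from the "noisy pool" — the three
unique peptides least correlated with their protein's others), and
`mse_against_reference()` scores such resampling runs against the
all-unique-peptides estimate.

Problem sizes used by the automated checks: 100 random small clusters for
the constraint suite; 20 seeds for weight recovery at noise sd 0.05;
20 benchmark replicates for the bias/variance and sensitivity/specificity
comparisons; 25 null replicates (500 protein-level tests) for type-I
calibration. These sizes give the directional comparisons comfortable
Monte-Carlo margins while keeping a full run of the suite in the
ten-minute range on a laptop.

## Numerical choices worth knowing

* **Oracle checks and flat optima.** At `M = 1e-3` almost all residuals are
  in the linear zone and the two-way robust fit's minimizer is a flat
  polytope: independent solvers agree on the objective to ten significant
  digits yet can return summaries differing by ~0.1. Solver-equivalence
  tests therefore run in the well-posed regime (inlier noise inside the
  quadratic zone, `M = 0.05`, gross outliers in the linear zone), where
  agreement is ~1e-8, and the default-`M` case is checked by objective
  equality.
* **Weight-solver boundary behavior.** Golden-section search never lands
  exactly on 0 or 1, so both vertices are evaluated explicitly and taken
  when optimal; barrier solutions within 1e-6 of a vertex are snapped when
  that does not worsen the objective. Exact 0/1 weights matter because they
  decouple the cluster cleanly.
* **Degenerate inputs.** All-missing rows/columns are excluded from the
  median polish with a warning; features observed in no channel keep their
  previous weights; clusters left empty by filtering are excluded and
  reported; zero-residual model fits are flagged degenerate in testing
  rather than dividing by a zero standard error.
* **Per-mixture independence.** Each mixture is fitted separately and
  weights are not pooled across mixtures; a peptide may legitimately
  receive different weights in different mixtures.

## Limitations

Absolute per-protein levels rest on the attribution convention above —
between-protein comparisons of absolute summaries are not meaningful (they
never are in relative quantification). Weight uncertainty is not quantified;
the convergence record and the flatness tie rule are qualitative guides.
The differential module does not implement variance moderation or
random-effect mixtures. Label-free data, with its far heavier missingness,
is out of scope.
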