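---
title: "Modeling tissue-specific competition at the Ras signaling hub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tissue-specific competition at the Ras signaling hub}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raswiring)
```

## The model

Active, GTP-loaded Ras binds the Ras-binding domain (RBD) of its effector
proteins in a mutually exclusive way: one Ras molecule carries one effector.
When the summed abundance of effectors exceeds the pool of active Ras — as
it does in healthy tissue at a ~20 % GTP load — effectors compete for a
limiting hub, and the spectrum of Ras–effector complexes (the "wiring" of
the hub) is decided jointly by each effector's abundance and its
dissociation constant.

For a panel of effectors $E_i$ with totals $E_{iT}$ and constants $K_{d_i}$,
the reactions $R + E_i \leftrightarrow RE_i$ at steady state give
$RE_i = R\,E_i / K_{d_i}$, and mass conservation per effector yields
$RE_i = R\,E_{iT}/(K_{d_i} + R)$. Substituting into Ras conservation leaves
a single scalar equation in the free active Ras $R$:

$$f(R) \;=\; R + \sum_i \frac{R\,E_{iT}}{K_{d_i} + R} - R_T \;=\; 0 .$$

$f$ is strictly increasing with $f(0) = -R_T \le 0$ and $f(R_T) \ge 0$, so
the equilibrium is unique and bracketed. `solve_equilibrium()` finds it by
bracketed root finding (`uniroot`) followed by a damped Newton polish, which
pushes the conservation residuals to machine precision (the package
hard-fails any solve whose relative residual exceeds 1e-9). The same
steady state can be reached by integrating the mass-action ODE system;
`ode_steady_state()` does exactly that (shared association rate $k_{on}$,
$k_{off} = K_d\,k_{on}$ — only the ratio is observable at equilibrium) and
serves as the independent cross-check in the test-suite. It is never used
in the analyses themselves: root finding is deterministic, provably
convergent and thousands of times faster.

The three isoforms HRAS, KRAS and NRAS are pooled into one active species:
each effector is assigned a single $K_d$ across isoforms, which makes the
explicit 3-isoform model algebraically identical to the pooled one, and
complexes are attributed to isoforms afterwards in proportion to their
active abundances (`isoform_split()`). Percentages are normalized after
pooling; the split is purely proportional and does not re-enter the
normalization.

### Units and degenerate inputs

Everything internal is in nM; $K_d$ enters files and function arguments in
µM (as affinities are usually reported) and is converted once at the
boundary. Effectors with zero abundance are retained with exactly zero
complex, so their sensitivities are exactly 0; zero active Ras produces an
all-zero state (with a warning for the undefined percentages), not an
error. Rankings sort by descending share with ties broken by name, so they
are reproducible.

## Receptor-mediated (piggyback) recruitment

A stimulated transmembrane receptor $Y$ binds selected effectors through a
secondary domain (SH2 for the EGF receptors EGFR+ErbB2; PDZ for the
nectin-3 receptor), concentrating them at the membrane where Ras sits.
The reaction set per targeted effector adds
$Y + E_j \leftrightarrow YE_j$ (constant $K_{YE}$, default 1 µM) and
$R + YE_j \leftrightarrow RYE_j$ with $K_{RYE} = K_{d_j}/\alpha$, the
recruitment raising the effective Ras affinity by $\alpha \approx 100$.
The fourth edge of the thermodynamic cycle ($Y + RE_j \leftrightarrow
RYE_j$, constant $K_{YE}/\alpha$) is implied by cycle closure and holds
exactly by construction.

Given the free receptor concentrations, each targeted effector's bound
fraction collapses to a Langmuir term with an effective
$K_d^{\mathrm{eff}} = (1 + \sum_s Y_s/K_{YE,s}) / (1/K_{d_j} + \sum_s
Y_s/(K_{YE,s} K_{RYE,js}))$, so the Ras equation keeps its monotone
one-unknown structure. `solve_piggyback()` therefore iterates an *exact*
scalar re-solve of free Ras against damped (factor 0.5) closed-form updates
of each free receptor from its own conservation equation, stopping when the
free-species vector changes by less than 1e-12 relative. This is a
deliberate strengthening of a plain damped fixed point on all free species
at once: the inner exact solve removes the only non-contractive direction,
and in practice a handful of receptor updates converge. Useful limits, all
tested: zero receptor reproduces the base model; $\alpha = 1$ leaves the
summed Ras–effector complexes exactly at base values (the receptor then
only shuttles effector); saturating receptor abundance approaches a base
solve with $K_d/\alpha$.

Fold factors compare stimulated (90 % GTP + recruitment) against the
unstimulated reference (20 % GTP, no recruitment) on nM complexes,
per effector or per class (class ratio = ratio of class sums), with an
explicit flag for the unbounded 0 → positive case.

## Kd sensitivity analyses

Both analyses are one-at-a-time: one affinity moves, all others stay at
reference. A factorial design over 56 parameters would be uninterpretable
at this model's scale, and the one-at-a-time reading — "what if this one
measured affinity is off" — matches how the $K_d$ inputs are actually
uncertain.

* **Local** (`local_sensitivity()`): re-solves at $0.9\,K_d$ and
  $1.1\,K_d$, reporting the absolute change of the effector's share
  (percentage points), the nM change, and the finite-difference ratio
  $\Delta C / \Delta K_d$.
* **Global** (`global_sweep()`): evaluates the share over
  `kd_grid()` — 81 evenly spaced points from 0.04 to 39 µM (step ≈ 0.487),
  chosen so the first, steepest interval is exactly [0.04, 0.527] µM. The
  summary $\Delta C$ is the drop over that first interval; the full curve
  is returned. Curves are monotone non-increasing in $K_d$ and flatten
  beyond ~10 µM, which is what makes the low-affinity region robust.
  The heatmap-style summary uses the absolute change; signs are available
  in the curve output.

## Mutant rewiring and the sweet-spot fit

An oncogenic mutation is modeled as a GTP-load change only: the mutated
isoform's active fraction is set to the mutant level (1.0 for a fully
active mutant; 0.5–1.5 spans single-allele to copy-number scenarios) while
the other two isoforms stay at 0.20, and effector abundances are held at
reference. The rewiring score is the ratio of total complexes, mutant over
wild type, so RS = 1 means no rewiring and the score is invariant to a
pure change of concentration units.

Mutation frequencies (consumed as a per-tissue, per-isoform table) are
related to RS through a three-parameter Gaussian
$freq = A \exp(-(rs-\mu)^2/2\sigma^2)$ — the "sweet spot" hypothesis that
intermediate rewiring is most tumorigenic. `fit_sweet_spot()` uses
unweighted Levenberg–Marquardt least squares with a deterministic start
($\mu_0$ = frequency-weighted mean, $\sigma_0$ = weighted sd bounded away
from 0, $A_0$ = max frequency), which recovers noiseless synthetic
parameters to better than 1e-6 and keeps replicate fits reproducible.
Fits exclude the nine tissues rarely associated with cancer (appendix,
fat, heart, fallopian tube, placenta, smooth muscle, small intestine,
spleen, tonsil); the PanRas fit pools all isoform-specific points, and
isoform-specific fits are independent three-parameter fits.

## Determinants of complex formation

At any solved equilibrium, effectors sharing a $K_d$ lie exactly on a line
through the origin in the (abundance, share) plane with slope
$100\,R^*/((K_d + R^*)\,C_{tot})$ — the analytic identity every fitted
slope is checked against. Groups use exact $K_d$ equality (that is what
makes the line exact); the printed µM interval bins ([0.04, 0.09],
[0.21, 1], [2.9, 50]) are reporting conveniences only. Singletons get the
two-point line through the origin and their own point, skipped below a
0.001 % share where the line would be numerical noise (the threshold is an
argument). Multi-effector groups are fit by OLS, which on exact data
recovers the identity with zero intercept. The landscape "surface" is a
piecewise-linear evaluation of these lines on an abundance grid — an
interpolation artifact for plotting, not a model object.

Key effectors are those holding ≥ 5 % (inclusive) of all complexes in at
least one tissue at the reference scenario.

## Effector classification

Group 1: reaches a 5 % share in some tissue unstimulated (20 % GTP,
reference $K_d$) — efficient binding through the RBD alone. Group 2:
reaches it only in the enhanced condition — operationalized as every $K_d$
divided by the piggyback factor 100 at a 90 % GTP load, i.e. the
global-sensitivity/stimulated regime; these are the effectors that need
membrane recruitment. Group 3: reaches it in neither. The rule keys
purely on the threshold outcomes; recruitment-domain annotations are
carried as evidence, not as a gate, since a domain list cannot tell how
strongly a domain is engaged in a given tissue.

## Tissue composition

For each of six basic subtypes (epithelial, muscle, adipose, neuronal,
connective, lymphoid), the three markers with the highest mean expression
across tissues are selected (ties by name), averaged per tissue into a
subtype score, and scores are normalized to percentages per tissue. Mean
(not max) ranking is the default — max would let one outlier tissue pick
the marker — and both are exposed. Only the lymphoid trio (PTPRC, CD68,
CD19) is literature-anchored; the shipped marker file is otherwise a
synthetic stand-in of canonical markers and is labelled as such.

## The synthetic generator

`synthesis_config()` fixes the study conditions; all draws run under a
private RNG stream derived from one integer seed, so outputs are
bit-reproducible and the caller's RNG state is untouched.

* **Panel**: the real 56 effector names, 12-class structure and SH2/PDZ
  recruitment tags ship as a fixture; $K_d$ anchors (ARAF 0.07, MLLT4
  3.03, SNX27 10, PIK3CD/ARAP1/RADIL/MYO9A 7.5 µM) are fixed regardless of
  seed, the remaining values sampled log-uniformly over 0.04–39 µM with a
  quarter of effectors below 1 µM — roughly the observed share of
  high-affinity RBDs.
* **Tissues**: log-normal effector abundances (log-mean log 30 nM, log-sd
  1.0, spanning the ~50-fold cross-tissue variation seen for individual
  complexes); KRAS-dominant isoform totals except a pancreas-like tissue
  with equal thirds; receptor abundances log-uniform over 5–200 nM; and an
  enforced competitive regime (summed effectors > active Ras at 20 % GTP),
  which real tissues satisfy.
* **Mutation frequencies**: drawn from a known Gaussian of the rewiring
  score (defaults $A = 30$, $\mu = 2.0$, $\sigma = 0.3$ — an amplitude and
  sweet-spot location of realistic magnitude) plus Gaussian noise (sd 5 %
  of $A$), truncated at zero, with the truth recorded for recovery tests.

What the generator does *not* emulate: the actual measured proteome values,
correlations between effector abundances, tissue-specific receptor biology,
or the real per-tissue mutation frequencies. Tests passing on synthetic
data therefore demonstrate the correctness of the machinery (solvers,
conservation, fits, classifications) and the qualitative phenomenology
(competition, KRAS leverage outside the pancreas-like tissue, targeted
classes rising most under stimulation) — not agreement with any particular
measured tissue's numbers.

## Problem sizes and numerical choices

The shipped analyses and tests run 29 tissues × 56 effectors; solver
cross-checks use 500 random panels of ≤ 10 effectors against ODE
integration (rtol/atol 1e-12, horizon doubling until the largest relative
derivative falls below 1e-10); Gaussian recovery uses 200 replicate fits.
Root finding uses relative tolerance 1e-12 with a 200-iteration cap;
piggyback iteration caps at 1e5 updates. These sizes keep every stage
deterministic and fast while exercising all code paths.

## Known limitations

Steady state only: no GDP/GTP cycling, GEF/GAP dynamics, receptor
activation kinetics, or time courses. One shared $K_d$ per effector across
isoforms (isoform-specific affinities would break the pooling identity).
Mutant scenarios change GTP load only, not expression. The classification
threshold (5 %) and the singleton cutoff (0.001 %) are conventions, exposed
as arguments. Undetected-protein imputation, clustering of effector
classes, and cancer-study curation are out of scope; mutation frequencies
are taken as given.
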