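---
title: "Transparent intrinsic-solubility models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transparent intrinsic-solubility models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soluphi)
```

## The problem and the model family

Intrinsic aqueous solubility, log *S*₀ (log10 molar, neutral species), is a
gatekeeper property in drug discovery. This package implements a family of
transparent models whose accuracy on drug-like chemical space approaches
that of machine-learning regressors while remaining a one-line equation:

* **GSE(classic)**: log *S*₀ = 0.5 − clog *P* − 0.01(mp − 25). Thermodynamically
  motivated (lipophilicity drives transfer out of water, the melting term
  proxies the crystal-lattice penalty), pre-trained, but weak for polar,
  zwitterionic or flexible molecules.
* **ABSOLV(GRP)**: the Abraham solvation LFER, log *S*₀ = a₀ + a₁A + a₂B +
  a₃S_π + a₄E + a₅V + a₆A·B, refit within six groups — acids, bases,
  zwitterions, neutrals (net charge at pH 7.4), big molecules
  (MW > 800 Da), and quaternaries. Grouping removes most of the method's
  bias; the A·B cross term is applied in all six groups.
* **GSE(Φ,B)**: the flexible-acceptor generalization. The three classic
  constants become smooth functions of x = Φ + B (Kier flexibility plus
  H-bond basicity): c₀ decays exponentially from 1.593 toward −4.456, c₁
  rises from −1.326 toward −0.268 (lipophilicity matters less for flexible
  acceptors), and c₂ is a gently rising line near the classic −0.01 per
  degree (the melting term here is scaled (mp − 25)/100). Liquids and
  low-melting solids (mp ≤ 25 °C) pay no melting penalty in either GSE
  variant.
* **Consensus** = mean of ABSOLV(GRP) and GSE(Φ,B); plus two selectors
  (below).

## The flexibility descriptor

Φ = ¹κ·²κ/N_HA from the Hall–Kier kappa shape indices of the
hydrogen-suppressed skeleton: ¹κ = A(A−1)²/P₁², ²κ = (A−1)(A−2)²/P₂², with
A heavy atoms and P_m simple paths of m bonds. Bond orders and aromaticity
do not enter the path counts. With `alpha_modified = TRUE` (the default) A
and P are shifted by the Hall–Kier α sum, which corrects each atom for
covalent radius and hybridization relative to sp³ carbon; this matches the
descriptor toolkits used in practice (our per-atom α table and the
conjugation-aware hybridization perception were validated atom-for-atom
against RDKit on a frozen reference set, including large drugs). The
unmodified variant is retained because it has clean closed forms (an
unbranched chain of A atoms has Φ = A − 1 exactly) on which the tests rest.
Φ is undefined below 3 heavy atoms; such records report `NA` and the
selectors fall back to the classic equation, which is the sensible model
for tiny rigid molecules. Multi-fragment SMILES (salts) keep the largest
fragment, since intrinsic solubility refers to the neutral parent.

The SMILES parser is hand-written (no cheminformatics package is assumed):
organic-subset and bracket atoms, branches, ring closures including `%nn`,
aromatic lower-case forms, directional bonds read as single, stereo and
isotope tokens accepted and ignored — none of which affect a topological
index.

## Selectors

Profiling prediction error across a large database, binned on Φ, shows the
classic equation winning only at the very rigid end (Φ < 1.66), the
flexible-acceptor model winning beyond Φ > 10.83, and the middle domain
flip-flopping between ABSOLV(GRP) and GSE(Φ,B) — "exclusive-or" behaviour.
`xor_select()` encodes this as a partition of [0, ∞): the published
per-bin winners are looked up between the two thresholds, with interval
edges at midpoints between consecutive bin-average Φ values (the raw
database is not public, so midpoints are the deterministic reconstruction).
We adopt the textual crossover 1.66 rather than the 1.95 that appears in
one figure caption of the source work; the two disagree and the text value
is used consistently there. Because bin winners are database-dependent,
`recommended_select()` is the prudent default: Consensus below Φ = 11
(boundary exclusive), GSE(Φ,B) above.

`closest_prediction()` reports, for a measured compound, which model lands
nearest and the signed residual obs − pred (positive = solubility
underestimated); ties break toward the first-listed model.

## Training procedure

`train_flex_acceptor()` reproduces the two-step protocol:

1. records are sorted on Φ + B and split into 20 bins. The source protocol
   says bins of "near-equal values" yet reports near-equal populations;
   equal-count binning is the default (it stabilizes the per-bin
   regressions and matches the reported populations), equal-width is a
   flag.
2. within each bin, ordinary least squares of log *S*₀ on clog *P* and
   (mp − 25)/100 yields (c₀, c₁, c₂). We use OLS where the original used
   PLS: with two near-orthogonal predictors and n ≫ p, full-rank PLS
   converges to OLS, and OLS removes a latent-component count that was
   never stated. Rank-deficient bins (constant clog *P* or melting term)
   raise an error naming the bin.
3. the three coefficient functions are fitted to the per-bin estimates.
   The 8-parameter problem separates into three disjoint sub-fits, so the
   joint least-squares optimum equals the per-curve optima: the two
   exponentials are fitted by `nls` with multi-start over decay rates
   (0.02–0.5), initialized from the curve tails, with a Nelder–Mead
   fallback on the raw objective (tolerance 1e−10); c₂ is an exact OLS
   line. A negative fitted decay rate aborts with a training error rather
   than silently returning a non-decaying "exponential".

`fit_absolv_groups()` fits the seven-term LFER per group by OLS, with an
8-record floor per group; smaller groups are reported unfit rather than
extrapolated. `profile_bins()` computes per-bin RMSE for the three base
models; exact ties crown the flexible-acceptor model first (the model
recommended for flexible space), then ABSOLV(GRP), then classic.

## The synthetic-data generator

`simulate_compounds()` emulates the descriptor table of a large curated
solubility database: independent uniform draws inside the published
marginal ranges (Φ 0.4–43, B 0.4–12.9, clog *P* −5.8–8.7, mp 25–350 °C;
Abraham A, S_π, E, V over typical drug-like spans), charge classes from a
multinomial proportional to the published group sizes
(1578/945/641/4246/93/39), and log *S*₀ = generating-model value +
N(0, σ) with σ = 0.5 by default — about the RMSE transparent models achieve
on drug-like test sets. Draws are made row-by-row from a single stream, so
the first n records are invariant to the total size at a fixed seed.

What it does **not** emulate: real multivariate descriptor correlations
(beyond an optional Φ–MW "comet" link, a linear coupling with jitter),
cluster structure in chemical space, measurement heteroscedasticity, or
real molecular structures (simulated records carry no SMILES). A green
parameter-recovery test therefore establishes correctness of the fitting
machinery under the stated noise model — not predictive accuracy on real
drugs, which only the frozen published coefficients and the printed worked
examples speak to.

Recovery studies use a *stratified* design: `phi_levels = 20` draws Φ from
20 evenly spaced levels (and B is held constant), one level per training
bin. With a continuous key, the coefficient functions vary inside each bin
and per-bin OLS estimates a population-weighted blend — a discretization
bias that does not vanish at zero noise. The discrete design removes that
bias by construction, so zero-noise recovery is exact (the same design as
the noiseless inversion check of the curve fitter) and noisy recovery
isolates estimation error. This was fixed before any acceptance
measurement.

## Metrics

All metrics are validation-type, referenced to the observations:
RMSE = √(Σ(obs−pred)²/n); r² = 1 − SS_res/SS_tot about the observed mean,
hence negative whenever residual variance exceeds observed variance (as
reported for classic models on big-molecule sets); bias = mean(obs − pred),
so overestimated solubility gives negative bias — the source work never
writes the formula, and this sign convention is the one consistent with its
prose; MPP = percentage within ±0.5 log of the identity line, boundary
inclusive ("within" read inclusively; documented so results are
bit-stable). Pairs with a missing member are dropped and counted.

## Numerical and interface choices

* Published coefficient tables are stored to exactly their printed
  precision; predictions are carried at full floating precision and rounded
  to 2 decimals only on CSV output (`full_precision = TRUE` disables this).
* The argument of the coefficient functions is the scalar sum Φ + B
  (the source alternates between "(Φ,B)" notation and "sorted on Φ+B"; the
  sum is the only reading consistent with the training protocol).
* Missing melting point for a non-liquid: GSE-family predictions are
  reported missing, never imputed.
* The charge-class heuristic (carboxylic/sulfonic/phosphonic acid or
  tetrazole → acid; aliphatic amine, amidine, guanidine → base; both →
  zwitterion; permanent N⁺ without an acid → quaternary) is a fallback
  only: a user-supplied `charge_class` always wins, and MW > 800 Da takes
  precedence as `big`.
* CSV I/O is comma-separated UTF-8 with case-insensitive canonical column
  names and a small alias map; the CLI uses exit codes 0/2/3/4 for
  success / input error / config error / training failure.

## Known limitations

* Abraham descriptors are inputs, not computed from structure (the source
  used a commercial program); likewise clog *P* and melting point.
* The charge heuristic knows nothing about pKa; borderline bases
  (anilines, azoles) default to neutral.
* The hand-written SMILES parser targets the common organic dialect; exotic
  valences or polymer notation are out of scope.
* Published per-bin XOR winners are tied to one database; on other data the
  middle-domain rule should be re-derived with `profile_bins()`.
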