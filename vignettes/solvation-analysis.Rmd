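---
title: "Minimum-distance solvation analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum-distance solvation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solvkb)
```

## The problem

Cosolvents such as 2,2,2-trifluoroethanol (TFE) shift the conformational
equilibria of peptides — most famously by stabilizing alpha-helices — and a
mechanistic account requires knowing *where the cosolvent sits* relative to
the solute. solvkb implements the minimum-distance route to that question:
distribution functions over the minimum distance between any solute atom
and any solvent-molecule atom, the Kirkwood-Buff integrals (KBIs) that
summarize them thermodynamically, and the preferential
interaction/hydration parameters that decide whether the cosolvent
accumulates at the solute or is excluded from it. Around that core sit the
diagnostics such a study needs: alpha-helix content from a Kabsch-Sander
hydrogen-bond criterion, geometric hydrogen-bond counting,
block-averaging/autocorrelation error analysis for correlated series, and
the replica-ladder arithmetic of replica exchange with solute tempering
(REST2), which is how such ensembles are sampled in practice.

## Minimum-distance distribution functions

For a solvent species c around a solute p, let $n_c(r)$ be the average
number, per frame, of solvent molecules whose *minimum distance* to the
solute falls in the bin at $r$ (bin width 0.1 Å by default, half-open
bins $[r, r+\Delta)$ from 0). The minimum distance of a molecule is the
minimum over all (solute atom, solvent atom) pairs of the minimum-image
distance; the realizing pair is recorded, with ties broken by lowest
solute then solvent atom index so results are bit-reproducible. The
distribution function is

$$g_{pc}(r) = \frac{n_c(r)}{n^*_c(r)},$$

where $n^*_c(r)$ counts the same quantity in an ideal-gas reference: the
same molecules re-inserted rigidly at uniform random positions and
orientations in the same box, i.e. with solute-solvent interactions
switched off. The reference is recomputed per frame with `nu` = 5
insertions per real molecule (internal geometries are resampled from the
frame, so flexible species would be represented correctly). Bins whose
reference count is zero are flagged undefined rather than reported as 0.
Unlike a radial distribution function, this construction needs no
site-site choice and absorbs the solute's shape into the reference.

Because each minimum-distance event has a realizing atom pair, the MDDF
decomposes exactly: attributing every event to the group containing its
argmin atom (solute side or solvent side) yields contribution curves that
sum, bin by bin and as integer event counts, to the total. The same
attribution by solute *residue*, normalized by the reference under a
uniform per-residue share, gives the residues-by-distance density map
used to read off which residues a cosolvent visits.

## Kirkwood-Buff integrals from counts

With $N_{pc}(R)$ and $N^*_{pc}(R)$ the cumulative observed and reference
counts below $R$,

$$G_{pc}(R) \approx \frac{1}{\rho_c}\left[N_{pc}(R) - N^*_{pc}(R)\right],$$

which converges, once $R$ exceeds the correlated "protein domain", to the
KBI: the excess (or deficit, for excluded volume) of solvent around the
solute, reported in L/mol. Two normalization details matter and are the
package's own choices:

* **Reference rescaling.** The formula requires the ideal system at the
  *bulk* density, but raw re-insertion reproduces the per-box density,
  which differs whenever the solute excludes or concentrates solvent. The
  reference histogram is therefore rescaled by one factor chosen so that
  its implied density in the bulk shell (10-15 Å from the solute surface
  by default) matches the observed bulk density.
* **Molecular shell measure.** The bulk density divides the mean shell
  occupancy by the shell measure *as seen by a molecular minimum
  distance*: $V_{box} \cdot P(\text{ideal insertion lands in the
  shell})$, estimated from the same reference insertions. For a
  single-site species this equals the geometric shell volume (which is
  also computed, by Monte-Carlo point sampling, and exposed for
  cross-checks); for a multi-atom species the geometric volume would be
  biased — we measured about 6% for a 3-atom rod — because a molecule can
  reach into the shell from outside it.

Unit conventions: coordinates in Å, concentrations in mol/L, $G$ in
L/mol, with the single conversion constant
$1\ \mathrm{mol/L} = 6.02214076\times 10^{-4}\ \text{molecules/Å}^3$
centralized in the package.

The preferential interaction and hydration parameters follow as

$$\Gamma_{pc}(R) \approx \rho_c\,[G_{pc}(R) - G_{pw}(R)], \qquad
  \Gamma_{pw}(R) \approx \rho_w\,[G_{pw}(R) - G_{pc}(R)],$$

so $\Gamma_{pw} = -(\rho_w/\rho_c)\,\Gamma_{pc}$ holds identically —
the package asserts this to machine precision. A positive $\Gamma_{pc}$
means the cosolvent accumulates in the solute domain and the solute is
effectively dehydrated. $\Gamma$ is reported at the KBI plateau found by
`convergence_check()` (smallest $R$ whose following 3 Å window stays
within a tolerance; 0.05 L/mol by default, sized for protein-cosolvent
KBIs — small synthetic fixtures whose entire $G$ is of order 0.1 L/mol
need a proportionally smaller tolerance, e.g. 0.005), or at `r_max` with
a warning when no plateau exists.

## Synthetic ensembles with analytic answers

No public trajectories accompany this kind of analysis, so validation
rests on generators whose distribution functions are known in closed
form. Solvent molecules are placed independently (solvent-solvent
ideality) by rejection sampling against a Boltzmann weight on the
molecular minimum distance $r$ to the solute:

* `ideal_gas` — no interaction, $g \equiv 1$;
* `hard_wall` — $g = 0$ below $d$, 1 beyond; the KBI converges to
  $-V_{excl}$, exactly $-\tfrac{4}{3}\pi d^3$ for a point solute;
* `square_well` — depth $\varepsilon$ (in kT) over $[d, d+w]$:
  $g = e^{\varepsilon}$ in the well, so
  $G \to [(e^{\varepsilon}-1)V_{well} - V_{excl}]$.

Independence makes these expectations exact, not approximations, which is
the entire point: every downstream estimator can be tested against them.
Because the generator fixes the molecule count at round($\rho V$), the
realized bulk density is slightly below the nominal $\rho$ when a well
concentrates molecules (by $V/V_{eff}$ with
$V_{eff} = V - V_{excl} + (e^\varepsilon - 1)V_{well}$); the bulk-shell
estimator measures exactly this realized density, so the oracles above
remain exact with respect to it.

What the generators deliberately do *not* emulate: solvent-solvent
correlations (no layering, no hydrogen-bond network), flexible molecules,
solute motion, or realistic water/TFE thermodynamics. Passing tests
therefore demonstrate the correctness of the estimators — binning,
reference construction, normalization, unit conversion, decomposition
bookkeeping — not the physics of any real mixture.

**Fixture sizes.** The oracle fixtures use 1000 molecules in a 31 Å cube
(a water-like number density of about 55.7 mol/L). The ideal-gas null
uses 100 frames; the hard-wall and square-well fixtures use 2000 frames,
because at realistic density the statistical error of a converged $G$
scales like $\sqrt{V_R/(\rho F)}$ and 2000 frames put it near 1%,
comfortably inside the 2%/5% bands the oracle tests assert. Frames cost
little here precisely because placements are independent.

## Helix assignment

Backbone hydrogen bonds are scored with the Kabsch-Sander electrostatic
energy
$E = 27.888\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$ kcal/mol,
bonded when $E < -0.5$; a bond CO($i$)→HN($i{+}4$) defines a 4-turn at
$i$. Among the inequivalent conventions for extending turns to residues,
the package uses the strict minimal rule: residue $j$ is alpha-helical
iff the turns at $j-1$ and $j$ are both bonded. This marks the helical
core — residues 2..8 of an ideal 12-mer, with single-turn tails left
unassigned — and has the property that breaking one turn (e.g. displacing
one carbonyl oxygen) visibly interrupts the assignment, which the laxer
"extend to $i{+}3$" convention does not. Only the alpha class is
assigned; 3-10/pi helices and strands count as "not alpha", which is the
quantity of interest when helix content is the observable. Missing amide
hydrogens are rebuilt 1.01 Å from N along the in-plane direction opposite
the C($i{-}1$)-N-CA bisector; residues missing other backbone atoms are
unassignable (`NA`). Ideal fixture geometry comes from
`gen_toy_peptide()`: polyalanine backbones at $\varphi=-57^\circ,
\psi=-47^\circ$ (helix) or $180^\circ/180^\circ$ (extended), built by
natural-extension internal coordinates; the helical form places every
O($i$)···H($i{+}4$) near 2.1 Å.

Hydrogen bonds elsewhere use a geometric criterion — donor-acceptor
$\leq$ 3.5 Å and donor-H···acceptor angle $\geq 150^\circ$ by default,
both configurable, since published counts rarely state their cutoffs —
with minimum-image distances throughout.

## Convergence diagnostics

`block_average()` estimates the standard error of the mean of a
correlated series from non-overlapping block means at dyadic block sizes,
keeping only sizes that leave at least 16 blocks. The plateau is the
smallest block size from which all larger estimates stay within 10%
relative, and the reported plateau SE averages from there up (damping the
noisy few-block estimates). The ratio (plateau SE / naive SE)² is the
statistical inefficiency, reported alongside as an
integrated-autocorrelation estimate. On iid Gaussian data ($n = 4096$)
the plateau recovers $\sigma/\sqrt{n}$ within a few percent of its own
sampling error; on AR(1) data with $\varphi = 0.9$ it recovers
$\sigma_x/\sqrt{n}\cdot\sqrt{(1+\varphi)/(1-\varphi)}$. The
`autocorrelation()` estimator is the standard biased (divide-by-$n$)
normalized ACF.

## REST2 arithmetic

Replica exchange with solute tempering keeps every replica at one
physical temperature and softens the solute terms of replica $m$ by
$\lambda_m = \beta_m/\beta_0$:
$E_m = \lambda\,E_{pp} + \sqrt{\lambda}\,E_{ps} + E_{ss}$, the
solvent-solvent term never scaling. (Compact write-ups sometimes show
both solute terms under one factor; the $\sqrt{\lambda}$ on the cross
term is the defining REST2 choice and is what `scaled_energy()`
implements.) `build_ladder()` produces $\lambda$ from 1 down to
$\lambda_{min}$ — geometric spacing by default, the standard choice since
it roughly equalizes neighbor overlap; linear is available for
comparison — with exact endpoints. `swap_acceptance()` evaluates the
Metropolis probability $\min(1, e^{-\Delta})$ with
$\Delta = \beta_0[E_i(\lambda_j) + E_j(\lambda_i) - E_i(\lambda_i) -
E_j(\lambda_j)]$, symmetric under label exchange. Running MD, and
emergent properties like realized exchange rates, are out of scope.

## Numerical and design notes

* **Orthorhombic boxes only**, minimum-image convention throughout;
  cubic boxes of the typical 30-90 Å sizes need nothing more. Minimum
  image is computed per component (valid for orthorhombic cells) and
  matches an explicit 27-image brute force exactly, which the tests
  assert on hundreds of random tiny systems.
* **Rigid-motion invariance** of histograms is exact for lattice
  rotations (90°) plus translations. Under an arbitrary rotation,
  molecules in box corners — min-image distance beyond $L/2$ — can
  rotate *into* the counted range, so invariance there is one-sided and
  statistical; the property tests encode exactly that.
* **1-based residue indexing** is preserved from input files, so author
  numbering (e.g. 120-152) survives into selections and density maps.
* **Polarity classes** (charged Asp/Glu/Lys/Arg/His⁺; polar uncharged
  Ser/Thr/Asn/Gln/Tyr/Cys/His; nonpolar the rest) live in one
  overridable table; whether His counts as charged is a configuration
  choice, not hard-coded.
* **Determinism**: every stochastic step (generation, reference
  insertion, Monte-Carlo volumes) derives its stream from explicit seeds;
  rerunning a pipeline with the same config reproduces CSV/JSON outputs
  byte-identically.
* **Formats**: PDB (via bio3d) and GRO structures; XYZ (plain text, box
  on the comment line) and DCD trajectories. XTC has no reader in this
  stack and is refused with guidance rather than half-supported.
* **Solute hydrogens** count as "any solute atom" in minimum distances
  (configurable through selections), matching the all-atom reading of
  the minimum-distance definition.

## A worked synthetic study

```{r study, eval = FALSE}
cfg <- default_study_config(seed = 1, n_frames = 60)
run <- run_pipeline(cfg, out_dir = "results")
print(run$gamma)    # Gamma_pc > 0: the square-well cosolvent accumulates
plot(run$kbi$cosolvent)
plot(run$residue_map)
```

The default study surrounds a 12-residue ideal helix with a square-well
3-atom cosolvent (depth 2 kT over 3-4 Å) and ideal-gas water at
water-like density in a 40 Å box — a deliberately minimal caricature of
a helical peptide in a TFE/water mixture that reproduces, by
construction, the qualitative signature of preferential solvation
($\Gamma_{pc} > 0$, $\Gamma_{pw} < 0$) together with a helix-content
profile and its block-averaged error. It takes about a minute on one
CPU; all numbers it reports are computed at run time.

## Known limitations

Solvent-solvent structure is absent from the generators, so nothing here
validates against real water correlations; the KBI finite-size treatment
is the open-shell bulk estimate only (no compressibility route, no
finite-size corrections); DSSP is reduced to its alpha class; and the
REST2 module does arithmetic, not sampling. These bounds are deliberate:
within them every number the package emits has an independent oracle.
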