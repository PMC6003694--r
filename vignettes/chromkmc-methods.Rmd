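---
title: "Modelling chromatin as a coarse-grained lattice polymer: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chromatin as a coarse-grained lattice polymer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromkmc)
```

## The physical picture

Chromosomes are very long polymers packed at high density into the cell
nucleus.  Two numbers organise most of their generic physics:

* the **Kuhn length** $l_k$ (stiffness), and
* the **entanglement length** $L_e$, the subchain scale above which chains
  cannot cross each other and topological constraints dominate.

Their interplay is summarised by the entanglement ratio $L/L_e$ of contour
length to entanglement length.  A budding-yeast chromosome ($L/L_e \lesssim
1$) moves like an ordinary Rouse chain; a fly or mammalian chromosome
($L/L_e \gg 1$) is strongly topologically constrained, and — because
chromosomes are essentially unknotted after mitosis — behaves like a
crumpled (fractal) globule rather than a reptating melt chain.

`chromkmc` implements this picture as a kinetic Monte Carlo (KMC) model of
a self-avoiding, semi-flexible chain on a face-centred cubic (fcc) lattice
with *stored length*, together with a coarse-graining calculus that chooses
lattice parameters so that **both** the volumic density and $L/L_e$ of a
fine-scale reference fibre are preserved at any resolution.

## The reference fibre and presets

The reference (fine-scale) model is a nucleosomal fibre: one monomer is
$\nu_0 = 200$ bp with bond length $b_0 = 10.6$ nm and Kuhn length $l_{k0} =
55.4$ nm (Kuhn size $\approx 1$ kbp).  A preset adds the nuclear volumic
density $\rho$ (genome size over nuclear volume, in bp/nm$^3$) and a
calibrated entanglement size $N_{e0}$:

```{r presets}
chromatin_preset("drosophila")
nuclear_density(6e9, nuclear_diameter = 9000)   # human: ~0.015 bp/nm^3
```

The entanglement length obeys the phenomenological relation
$L_e = l_k\,(c/(\rho_k l_k^3))^2$ with $c \approx 19$ and $\rho_k$ the Kuhn
segment density, which implies $N_e \propto \rho^{-2}$ at fixed fibre
parameters.  The absolute normalisation of this relation is uncertain at
the factor-of-two level: evaluating it directly with the reference fibre
parameters gives $N_e$ values ~1.6× smaller than the calibrated
per-species values (920 kbp for yeast at $\rho = 0.005$, 285 kbp for
drosophila at 0.009, 102 kbp for mammals at 0.015) that make all downstream
numbers internally consistent.  Presets therefore carry $N_{e0}$ as an
explicit calibration, and the relation itself supplies only the
$\rho^{-2}$ density scaling; presets without a calibration fall back to the
absolute relation with a warning.

```{r entanglement}
entanglement(chromatin_preset("drosophila"), chain_length = 20e6)
```

## Entanglement-conserving coarse-graining

Naively lumping $n$ fine monomers into one and dropping the bending
rigidity forces the lattice volume fraction up as
$\Phi/\Phi_0 = n^{1/2} (l_{k0}/b_0)^{3/2}$, which exceeds 1 (unsimulable)
already at kbp resolutions for fly-like densities.  Instead, the package
keeps an *artificial* bending rigidity at the coarse scale and solves, for
a requested coarse-graining $n$ and volume fraction $\Phi$,

$$ b = \left(\frac{\sqrt{2}\, n \Phi}{\rho_{FS}}\right)^{1/3}, \qquad
   \frac{l_k}{b} = \left[\frac{b_0}{L_{e0}}\, \frac{n c^2}{\Phi^2}\right]^{1/3}, $$

where $\rho_{FS} = \rho/\nu_0$ and the $\sqrt 2$ is the fcc per-site
volume $b^3/\sqrt2$ (a cubic cell of edge $b\sqrt2$ holds 4 sites).  These
two relations conserve the box volume and the ratio $L/L_e$
simultaneously.  The numerical constants were fixed once by requiring that
the solver regenerate the published drosophila parameter table, which it
does to better than 0.5%; with the alternative literal reading (a factor 2
instead of $\sqrt2$ in $b$, an extra $1/2$ inside the $l_k/b$ root) the
same table is missed by 10–20%, so we regard those as typesetting
artefacts.  The derived $\Phi_0 = \rho_{FS} b_0^3/\sqrt2$ (0.038 for the
drosophila preset) is reported for reference; it differs slightly from the
0.043 sometimes quoted for the same density, which corresponds to
$b_0 \approx 11.1$ nm — the reference fibre's $b_0$ (10.6 nm) and Kuhn
size (1 kbp at $l_{k0}/b_0 = 5$) are themselves mutually inconsistent at
the 5% level, and we keep both as published inputs rather than "correcting"
either.

```{r cgtable}
build_cg_table(chromatin_preset("drosophila"),
               nu = c(2000, 10000), phi = c(0.049, 0.97))
```

The rigidity is artificial — it controls $\Phi$, it does not claim to
describe fibre mechanics below a few $l_k$; the coarse model is
quantitative only above that scale.

## From Kuhn ratio to lattice bending energy

On the fcc lattice the 12 bond directions relative to a fixed previous
bond have $\cos\theta \in \{1, \tfrac12, 0, -\tfrac12, -1\}$ with
multiplicities $\{1,4,2,4,1\}$.  With a per-angle bending energy
$E(\theta) = \kappa (1 - \cos\theta)$, the Boltzmann mean
$\langle\cos\theta\rangle(\kappa)$ has a closed form, and the
stored-length chain (13 bond states: 12 directions plus the zero-length
bond) has bond correlation $x = \tfrac{12}{13}\langle\cos\theta\rangle$ and

$$ \frac{l_k}{b} = \frac{1+x}{1-x} \in [1, 25). $$

The cap at 25 is the infinite-rigidity limit; a coarse-graining request
that needs $l_k/b \ge 25$ is refused as unreachable.  `kappa_from_kuhn_ratio()`
inverts the strictly monotone map by root bracketing.  The same $x$ gives
the phantom-chain mean squared end-to-end distance (`phantom_end_to_end()`),
used for consistency tests and for locating the Rouse-time scale.

A note on conventions: the package applies $E(\theta)=\kappa(1-\cos\theta)$
*per angle*, with no $\tfrac12$ prefactor, because only this convention is
consistent with the $\kappa \leftrightarrow l_k/b$ mapping above and hence
with the regenerated parameter table.  A zero-length (stored-length) bond
contributes no bending term and interrupts the angle chain, consistent
with the $12/13$ statistics of the closed form.

## The lattice chain and its dynamics

The fcc lattice is embedded as the even-parity sites of a cubic grid of
edge $2S$ (grid spacing $b/\sqrt2$); a box of $S^3$ fcc cells holds
$4S^3$ sites.  A conformation is a sequence of sites in which consecutive
monomers are either nearest neighbours (bond length $b$) or share a site
(bond length 0, "stored length").  At most two monomers may occupy a site,
and only if they are consecutive — stored length models contour-length
slack and lets density fluctuations travel along the chain, which is what
makes reptation-like dynamics possible in dense systems without bond
crossing.  The box volume fraction is $\Phi = N/(4S^3) \le 2$.

Dynamics: one Monte Carlo step (MCS) is $N$ trial moves; each picks a
monomer and one of its 12 neighbour sites uniformly, checks the occupancy
and connectivity rules, and accepts with the Metropolis probability
$\min(1, e^{-\Delta E/k_BT})$ (temperature fixed at 1; energies in
$k_BT$).  The energy is the bending term plus, for the epigenomic
copolymer, $U_{e(i),e(j)}$ for every pair $|i-j|\ge2$ on nearest-neighbour
sites.  Bonded pairs ($|i-j|=1$) are excluded from the interaction sum by
default: counting them would add a state-independent offset that never
changes with a move between the same neighbours, and whether the
interaction applies to them is not determined by the model definition; an
`include_bonded_pairs` flag provides the alternative reading.

The move loop is compiled (Rcpp) and runs at roughly $2\times10^7$ trial
moves per second per core, with an incrementally tracked total energy that
is audited against a full recomputation on a configurable cadence (the run
aborts if the drift exceeds $10^{-6}\,k_BT$).  Each run has its own
counter-seeded random stream, so trajectories are bit-reproducible given
the seed and independent of R's global RNG state; replica $k$ of an
ensemble uses seed $\mathrm{base}+k-1$ for both its initial state and its
dynamics.

## Initial states

Chromosomes emerge from mitosis compact and essentially unknotted, and in
the strongly entangled regime they keep their initial topology for a very
long time.  The `hedgehog` initialiser therefore grows a knot-free compact
configuration: a short straight scaffold (8 monomers) through the box
centre is extended by repeatedly picking a random bond and inserting a
monomer either at an empty site adjacent to both bond endpoints or as
stored length on an endpoint; insertion into a zero-length bond is
disallowed (it would strand the two same-site monomers as a non-consecutive
pair).  Every insertion is local, so the chain can never thread through
itself: the result is unknotted by construction, with no need for knot
detection.  We keep the scaffold short deliberately: growth around a short
scaffold yields an isotropic compact ball (a reasonable cartoon of a
post-mitotic chromosome), whereas a box-spanning scaffold yields an
elongated "sausage" whose anisotropy contaminates the contact statistics
for a long time.  `line` (a straight, possibly stored-length-folded path)
and `random_collapse` (random valid growth; possibly knotted — useful as a
control that recovers reptation-like behaviour) are also provided.

## Observables

All measurements use unfolded coordinates (site plus accumulated periodic
image), so chains can spread over arbitrary distances.

* `msd_monomer()` ($g_1$) and `msd_com()` ($g_3$): mean squared
  displacements averaged over monomers, all snapshot-grid time origins and
  replicas.  Standard errors come from between-replica scatter, which
  honestly reflects the correlation induced by overlapping origins.
* `distance_moments()`: $\langle R^2(s)\rangle$ and $\sigma^2(s) =
  \langle R^4(s)\rangle - \langle R^2(s)\rangle^2$ versus genomic
  separation.
* `contact_probability()` and `contact_map()`: a contact is a pair at 3D
  distance strictly below $d_c$.  The default $d_c = \sqrt2\,b$ (the fcc
  cubic-cell edge) scales across coarse-graining levels and equals 163 nm
  at the 10-kbp drosophila coarse-graining ($b = 115$ nm); map frequencies
  are per (pair, snapshot) sample, so maps from different windows combine
  linearly.
* `pc_by_state()` and `ratio_timecourse()`: contact probabilities split by
  epigenomic state.  The pair-count-weighted average of $P_{intra}$ and
  $P_{inter}$ equals $P_c$ exactly (a test enforces this identity).  The
  enrichment time course forms the $P_{intra}/P_c$ ratio per separation
  (after pooling replicas) and averages the ratios across each band —
  pooling the band *before* taking the ratio would bias the estimate,
  because same-state pairs concentrate at short separations where contacts
  are more likely anyway.
* `pair_kinetics()` / `ensemble_kinetics()`: from a distance time series,
  the first-encounter time $\tau_{first}$ (censored at the span if the
  pair never meets — the censored fraction is reported, never imputed),
  contact durations $\tau_c$ (maximal runs below threshold, default
  $2\sqrt2\,b$, i.e. 325 nm at the 10-kbp coarse-graining) and search
  times $\tau_s$ (gaps between consecutive runs).  The durations satisfy
  $\tau_{first} + \sum\tau_c + \sum\tau_s + \mathrm{trailing} =
  \mathrm{span}$ exactly.

### Power-law fits and the time mapping

`fit_power_law()` is an ordinary least-squares fit on log–log axes.
Exponents are only quoted on declared windows.  For $g_1$ the intermediate
window is bounded below by the Kuhn-scale lag (the first lag with
$g_1 \ge l_k^2$, i.e. local stiffness equilibrated) and above by the
estimated Rouse scale ($g_1 \le \langle R_e^2\rangle/2$, from the phantom
formula) and by half the trajectory span — beyond half the span,
time-origin averaging rests on too few independent origins to be trusted.
If the window collapses (a run too short to contain an intermediate
regime), the exponent is reported as unavailable rather than fitted on an
arbitrary range.

`time_map()` converts MCS to seconds by matching the measured $g_1$ (in
$\mu m^2$) to the experimentally motivated reference $0.01\,t^{0.5}$
$\mu m^2$: the least-squares solution in log space has a closed form, and
when the measured local exponent deviates from 0.5 the result reduces to
an amplitude match at the window's geometric midpoint — the mapping is
then flagged in the output rather than silently reported.

## The epigenomic copolymer

Fly chromatin annotations distinguish five principal chromatin types; the
two transcriptionally active (euchromatic) ones are merged into a single
"active" state, alongside HP1-associated constitutive heterochromatin,
Polycomb-associated facultative heterochromatin and the quiescent "black"
state.  `load_epigenome()` reads a 4-column BED (0-based, half-open),
merges labels, and assigns one state per $\nu$-bp monomer by majority
base-pair overlap (uncovered monomers default to "black" with a warning).
Monomers of the same state attract with energy $E_i < 0$ when on
nearest-neighbour sites — one parameter, identical for all states.

Because the real annotation is an external dataset, the package ships
`synthetic_epigenome()`: alternating-state blocks with geometric length
distribution (mean 10 monomers, i.e. 100 kbp at 10-kbp resolution — the
scale of fly epigenomic domains) and configurable state frequencies
(default 0.3 active / 0.1 HP1 / 0.1 PcG / 0.5 black, black being the
prevalent form).  For strongly skewed frequencies the no-repeat constraint
biases realised frequencies slightly; for near-uniform ones they match.
Synthetic annotations are labelled as such and used by the tests; nothing
in the package downloads or bundles external data.

## What the tests do and do not show

The simulation-backed tests run desk-scale systems chosen to finish in
minutes on one core, not the full-scale ensembles a production study would
use (which are cluster-scale: $10^5$ monomers, $10^7$–$10^8$ MCS, hundreds
of trajectories):

* **Rouse regime** — $N = 512$ at the yeast-like volume fraction
  $\Phi \approx 0.022$ ($S = 18$) with $l_k/b = 5$, 8 replicas of $10^6$
  MCS from hedgehog initial states.  The $g_1$ exponent on the
  amplitude-declared window is $0.5$ within $\pm 0.07$, and the late-window
  contact probability decays as $s^{-1.5}$ over $s \in [10, 100]$ monomers
  with $\langle R^2(s)\rangle \sim s$ — worm-like-chain-at-equilibrium
  behaviour at the locally equilibrated scales.  The full Rouse time of
  this chain is of order $10^9$ MCS, so large separations retain memory of
  the compact initial state, exactly as the corresponding full-scale
  systems do within a cell cycle; the checked decade is the locally
  relaxed one.
* **Isolated chain** — the same chain at $\Phi \approx 0.004$ with
  $\kappa = 0$ shows $P_c(s) \sim s^{-2}$, the isolated self-avoiding-walk
  law, illustrating why ignoring confinement produces qualitatively wrong
  contact statistics.
* **Copolymer behaviour** — on toy copolymers (tens to hundreds of
  monomers at $\Phi \approx 0.5$): intra-state enrichment and inter-state
  depletion relative to the sequence average when $E_i < 0$, block-diagonal
  contact-map enrichment versus the $E_i = 0$ control, and monotone slowing
  of $g_1$ as $E_i$ decreases — the qualitative signatures of
  epigenome-driven microphase separation and the associated glass-like
  slowing, at sizes where they are testable in seconds.
* **Statistical mechanics** — exact enumeration oracles: the
  $\langle\cos\theta\rangle$ closed form against the 12-direction
  Boltzmann sum ($10^{-12}$); detailed balance on a 3-monomer system whose
  full configuration space is enumerated ($\chi^2$ against Boltzmann
  weights); the dilute 4-monomer chain against exhaustive enumeration of
  all $13^3$ bond sequences.  At $N = 8$ the excluded-volume swelling over
  the phantom formula is a genuine ~30% effect — the tests assert its
  sign and magnitude rather than pretending the phantom value is exact.

Passing these tests shows the machinery is correct and the generic physics
is right at desk scale; it does not by itself validate quantitative
agreement with any particular Hi-C dataset, which requires the real
annotation, full-length chromosomes and population-scale ensembles.

## Numerical choices and degenerate inputs

* Box size for a target $\Phi$: the integer $S$ minimising
  $|N/(4S^3) - \Phi|$; the *realised* $\Phi$ is then fed back into the
  geometry solver so the simulated lattice and the theory agree.
* Root finding for $\kappa(l_k/b)$: bracketing plus `uniroot` at
  $10^{-12}$; targets outside $[1, 25)$ are errors, not clamps.
* $x \to 0$ in the phantom formula is taken analytically (freely-jointed
  limit) to avoid $0 \cdot \infty$ noise; $x$ is bounded away from 1 by
  the lattice cap.
* Invalid initial conformations are rejected by `kmc_run()` up front;
  illegal proposals during a run count as rejected moves, as in any
  Metropolis scheme.
* Contact thresholds use strict inequality (distance $< d_c$).
* The energy audit tolerance ($10^{-6}\,k_BT$) is far above double
  round-off for desk-scale runs and far below any physically meaningful
  energy difference.

## Limitations

* The coarse model is not predictive below a few Kuhn lengths; at the
  10-kbp coarse-graining that means sub-100-kbp structure is cartoonish.
* Volume fractions above 1 are representable (stored length allows
  $\Phi \le 2$) but dynamics there slow drastically and are not
  recommended.
* Knot-freeness is guaranteed by construction of the hedgehog initial
  state, not verified algorithmically; `random_collapse` states may be
  knotted.
* Loop extrusion, supercoiling and lamina attachment are outside the
  model; the copolymer interaction is a single $E_i$ for all states.
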