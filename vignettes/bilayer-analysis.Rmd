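---
title: "Constructing and analysing united-atom oxidised-lipid bilayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and analysing united-atom oxidised-lipid bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxbilayer)
```

## Scope and model

`oxbilayer` rebuilds, as a tested pipeline, the structural analysis of
united-atom POPC/cholesterol bilayers containing lipid-peroxidation
products. Three oxidation products of POPC are modelled: a hydroperoxide of
the oleoyl chain (OX1) and two chain-cleaved aldehydes (OX2 keeps only the
phospholipid fragment; OX3 keeps both the phospholipid aldehyde, OX3a, and
the complementary short-chain aldehyde nonanal, OX3b). The OX3 fragment pair
originates from one POPC molecule and is therefore bookkept as **one lipid**
in every per-lipid quantity; in coordinate files the two fragments share a
residue number, which is how the pairing survives a GRO round trip.

In the united-atom reduction each aliphatic carbon merges its bonded
hydrogens (`n_merged_h` of 1-3); polar hydrogens (cholesterol's hydroxyl,
the hydroperoxide proton) stay explicit. POPC (134 atoms) becomes 52
particles. Particle masses are heavy-atom plus merged-hydrogen masses, so
every template's total mass equals its all-atom molecular mass; the test
suite checks this against the molecular formulas to 0.1 amu.

The package deliberately contains **no energetics**: no force field, no
minimisation, no dynamics. It builds initial configurations, generates
statistically realistic synthetic trajectories with known ground truth, and
analyses trajectories from any source (multi-frame GRO, or DCD via bio3d
against a GRO/PDB topology).

## The analysis battery

All analyses discard an equilibration period first. The default is the
first half of the trajectory, mirroring the common convention of analysing
the final half of a production run (e.g. the last 80 of 160 ns); every
function takes an explicit `equil_time` override.

**Area per lipid.** Per frame the lateral box area is `box_x * box_y`; the
APL is its post-equilibration time mean divided by the number of lipids in
one leaflet. Cholesterol counts as a lipid and an OX3 pair counts once.
Whether cholesterol-containing systems should instead be normalised by the
phospholipid count alone is left to the caller via `n_per_leaflet`. The
error bar comes from `block_error()` (below).

**Bilayer thickness.** The box is divided into 100 z-intervals (fractional
binning against the instantaneous box, so NPT area fluctuations do not
smear the profile), recentred per frame on the mean phosphate z. Thickness
is the peak-to-peak distance of the phosphate density maxima on either side
of the midplane. Ties within one side break toward larger |z| (the outer
shoulder), and the quoted error is one full bin width: the resolution limit
of the histogram, since the peak position is only known to its bin. A
profile without a clear maximum on each side (merged leaflets) is an error,
not a number.

**Deuterium order parameter.** United-atom chains carry no deuteriums, so
they are reconstructed geometrically: for each sn-1 carbon with exactly two
heavy chain neighbours A and B, the two C-D unit vectors lie in the plane
bisecting A-C-B, spanning an ideal tetrahedral D-C-D angle of 109.47
degrees ("ideal tetragonal symmetry" implemented as sp3 tetrahedral; the
C-D bond length is irrelevant because only directions enter the formula).
Then S_CD = mean of (3 cos^2(theta) - 1)/2 over both C-D bonds, all lipids
with an sn-1 palmitoyl chain, and all post-equilibration frames, per carbon
and averaged over carbons. The carbonyl carbon and the terminal methyl have
no unique tetrahedral frame from two chain neighbours and are excluded: the
average runs over the CD2 carbons C2-C15. Whether C2 (adjacent to the
ester) belongs in the chain average is genuinely ambiguous in the
literature; it is included by default and removable with `include_c2 =
FALSE`. Note the sign convention: chains perfectly *along* the normal give
S_CD = -1/2 for their C-D bonds (which are perpendicular to the normal),
while a C-D bond along the normal gives +1. The formula is applied to bond
angles, and both limits are asserted in the tests.

**Density profiles and core water density.** Profiles accumulate selected
particle mass per fractional z-bin over frames and divide by the
accumulated bin volume; this convention makes the profile integral recover
the selected mass exactly under box fluctuations (the per-frame-density
average instead carries an O(variance) bias). Units are kg m^-3 throughout
-- mass density, matching how core polarity is usually quoted (a "water
density of 1.3 kg m^-3" is a mass density). The core water density is the
water mass in the slab within 0.5 nm of the phosphate midplane (the "inner
1 nm") divided by the slab volume.

**Pore detection.** No standard definition exists for "the pore diameter",
so the package defines one and documents it: waters (O sites) strictly
between the two phosphate-peak planes are clustered by single linkage at a
0.35 nm cutoff under periodic minimum-image distances (0.35 nm is the
first-shell O-O distance cutoff commonly used for hydrogen-bond networks).
A pore spans when one cluster reaches within the cutoff of both planes.
The spanning cluster is sliced into 0.1 nm z-slabs; each slab's effective
radius is r = sqrt(n v_w / (pi h)) with v_w = 0.030 nm^3 per water,
i.e. the radius of the cylinder that would hold the slab's waters at bulk
packing. Slab counts are averaged over the spanning frames before the
radius is taken, which suppresses per-frame occupancy noise. Both the
maximum diameter (the figure usually quoted) and the minimum (the
bottleneck) are reported, with the onset time of the first spanning frame.

**Block-averaged errors.** Correlated time series (areas, for instance)
need decorrelation-aware error bars. `block_error()` blocks the series at
sizes 2^k and estimates the SE of the mean from block means at each size;
the plateau at large blocks is the honest SE. Rather than eyeballing the
plateau, the blocked-variance curve is fitted with the two-parameter closed
form that an AR(1) correlation structure implies,
`s^2(b) = (sigma^2/n) [ (1+phi)/(1-phi) - 2 phi (1 - phi^b) / (b (1-phi)^2) ]`,
weighted by block counts; the reported error is the fitted plateau
`sigma sqrt((1+phi)/((1-phi) n))`. The AR(1) form is an approximation for
general data, but it uses every block size (small blocks constrain sigma,
large blocks the plateau), which makes the estimate far more stable than a
plateau read off the noisy largest blocks; across repeated simulations it
stays within a few percent of the closed-form SE for both iid and strongly
correlated series. If the fit degenerates, the maximum blocked SE is used.

## System construction

`make_composition()` converts fractions to counts: cholesterol fraction
applies to all 72 lipids, the oxidation fraction to the non-cholesterol
pool (oxidised lipids replace POPC). Counts round to the nearest integer
with ties to even, POPC absorbing the remainder, and realised fractions are
reported back -- percentages like 11.1% only exist as 8 of 72.

`pack_initial_configuration()` is rejection sampling: lipids alternate
between leaflets, drop at uniform lateral positions and azimuths, and a
candidate is accepted only if all its particles stay at least 2 Angstrom
(default) from every particle of a different lipid, under periodic
minimum-image distances. The candidate check is a single vectorised
distance evaluation against all placed particles; at 72 lipids (~4000
lipid particles) this is fast enough that a cell-list acceleration would
add code without adding capability, so none is used. Waters fill the two
slabs outside the lipid region on a jittered lattice at bulk packing
(33.4 molecules nm^-3, about 999 kg m^-3); when the requested water count
exceeds the slab capacity at bulk spacing the lattice is compressed to fit,
since only the total mass matters downstream. Water is a rigid 3-site
molecule (18.015 amu) -- no water model physics is implied, only mass and
connectivity.

## What the synthetic generator does and does not emulate

`gen_bilayer_trajectory()` produces trajectories whose *statistical
structure* matches what the analyses assume, with every observable's truth
known by construction:

* phosphates on two jittered planes (truth for thickness),
* rigid all-trans sn-1 chains tilted by a fixed or per-lipid random angle,
  with a fresh uniform spin about the chain axis each frame -- the
  rotational average makes the expected mean S_CD exactly
  `-1/2 * P2(cos tilt)` per chain,
* an AR(1) lateral box-area series around `apl_truth * n_per_leaflet`
  (truth for APL and a realistic testbed for block errors),
* bulk-packed water slabs, and optionally a bulk-packed water cylinder
  spanning the core (truth for core water density, `rho_bulk pi r^2 / A`,
  and for the pore diameter `2 r`); cylinder waters are stratified in z so
  slab occupancies are near-deterministic,
* polar oxidation markers pinned either halfway the bilayer (the
  post-oxidation starting state) or just below the phosphate planes (the
  equilibrated, bent-tail state).

Chains are rigid by design: intra-chain disorder would destroy the exact
closed form, and tilt disorder already exercises the full code path.
Consequently the generator does **not** emulate conformational entropy,
per-carbon S_CD profiles that decay along the chain, lipid diffusion,
undulations, or leaflet asymmetry. Passing the closed-loop tests therefore
demonstrates that the estimators are unbiased on data satisfying their
assumptions -- it does not validate force-field physics, which is outside
the package on purpose.

Generator defaults are the study conditions: 72 lipids, 4000 waters,
a ~5.5 x 5.5 x 11 nm box, frames every 100 ps. Defaults chosen where the
study conditions are silent: phosphate-plane separation 3.8 nm and APL
0.65 nm^2 (typical fluid-phase POPC values), area AR(1) sd 0.25 nm^2 with
phi = 0.8 (a ~1% area fluctuation with a few-frame correlation time, the
scale seen in small-patch NPT runs).

## Numerical choices and degenerate inputs

* Collinear A-C-B chain geometries have no bisecting frame; those carbons
  are skipped with a warning rather than poisoning the average.
* Chain displacement vectors take the periodic minimum image, so wrapped
  trajectories analyse identically to whole ones (asserted by test).
* Thickness needs a positive maximum on each side of the midplane and at
  least two bins of separation; anything else raises an error naming the
  merged-leaflet case.
* `block_error()` requires 16 points; `area_per_lipid()` falls back to the
  naive SE below that, labelled `"naive"` so downstream consumers can tell.
* Packing failure (attempt cap) reports the offending lipid density
  instead of looping forever; impossible pore radii (wider than the
  lateral box) are rejected at spec construction.
* All RNG flows through a single seed per entry point, restored afterwards,
  so identical calls are bit-identical and callers' RNG streams are
  untouched.

## Problem sizes in the tests

The suite runs closed-loop recovery on 20 random specifications of 16-32
lipids and 16 frames each (pore systems use 32 lipids so the widest test
pore fits the lateral box), block-error validation on series of 10^4-10^5
points, and Monte-Carlo checks with up to 10^6 draws; the full suite
completes in about half a minute on one core. The `analysis/` scripts
run the same battery at full 72-lipid scale with 30-frame trajectories.

## Known limitations

* The pore diameter definition is package-defined (clustering plus
  slab-effective radii); other reasonable definitions (e.g. largest
  inscribed sphere) would give systematically different numbers for
  irregular pores.
* Profiles assume the bilayer does not wrap across the periodic z
  boundary; trajectories with a drifting bilayer should be recentred
  upstream.
* The AR(1) form inside `block_error()` is a model; series with strongly
  non-exponential correlation (e.g. slow oscillations) may need a manual
  plateau inspection.
* DCD ingestion takes the box from the topology frame (fixed-box
  trajectories only); fluctuating-box binary trajectories should be
  converted to multi-frame GRO.
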