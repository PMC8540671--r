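---
title: "VAE-driven multiscale enhanced sampling: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{VAE-driven multiscale enhanced sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem and the method

Two-domain binding proteins such as periplasmic sugar-binding proteins
interconvert between a ligand-bound/closed and a ligand-free/open
conformation. Plain molecular dynamics started in one basin rarely crosses to
the other within affordable simulation time. Multiscale enhanced sampling
(MSES) attacks this by coupling the simulated system to an accelerated
low-dimensional driver through a harmonic term,

$$V = V_{\mathrm{sys}}(r) + k\,\sum_p \big(d_p(r) - d^{\mathrm{target}}_p(t)\big)^2,$$

and removing the bias afterwards by Hamiltonian replica exchange over a
ladder of coupling constants $k$ that ends at $k = 0$. The ensemble collected
from whichever replica currently holds $k = 0$ is, by detailed balance,
a sample of $V_{\mathrm{sys}}$ alone — that is the central unbiasing claim,
and the property the test suite checks against the analytic Boltzmann
density of a harmonic reference system.

This package implements the variant in which the driver is not a
coarse-grained model but a *generated time series of inter-residue distance
restraints*: a variational autoencoder (VAE) is trained on the normalized
inter-domain C$\alpha$ distances of two single-basin trajectories, the two
states are connected in the VAE's low-dimensional latent space
(interpolation, or linear-response extrapolation when one state is withheld),
and the latent path is decoded back into distance targets
$d^{\mathrm{target}}(t)$, one vector per exchange window. The classic
CG-driven mode (a single hot, heavy dual-basin copy driving the ladder
one-way) is also provided for comparison (`run_original_mses()`).

## Features and normalization

Features are all C$\alpha$ pair distances between two *dynamic domains*
with sequence separation $|i-j| \ge 3$ (excluding virtual-bond and
virtual-angle neighbours in the original residue numbering). Distances are
normalized by the reciprocal map

$$x = 0.4\,(1/d_{\mathrm{nm}} - 0.14),$$

which emphasizes close contacts; the package keeps Angstrom everywhere and
converts to nm only inside `normalize_distances()` / its exact inverse.
The map is invertible on roughly 3.8–71.4 Å; values falling outside
$[0,1]$ are clipped and counted (attribute `n_clipped`) rather than
rejected, since a handful of sub-3.8-Å contacts in a dense core carry no
usable gradient information for the restraints.

Domains come either from the user or from the Motion Tree: residues are
clustered hierarchically (UPGMA/average linkage by default; the linkage is a
configuration option) with the pooled two-state distance-fluctuation matrix

$$D_{mn} = \big\langle (d_{mn} - \langle d_{mn}\rangle)^2 \big\rangle^{1/2}$$

as dissimilarity (population form, matching the ensemble-average notation).
`extract_domains()` takes a node's two children as domains and moves
subtrees smaller than `min_domain_size` (default 5) that split off above the
chosen node into a removed set — an explicit operationalization of the
usual by-inspection removal of floppy tails; flexible subtrees at lower
nodes can be flagged manually via `flexible_nodes`.

## The autoencoder

The network is the seven-layer fully connected architecture
$N_{\mathrm{inp}}$–$h$–$h$–$L$–$h$–$h$–$N_{\mathrm{inp}}$ with a stochastic
Gaussian coding layer (mean and log-variance heads), ReLU hidden units and a
sigmoid output, trained with Adam (learning rate $10^{-3}$, batch 256) on
reconstruction loss plus the closed-form KL divergence from the standard
normal prior, using the reparameterization trick. Training, encoding and
decoding are deterministic given the seed; `vae_encode()` returns the
posterior *mean* so that all downstream interpolation and free-energy
estimation are deterministic.

Two choices deserve justification:

* **Reconstruction loss.** The default is Bernoulli cross-entropy, not
  squared error. With the reciprocal normalization most features sit far
  below 0.5 (long distances map to $x \approx 0.02$–0.1), and under a
  summed-MSE loss with unit KL weight the KL term dominates and collapses
  the posterior long before 300 epochs; cross-entropy re-weights exactly
  those small-$x$ features and trains stably. MSE remains available via
  `vae_config(loss = "mse")`, as does `kl_weight = 0`, which reduces
  training to a plain autoencoder (a property the tests exploit: the
  unregularized autoencoder must reach a lower reconstruction loss).
* **Hidden width.** The architecture default is $h = 1000$; the bundled
  pipeline and the test suite use $h = 256$, which reproduces the same
  qualitative behaviour on the toy system at a fraction of the cost.
  Reported runs state their width in the run configuration, which is echoed
  into every output directory.

Latent dimension $L=2$ is the default for the closed/open problem: the toy
system's slow manifold is essentially the one-dimensional hinge angle, and
two latent coordinates leave headroom. Reconstruction adequacy is judged
with `reconstruction_report()` — the per-feature frame-averaged relative
difference $\langle |x-y|/x \rangle$ and the per-feature Pearson correlation
of $x$ and $y$; zero-variance features are flagged rather than dropped.

## Latent series and restraint schedules

`interpolate_series()` draws anchors alternately from the two latent pools
(uniformly without replacement, reshuffling an exhausted pool — the
"one by one" prescription made reproducible), and connects consecutive
anchors with 25 equal linear steps by default. One step corresponds to one
40-ps exchange window, so a segment is 1 ns — the timescale assumed for one
open–close transit. By default every pool member is used once as an anchor,
so the series provably revisits both basins; `n_anchors` can be reduced to
match a shorter replica-exchange run (the bundled pipeline uses 9 anchors
for its 125-window demonstration runs).

For the blind setting (open state withheld) the extrapolated pool is

$$z'_{\mathrm{ext}} = z'_{\mathrm{close}} + \alpha\,
\big(\langle z'\rangle_{\mathrm{close}} - \langle z'\rangle_{\mathrm{holo}}\big),$$

the linear-response assumption that the ensemble shift upon ligand removal
points along the opening direction. The full $L$-dimensional mean-shift
vector is used; coordinates that do not respond contribute a near-zero
shift, and each pool member keeps its own fluctuation around the shifted
mean. The scale $\alpha$ is chosen by `determine_alpha()` as the largest
value on a grid (default 0.5–10 in steps of 0.5) for which the *decoded
extrapolated pool mean* keeps a chosen hinge residue pair below a distance
cap — the "hinge must not over-extend" criterion. The check is made on the
decoded pool mean, not per frame; per-frame checking would only tighten the
same bound. If even the smallest grid value violates the cap it is returned
with a warning, because a rough over-extended estimate is still usable — the
replica-exchange refinement, not the generator, owns the final ensemble.

## The replica-exchange engine

Dynamics are BAOAB-discretized Langevin (collision frequency 1 ps$^{-1}$,
300 K by default; the zero-friction limit is velocity Verlet, which the
tests verify conserves energy). Units are kcal/mol, Å, amu and ps with
$k_B = 0.0019872041$ kcal/mol/K. Exchanges are attempted every 40 ps
between adjacent rungs in alternating even/odd sweeps; the Metropolis
criterion needs only the coupling energies because swapping $k$ leaves the
system potential unchanged. On acceptance the coupling constants (ladder
positions) are swapped, never coordinates — the $k=0$ ensemble is assembled
by following the $k=0$ label across replicas. All replicas share the same
schedule row inside a window and the row advances synchronously; a schedule
shorter than the run is recycled cyclically with a warning.

The reference ladder is the ten-rung set
(0 … 4.9 × 10⁻⁴ kcal/mol/Å²), which was designed for roughly 14.4×10³
restrained pairs. Because the coupling energy scales with the number of
pairs, `scale_ladder_k()` rescales the ladder by the pair-count ratio; the
toy system (~620 pairs) therefore runs a proportionally stiffer ladder.
A deliberately sparse two-rung ladder can drive the biased replica across
the barrier but hands the $k=0$ label over too rarely to be useful — the
graded ladder is what produces both the high average acceptance and the
$k=0$ transitions, which is exactly the ladder's purpose.

## The toy system: what it emulates and what it does not

The generator (`toy_spec()`, defaults in parentheses) builds a two-domain
bead protein: two helical arms (24 beads each, 1.5 Å rise / 2.3 Å radius,
3.8 Å virtual bonds) joined by 2 hinge beads, with the first arm rigidly
rotated about a hinge pivot to set the opening angle — 25° closed, 70° open,
10° for the ligand-bound holo surrogate. Angles were chosen once so that all
inter-domain distances stay inside the invertible range of the
normalization. The pivot sits midway between the arm root and the first
hinge bead rather than on a bead: a bead exactly at the pivot would have
near-zero distance fluctuation to *both* rigid bodies and its Motion-Tree
assignment would be decided by noise.

Single-basin force fields are elastic networks of each state's reference
(10 Å cutoff, bonds 50, contacts 2 kcal/mol/Å²) plus a sparse inter-domain
lattice (0.02 kcal/mol/Å²) that pins the opening angle — the deliberately
soft slow mode. The ground-truth two-state potential mixes the closed and
open networks through a log-sum-exp dual-basin form with
$\beta_{\mathrm{mix}} = 0.2$ mol/kcal (a generic dual-basin construction,
not a reparameterization of any particular CG model); bonds whose length is
state-dependent (the cross-hinge bond) are mixed with the contacts so
neither basin is strained. The resulting barrier along the rigid-rotation
path is several tens of $k_BT$, so an unrestrained 300 K run started closed
stays closed for the whole demonstration length — which is the point.

The holo surrogate is both stiffer (2×, ligand rigidification) and slightly
more closed than apo-closed (10° vs 25°, ligand clamping). The second
property is essential for the extrapolation demonstration: if holo and
closed shared an identical mean geometry, the closed-minus-holo latent
shift would be pure sampling noise and the linear-response direction would
be undefined. Real ligand binding shifts both the mean and the width of the
ensemble; the toy makes that shift explicit.

What the toy does *not* emulate: solvent and friction heterogeneity,
side-chain packing, rugged intra-basin landscapes, and the sheer
dimensionality of an all-atom system. Passing tests therefore demonstrate
the *logic* of the method — featurization, compression, generation,
driving, unbiasing — not its performance on real proteins.

## Problem sizes and numerical choices

Default desk-scale study conditions (stated in `run_config()` and echoed
into each run directory): 400 frames per state at 1 ps spacing after 20 ps
equilibration; 300 training epochs; 125 exchange windows of 40 ps at a
0.02 ps timestep; FES histograms of 50×50 bins over the 5%-padded data
range, in units of $k_BT$ with the minimum shifted to zero and empty bins
undefined. The demonstration runs in the test suite use 201 windows, the
published window length (40 ps) and exchange count arithmetic
(5000 × 40 ps = 200 ns) being checked symbolically rather than simulated.
The qualitative "the series' surface covers both states" claim is
operationalized as ≥95% of each pool's points falling in 2-D latent bins
occupied by the series.

Other numerics: log-variances are clamped to $[-12, 12]$ during training;
the dual-basin mixture is evaluated with a log-sum-exp shift so
$\beta_{\mathrm{mix}} \to \infty$ degenerates cleanly to the pointwise
minimum; tiny negative variances from the two-pass fluctuation accumulation
are truncated at zero before the square root; superposition enforces a
proper rotation (determinant +1) via the SVD sign correction; PCA aligns on
the large domain in two passes (first frame, then the mean) before
diagonalizing the small-domain covariance. Integrator noise is generated in
compiled code from a dedicated 64-bit stream per window and replica, so
replica-exchange runs are reproducible bit-for-bit for a given master seed
on a given platform.

## Known limitations

* Decoder extrapolation beyond the training support is uncontrolled: the
  extrapolated restraints are a *rough estimate* by design, and the
  hinge-cap rule bounds but does not validate them. The MSES refinement is
  what makes the blind prediction usable, mirroring the method's own logic.
* Only the $k=0$ replica is analyzed; no WHAM/MBAR reweighting across the
  ladder is attempted.
* The Motion Tree uses standard average linkage; bespoke amendments of
  dedicated Motion-Tree software (e.g. contact-distance corrections) are not
  reproduced, and trees from real trajectories may differ in detail.
* Trajectory input is PDB (single/multi-model) and DCD with a PDB topology;
  XTC is not read.
* The VAE is plain (fixed unit KL weight, no annealing, dense layers only),
  and unused latent coordinates can collapse toward the prior when the data
  manifold has lower intrinsic dimension than $L$ — visible as a posterior
  standard deviation near zero for that coordinate.
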