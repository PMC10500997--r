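---
title: "The sugres coarse-grained heparin model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sugres coarse-grained heparin model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sugres)
```

## The model

Heparin is a linear, highly anionic glycosaminoglycan built from repeating
IdoA2S--GlcNS6S disaccharides carrying a net charge of $-4\,e$ per
disaccharide. `sugres` simulates free heparin chains in the SUGRES-1P
one-site-per-residue representation: the glycosidic linkage oxygens serve as
*anchor points* of a virtual-bond chain, and each sugar residue is reduced
to a single interaction site placed exactly midway between its two flanking
anchors. Chain geometry is fully described by the virtual-bond lengths
$d_i$, virtual-bond angles $\theta_i$ and virtual-bond dihedrals
$\gamma_i$; `internal_coordinates()` and `rebuild_cartesian()` convert
between the two descriptions and are exact inverses to better than
$10^{-6}$ Å for chains up to dp 68.

Because the center of charge of a sulfated sugar residue is displaced from
its geometric center, each site is split into a charged **head** and an
uncharged **tail**. Both lie on the *site axis* (the unit vector of the
site's virtual bond) at signed offsets from the site center
(`head_offset`, `tail_offset`, defaults $+1$ and $-1$ Å). With both
offsets at zero the head, tail and site coincide and every
orientation-dependent term collapses to its isotropic limit — the
"collapsed" mode used for isotropic testing. Placing the offsets along the
axis (rather than giving them a normal component) makes the tail-to-head
direction coincide with the site axis, which is then the orientation vector
of all anisotropic terms; a normal component would require an arbitrary
convention for the terminal residues without adding a tested behavior.

## The effective energy function

The total effective energy is the weighted sum

$$U = \sum_k w_k\, f_{n_k}(T)\, U_k$$

over ten named terms, each with its own dimensionless weight
(`default_weights()`), evaluated over the bonded internal coordinates and
all non-bonded site pairs. Pairs closer in sequence than
`exclude_near = 2` positions are excluded from the non-bonded sum — their
geometry is already governed by the bonded terms, and including them would
double-count; this is standard coarse-grained practice. No distance cutoff
is applied: with at most ~70 sites the all-pairs sum is cheap and cutoff
artifacts are avoided entirely.

**Bonded terms.** The shipped forms are a harmonic bond
$U_\mathrm{bond} = \tfrac{k_d}{2}(d - d_0)^2$, a harmonic virtual-bond
angle $U_b = \tfrac{k_\theta}{2}(\theta - \theta_0)^2$, and a torsion that
receives the dihedral *and both adjacent virtual-bond angles* jointly,

$$U_\mathrm{tor} = k_\gamma \sin\theta_{i-1}\sin\theta_i\,
  \bigl[1 - \cos(\gamma_i - \gamma_0)\bigr].$$

The sine factors switch the torsional energy off continuously as either
adjacent angle approaches collinearity, exactly where a dihedral becomes
ill-defined; they also make the extended conformation
($\gamma = \gamma_0 = 180^\circ$, $\theta = \theta_0$) a stationary point
of the full bonded energy.

**Non-bonded terms**, per site pair $(i, j)$:

* *Gay–Berne tails* (`gay_berne()`): the shifted anisotropic 12-6 form
  $4\epsilon(\omega)(\rho^{-12} - \rho^{-6})$ with
  $\rho = (r - \sigma(\omega) + \sigma^0)/\sigma^0$, the standard
  orientation-dependent contact distance $\sigma(\omega)$ (shape
  anisotropy `chi_gb`) and well depth $\epsilon(\omega)$ (exponents
  $\mu = 2$, $\nu = 1$, coupling `chi_gb_prime`). Zero at
  $r = \sigma(\omega)$ for every orientation; exactly Lennard-Jones when
  both anisotropies vanish.
* *Generalized Born polarization of the heads* (`gb_polarization()`):
  $-k_e\,(1/\epsilon_{in} - 1/\epsilon_{out})\, q_i q_j / f_{GB}(r')$ with
  Still's interpolation
  $f_{GB}(r) = \sqrt{r^2 + a_i a_j \exp(-r^2/4 a_i a_j)}$, which runs from
  the Born limit $\sqrt{a_i a_j}$ at contact to the Coulomb limit $r$ at
  large separation.
* *Screened electrostatics of the heads* (`electrostatics()`):
  $k_e\, q_i q_j\, e^{-\kappa r'} / (\epsilon_{in} r')$, carrying its own
  weight `eel` so the chain-extending charge repulsion can be tuned
  independently of every other interaction. The Coulomb part deliberately
  uses the *interior* dielectric: the solvent's dielectric screening is
  exactly what the generalized Born polarization term supplies, and the sum
  of the two tends to $k_e q_i q_j/(\epsilon_{out} r)$ at large
  separation. (Using $\epsilon_{out}$ in both terms would double-count the
  solvent response and turn the net like-charge interaction attractive,
  collapsing every chain regardless of $\kappa$.) Counterion screening
  enters through the Debye–Hückel factor $e^{-\kappa r}$; $\kappa$ is an
  inverse screening length in Å$^{-1}$, and `debye_length()` documents the
  mapping to ionic strength.
* *Head–tail polarization* (`head_tail_polarization()`): each charged head
  polarizes the uncharged tail of the partner site. The shipped form is a
  screened charge-induced-dipole attraction over the two cross distances,
  with solvation coefficients $\alpha_1$ ($r^{-4}$) and $\alpha_2$
  ($r^{-6}$) and screening $e^{-2\kappa r}(1 + \kappa r)^2$ — the squared
  field of a Debye-screened charge. Symmetric under particle exchange and
  continuous in $\kappa$.
* *Cavity terms* (`cavity_iso()`, `cavity_tails()`): the desolvation-shell
  free energy is modeled as a Gaussian shell of width `cav_width` centered
  at the contact distance — $\sigma_i^{iso} + \sigma_j^{iso}$ for the
  heads, and an orientation-dependent
  $\sigma^0[1 - (\chi''^{(1)}/2) S(\chi''^{(2)})]^{-1/2}$ for the tails,
  which reduces to the isotropic shell when $\chi''^{(1)} = 0$. The shell
  form is finite everywhere, symmetric and decaying, which is all the
  surrounding theory requires of it.
* *Head Lennard-Jones* (`lj_heads()`): plain 12-6 with
  (`sigma_head`, `eps_head`).

**Temperature factors.** Every inter-residue pair term (the extracted
electrostatic term included) is multiplied by the second-order factor

$$f_2(T) = \frac{\ln(e + e^{-1})}{\ln\bigl[\exp(T/T_0) +
  \exp(-T/T_0)\bigr]}, \qquad T_0 = 300\ \mathrm{K},$$

equal to 1 at $T_0$ and smooth in $T$; bonded terms are first order
($f \equiv 1$). All production simulations run at 300 K, where every
factor is unity.

## Parameters and their defaults

The published parametrization tables for the sugar-sugar interaction are
not distributed with this package; the numeric defaults in `cg_params()`
are therefore **documented placeholders at physically sensible
coarse-grained magnitudes**, and `read_params()` loads user-supplied
values from a flat key-value file. The defaults that matter most:

| parameter | default | rationale |
|---|---|---|
| `d0` | 5.0 Å | anchor spacing giving a dp12 contour of 60 Å at full extension, the scale of the experimental dp12 end-to-end distance |
| `theta0` | 150° | gently bent virtual-bond angle typical of pyranose chains |
| `k_bond`, `k_angle`, `k_tor` | 20, 8, 1 | stiff bonds, softer angles, soft torsions (kcal/mol units per Å² or rad²) |
| `charge_split` | $-2/-2$ | only the $-4\,e$ disaccharide sum is fixed by the chemistry; an even split is the default and the split is configurable |
| `eps_in`, `eps_out` | 2, 80 | interior vs aqueous dielectric |
| `born_radius` | 3 Å | head solvation radius |
| `sigma0_tail`, `eps_tail` | 4.5 Å, 0.3 | residue-sized tails with a weak dispersion well |
| `chi_*` anisotropies | 0.2–0.3 | moderate ellipsoidal anisotropy; 0 recovers isotropic limits |
| `site_mass` | 288 amu | mass of half a $-4\,e$ repeat disaccharide; only equilibrium distributions matter for the observables, so the precise value is uncritical |
| `exclude_near` | 2 | non-bonded exclusion window (see above) |

## Dynamics

`run_simulation()` integrates canonical Langevin dynamics with the BAOAB
splitting, chosen for the accuracy of its configurational averages at
large time steps; with `friction = 0` the O-block is the identity and the
scheme reduces to symplectic velocity Verlet. The default time step of
4.89 fs is one tenth of the natural time unit
$\sqrt{\mathrm{amu}\,\text{Å}^2/(\mathrm{kcal/mol})} \approx 48.9$ fs of
the (Å, kcal/mol, amu) unit system, the recommended safe step for this
class of coarse-grained MD; the default run length is 2,000,000 steps.
Times are reported in nominal femtoseconds — coarse-grained dynamics are
effectively faster than physical time (a full run corresponds to roughly a
microsecond of real time), but no scale factor is asserted. The friction
coefficient defaults to 1 ps$^{-1}$, the common coarse-grained choice; it
affects sampling efficiency, not the sampled ensemble.

The degrees of freedom are the anchors, each carrying `site_mass`; heads,
tails and site centers are deterministic functions of the anchors, and the
analytic forces chain-rule every term's gradient onto the anchor
coordinates (verified against five-point central finite differences to
better than $10^{-5}$ relative error per component, with zero net force
and torque). Because Langevin friction keeps the center-of-mass velocity
bounded, only the center-of-mass *position* is recentred at snapshot
times; velocities are untouched, so the kinetic-temperature estimator
(mean over all $3N$ degrees of freedom) is unbiased. A non-finite force or
coordinate aborts the run with a `sugres_blowup` condition carrying the
last good frame.

## Observables, clustering and calibration

`end_to_end_distance()` is the distance between the two terminal anchors
(the experimental definition of chain extension); `radius_of_gyration()`
is the RMS distance of site centers from their centroid with uniform
masses, matching the one-site resolution. `rmsd_anchors()` superposes
anchor sets with the Kabsch SVD algorithm (reflection-guarded).
`cluster_frames()` runs DBSCAN on the pairwise superposition RMSD with the
production settings `eps = 4` Å and `min_size = 2`; an implementation is
included because no DBSCAN package is part of the supported stack, and the
test suite checks it against an independent brute-force enumeration.

Trajectory means discard an initial equilibration window (default: the
first 10% of frames). The production protocol starts from the fully
extended conformation, so early frames are an atypical transient;
convergence is monitored by RMSD to the start in practice, and the window
fraction is configurable where 10% is too little or too much.

`sweep_calibration()` reproduces the empirical weight/κ calibration: one
weight family varied over 1–10 (all others at 1) crossed with the eleven
κ values 0.0–1.0 (generated decimally so grid values are exact dictionary
keys), one seeded simulation per cell, scored as percentage errors of mean
end-to-end distance and radius of gyration against `reference_table()`.
The packaged table ships only the dp12 end-to-end distance of 60 Å — the
one reference value that is fixed in this package's sources — with
`set_reference()` for the user's own data; ranking uses ascending
percentage error with a deterministic tie-break (lower κ, then lower
weight). `preset_combinations()` returns the three production parameter
sets (κ = 0.2 with $w_{eel} = 7$; κ = 0.7 with $w_{eel} = 7$; κ = 0.7 with
$w_{bond} = 4$).

## Synthetic inputs

`make_helix_template()` generates idealized regular helices (configurable
rise, twist and radius) standing in for the NMR-derived helical heparin
template: every test and example runs without any external download. The
default 5 Å rise matches the `d0` convention above. The fixture emulates
the *regularity* of the template — uniform bond lengths, periodic internal
coordinates — not the true atomic geometry of heparin, and
`make_toy_dimer()` builds fully explicit two-site arrangements
(side-to-side, end-to-end, seeded random) for closed-form energy checks.
Consequently, passing tests demonstrate correctness of the machinery and
the qualitative physics (screening compacts chains, electrostatic weight
extends them), not quantitative agreement with experimental heparin data.

## Numerical choices

* **Degenerate dihedrals** (collinear anchor triples) are set to 180° with
  a warning — continuous with the extended conformation, where the torsion
  energy vanishes anyway through its $\sin\theta$ factors.
* **Angle clamping:** $\cos\theta$ is clamped to $\pm(1 - 10^{-12})$
  before `acos`, so exactly straight geometries do not produce NaN forces.
* **Overlap handling:** a separation inside the shifted Gay–Berne core
  returns an infinite energy, which the dynamics driver converts into the
  blow-up condition rather than silently clamping forces.
* **Equilibration window** and **snapshot stride** are configurable; the
  test suite and the acceptance script use reduced problem sizes (dp 6–24,
  $2\times10^5$–$10^6$ steps, 3 seeds for stochastic comparisons) chosen
  so the full battery completes in minutes while the compared quantities
  (temperature, drift, trend directions, grid cardinalities) are already
  stable at those sizes.
* **Determinism:** all stochastic components draw from R's RNG, seeded per
  run; equal seeds give bitwise-identical trajectories.

## Known limitations

* The shipped force-field constants are placeholders: quantitative
  percentage errors against experimental chain dimensions depend on the
  unpublished parametrization tables and are **not** reproducible from
  this package alone. The machinery (sweep, ranking, presets) is complete,
  so supplying a parameter file upgrades the calibration to a quantitative
  one.
* The solvent and counterions are implicit; κ is a model parameter, not a
  measured ionic strength (see `debye_length()` for the documented
  conversion under the monovalent assumption).
* Only the unbranched IdoA2S–GlcNS6S repeat is modeled — no branched
  topologies, mixed glycosaminoglycans or alternative sulfation patterns,
  and no protein partners.
* No periodic boundary conditions and no explicit-ion electrostatics.
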