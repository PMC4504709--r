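---
title: "Geometry and contact analysis of intermediate filament dimers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry and contact analysis of intermediate filament dimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IFDimerTools)
```

# Scope and data model

IFDimerTools quantifies the structure of intermediate filament (IF) protein
dimers — the keratin K1/K10 heterodimer being the motivating system. An IF
dimer is a tri-domain object: a disordered N-terminal head, a central rod of
four coiled-coil subdomains (1A, 1B, 2A, 2B) joined by linkers (L1, L12,
L2), and a disordered C-terminal tail. The head and tail are further
partitioned E1–V1–H1 and H2–V2–E2, with V1/V2 the large glycine-rich
globular cores.

Structures are held as S4 objects: `ChainStructure` (per-atom table, one
chain), `DimerStructure` (two labelled chains), `StructureEnsemble` (frames
with model ids and full/truncated scope) and `SubdomainAnnotation`
(chain/subdomain/start/end intervals). PDB I/O goes through bio3d, with a
whitespace-delimited fallback dialect for plain-text coordinate
depositions. All computation is in ångström; report columns add nm where
sizes are conventionally quoted in nm.

The shipped K1/K10 annotation table (`inst/extdata/k1_k10_subdomains.tsv`)
is a best reconstruction assembled from published anchor points (the 1B
C-terminal truncation residues K1:328/K10:296, V1 = K1:61–153 and
K10:31–137, V2 and H2 boundaries, 35/101-residue 1A/1B coils). Exact
head/tail boundaries are not published in machine-readable form, so the
table is deliberately a user-editable data file rather than code.

# Coiled-coil profile

For each chain the α-helix axis path $p_N(i)$ is estimated from the
C$_\alpha$ positions of residues $i-1 \dots i+2$ by the second-difference
(bisector) construction: on an ideal helix the second difference
$A(i) = p(i-1) - 2p(i) + p(i+1)$ points from the C$_\alpha$ exactly toward
the local axis, the per-residue twist $\Delta\varphi$ follows from the
angle between consecutive second differences
($\cos\Delta\varphi = \hat A(i)\cdot\hat A(i+1)$), and the helix radius
from $r = |A|/(2(1-\cos\Delta\varphi))$. The axis point is
$p(i) + r\,\hat A(i)$. On generated ideal helices the recovered points sit
on the true axis to machine precision; with 0.1 Å coordinate noise they
stay within 0.3 Å.

The coiled-coil profile then follows the standard decomposition:

* central axis $P(i) = (p_{K1}(i) + p_{K10}(i))/2$;
* local radius $R(i) = (|p_{K1}(i)-P(i)| + |p_{K10}(i)-P(i)|)/2$;
* rotation angle $\Psi(i)$: the dihedral rotation of each chain's
  center-to-axis vector about the local central-axis direction, averaged
  over the four available estimates (steps $i-1{\to}i$ and $i{\to}i+1$,
  two chains each). The four estimates are combined by an unweighted
  arithmetic mean; nothing in the construction suggests another weighting.
* local pitch $\lambda(i)$: local rise per residue along $P$ times the
  residues per full turn, $\lambda(i) = \tfrac12(|P(i{+}1)-P(i)| +
  |P(i)-P(i{-}1)|)\cdot 360/|\Psi(i)|$.

Two conventions needed a decision. First, the pitch is implemented as the
physical axial distance per full supercoil turn (rise × 360/|Ψ|); a form
that instead *multiplies* rise by the fractional turn would produce
sub-ångström numbers, inconsistent with the ~170 Å pitch that two-stranded
IF coiled-coils are known to have, so it is not used. Second, the sign
convention $\Psi < 0 \Leftrightarrow$ left-handed supercoil was calibrated
once against the generator (whose handedness is set by construction) and
frozen in a test; under coordinate reflection Ψ flips sign exactly.

Where $|\Psi|$ falls below `psi_min` (default 0.5°/residue, i.e. apparent
pitch beyond ~1100 Å) the strands are effectively parallel: pitch is
reported as `NA` ("indeterminate") rather than a divergent number, and
handedness as "indeterminate". This matches how near-parallel stretches
(such as the 2A/L2 region of keratin rods) are described qualitatively
rather than by a pitch value. Axis points are undefined for the first
residue and last two residues of a range (the estimator needs
$i-1 \dots i+2$); these are reported missing, never extrapolated.

A subdomain's **major axis** is the unit vector between the central-axis
points at its 2nd and 3rd-to-last residues — deliberately inset one
residue from each end of the defined axis range to avoid end effects. The
**hinge angle** between adjacent subdomains is, by default, the interior
angle $\cos^{-1}(u \cdot v) \in [0°, 180°]$ of the N→C oriented axes. A
"reflex" convention (360° minus the interior angle) is exposed as an
option: a printed formula of that form maps into [180°, 360°], yet the
hinge magnitudes reported for IF dimers (≈107° between 1A and 1B) are
interior-angle magnitudes, so the interior convention is the default and
neither is silently reconciled into the other.

# Head/tail globule placement

The V1 (or V2) globule of a chain is summarized by two coordinates
relative to the rod terminus. With $\vec V$ from the anchor — the
central-axis point at the 2nd residue of 1A (head) or the 3rd-to-last
residue of 2B (tail), consistent with the major-axis anchors — to the
globule's C$_\alpha$ center of mass, and $\vec M$ the outward unit anchor
axis:

* axial displacement $d = \vec V \cdot \vec M$ (positive: projected out
  beyond the rod terminus);
* radial orientation $\theta_r$: the angle, in the plane perpendicular to
  $\vec M$, between the projection $\vec P$ of $\vec V$ and a reference
  $\vec O$ pointing from the inter-chain center toward the K1 chain.

$\theta_r$ is reported *signed* via the right-hand rule about $\vec M$,
because an arccos definition is blind to side; the unsigned value is
$|\theta_r|$. $\theta_r = 0°$ means the globule sits on the K1 side, 180°
on the K10 side, ±90° between the chains. When the globule center lies on
the axis ($\|\vec P\| \approx 0$) the orientation is reported `NA`.

Positions classify into Category I ($d$ above a band: projected out along
the dimer long axis), Category II ($|d|$ within the band: at right angles
to the rod end) and Category III ($d$ below the negative band: folded
back down onto the rod). The band half-width defaults to 10 Å —
the category names come with no published thresholds, so the default was
chosen once as roughly half a globule radius and is configurable
everywhere it is used.

Shape metrics are the radius of gyration over backbone atoms (N, CA, C, O
when present, else C$_\alpha$), the end-to-end distance from the chain
terminus to the rod anchor, and principal extents (max-minus-min spread
along the principal axes of the centered point cloud). Occurrence
histograms of $(d, \theta_r)$ can be pooled per frame or per model: both
weightings are exposed because pooling frames within a model first gives
each of the starting models equal weight, whereas frame pooling weights
long ensembles more.

# Contacts

**C$_\alpha$ maps.** A residue pair is in contact when the C$_\alpha$
distance is strictly below the cutoff (default 12 Å; the boundary itself
is excluded, so a pair at exactly 12 Å does not count). Intra-chain pairs
with $|i-j| \le 2$ are excluded as trivially close. Pairs are classed
K1-K1, K10-K10 or K1-K10. The production path is a vectorized all-pairs
distance computation; the test-suite oracle recomputes every map with an
independent double loop.

**Ensemble probabilities.** The probability of a pair is the weighted
fraction of frames containing it. Mixed full/truncated ensembles are
normalized by restricting each pair's denominator to the models that
contain both residues, so head/rod pairs are averaged over all 25 models
while tail pairs are averaged over the full-dimer models only. Per-model
weighting (each model counts equally, via its within-model frame
frequency) is the default; per-frame weighting is available.

**Typed side-chain census.** Each residue-type pair maps to at most one
interaction class, by precedence: acid-base > hydrogen-bond > aromatic >
hydrophobic. A contact exists when the minimum distance over the class's
reference atoms is below the class cutoff: acid-base 4.0 Å between
charged-group N/O atoms; hydrogen-bond 3.5 Å between polar side-chain
heavy atoms, with both candidate sites checked for Ser/Thr/Gln/Asn;
aromatic 7.0 Å between ring centroids; hydrophobic 5.4 Å between closest
side-chain carbons. The published pairing matrix this emulates is not
available in machine-readable form; the shipped table
(`inst/extdata/contact_types.tsv`) is therefore a declared substitute
with conventional structural-biology cutoffs, editable by the user, not a
reconstruction.

**Ideal a/d contacts.** The heptad register (letters a–g, with stutters
advancing the phase by three) supports an ideal knobs-into-holes count:
per aligned heptad the core layers contribute a-a′ and d-d′, plus the
same-heptad cross pairings a-d′ and d-a′ — four pairings per complete
heptad. The rule is frozen in one documented function and enumerated
directly from register letters, so stuttered registers are handled by
construction.

**Hydrogen bonds.** Donor (N, hydroxyl/thiol O) to acceptor (O) heavy-atom
pairs within 3.5 Å, with a Baker–Hubbard-style angle criterion at the
acceptor (donor⋯acceptor–antecedent ≥ 120°) replacing the
donor-H-acceptor angle when no hydrogens exist. The angle criterion
matters: a pure distance criterion also collects $i,i{+}2$ and $i,i{+}3$
backbone pairs in α-helices (their N⋯O distances sit near 3.2–3.4 Å);
with it, an ideal 20-residue helix yields exactly the sixteen
$i \to i{+}4$ bonds.

# Model building

Starting configurations of the disordered domains are built from backbone
dihedrals using canonical bond geometry (N–CA 1.458 Å, CA–C 1.525 Å, C–N
1.329 Å; angles 111.2°/116.2°/121.7°): a β-strand-like stretch with a
nine-residue hairpin turn at φ = −162.5°, ψ = +162.5°, ω = 180°. The
build/measure round trip is exact to numerical precision and is
property-tested on random legal dihedral specifications.

The 25 starting models are the full grid of five fold orientations (A:
both chains toward the K1 face; B: toward the K10 face; C: each onto the
opposite chain's face; D: each onto its own face; E: extended) × five
hairpin shifts (n ∈ {−5, 0, 3, 5, 10} residues toward the rod — increasing
residue numbers for the head, decreasing for the tail, since the rod lies
C-terminal and N-terminal of them respectively). Base turn windows are
K1:103–111/K10:86–94 (head) and K1:534–542/K10:498–506 (tail), applied
with the same n to every chain. Ten models are full dimers (head and tail
folded in the same direction) and fifteen are truncated (head–1A–L1–1B,
cleaved at K1:328/K10:296 with a harmonic C$_\alpha$–C$_\alpha$ restraint,
equilibrium 14.37 Å, force constant recorded as printed, 1000 kcal
(Å mol)⁻¹ — a dimensionally odd unit that is flagged, not silently
"corrected", in the emitted restraint block). Which grid cells are full
versus truncated is not published in machine-readable form; the shipped
allocation (`inst/extdata/model_allocation.tsv`, full scope at n ∈ {0,10})
is an editable reconstruction. Energy minimization and molecular dynamics
are out of scope: the package builds and analyzes coordinates, it does
not simulate them.

# The synthetic generators, and what passing tests show

Every analysis stage is validated against structures with known ground
truth:

* `generateCrickCoil()`: two minor helices (radius 2.26 Å, rise 1.51
  Å/residue, 3.6 residues/turn — the canonical α-helix values, which
  reproduce the 3.8 Å C$_\alpha$ spacing) wound about a superhelix of
  prescribed radius, pitch and handedness, the second chain 180° across
  the axis. Parameter recovery holds to <2 % (radius) and <5 % (pitch)
  with exact handedness over r₀ ∈ [3, 8] Å and pitch ∈ [100, 300] Å.
* `generateAlphaHelix()`: ideal isolated helix, C$_\alpha$-only or full
  backbone from ideal helical dihedrals.
* `generateGlobularChain()`: self-avoiding random walk (3.8 Å steps,
  4.0 Å exclusion, rejection sampling) rescaled to an exact target radius
  of gyration. Targets below a dense-packing estimate (~1.8 n^⅓ Å) are
  refused.
* `perturbEnsemble()`: seeded isotropic Gaussian jitter, for contact
  frequency fixtures with predictable statistics.
* `assembleSyntheticDimer()`: places globules at requested (d, θ_r), the
  exact inverse of the measurement, closing the placement→measurement
  loop to 0.1 Å and 1°.

All randomness flows through explicit seed arguments; global RNG state is
saved and restored. Test problem sizes (60–120-residue coils, 25–30
residue globules, ≤200-frame jitter ensembles) were chosen so the whole
suite completes in seconds while keeping every statistical check several
standard errors away from its threshold.

These fixtures are idealized: perfect helices, isotropic noise, globules
with no sequence character, and no side chains except where constructed
by hand. Passing tests therefore demonstrate that the estimators are
correct on their defining geometry and stable under noise — not that real
equilibrated keratin ensembles (which contain kinks, stutters, splayed
ends and correlated motion) are reproduced. On real data the profile
quantities remain well-defined but their interpretation near
discontinuities (the 2B stutter, the C-terminal splay) needs the same
care as with any local estimator.

# Numerical choices and limitations

* Strict `<` at contact cutoffs; `<=` for the hydrogen-bond distance.
* Degenerate geometry returns `NA` markers (indeterminate pitch,
  on-axis θ_r) rather than errors; genuinely invalid input (too-short
  ranges, missing C$_\alpha$, empty point sets) errors with the offending
  chain/residue named.
* Axis estimation assumes locally helical geometry; across hard kinks the
  bisector construction blends the two sides over its 4-residue window.
* The whitespace PDB dialect assumes per-chain 1-based numbering; altloc
  records other than blank/'A' are dropped.
* Sequence-level metrics use fixed formal charges (K/R = +1, D/E = −1,
  His neutral at pH 7); no pKa modelling.
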