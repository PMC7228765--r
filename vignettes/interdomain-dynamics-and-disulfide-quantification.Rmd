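---
title: "Methods: inter-domain distance correlation and disulfide-bond quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inter-domain distance correlation and disulfide-bond quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dicckit)
```

dicckit implements two complementary analyses for studying multi-domain
membrane transporters: a trajectory pipeline that measures concerted
inter-domain motion, and a mass-spectrometric pipeline that quantifies how
completely an engineered cysteine pair is disulfide-bonded. This vignette
documents the models, the estimator conventions, the tunable parameters,
and what the synthetic-data generators do and do not emulate.

## 1. The distance correlation coefficient (DiCC)

### Model and conventions

Given an aligned trajectory, each domain is reduced to a vector series: one
row per frame, holding either all of its C-alpha coordinates concatenated in
atom order (`mode = "concatenated"`, the default) or the unweighted C-alpha
centroid (`mode = "centroid"`). For a series $A$, the inter-frame Euclidean
distance matrix $d^A_{ij}$ is double-centered,
$a_{ij} = d^A_{ij} - \bar d^A_{i\cdot} - \bar d^A_{\cdot j} + \bar d^A_{\cdot\cdot}$,
and the distance covariance is the biased V-statistic
$v(A,B) = n^{-2} \sum_{ij} a_{ij} b_{ij}$. The coefficient reported is

$$\mathrm{DiCC} = \frac{v(A,B)}{\sqrt{v(A,A)\,v(B,B)}}.$$

Two conventions deserve emphasis:

* **The $1/n^2$ normalization is kept as is.** No unbiased (U-statistic)
  correction is applied. The estimator is therefore positively biased for
  independent series at finite $n$: two unrelated stationary series of a
  few hundred effective samples typically show DiCC of a few hundredths,
  not zero.
* **No outer square root is taken.** In the common convention the ratio of
  V-statistics equals the *squared* distance correlation; dicckit reports
  the ratio itself. Values are therefore lower than the square-rooted
  convention would give, but the ordering of domain pairs — which is what
  the analysis interprets — is unchanged.

Degenerate (constant) series raise an error rather than returning zero: a
silent zero would corrupt the ranking of matrix entries. Tiny negative
round-off (above $-10^{-12}$) is clamped to zero; diagonal entries of a
DiCC matrix are set to 1 by construction without being computed.

### Superposition and its interaction with DiCC

Frames are superposed with the Kabsch algorithm (SVD of the 3×3
cross-covariance; the rotation is constrained to determinant +1). The
default reference is the first frame, on all C-alpha atoms, unweighted; the
reference frame is configurable. Fewer than three selected atoms, or a
collinear selection, is an error.

One subtlety matters when validating against synthetic ground truth.
Superposition removes the *best-fit rigid component* of every frame's
displacement. If the domains of a system move purely by rigid translations
(as the minimal generator below produces), that best-fit component contains
part of the inter-domain signal itself: in the extreme case of two domains,
alignment makes their residual motions exact mirror images and DiCC
approaches 1 regardless of the true coupling. For this reason:

* `dicc_matrix(align_first = TRUE)` (the API default) is appropriate for
  raw trajectories that carry genuine global motion;
* ground-truth validation on generator output — which is already expressed
  in a common frame — uses `align_first = FALSE`, and the command-line
  `analyze-dicc` likewise treats its input as pre-aligned unless
  `--align true` is passed.

When the generator's optional global rigid motion is enabled, alignment
removes it exactly (the fitted transform composes with the injected one),
and the resulting matrix agrees with the motion-free run to machine
precision.

### Replica averaging

Production analyses average DiCC matrices element-wise over independent
replica trajectories of the same system (`replica_average()`), with the
diagonal pinned at 1. The package's own recovery checks use three replicas
per condition: a single stationary run of 1000 frames with an
autocorrelated latent process carries only a few hundred effective samples,
and near the bottom of the coupling range the single-replica estimate is
statistically indistinguishable from the V-statistic bias floor.

### RMSD

`rmsd_series()` reports the per-frame root-mean-square deviation of a
selection (typically backbone atoms N, CA, C, O) from a reference frame,
without per-frame re-fitting; set `align_first = TRUE` to superpose on the
selection first, which yields the conventional RMSD-versus-time trace. The
reference defaults to the first frame; an energy-minimized or mean
structure can be substituted by placing it as the reference frame.

## 2. The synthetic trajectory generator

`simulate_trajectory()` emulates the one feature of a production MD
trajectory that the DiCC analysis consumes — correlated rigid-body domain
motion — and nothing else. Domain $k$ is displaced at frame $t$ by

$$u_k(t) = \lambda_k\, s(t) + \eta_k(t),$$

with $s$ a shared latent 3-vector process, $\lambda_k \in [0,1]$ the
per-domain loading, and $\eta_k$ independent per-domain noise. Defaults,
chosen once to mimic an equilibrated production run over a few domains of a
large membrane protein:

| parameter | default | meaning |
|---|---|---|
| `n_domains` | 4 | the NTD/MLD/CTD/TMD-style partition |
| `atoms_per_domain` | 30 | one C-alpha per residue |
| `n_frames` | 1000 | snapshots of one replica |
| `latent_process` | mean-reverting, step 1.0 Å, reversion 0.1 | stationary AR(1); a random-walk option mimics drifting runs |
| `latent_loadings` | 0.7 | moderate shared motion |
| `independent_noise_sd` | 0.5 Å | per-domain wobble |
| `per_atom_jitter_sd` | 0 | optional thermal jitter |
| `global_rigid_motion` | off | optional whole-body tumbling, removable by alignment |

The mean-reverting default keeps the series stationary so DiCC estimates
stabilize with $n$; the random-walk option is retained for drifting
trajectories. Seeds are mandatory — no generator call is silently
stochastic — and output is bit-reproducible per seed.

`locked_pair_config()` emulates an engineered inter-domain disulfide: the
two locked domains share one pair-specific latent (loading 1) and a single
shared noise process, making their displacement series identical; other
domains are untouched. The locked pair is then, by construction, the
arg-max off-diagonal DiCC entry — mirroring what an engineered
domain-locking bridge does to a real correlation matrix.

**What the generator does not emulate:** internal domain deformation,
rotational domain motion, solvent and membrane coupling, or any real
protein geometry beyond contiguous residue blocks placed ≥ 20 Å apart.
Passing recovery tests on this generator therefore demonstrates estimator
correctness (the pipeline recovers known coupling from trajectories of this
motion class), not fidelity of any particular force field or system.

## 3. Peptide mass arithmetic

Monoisotopic masses are computed from a fixed atomic-mass table (H
1.007825, C 12, ¹³C 13.003355, D 2.014102, N 14.003074, O 15.994915, S
31.972071; proton 1.007276), residue compositions of the 20 standard amino
acids, one water per peptide, and modification deltas derived from the
element table rather than hard-coded: carbamidomethyl +C₂H₃NO (+57.02146
Da) and its ¹³C₂D₂ heavy counterpart (+61.04072 Da, Δ 4.01927 Da).
Enriched labels are treated as isotopically pure; at the 10 ppm matching
tolerance used downstream, the ~98–99 atom % purity of commercial reagent
does not shift any quantity this package computes.

Disulfide formation between two peptides removes exactly two hydrogens.
For electron-transfer dissociation of a disulfide precursor, the
conventions are: thiol fragment = peptide + H (even-electron), radical
fragment = peptide (thiyl radical); both assignments of a peptide pair are
reported.

Isotope envelopes are aggregated isotopologue distributions built by
successive convolution of per-element natural-abundance vectors at unit
nominal-mass spacing — no fine structure — with peaks placed at
$m/z_{\mathrm{mono}} + k \cdot 1.00336/z$ and intensities renormalized over
the retained peaks (default 6). The implementation is checked against an
independent exhaustive enumeration of isotopologue combinations with
closed-form multinomial probabilities.

## 4. Quantifying the disulfide-protected fraction

### Labeling model

The experiment labels free cysteines with heavy iodoacetamide, reduces
disulfides, then labels the newly freed cysteines with light reagent. The
light-labeled envelope therefore marks molecules whose cysteine was
disulfide-protected; light/light and heavy/heavy control samples provide
the limiting envelopes.

### Estimator

The observed heavy/light envelope is modeled as a non-negative linear
combination of the two measured controls, each first normalized to unit
total intensity so the weights act as molar-fraction proxies:

$$\mathrm{obs} \approx w_L \cdot \mathrm{light} + w_H \cdot \mathrm{heavy},
\qquad f = \frac{w_L}{w_L + w_H},$$

solved by non-negative least squares. This formalizes, deterministically,
what is otherwise done by manual fitting of intensity-weighted control
distributions. The residual reported is the fraction of observed intensity
unexplained, $\sum|\mathrm{obs} - \mathrm{fit}| / \sum \mathrm{obs}$. The
estimate is invariant to uniform rescaling of any input's intensities.

### Peak matching and the near-coincidence of the label grids

All three samples are extracted on the combined light+heavy m/z grid with
nearest-by-ppm matching (default tolerance 10 ppm), each observed peak
assigned to at most one expected position. One numerical fact shapes this
step: the heavy-minus-light shift (4.01927 Da per label) is close to, but
not equal to, four isotopologue spacings (4 × 1.00336 Da), so the light
peptide's 4th isotopologue and the heavy monoisotopic peak are separated by
only ~5.5/z ppm. At MS1 resolving power these two species produce a single
centroid. dicckit therefore merges expected positions closer than the
matching tolerance into one shared grid slot, treated as an m/z *interval*
(ppm distance measured from the nearer edge), and the linear model
apportions the shared intensity between the labels. Without this merge,
hard per-peak assignment under ppm-scale calibration error misattributes
the dominant peak and the fit degrades badly; with it, recovery is exact in
the noiseless limit and accurate to well within ±0.02 under realistic
noise.

### The synthetic spectrum generator

`simulate_peak_list()` produces the observed mixture
$f \cdot \mathrm{light} + (1-f) \cdot \mathrm{heavy}$ plus both controls,
with: normal m/z jitter of 3 ppm (default), multiplicative intensity noise
of 2 % CV (default), optional decoy peaks kept ≥ 50 ppm from every expected
position, and centroid coalescence below 10 ppm as described above
(`centroid_merge_ppm`, emulating ~60k resolving power). With all noise at
zero, $f = 1$ reproduces the light control exactly and $f = 0$ the heavy
control. It does not emulate chromatographic integration, charge-state
envelopes other than the one requested, deamidation or oxidation
satellites, or detector saturation — so passing recovery tests shows the
estimator handles envelope mixing, calibration error, multiplicative noise
and unrelated ions, not every failure mode of a real LC-MS run.

## 5. Numerical choices and degenerate inputs

* Kabsch: rotations are proper by construction; collinear or < 3-point
  selections raise a degenerate-superposition error naming the frame.
* DiCC: constant series raise a degenerate-series error naming the domain;
  values in $(1, 1+10^{-9}]$ from round-off are clamped to 1.
* Arg-max reporting: ties in the strongest-pair report break by
  lexicographic label order, deterministically.
* Peak matching conflicts resolve globally in order of increasing ppm
  error; the tie is deterministic.
* Multi-model PDB I/O delegates parsing and formatting to bio3d, with
  added validation: models must agree in atom count and ordering, residue
  numbers above 9999 refuse to write, and the first alternate location
  wins. Coordinates round-trip to the format's 10⁻³ Å precision; metadata
  round-trips exactly.
* Problem sizes in the shipped checks (chosen as the smallest that make
  the statistical assertions stable): 1000-frame series for coupling
  recovery with three replicas per loading; 500-frame series for
  locked-pair ranking; 200-frame series for self-correlation.

## 6. Known limitations

* DiCC values from the concatenated and centroid reductions differ in
  general; neither is claimed to reproduce any particular published
  matrix, whose values depend on trajectories not distributed with their
  paper. The package's validation targets are ground-truth recovery and
  internal identities, plus the printed peptide masses.
* The V-statistic bias means small DiCC values (≲ 0.05 at these problem
  sizes) should be read as "indistinguishable from independent".
* The quantification assumes exactly one cysteine site per peptide;
  multi-cysteine peptides are rejected rather than deconvolved.
* No profile-spectrum processing: inputs are centroided peak lists.
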