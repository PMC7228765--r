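# dicckit

Quantitative analysis of **inter-domain protein dynamics** and of
**engineered disulfide bonds**, built around two questions that arise when
probing multi-domain membrane transporters such as the cholesterol
transporters NPC1 and NPC1L1:

1. *Do two protein domains move together?* From a structural trajectory,
   dicckit superposes frames (Kabsch), computes backbone RMSD traces, and
   measures concerted motion between domain pairs with the **distance
   correlation coefficient (DiCC)**.
2. *Did an engineered cysteine pair actually form its disulfide, and in
   what fraction of molecules?* dicckit provides the peptide mass
   arithmetic for disulfide-linked species (precursor m/z, electron-transfer
   dissociation fragment masses, isotope envelopes) and quantifies the
   **disulfide-protected fraction** from heavy/light iodoacetamide-labeled
   MS1 envelopes.

A synthetic-data module generates trajectories with controlled inter-domain
coupling and labeled-peptide peak lists with known protection fractions, so
every analysis stage can be validated against ground truth.

## The statistics at the core

**Distance correlation.** For two vector series $\{A\}$ and $\{B\}$ of $n$
frames (the per-frame positions of two domains), let $d^A_{ij}$ be the
Euclidean distance between frames $i$ and $j$ of series $A$, and let

$$a_{ij} = d^A_{ij} - \bar d^A_{i\cdot} - \bar d^A_{\cdot j} + \bar d^A_{\cdot\cdot}$$

be its double-centered form. The (biased, V-statistic) distance covariance
is

$$v(A,B) = \frac{1}{n^2}\sum_{ij} a_{ij} b_{ij},$$

and the distance correlation coefficient is

$$\mathrm{DiCC} = \frac{v(A,B)}{\sqrt{v(A,A)\,v(B,B)}} \in [0, 1].$$

DiCC approaches 1 for concerted domain motion and 0 for independent motion,
and is invariant to translation, rotation, and uniform scaling of either
series. See the methods vignette for the estimator conventions.

**Protection fraction.** Free cysteines are alkylated with heavy
(¹³C₂D₂) iodoacetamide, disulfides are then reduced and alkylated with
light reagent, so the *light*-labeled envelope marks cysteines that were
disulfide-protected. The observed MS1 envelope is fit as a non-negative
linear combination of measured light/light and heavy/heavy control
envelopes (unit-normalized); the protected fraction is
$f = w_L / (w_L + w_H)$.

## Worked example

```r
library(dicckit)

## 1. Mass arithmetic for the engineered-cysteine peptides
p1 <- peptide("CQPPPPPMK")   # linker cysteine site
p2 <- peptide("NAAECDTY")    # C-terminal-domain cysteine site
peptide_mz(carbamidomethylate(p1), 2)   # 526.2568
peptide_mz(carbamidomethylate(p2), 1)   # 943.3462
disulfide_mz(p1, p2, 3)                 # 626.6004
print(as.data.frame(etd_disulfide_fragments(p1, p2)), digits = 6)
#>   thiol_peptide radical_peptide thiol_mass radical_mass
#> 1     CQPPPPPMK        NAAECDTY    994.485      885.317
#> 2      NAAECDTY       CQPPPPPMK    886.325      993.478

## 2. Quantify a disulfide-protected fraction (synthetic ground truth 0.84)
cfg <- spectrum_config(p1, true_fraction_protected = 0.84, charge = 2,
                       baseline_peaks = 5, seed = 42)
sim <- simulate_peak_list(cfg)
fit <- quantify_site(sim$observed, sim$light_control, sim$heavy_control,
                     p1, z = 2)
fit
#> <protection_fit: fraction protected = 0.843
#>  (w_light = 8.62e+04, w_heavy = 1.61e+04, residual = 0.0268)>

## 3. DiCC matrix of a synthetic 4-domain system with a locked MLD-CTD pair
lk <- locked_pair_config(trajectory_config(latent_loadings = 0.5, seed = 7),
                         pair = c(2, 3))
traj <- simulate_trajectory(lk)
m <- dicc_matrix(traj$trajectory, traj$domains, align_first = FALSE)
m
#> <dicc_matrix: 4 domains, mode=concatenated, 1000 frames>
#>       NTD   MLD   CTD   TMD
#> NTD 1.000 0.050 0.050 0.259
#> MLD 0.050 1.000 1.000 0.064
#> CTD 0.050 1.000 1.000 0.064
#> TMD 0.259 0.064 0.064 1.000
#> strongest inter-domain correlation: CTD-MLD = 1.000
```

The locked pair (here MLD–CTD) is exactly the pair with the strongest
correlated motion — the behavior expected of a domain pair tied together by
an engineered disulfide bridge. `tidy()`, `glance()` and `autoplot()`
methods are available for `dicc_matrix`, `rmsd_series` and
`protection_fit` objects; `write_dicc_tsv()`/`write_dicc_json()` and
`write_rmsd_tsv()` export results.

A command-line wrapper (`inst/cli/dicckit`) exposes the same stages as
subcommands (`simulate-traj`, `analyze-rmsd`, `analyze-dicc`,
`peptide-mass`, `simulate-spectrum`, `quantify-disulfide`).

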