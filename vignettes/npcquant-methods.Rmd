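---
title: "npcquant: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{npcquant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npcquant)
```

# Background

Loss-of-function mutations in *NPC1* cause Niemann-Pick type C1
disease: most are missense mutations whose protein product misfolds,
is retained in the endoplasmic reticulum, degraded by ERAD, and never
reaches the lysosomal membrane, so free cholesterol accumulates in
late endosomes/lysosomes. Pharmacological chaperones are small
molecules that bind the folding intermediate — here, the cholesterol
binding N-terminal domain (NTD) — stabilize it, and restore
trafficking. A chaperone screen of this design has two halves: an *in
silico* half (dock a drug library against the NTD, triage by score)
and a cell-based half (filipin staining for cholesterol storage,
NPC1/LAMP2 colocalization, Western blots with Endo H digestion for
maturation). `npcquant` implements the quantification chain of both
halves; it does not dock, segment cells, or detect bands.

# Docking triage

**Ligand (binding) efficiency.** Docking scores favour large
molecules, so affinity is normalised by size:
$$BE = E_b / N_{heavy} \quad \text{[kcal/mol per heavy atom]},$$
with $N_{heavy}$ the non-hydrogen atom count of the standard
structure. The packaged 12-row worked example reproduces every printed
efficiency under this formula at each row's own printed precision
(`verify_efficiency_table()` asserts
$|E_b/N_{heavy} - BE_{printed}| \le 0.5\cdot10^{-d}$ per row, with $d$
the row's printed decimals — one row is printed at 2 decimals, the
rest at 3).

**Heavy-atom counting.** No cheminformatics dependency is available to
the package, so `heavy_atom_count()` is a small SMILES lexer: organic
subset and aromatic symbols, two-letter halogens, bracket atoms
counting one each unless the element is hydrogen. Implicit hydrogens
never matter for a heavy-atom count, and no valence model is needed.
Anything unrecognised is a structured parse error, never a guess.

**Hit calling.** A compound is a hit when its binding energy is at
least as favourable as the natural-ligand reference
($E_b \le E_{ref}$, more negative = stronger). The comparison is
*inclusive* by construction: the worked example lists three compounds
exactly at the cholesterol reference of −11.3 kcal/mol as hits, which
forces tie inclusion. Ranking is deterministic: energy ascending, then
efficiency ascending, then compound id — ties in floating-point
energies would otherwise make report order platform-dependent.

**Engine output.** `parse_vina_result()` reads the two AutoDock Vina
result dialects (PDBQT `REMARK VINA RESULT` lines; the console
affinity table). Mode 1 is the best pose, per the engine's sorting; a
file whose affinities are not non-decreasing is rejected as corrupt
rather than silently re-sorted. Other formats are rejected explicitly.

# Filipin LSO compartment ratio

The statistic relates cholesterol storage to cell area using two
intensity thresholds on a single-channel image: the low threshold
delineates total cell area, the high one the bright storage-organelle
puncta. With $p_i$ the pixel intensities,
$$R_{LSO} = \frac{\sum_{p_i > T_{high}} p_i}{\#\{p_i > T_{low}\}}.$$

Numerical conventions, fixed at build time and recorded in every
output:

* **Strict inequalities** for both thresholds. The source assay
  description does not specify boundary handling; on real-valued data
  ties are measure-zero, so the choice is documented rather than
  configurable.
* The numerator is the **full intensity** of supra-threshold pixels,
  not the excess over the threshold — "total fluorescence intensity
  above the high threshold" is read as the summed intensity of the
  supra-threshold pixels.
* The thresholds themselves are **explicit per-run configuration**.
  The originating assay never reports its two values, and whether they
  were fixed across cell lines or chosen per image is unknown;
  `suggest_thresholds()` (50th/99th intensity percentiles of a control
  image) is provided for synthetic work and labelled an artifact
  default.
* A field with no pixel above $T_{low}$ is a *degenerate-field* error
  (classed condition), to be excluded and logged, not a zero.
* No background subtraction or flat-field correction is applied; none
  is described for the assay.

Fields are aggregated per experiment by the arithmetic mean (the assay
design images 10 random fields per experiment); that mean is the
replicate value passed to the statistics stage.

# Pearson colocalization

`pearson_colocalization()` computes plain Pearson correlation over all
paired pixels (or a supplied mask), the behaviour of the common ImageJ
colocalization plugin without Costes thresholding — whether Costes was
used in the source workflow is not stated, so the plain statistic is
implemented. Degenerate scope (fewer than 2 pixels, or a constant
channel) is a structured error: a correlation of a constant channel is
undefined, not zero. The statistic is invariant under positive affine
transforms of either channel and flips sign under negation, both of
which are property-tested.

# Blot densitometry and glycoforms

Total NPC1 (~180 kDa) is normalised per lane to beta-actin (43 kDa):
`level = npc1_signal / actin_signal`; treatment conditions are
compared to the DMSO control as `fold = level / control_level`.
Endo H digestion splits NPC1 into a resistant (~170 kDa, post-medial
Golgi) and a sensitive (~130 kDa, ER-retained) glycoform; fractions are
$f_R = R/(R+S)$ and $f_S = S/(R+S)$, computed **per lane** before any
averaging (the alternative — fractions of summed signals — is not what
the figure captions describe). All outputs are invariant to the
densitometer's arbitrary units, which is property-tested. Inputs are
assumed background-corrected upstream. Frameshift-truncated alleles
produce no band with a C-terminal antibody and are invisible to this
quantification. Replicate fold changes are aggregated arithmetically
(mean, SD); the source does not state its aggregation, so the choice
is recorded here.

# Group statistics

The decision logic mirrors the study design:

1. **Two groups**: unpaired two-sided Student's t-test (equal
   variances). No nonparametric two-group fallback is specified, so
   none is applied.
2. **More than two groups**: Shapiro-Wilk on *each group* at
   $\alpha = 0.05$ (the source names the test but neither the level
   nor whether it was per group or on residuals; per group is
   implemented). All pass → one-way ANOVA, then Dunnett's many-to-one
   post hoc vs the control. Any fail → Kruskal-Wallis, then Dunn's
   test vs the control with Bonferroni over the $k-1$ comparisons
   (the adjustment is unstated in the source; Bonferroni is the common
   conservative package default).
3. Stars from adjusted p-values with **strict** thresholds:
   `***` < 0.001, `**` < 0.01, `*` < 0.05, `ns` otherwise — p = 0.05
   exactly is `ns`.

A group with zero variance routes to the rank-based path: Shapiro-Wilk
is undefined on constant data, and treating that as "normal" would be
indefensible. All groups constant *and* identical is a degenerate-data
error.

**Dunnett without `multcomp`.** The many-to-one statistics
$T_i = (\bar x_i - \bar x_0) / (S\sqrt{1/n_i + 1/n_0})$ share the
control mean and pooled SD; their correlation matrix has the product
form $\rho_{ij} = \lambda_i\lambda_j$ with
$\lambda_i = \sqrt{(1/n_0)/(1/n_i + 1/n_0)}$. Conditioning on the
control deviate and on $U = S/\sigma$ factorises
$P(\max_j |T_j| \le q)$ into a product of normal CDFs under a 2-D
integral, which is evaluated with fixed Gauss-Hermite (64 nodes, over
the shared normal deviate) and Gauss-Legendre (64 nodes, over the chi
probability scale) quadrature. The result is deterministic —
bit-identical on repeated calls, unlike quasi-Monte-Carlo multivariate
t — and the test suite cross-validates it against `mvtnorm::pmvt` to
about $10^{-3}$. Adjusted p-values are single-step:
$p_i = 1 - P(\max_j |T_j| \le |t_i|)$.

# Synthetic data: the stated world

The generators exist so that every stage has inputs with the
*statistical structure* the stage assumes; they are deliberately
stylized. Defaults were chosen once, before any acceptance result was
observed, and are not revisited:

* **Filipin fields**: 256×256 px, 8 non-overlapping cells of radius
  18–30 px (a 20× fibroblast field at roughly 0.5 µm/px), cytoplasm
  baseline 40 and background 5 on an 8-bit-like scale, puncta of
  radius 2 px adding 150 intensity units in a perinuclear annulus at
  0.3–0.6 of the cell radius, additive Gaussian noise SD 5. The
  accumulation parameter $a \in [0,1]$ scales the punctum count per
  cell (≤ 15 at $a = 1$). Recommended thresholds sit halfway between
  background and baseline ($T_{low} = 22.5$) and halfway between
  baseline and the punctum level ($T_{high} = 115$). The ground-truth
  record (cell area, punctum pixels and their noise-free intensity
  sum) predicts the noise-free LSO ratio in closed form, which is
  tested.
* **Channel pairs**: shared-latent construction
  $ch_i = \mu_i + \sigma_i(\sqrt{\rho}Z + \sqrt{1-\rho}E_i)$ (sign
  flip in one channel for $\rho < 0$), exactly calibrated in
  population, defaults $\mu = 1000$, $\sigma = 100$ (clamping at zero
  is practically never active at this scale).
* **Blot tables**: mean-preserving lognormal noise
  ($\mathrm{meanlog} = -s^2/2$, $s^2 = \log(1+CV^2)$) so arithmetic
  recovery is unbiased; defaults CV 15 %, 4 lanes/condition, control
  NPC1/actin level 0.6 — a plausible infrared-blot regime.
* **Screen tables**: 1920 compounds (the filtered-library scale of
  the motivating screen) with a planted number of hits at or below
  the reference energy on the engine's printed 0.1 kcal/mol grid;
  non-hits at least 0.2 kcal/mol above, so the planted count is
  recovered exactly by construction.

Every generator runs under its spec's seed with the caller's RNG state
saved and restored: specs are pure functions, regeneration is
bit-identical, and generation never perturbs user code.

**What a green test does *not* establish.** The synthetic fields have
no cell-to-cell intensity variation, no uneven illumination, no
out-of-focus light, no shot noise, no segmentation ambiguity; the blot
generator has no band overlap or saturation. Green acceptance tests
establish that the *statistics are computed correctly and recover
planted truth under the stated noise model* — not that the pipeline
reproduces any wet-lab number. The study's cell-level results (e.g.
~92 % and ~50 % storage reductions, 2–3-fold proteasome-inhibition
increase, per-cell-line PCC and Endo H fractions) depend on real
images and lysates and are outside what desk-scale computation can
reproduce; they are echoed only qualitatively (e.g. a planted 2.5-fold
change is recovered within 15 % at n = 4, CV 15 %).

# Pipeline and provenance

`run_pipeline()` executes the configured stages in dependency order
(simulation → triage → imaging → blot → statistics). Each stage is
isolated: a structured failure is recorded in the report and the other
stages still run. The report carries a provenance block (config echo,
package and R versions, seed, timestamp); given the same config and
seed, stage results are identical. JSON reports are written at full
precision (`digits = NA`) so a write/read round trip preserves every
numeric value.

# Known limitations

* The SMILES lexer counts atoms; it does not validate chemistry.
* The TIFF codec reads only uncompressed single-sample baseline
  images (8/16-bit unsigned, 32-bit float); compressed, tiled or
  multi-sample files are rejected with a clear error.
* Dunnett p-values use fixed 64-node quadrature; accuracy is ~1e-5
  for the designs tested, which is ample for star annotation but not
  for extreme tail p-values.
* The LSO statistic is whole-image (or mask-based); there is no per
  cell segmentation, so the denominator mixes all cells in the field,
  exactly as in the whole-field assay it implements.
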