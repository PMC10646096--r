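---
title: "Models and methods behind ubiscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ubiscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubiscreen)
```

`ubiscreen` analyses proteome screens in which each ubiquitin-conjugating
enzyme (E2) is knocked down and the consequences are read out by
multiplexed TMT proteomics, RNA-seq, IP-MS interactome mapping, and
fluorescence imaging of peroxisomal protein import. This vignette
describes the statistical models, the parameters that matter, the
synthetic-data layer the package validates itself against, and the design
choices made where more than one reasonable convention exists.

## 1. Differential proteomics against in-set controls

A TMT "set" multiplexes several knockdown conditions with their own
non-targeting controls in one mass-spectrometry run; the default layout
in `experiment_design()` is 4 conditions × 3 replicates + 4 controls
per 16-plex set. Because a set is also a technical batch, every
comparison in `protein_differential()` is strictly *within set*:
knockdown replicates versus the controls of the same batch.

Abundances live on the log2 scale, so the fold change is an arithmetic
mean difference,

$$\log_2\!FC = \bar{y}_{kd} - \bar{y}_{ctrl},$$

and the p-value comes from a two-sided two-sample t-test. The
pooled-variance (Student) form is the default — "unpaired two-tailed
t-test" is the textbook reading with groups of 3 and 4 — and Welch is
available via `var_equal = FALSE`; the choice is recorded in the output's
`test` attribute. Two conventions keep degenerate inputs total rather
than erroring:

* proteins with fewer than two quantified replicates in either group are
  reported with missing statistics (never zero), and
* zero-variance inputs return p = 1, so noise-free simulations run
  through the full pipeline without special-casing.

The t statistics are evaluated rowwise in vectorised form across the
10^4-scale protein set; on any single protein the result agrees with
`stats::t.test` to numerical precision (the test suite asserts this on
randomized instances).

## 2. RNA-seq integration and transcription-independent calls

RNA evidence is tested non-parametrically on `log2(TPM + 1)`:
Kruskal–Wallis across the condition and in-set control groups (with two
groups this is the Wilcoxon rank-sum situation), plus Dunn's pairwise z
with tie correction,

$$z = \frac{\bar{R}_1 - \bar{R}_2}
{\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3 - t)}{12(N-1)}\right)
\left(\frac{1}{n_1} + \frac{1}{n_2}\right)}},$$

where $\bar R_g$ are mean ranks and $t$ runs over tie groups. Both
p-values are returned; `p_value` defaults to Dunn's (switchable with
`p_from = "kw"`), and all-tied genes are degenerate with H = 0, p = 1.
No cross-gene multiplicity correction is applied at this stage;
`p.adjust`-style FDR can be layered on the output.

`call_transcription_independent()` applies the screen thresholds
(defaults α = 0.05, |log2FC| > 0.2, both strict inequalities, recorded
verbatim in the output attributes). "No corresponding mRNA change" needs
an operational definition; the package uses the symmetric one: the mRNA
change *corresponds* iff it is significant at the same α, exceeds the
same fold-change threshold, and has the same sign as the protein change.
Proteins without a gene mapping or without mRNA data lack
counter-evidence: a significant protein call then stays
transcription-independent, and the number of such proteins is messaged
so silent drop-outs cannot occur. Calls are monotone in the thresholds —
shrinking α or raising the fold-change cutoff never adds calls — which
the property tests exercise.

`count_regulators()` summarises, per protein, how many conditions
modulate it transcription-independently, binned 1 / 2–4 / 5–9 / ≥10.
`overrepresentation()` is a plain upper-tail hypergeometric test with
Benjamini–Hochberg adjustment for annotation categories.

## 3. Interactome scoring from spectral counts

Spectral counts scale with protein length, so counts are first
normalised per residue and rescaled to the median prey length (keeping
the numbers on a count-like scale), then rounded to integer support.
For prey $p$ and bait replicate $r$ with rescaled count $x_{pr}$, the
enrichment probability is a Poisson mid-p value against the control
purifications:

$$s_p = \frac{1}{R}\sum_r \left[ P(X < x_{pr}) + \tfrac12 P(X = x_{pr})
\right], \qquad X \sim \text{Poisson}(\lambda_p),$$

with $\lambda_p$ the mean rescaled control count floored at
`pseudo_rate` (default 0.1) so that preys never seen in controls are
still scored against a small background. The score lies in [0, 1], is
monotone in every replicate count, and equals ≤ 0.5 when the bait never
detects the prey. It is deliberately a transparent, fully reproducible
probability; externally computed interaction probabilities (e.g. SAINT)
can be substituted column-for-column, since the downstream filter only
consumes `score`.

`filter_interactions()` keeps pairs with score ≥ threshold (inclusive,
default 0.65), and optionally requires (i) a contaminant frequency —
CRAPome-style, prey → fraction of control experiments detecting it,
either user-supplied or computed from the table's own controls by
`control_detection_freq()` — at or below a cap, and (ii) the maximum
bait-run spectral count to *strictly* exceed the maximum control-run
count ("consistently higher" reads as strict). Thresholds nest: lowering
the cutoff only adds edges. `bait_self_enrichment_check()` verifies each
bait is enriched in its own pull-down (a failed purification control),
and `build_network()` assembles an igraph-backed node/edge structure with
functional roles (UBL/E1/E2/E3/DUB/proteasome/autophagy/other, default
"other" with a warning).

## 4. Pairwise similarity and batch-aware z-scores

Starting from the proteins significantly modulated by at least one
knockdown (`select_regulated_union()`), each condition pair gets

* $R^2$: squared Pearson correlation of the two log2FC profiles over the
  pair's regulated proteins (equivalent to simple-regression R²;
  pairwise-complete). $R^2$ is sign-blind by construction; fewer than 3
  shared proteins or a zero-variance profile yields NA, not a number.
* $S = R^2 \times n$, the similarity score, where $n$ counts the
  regulated proteins entering that comparison. The default rule for
  "regulated in this comparison" is *either* condition calls the protein
  (the closest literal reading); `pair_universe` also offers the
  screen-wide union or the pair intersection.
* a z-score that absorbs batch structure: pairs sharing a TMT set form
  one group per set, all remaining pairs pool into a single extra-batch
  group, and each value is standardised against its own group's mean and
  sample SD. Groups with fewer than two values or zero SD give NA.
  Self-comparisons (the diagonal) are excluded from every group.

Interactome similarity applies the same R² to two baits' prey score
vectors over the union of scored preys, absent scores counting as 0; a
two-prey union always fits perfectly (R² = 1) and is flagged
`degenerate`. Sequence identity uses a Needleman–Wunsch global alignment
(Biostrings) with unit scoring — match +1, mismatch 0, linear gap −1 —
and reports matches / alignment length × 100; the scheme is configurable
and recorded in the result. `compare_similarity_layers()` joins any set
of layers into one tidy pair table with Spearman rank correlations,
returning NA (not zero) when a layer is constant.

## 5. Peroxisomal panel

`annotation_set()` carries a user-supplied panel (e.g. the peroxisomal
proteome) with a peroxin flag. `cumulative_pex_log2fc()` sums the
*signed* log2FC of PEX proteins over each condition's significant
transcription-independent calls — ups and downs may cancel, which is the
point of a net-adaptation summary; `split_direction = TRUE` gives the
separate sums, and `significant_only = FALSE` the unfiltered alternative.
The sum is additive over disjoint panels and unaffected by
non-significant members, both covered by tests.
`pex_regulator_counts()` reports, per peroxin, the number of conditions
with independent up- and down-calls.

## 6. Import imaging

The published screens segmented nuclei and puncta with trained ML tools
(StarDist-, ilastik-class). The defined computation, however, is the
overlap classification, so this package pairs it with deterministic
classical segmentation — Gaussian smooth → global threshold (Otsu or
absolute) → connected components → area filter — and an explicit seam:
label maps from any external segmenter can be wrapped with
`labeled_puncta()` and fed straight into classification.

Conventions are fixed for oracle-testability: 8-connected components
(diagonal pixels join), 0-based (row, col) centroids, areas in pixels
internally and µm² on export. Each PMP70 punctum's `overlap_fraction` is
the share of its pixels covered by any PTS1 punctum; puncta at or above
`min_overlap_fraction` (default 0.1 — robust to single-pixel
coincidences; pass a tiny value for an any-overlap rule) are functional,
the rest ghosts. Only PMP70 defines peroxisomes: PTS1-only spots never
create calls, and functional + ghost always equals the PMP70 punctum
count. Field statistics are the functional fraction with a Wilson score
interval (`prop.test`, no continuity correction), puncta per nucleus,
and punctum size summaries.

## 7. The synthetic-data layer

Every analysis stage is validated end to end against generators with
known ground truth. The generator defaults *are* the screen's design
conditions and are not tuned per analysis:

* **TMT** (`simulate_tmt_experiment`): per-protein baseline
  N(10, 1) log2 units; per-(batch, protein) offset N(0, 0.3) drawn once,
  shared by all samples of the set — this is precisely the structure the
  intra-/extra-batch z-scoring is designed to absorb; injected effects in
  log2FC units; i.i.d. measurement noise N(0, `noise_sd`), default
  0.1 log2 units (a realistic replicate CV for deep TMT data). At
  `noise_sd = 0` the pipeline inverts the generator exactly.
* **Truth** (`simulate_regulation_truth`): regulated proteins per
  condition with ±`effect_size` (default 0.5); designated condition
  pairs draw a configurable fraction (default 0.5) of their targets,
  with matching sign, from a shared pool — the minimal mechanism that
  produces graded pairwise R². mRNA concordance defaults to 0.2: in this
  class of screen most protein-level changes arise
  post-transcriptionally, so a minority of effects are mirrored in mRNA.
* **RNA-seq** (`simulate_rnaseq_counterpart`): log-normal baseline
  expression, multiplicative log2-normal noise (default SD 0.25),
  columns rescaled to TPM (sum 10^6). The rescaling slightly perturbs
  individual fold changes; with effects sparse relative to the gene
  background the factor is ≈ 1.
* **IP-MS** (`simulate_ipms_counts`): Poisson counts; true prey rates in
  bait runs only, contaminants in all runs, high bait self-counts
  (default mean 50); defaults of 3 bait and 10 control runs.
* **Imaging** (`simulate_scene`, `render_peroxisome_field`): isotropic
  Gaussian spots truncated at 4σ (closed-form centroids for oracle
  tests), filled-disc nuclei, and a noise model with background,
  Gaussian, and optional Poisson stages. Object placement guarantees
  pairwise separations large enough for the default segmentation to
  recover every object (puncta ≥ 10 px; nuclei get a wider clearance
  because they are smoothed at a coarser scale).

What the generators deliberately do **not** emulate: reporter-ion ratio
compression and interference in TMT, count-based (negative-binomial)
RNA-seq noise at the read level, correlated contaminant structure in
IP-MS, and realistic optics (PSF shape, uneven illumination, 3-D
structure) in imaging. Passing the recovery tests therefore shows the
analysis inverts its own stated data model — it does not certify
performance on real acquisitions, where the segmentation seam and the
external-score override exist precisely so that specialised upstream
tools can be swapped in.

## 8. Validation scale and numerical choices

The packaged validation (test suite and `scripts/acceptance.R`) runs at
deliberately desk-sized problem scales, chosen to estimate each property
with comfortable margin: null type-I error from 10 screens × 10^4
proteins (99% binomial band around α), similarity discrimination and
noisy-imaging recovery over 100 seeded runs each, IP-MS recall/FDP over
50 seeded networks, and oracle equivalence on ≥100 randomized small
instances per statistic. Tolerances in tests are either exact
(conventions, conservation laws, 10^-10-level oracle agreement) or the
binomial/Monte-Carlo bands implied by those run counts — never tuned
constants.

Known limitations: Dunn's z uses the normal approximation (exact
permutation p is impractical beyond toy sizes and is used only as a test
oracle); the Poisson mid-p score is a calibrated ranking device, not a
posterior probability of interaction; global-alignment identity depends
on the scoring scheme when sequences diverge; and co-optimal alignments
can differ in gap placement, so identity is reported for the alignment
actually returned.
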