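---
title: "Methods: paired proteome/phosphoproteome differential analysis and KSEA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired proteome/phosphoproteome differential analysis and KSEA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`phosphopair` analyses label-free quantitative proteomics and
phosphoproteomics from paired tumor and noncancerous adjacent tissue (NAT),
stratified into two histological subtypes (invasive ductal carcinoma, IDC,
and invasive lobular carcinoma, ILC). The canonical design is five tumor/NAT
pairs per subtype — twenty samples, ten patients — and every computation in
the package is organized around that pairing.

Inputs are MaxQuant-style tables: a proteinGroups-dialect table with
`Intensity <sample>` columns, and a Phospho(STY)Sites-dialect table whose
intensities carry `___1/___2/___3` suffixes separating quantifications by
peptide multiplicity (the number of phosphates on the carrier peptide). Two
conventions are enforced at read time and nowhere else:

* intensity `0` means *not quantified* and becomes an explicit missing
  value; a zero can never re-enter through a round trip;
* reverse-decoy and contaminant rows (flagged `+`) are removed. Decoy-based
  FDR control is assumed to have been applied by the upstream search and is
  not recomputed.

The protein-group identifier is the first accession of
`Majority protein IDs`: deterministic, and the common practice for
protein-group keyed joins. The intensity column family is configurable
(`Intensity` vs `LFQ intensity`) because either may be exported; `Intensity`
is the default.

# Normalization

Samples differ in loading and acquisition efficiency by a roughly
multiplicative factor, so normalization acts additively in log2 space.
`global_normalize()` shifts each sample so that its median of *present*
log2 intensities equals the grand median of the pre-normalization sample
medians. Missing values are excluded from the statistics and untouched by
the shift; consequently the operation is idempotent, preserves ranks within
each sample, and recovers planted per-sample scale biases on null synthetic
data with Pearson r > 0.99 at 5,000 features (the acceptance script
recomputes this correlation; at 1,000 features the sampling noise of a
median leaves r around 0.98–0.995, so the validation uses the larger
feature count). A total-intensity variant is available via
`method = "total"` for users who prefer scaling to summed signal; the
median was chosen as the default because it is robust both to missingness
and to a modest fraction of truly differential features. Protein and
phosphosite matrices are normalized independently by the same procedure.

Note that median alignment fixes only the per-sample location. Under
intensity-dependent dropout the observed median is a biased estimate of the
sample's scale, which is why the bias-recovery property is validated
without dropout; with 10% missing-not-at-random cells the recovered offsets
remain strongly correlated with the truth but no longer reach r = 0.99.

# The three-criterion paired screen

For each feature and subtype, three quantities are computed:

1. **Per-pair fold changes.** For each patient, FC = tumor / NAT on the
   linear scale; if either member is missing the pair contributes nothing.
   The subtype **mean FC** is the geometric mean of present pair FCs
   (arithmetic mean of log2 ratios, exponentiated) — ratios compose
   multiplicatively, so the geometric mean is the natural center; an
   arithmetic option exists.
2. **Welch t-test.** A two-tailed unequal-variance t-test of all tumor
   versus all NAT log2 intensities within the subtype, with
   Welch–Satterthwaite degrees of freedom. The unpaired form is deliberate
   (it is the test named for this screen); a patient random effect in the
   synthetic generator makes the validation conservative with respect to
   the ignored pairing. Features with fewer than two present values in
   either group are uncallable. The implementation is vectorized over
   features; `stats::t.test(var.equal = FALSE)` serves as the independent
   oracle in the test suite, with agreement to 1e-10.
3. **Concordant-pair fractions.** The fraction of present pairs whose
   individual FC reaches the threshold in each direction
   (FC ≥ 1.5 up, FC ≤ 1/1.5 down). Present pairs are the denominator,
   consistent with excluding missing values everywhere else; this choice is
   documented here because with ≤ 5 pairs the two denominators genuinely
   differ.

A feature is called **up** when p < 0.05 AND mean FC > 1.50 AND the up
fraction exceeds 0.60 strictly; **down** symmetrically with FC < 0.67
(= 1/1.5) and the down fraction; otherwise **ns**. The strict inequality is
the only reading under which "more than 60%" and "more than 3 of 5 pairs"
agree (4+ of 5, 7+ of 10), so strictness is applied to every fraction,
including the patient-coverage filter that admits only features quantified
(both members present) in more than 60% of *all* pairs in the design.

No multiple-testing correction is applied by default — the screen filters
on the raw p-value and relies on the conjunction with the fold-change and
concordance criteria, which makes it conservative relative to p < 0.05
alone (on null synthetic data fewer than 5% of features are called;
the suite verifies this over 20 seeds). `p.adjust` can be applied by users
on the emitted tables if desired.

# Phosphosite processing

Sites pass a class-I filter: localization probability strictly greater
than 0.75, flags clear. Multiplicity classes are kept as separate
quantitative features — the same site quantified from singly- and
doubly-phosphorylated peptides carries distinct biology — keyed
`"<protein>:<residue><position>:<multiplicity>"` (e.g. `P1:S15:2`), which
lets sites flow through the identical normalization/screen machinery as
proteins.

Protein-level phosphorylation fold change is the **median** of the
protein's site-level log2 mean FCs, exponentiated, with the minimum site
p-value and the site count carried along. The median was chosen for
robustness to a single outlying site; a mean option exists. A protein
counts as a *differential phosphoprotein* when at least one of its sites
receives a non-ns call. On synthetic data with a protein-level shift
applied to all four sites of a protein, the aggregate recovers the true FC
within 1.3x for ≥ 90% of planted proteins.

# Cross-subtype integration

`quadrant_classify()` partitions (FC_IDC, FC_ILC) pairs into five mutually
exclusive regions with the screen's strict thresholds: both up, both down,
the two discordant quadrants, and "other".

`discordance_groups()` classifies the 4-tuple of directional states
(protein-IDC, protein-ILC, phospho-IDC, phospho-ILC), where a state is up
(FC above 1.5), down (below 1/1.5) or maintained:

* **G1** — protein up in both subtypes, phosphorylation up in IDC and down
  in ILC;
* **G2** — protein not down in either subtype, phosphorylation down in IDC
  and not down in ILC;
* **G3** — protein maintained in IDC and up in ILC, phosphorylation down or
  maintained in IDC and maintained or up in ILC.

Two numerical choices matter here. First, when classifying *printed*
fold-change tables (rounded to two decimals) the state bounds are
inclusive: a printed 0.67 is a value rounded to 1/1.5, and only the
inclusive rule reproduces printed groupings; full-precision pipeline values
use strict bounds. Second, G2 and G3 overlap on part of the state space
(e.g. the tuple maintained/up/down/up satisfies both). Precedence is
most-specific first — G1, then G3, then G2 — because G3's protein pattern
(`maintained` exactly, in IDC) is the narrower condition; every pattern a
feature satisfies is additionally surfaced in a `matches` column so that
borderline tuples are reported rather than silently resolved. Features
matching no pattern are `unassigned` — deliberately: some published
dual-layer values are inconsistent with their accompanying prose, and the
classifier reports what the numbers say.

# Kinase-substrate enrichment analysis

For kinase k with m quantified substrate sites, the activity score is

$$ z_k = \frac{(\bar{s}_k - \bar{p})\sqrt{m_k}}{\delta} $$

where \(\bar{s}_k\) is the mean log2 FC over the kinase's substrate sites
and \(\bar{p}\), \(\delta\) are the mean and sample (n−1) standard
deviation over **all** quantified sites. The two-tailed p-value is the
standard-normal tail; positive z reads as activation in tumor. Design
details:

* sites contribute once per (gene, site) key — multiplicity classes of the
  same site are collapsed by their mean log2 FC, and duplicate annotation
  rows count once;
* gene-symbol matching is case-insensitive; the site string (`S473`) must
  match exactly, following the PhosphoSitePlus `SUB_MOD_RSD` convention;
* the site-level log2 FCs fed in are the per-subtype geometric-mean pair
  FCs, because kinase activity is reported per subtype;
* significance requires p < 0.05 **and** m ≥ 3 substrates;
* a constant shift or positive rescaling of all site FCs leaves every z
  unchanged (the suite asserts both invariances to 1e-12), and an
  all-identical background is rejected as degenerate rather than scored.

Kinases are annotated with the ten sequence-based kinome groups (AGC, CAMK,
CK1, CMGC, STE, TK, TKL, RGC, Atypical, Other) from a bundled map that
covers common exemplars; it is a lookup fixture, not a complete kinome
classification, and unmapped kinases are reported as `unknown`.

# The synthetic-data generator

`simulate_protein_dataset()` / `simulate_phospho_dataset()` generate the
canonical study design with known ground truth. The measurement model on
the log2 scale is

$$ y_{fs} = \mu_f + u_{f,\mathrm{pat}(s)} + \beta_f\,[\,s\ \mathrm{tumor}\,]
  + o_s + \varepsilon_{fs} $$

with feature baselines \(\mu_f \sim N(25, 2^2)\) (typical extracted-ion
intensity magnitudes), a patient random effect \(u\) (SD 0.3) shared by the
two members of a pair, planted true effects \(\beta\), per-sample scale
offsets \(o_s\) (SD 0.25), and residual noise (SD 0.5). Dropout is
missing-not-at-random: the probability of losing a cell is logistic in its
standardized log2 intensity (slope 1.0), with the intercept solved
numerically so the overall missing fraction hits the requested rate (10%
by default). MNAR rather than MCAR because label-free phosphoproteomics
missingness is strongly intensity-dependent, and the present-pairs
denominators in the screen deserve to be stress-tested by it.

Defaults are fixed as the study conditions: 5 pairs per subtype, 1,000
proteins (10% planted differential at FC 3.0, random direction, the same
effect in both subtypes), 2,000 phosphosites, kinase activations expressed
as a coherent log2 shift on all of a kinase's annotated substrate sites in
the tumors of one subtype, localization probabilities drawn so ~10% of
sites fail the class-I filter, multiplicities from {1, 2, 3} at
0.6/0.3/0.1. All randomness flows from a single seed and the session RNG
state is restored afterwards; equal seeds give byte-identical fixture
bundles.

What the generator does **not** emulate: correlated missingness between
multiplicity classes, match-between-runs artifacts, shared peptides between
protein groups, batch structure beyond the per-sample offset, and any
relationship between the protein and phosphosite universes (they use
independent feature identifiers, so cross-layer overlap statistics are
exercised on the bundled printed-table fixture, not on simulations).
Passing the recovery suites therefore demonstrates correctness of the
computations under a credible noise model, not performance on real tissue
data.

# Validation summary and problem sizes

The test suite and `scripts/acceptance.R` recompute, at these sizes chosen
to keep a full run in the low minutes on one CPU:

* printed-table worked examples (13 proteins): discordant quadrant counts
  (1 and 2), dual-layer overlap (10), and G1 exactly
  {KTN1, ROA1, SEPT2, SEPT9} under the inclusive-bound rule;
* Welch and KSEA oracle equivalence (100 and 50 random instances, 1e-10);
* screen monotonicity in all three thresholds; normalization idempotence
  and bias recovery (5,000 features);
* planted-protein recovery at the study conditions over 20 seeds: median
  recall lands near the low seventies of percent against the 80% design
  target with ±10-point stochastic tolerance — the patient-coverage filter
  under MNAR dropout removes roughly a sixth of planted features before
  the screen sees them (without dropout the screen's own power is ~93%) —
  with median FDR well under 10%;
* planted-kinase top-|z| recovery in 100 seeded runs (observed 100%) and
  KSEA null calibration (observed ≈ 5% of kinases at p < 0.05 under no
  planted effect).

# Known limitations

* The Welch test ignores the pairing it sits next to; with five pairs per
  subtype this forfeits power but never inflates type I error. A paired
  alternative is a natural extension.
* Median normalization cannot separate a true global expression shift from
  a scale bias; a dataset where most features genuinely move will be
  over-corrected.
* Protein-level phospho aggregation by median discards site heterogeneity;
  proteins with oppositely-moving sites are summarized near 1.0 while
  still being flagged through `any_called`.
* The KSEA p-value assumes independent substrate sites; sites on one
  substrate protein violate this mildly.
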