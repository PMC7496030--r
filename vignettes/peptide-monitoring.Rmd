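---
title: "Targeted peptide monitoring for mAb quality attributes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted peptide monitoring for mAb quality attributes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mampep)
```

## The problem

Multi-attribute monitoring of a therapeutic monoclonal antibody quantifies
many product quality attributes — deamidation, oxidation, succinimide
formation, N-terminal pyroglutamate, C-terminal lysine clipping, the Fc
N-glycoform distribution — in a single LC-MS run of a tryptic digest. Each
attribute is measured at the peptide level: the protein is digested, the
modified and unmodified forms of the site-bearing peptide elute as separate
chromatographic peaks (or separate masses), and the attribute value is the
modified share of the summed extracted-ion-chromatogram (XIC) areas.

`mampep` implements that computation openly: digestion, mass and isotope
arithmetic, XIC peak integration, attribute rollup and precision
statistics, plus a synthetic run generator that stands in for raw
instrument data, so that every downstream stage can be validated against a
known ground truth.

## Digestion model

Trypsin cleaves C-terminal to K and R, never before P; chain termini count
as canonical termini. `digest_chains()` enumerates all fully specific
peptides with up to `max_missed` internal missed cleavage sites as unions
of consecutive zero-missed fragments, so the peptide set with
`max_missed = 1` covers every residue even where a perfect digest would
produce unobservably short fragments. Peptides shorter than 2 residues are
dropped by default (single residues are not retained or observed in this
LC setup); the cut-off is a parameter. `enumerate_semi_specific()`
enumerates peptides with exactly one canonical terminus; these are used
only to classify observed components for the non-specific cleavage rate.

Ambiguous deamidation sites (two candidate asparagines in one peptide,
written with a tilde, e.g. `HC~N392/N387`) are treated as a single
peptide-level attribute: MS1-only data cannot localise the modification,
so no attempt is made to split it between candidate residues.

## Masses, modifications and isotope envelopes

Residue elemental compositions, isotope masses/abundances, modification
deltas and glycan compositions live in versioned CSV tables under
`inst/extdata/` and are exposed via `amino_acid_table()` and friends.
A peptide's monoisotopic mass is the sum of residue masses plus water plus
the modification delta; `m/z = (M + z·1.007276)/z`. Fixed-delta
modifications are elemental (deamidation `+O −N −H` = +0.98402 Da), so the
isotope envelope of a modified form is always computed from its true
composition. Glycans are monosaccharide compositions; `A2Ga1G1F` is
deliberately composition-identical to `A2G2F` — the pair is isobaric and
distinguishable only chromatographically, as is aspartate isomerisation
(mass delta zero).

`isotope_envelope()` convolves per-element isotope distributions
(binomial/multinomial powers by binary exponentiation, truncated to the
requested number of peaks) and renormalises the returned peaks to sum
to 1. Tests verify it against a direct atom-at-a-time polynomial-expansion
oracle to 1e-6 for a 50-residue peptide.

## The synthetic study generator

The generator emulates the *acquisition conditions of the study design it
is meant to exercise*: centroided MS1-only runs of tryptic digests on a
105-min gradient, mass range 200–2000 m/z, triplicate digests per
laboratory, near-constant per-laboratory retention-time offsets of up to
about 2 min, and forced-degradation series with rising deamidation,
isomerisation and oxidation. Its defaults are therefore fixed:

| parameter | default | meaning |
|---|---|---|
| `gradient_min` | 105 | gradient length (min) |
| `scan_interval_s` | 2 | MS1 scan spacing (s); ~30 points across a peak |
| `peak_sigma_min` | 0.25 | Gaussian elution sigma (min) |
| `mz_range` | 200–2000 | acquired m/z range |
| `n_isotopes` | 4 | isotopologue peaks simulated per form and charge |
| `replicates` | 3 | replicate digests per laboratory |
| `noise_cv` | scenario-specific | log-normal intensity noise CV |
| `mc_fraction` | 0.15 | missed-cleavage form loading as a share of its parent |

Retention times come from an additive hydrophobicity score mapped affinely
onto [6.5, 98.5] min (leaving headroom so modification offsets stay inside
[5, 100]). This is a deterministic *synthetic elution model*, not a
calibrated retention predictor: it only needs to be bounded, reproducible,
and order-preserving for modified/unmodified pairs. Modification offsets
are fixed: deamidation +0.4 min (deamidated peptides elute slightly later),
oxidation −1.2 min, glycans −1.5 min, and isobaric variants
(isomerisation, A2Ga1G1F) +0.8 min relative to their mass-identical
partner — the default separation for species that must be resolved
chromatographically.

Ground truth is declarative (`make_ground_truth()`): pairwise attributes
carry a true modified fraction *f*, glycosylation sites carry glycoform
fractions renormalised to sum to 1 (the unglycosylated form is a member),
and each parent peptide carries a base loading *L*. Form abundances are
derived so the pipeline's estimators are exact at zero noise:

* pairwise modified form: `L·f/(1−f)` against reference `L`, so
  `mod/(mod+unmod)` equals *f* even when several modifications share one
  peptide (allocating `L·f` directly would bias each attribute by the
  others' totals);
* profile member: `L·f_g`;
* missed-cleavage partner: `mc_fraction` times its parent form's abundance,
  so combined-area rollups are exercised.

Charge states follow a fixed length rule (length < 15: z 1–2, otherwise
z 2–3), filtered to the acquired m/z range, with weights renormalised over
the surviving charges — so each form's total simulated XIC area equals its
abundance regardless of how many charges fall inside the mass range
(conservation; a glycopeptide losing z = 1 to the 2000 m/z limit is not
under-represented).

Noise is i.i.d. multiplicative log-normal per sampled centroid, with
`meanlog = −σ²/2` so the expectation is exactly 1. Because a peak is
sampled at ~30 scans, per-centroid noise largely averages out of peak
areas; replicate-level RSDs of recovered attributes are therefore smaller
than the RSDs of real injection replicates, which include digestion and
injection variability the generator does not model. Other real-data
features deliberately out of scope: profile-mode spectra, chimeric and
in-source artefacts (including in-source oxidation), ion mobility, and RT
*warping* (drift is a single per-laboratory affine shift, matching the
near-constant offsets the shift-correction step is designed for). Passing
tests demonstrate correctness of the computation under these conditions,
not instrument-level realism.

Runs are written to and read from standard mzML (centroided MS1, RT in
seconds per the controlled vocabulary) via Bioconductor `mzR`; identical
truth, scenario and seed give byte-identical peak lists.

## XIC quantitation

`extract_xic()` sums, per scan, all centroid intensities within a ppm
tolerance of the target m/z (tolerance on m/z, not neutral mass; the
monitoring default is 5 ppm). `detect_peak()` is a documented stand-in for
the vendor's unpublished peak detector, with these numerical choices:

* the trace is smoothed with a fixed 3-point moving mean for detection;
  integration uses the raw trace;
* the baseline is the median of the lowest decile of a *context region*
  around the expected RT (at least ±1 min, independent of the search
  window): a window narrow enough to isolate an isobaric pair is mostly
  peak, and a baseline estimated inside it would mask the peak itself;
* the noise level is a robust high-frequency estimate — the median
  absolute successive difference scaled to a white-noise sigma — rather
  than a whole-trace MAD, which a large genuine peak elsewhere in the
  context would inflate until small neighbours fall below threshold;
* candidate apexes are local maxima above `baseline + 3·noise` inside the
  search window; the candidate closest to the expected RT wins, ties to
  the larger height;
* bounds extend outward until the first *significant* valley (a rise above
  the running minimum exceeding 5% of apex height — plain noise wiggles do
  not truncate the tail) or a baseline crossing; the area is the
  trapezoidal integral in intensity·seconds;
* a candidate that does not rise above both its bounds by that same margin
  is a shoulder or noise bump, not a peak, and is reported not-found.
  Not-found is a value, never an error.

By default the XIC targets the monoisotopic isotopologue only, once per
charge state; summing further isotopologues is a sensitivity flag
(`sum_isotopes`). Either way, each component's area is divided by the
theoretical fraction of its isotope envelope that the XIC targeted
(`isotope_correct`): without this, mono-only areas of different
compositions are not comparable — the monoisotopic peak carries ~53% of
EEQYNSTYR's signal but only ~26% of its glycoforms', which would distort a
glycoform profile about two-fold on the unglycosylated member.

Inter-laboratory RT drift is corrected per run by `estimate_rt_shift()`:
the median observed-minus-expected apex over non-isobaric, fully cleaved
landmark components searched with wide (±3 min) windows. At least three
found landmarks are required; otherwise the function stops and advises a
manual retention-time update.

## Attribute rollup

Pairwise attributes are `100 · Σ area(modified set) / (Σ modified + Σ
reference)`, sums spanning all charge states and listed missed-cleavage
partners; the value is invariant to global intensity scaling and to adding
partners in the same modified:unmodified ratio. Zero denominators are
flagged undefined and excluded from statistics — never reported as 0,
which would bias precision estimates. C-terminal lysine loss is defined on
the chain C-terminal peptide pair, the clipped form being the "modified"
species (the dominant species in a typical IgG1).

Glycoform profiles report each member (including unglycosylated) as a
percentage of the site total; per-run values sum to 100 by construction.
Isobaric members are integrated from their separate RT windows. When the
chromatography cannot resolve such a pair — under the generator's fixed
0.25-min sigma and 0.8-min isomer offset, a pair at height ratio ~7.6
(A2G2F : A2Ga1G1F at their typical abundances) produces no distinct local
maximum for the minor isomer — the minor member is reported not-found and
the whole isobaric set is flagged `unresolved`, because the found
partner's peak necessarily absorbs the missing member's area. Flagging
rather than guessing is deliberate: no deconvolution of co-eluting isobars
is attempted. Equal-height isomer pairs (aspartate isomerisation at tens
of percent) are resolved and quantified normally.

Coverage maps mark a residue covered when any identified peptide spans it;
the recovery class bins the residue's summed MS1 area relative to the
chain's most-covered residue at thresholds >50 / >20 / >10 / >5 / >2 / >1%.
The normalising reference (most-covered residue) is a documented choice —
"recovery" has no universal numeric definition. Missed-cleavage and
non-specific rates are area-based shares (missed-cleavage area over all
specific peptide area; semi-tryptic area over all identified area), and
cross-laboratory peptide Venn membership matches peptides by (sequence,
modification) identity with mass agreement within the ppm tolerance,
ignoring charge state.

## Precision statistics

RSD is `100·s/x̄` with the sample (n−1) standard deviation throughout —
the convention of analytical chemistry at n = 3–4. `anova_precision()`
fits a one-way ANOVA with laboratory as the factor, per attribute:
repeatability variance is the within mean square; the between-laboratory
component is `max(0, (MS_B − MS_W)/n₀)` with `n₀` the effective cell size
for unbalanced designs. Intra-laboratory RSD derives from the within MS
and pooled inter-laboratory RSD from the total variance, both relative to
the grand mean. A second inter-laboratory figure — the RSD of laboratory
means — is reported alongside, clearly labelled, because published
inter-laboratory RSDs are most often computed that way; the two differ
when within-laboratory scatter is large. P-values are descriptive; no
multiple-testing correction is applied.

One floor-behaviour property is worth stating precisely: under a zero lab
effect the between component is floored at 0 exactly when F < 1, which for
3 laboratories × 3 replicates happens with probability
`pf(1, 2, 6) ≈ 0.58` — not almost always. The tests assert that observed
rate, since no unbiased moment estimator can floor more often.

`trend_summary()` summarises degradation series per attribute and time
point (mean, RSD, delta versus the first time point, monotone-increase
flag), flagging missing cells rather than erroring.

## Workflow orchestration

`mam_config()` binds sequences, the component panel, simulation or mzML
inputs and all processing parameters into one validated configuration
whose hash is recorded in every output; `run_workflow()` executes
digest → simulate/read → shift-correct → quantify → rollup → statistics
and emits the report bundle as tibbles and CSVs. Identical configuration
and inputs give byte-identical report bodies. Component validation mirrors
the monitoring panel's exclusion rules — sodium/potassium adducts, unknown
modification names and components above the missed-cleavage cap are
rejected with per-row diagnostics (non-fatally, so a panel can be
triaged). Per-component found/not-found tallies are logged so peak
integration can be audited.

## Problem sizes and test design

The test suite and the acceptance script run entirely on synthetic data
generated at run time: the bundled two-chain synthetic IgG1-like construct
(108 + 63 residues, chosen so its tryptic map contains the classic
site-bearing peptides), study panels of ~20–46 components, and 1–6 runs of
3151 scans each. These sizes make a full end-to-end study simulate and
quantify in a few seconds while exercising every code path (isobaric
pairs, missed-cleavage partners, multi-charge forms, drift correction).
Property tests use exhaustive independent oracles on small random inputs:
substring-enumeration digestion on ≤80-mers, atom-at-a-time isotope
convolution, per-scan XIC window sums, and closed-form two-group ANOVA.

## Known limitations

* The peak detector is a documented stand-in, not a vendor reimplementation;
  absolute areas are not comparable to any specific commercial integrator,
  only ratios and recoveries are meaningful.
* Isobaric pairs at extreme height ratios are flagged unresolved rather
  than quantified (see above); real chromatography with sharper peaks may
  resolve what the generator's fixed peak width cannot.
* Replicate RSDs on synthetic data understate real inter-injection
  variability (no digestion/injection noise model).
* Drift correction is a single affine shift per run; gradient warping is
  out of scope, as are MS/MS identification, localisation scoring and
  intact-mass deconvolution.
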