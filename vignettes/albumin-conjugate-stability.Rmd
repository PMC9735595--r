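---
title: "Covalent albumin binding and plasma stability of thiol peptides: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covalent albumin binding and plasma stability of thiol peptides: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(albustab)
```

## The problem

Peptide drugs carrying a free cysteine can react in plasma with the body's
thiol pools. Human serum albumin (HSA) contributes by far the largest
reduced-thiol pool (Cys34, roughly 0.4 mM of reactive thiol), with
low-molecular-weight (LMW) thiols — cysteine, homocysteine,
cysteinylglycine, glutathione — adding some 12–20 µM. A peptide whose
cysteine forms a mixed disulfide with one of these partners disappears
from a conventional LC-MS assay of the free analyte while potentially
remaining biologically active, so an MS-based stability read-out and a
functional (receptor-competition) read-out can disagree by an order of
magnitude. `albustab` implements the computational chain needed to detect
and quantify this situation:

1. **masses** — exact monoisotopic mass and elemental-composition algebra
   for peptides, modifications, disulfide links, and thiol adducts;
2. **digestion** — in-silico tryptic proteolysis with missed cleavages;
3. **conjugate search** — enumeration of candidate species (free peptide,
   carrier-fragment crosslinks, LMW adducts, dimers, oxidation forms,
   alkylated controls) and ppm-tolerance assignment of observed masses,
   including a reduction/alkylation consistency control;
4. **quantify** — isotope-pattern prediction, extracted-ion chromatograms
   (XICs) at the most intense isotopologue, trapezoidal peak areas per
   incubation timepoint;
5. **kinetics** — one-phase decay half-lives and 4PL IC50
   competition-curve fits;
6. **synthetic data** — a seeded generator producing peak lists and
   activity tables with a ground-truth manifest, so the entire chain is
   testable without instrument data.

## Mass arithmetic

All masses derive from one table of monoisotopic element masses
(`ELEMENT_MASS`; H = 1.0078250319, C = 12 exactly, N = 14.0030740,
O = 15.9949146, S = 31.9720707; proton = 1.0072765). A peptide's formula
is the sum of its residue formulas plus one water; a disulfide bridge
removes two hydrogens (−2.015650 Da) once per link. Thiol-adduct deltas
are therefore *free compound minus H2*: cysteine C3H7NO2S gives
+119.0041 Da, homocysteine +133.0197 Da, cysteinylglycine +176.0256 Da,
glutathione +305.0682 Da. Symmetric dimer adducts (e.g. cystine bound to
the peptide thiol) lose H2 twice, once internally and once on attachment.
Carbamidomethylation adds C2H3NO (+57.0215 Da) and marks a reduced
cysteine.

Two interpretation choices are deliberate:

* A printed "+31.98 Da" oxidation is modelled as **dioxidation**
  (+2 × 15.994915 = +31.9898 Da). A printed "+47.94 Da" species is
  modelled as **trioxidation** (+47.9847 Da); no standard modification
  sits at exactly +47.94, and the value is treated as an imprecisely
  printed trioxidation rather than given its own entry.
* Masses are carried at full double precision throughout; rounding to the
  3–4 decimals used in reports happens only at the reporting layer.

## Digestion

Trypsin cleaves C-terminal to K or R, except before proline (the field's
default rule; both lead-peptide fragments VPCVS and KLPCVS are consistent
with it, and the internal `...KLP...` motif requires the proline
exception to yield KLPCVS at one missed cleavage). Fragments carry
1-based inclusive positions, a missed-cleavage count equal to the number
of internal sites spanned, and default `max_missed_cleavages = 2` (the
workflows need 1; the headroom is cheap). At zero missed cleavages the
fragments tile the parent exactly — a property the test suite checks on
random sequences.

## Conjugate search

`enumerate_conjugates()` forms the Cartesian product of cysteine-containing
carrier and analyte fragments as disulfide-linked candidates;
`enumerate_adducts()` adds the free peptide, LMW adducts, the homodimer,
+O2/+O3 oxidation of the free peptide (oxidation is not stacked on
adducts by default, which keeps the candidate space linear), and the
carbamidomethylated control. Matching reports *every* candidate within
tolerance ranked by |ppm| — no silent best-hit selection — with a default
20 ppm window and a strict 5 ppm tier for crosslink confirmation.
Intra-peptide disulfides and species linking three or more peptides are
out of scope: the chemistry under study is a single mixed disulfide.

The **reduction/alkylation control** encodes the logic that a genuine
disulfide crosslink must vanish after DTT reduction plus iodoacetamide
alkylation, being replaced by the carbamidomethylated carrier fragment.
Each crosslink match is marked `pass` only if both conditions hold in the
reduced-condition mass list; absent reduced-condition data the control is
explicitly `not evaluated`, never silently passed.

One observed value in the motivating data set is internally inconsistent:
a reported 3100.753 Da fragment attributed to albumin 21–41 linked to
KLPCVS. The stated components sum to 3075.593 Da, 25.16 Da short of the
reported mass, and no standard modification accounts for the difference.
`crosslink_components()` reproduces the component arithmetic and reports
the discrepancy; the pipeline does not force a match.

## Quantification

Isotope patterns are computed by per-element convolution of
natural-abundance distributions at nominal (integer) mass-offset
resolution, with offset spacing 1.00336/z — fine structure within an
isotopologue is far below the ±20 ppm extraction window and is not
modelled. The XIC for a species is extracted at its *most intense*
theoretical isotopologue (for peptides above ~92 carbons this is the A+1
peak, not the monoisotopic one). Default charge states are {3, 4} for
conjugates and {1, 2, 3} for the free peptide and small adducts.

Peak areas are trapezoidal integrals of the XIC over retention time.
Interactive vendor tools pick peak boundaries with proprietary defaults
that cannot be reproduced bit-exactly; the package integrates the full
trace by default and offers `apex_window()` (contiguous region above 5%
of the apex) as a documented, reproducible alternative. Retention-time
prediction is not attempted — species identity comes from mass alone.

## Kinetics

Half-lives come from least-squares fits of
\(Y(t) = (Y_0 - P)\,e^{-Kt} + P\), with half-life \(= \ln 2 / K\).
Fitting uses bounded Levenberg–Marquardt with a deterministic
initialization (Y0 from the earliest observation, plateau from the
minimum or fixed 0, K from a log-linear regression over the first decade
of decay) and bounds \(K \in (10^{-6}, 10]\) /min, so results are
reproducible without random restarts. The plateau is fixed at 0 for MS
peak-area decays and free (bounded by the data) for functional-activity
decays, where residual plateaus of activity are commonly observed for
albumin-bound species. Non-decaying data return a fit with the half-life
flagged *not determined* — never a fabricated number.

Dose–response curves use the standard 4PL inhibition model on
log-concentration,
\(Y = B + (T - B) / (1 + 10^{(\log_{10} IC_{50} - \log_{10} c)\,h})\)
with Hill slope \(h < 0\) for inhibition; top/bottom can be constrained
to 100/0 when responses are normalized (100% = vehicle, 0% = isotype
control — a documented preprocessing step upstream of the fit).
Monotone-increasing "competition" data are flagged, not fitted.

**Remaining activity.** Activity loss is quantified from the IC50
trajectory. The literal ratio \(IC_{50}(t)/IC_{50}(0) \times 100\)
*increases* as a compound loses potency, which contradicts its use as
"remaining activity"; the package therefore reports
\(IC_{50}(0)/IC_{50}(t) \times 100\) as the default convention (activity
falls from 100% as IC50 rises) and also emits the literal ratio labelled
`as_printed`. Both numbers are returned so either convention can be
audited.

## The synthetic-data generator

The generator emulates the structure of a spiked-plasma experiment, not
its mechanism: a free peptide pool that disappears with rate
\(a = k_{deg} + k_{conv}\) (proteolysis plus conversion), feeding bound
pools (LMW adduct, albumin-fragment crosslink, dimer) that each decay
with their own, typically much slower, rate. The two-compartment system
has the closed-form solution

\[F(t) = F_0 e^{-at}, \qquad
B_i(t) = B_{i0}e^{-k_i t} + \frac{c_i F_0}{k_i - a}\,(e^{-at} - e^{-k_i t}),\]

which the test suite verifies against an independent ODE integration.
Defaults mirror the studied system: analyte ILRWSRKLPCVS with carrier
fragment ALVLIAFAQYLQQCPFEDHVK, free-pool degradation half-life 1.7 min,
conversion half-time 2.5 min, stable bound pools, sampling at
0, 5, 10, 20, 30, 45, 60, 90, 120 min. The true interconversion rates in
plasma are not known quantitatively; these conversion defaults are
illustrative and the qualitative pool behaviour (fast free-pool loss,
stable Cys-bound pools) is what they encode.

Peak lists place each species as a Gaussian elution profile (SD 0.06 min,
scans every 0.02 min) whose isotope-cluster intensities follow the
theoretical pattern, with multiplicative log-normal intensity noise
(default CV 10%) and Gaussian m/z jitter (default SD 3 ppm — plausible
high-resolution Orbitrap-class behaviour), plus Poisson-count decoy peaks
constrained to lie at least 50 ppm from any true signal so that decoys
can never leak into a correctly-extracted XIC. Seeds are mandatory
arguments and fully determine the output. The generator does **not**
simulate profile-mode spectra, chromatographic tailing, ion suppression,
co-eluting isobars inside the ppm window, or retention-time drift — so
passing round-trip tests demonstrate correctness of the extraction and
fitting chain, not robustness to every artefact of real LC-MS data.

## Problem sizes and numerical choices

The test suite and the reproduction script run at desk scale: mass
checks are closed-form; parameter-recovery experiments use 200 seeded
replicates per half-life regime (9, 6, 1.7, 0.7 min) at CV 10% on the
experiment's sampling grids, and 50 replicates for IC50 recovery at 5%
noise. For the 0.7 min regime the functional grid alone (first sample at
5 min, seven half-lives in) cannot constrain the rate, so the grid is
augmented with t = 1 and 2 min points, matching how sub-minute decays
need early sampling. Isotope convolution uses exponentiation-by-squaring
with the distribution truncated at 64 offsets; patterns are normalized
before pruning (default threshold 1e-4 of total abundance) so that
retained-mass bookkeeping is exact. Digest output is deterministically
ordered by start position then length; candidate tables by mass;
matching ties are all reported.

## Known limitations

* Precursor-mass logic only: no MS/MS fragment-ion scoring of crosslinks.
* Average (isotope-weighted) masses, non-canonical residues, and intact
  protein masses are out of scope; carriers are represented by their
  digested fragments.
* One protease (trypsin) is built in; the rule table is extensible.
* The decay and 4PL fitters are single-phase/single-site by design —
  matching the analysis they reproduce — and will flag, not model,
  more complex kinetics.
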