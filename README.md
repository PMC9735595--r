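# albustab

Peptide drugs that carry a free cysteine can bind covalently to plasma
thiols — above all to Cys34 of human serum albumin, the largest
reduced-thiol pool in blood — by forming a mixed disulfide. The free
peptide then vanishes from a conventional LC-MS stability assay within
minutes while a functional (receptor-competition) assay still sees
activity, because the albumin-bound peptide remains active. `albustab`
implements the computational chain that detects and quantifies this
situation for cysteine-containing CXCR4-antagonist peptides and their
plasma conjugates:

* **Exact mass arithmetic** — monoisotopic masses and elemental-composition
  algebra for peptides, disulfide links (−2 × 1.0078250 Da per bridge),
  low-molecular-weight thiol adducts (Cys +119.0041, homoCys +133.0198,
  CysGly +176.0255, GSH +305.0682 Da), dimers, oxidation forms, and the
  carbamidomethyl alkylation control (+57.0215 Da).
* **In-silico tryptic digestion** with missed cleavages (cleave after K/R,
  not before P) and cysteine-fragment filtering.
* **Conjugate search** — enumeration of crosslink/adduct candidate species
  and ppm-tolerance assignment of observed masses, with a
  reduction + alkylation consistency control for every crosslink call.
* **XIC quantification** — theoretical isotope patterns, extracted-ion
  chromatograms at the most intense isotopologue (±20 ppm, z = 3/4 for
  conjugates), trapezoidal peak areas per incubation timepoint.
* **Kinetics** — one-phase decay half-lives
  (`Y(t) = (Y0 − P)·exp(−Kt) + P`, t½ = ln 2 / K) and 4PL IC50
  competition-curve fits with remaining-activity tracking.
* **Synthetic data** — a seeded generator for peak lists and activity
  tables with a ground-truth manifest, so the whole chain runs and is
  tested without instrument data.

## Worked example

Confirm the albumin–peptide crosslink from digest masses, then fit a
half-life from a simulated incubation:

```r
library(albustab)

res <- cmd_conjugates(list(analyte_seq = "IVRWSKKVPCVS",      # WSC02
                           carrier_seq = "ALVLIAFAQYLQQCPFEDHVK",
                           observed = 2933.484,               # native digest
                           reduced  = 2489.2799))             # after DTT + IAA
res$matches
#>                            label     class theoretical      ppm
#> 1 ALVLIAFAQYLQQCPFEDHVK-SS-VPCVS crosslink    2933.482 0.696374
res$reduction_control
#>                            label crosslink_absent cam_fragment_present status
#> 1 ALVLIAFAQYLQQCPFEDHVK-SS-VPCVS             TRUE                 TRUE   pass
```

The observed 2933.484 Da digest fragment matches the disulfide-linked
albumin-21–41 × VPCVS candidate within 0.7 ppm, disappears on reduction,
and is replaced by the carbamidomethylated carrier fragment
(2489.278 Da theoretical): the crosslink call passes its control.

```r
sc <- simulation_scenario(seed = 1, times = c(0, 1, 2.5, 5, 10, 15, 20))
runs <- emit_peaklists(sc)                  # centroided peak lists + manifest
species <- attr(runs, "species")
tc <- timecourse(runs, species[species$label == "free", ], charges = 1:3)
fit_one_phase_decay(tc$time_min, tc$area)
#> <decay_fit> Y(t) = (Y0 - Plateau) exp(-K t) + Plateau
#>   Y0 = 6.267e+04, plateau = 0 (zero), K = 0.7011 /min
#>   half-life = 0.9886 min (RSS 3.516e+05, n = 7)
```

The free pool disappears with rate `k_deg + k_conv` (degradation half-life
1.7 min plus conversion into bound pools at half-time 2.5 min ⇒ apparent
half-life ≈ 1.01 min); the fitted 0.99 min reflects that combined rate at
the generator's 10% intensity noise.

A thin shell front-end wraps the same functions:

```sh
exec/albustab digest --sequence ILRWSRKLPCVS --mc 1 --out fragments.tsv
exec/albustab simulate --seed 5 --out simdir/
```

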