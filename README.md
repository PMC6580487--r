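# cdpqc

Quality-control toolkit for cystine-dense peptide (CDP) production
pipelines.

CDPs are small disulfide-stabilized mini-proteins explored as therapeutic
scaffolds. Whether the disulfide core actually formed is a critical quality
attribute of every produced batch. The standard bench readout is a pair of
UV chromatograms of the same protein — one intact, one treated with the
reducing agent dithiothreitol (DTT). If disulfides formed and were reduced,
the DTT trace elutes at a shifted retention time; the overlay pattern
places each sample into one of four categories:

| Category         | Overlay pattern                                           |
|------------------|-----------------------------------------------------------|
| `Perfect`        | one intact peak, one reduced peak, clearly shifted         |
| `PerfectPartial` | one intact peak; reduced trace has one overlapping and one shifted peak (partial reduction — DTT-resistant core) |
| `Simple`         | up to the `-Classification` bound of peaks (default 2), shoulders included |
| `Complex`        | more than the bound in either trace                        |

`cdpqc` automates this call: traces are normalized by subtracting the blank
injection that precedes every three sample pairs, baseline noise σ is
estimated robustly (1.4826 × MAD of the peak-free flanks), and local maxima
are accepted as peaks when both height and topographic prominence reach
`SN × σ` inside the retention-time window `[MinRTForPeak, MaxRTForPeak]`.
Partially resolved shoulder peaks are recognized by a valley-fraction
criterion (plus a curvature recruit for shoulders that never form a second
maximum) and count toward the peak totals.

The package also covers the surrounding in-silico bookkeeping of a CDP
registry:

* **Peptide properties** — average and monoisotopic mass with the
  disulfide correction (−2 m_H per bond: full oxidation assumed,
  `n_SS = ⌊n_Cys/2⌋`), net charge at pH 7.4 by Henderson–Hasselbalch
  summation (EMBOSS pKa set), Kyte–Doolittle GRAVY hydrophobicity, and
  duplicate-sequence detection.
* **ESI m/z validation** — observed m/z checked against
  `(M + z·m_p)/z` for z = 1..6 at 20 ppm.
* **Whole-body autoradiography (WBA)** — ordinary least-squares standard
  curve `dpm = a·raw + b` and transformation of tissue signals to
  decays per minute.
* **Synthetic data** — a labeled chromatogram batch generator (Gaussian
  peaks, baseline drift, additive noise, blank-every-three-pairs layout)
  used throughout the test suite.

## Worked example

```r
library(cdpqc)

## a labeled synthetic batch: one pair per category, noise sd = 2 mAU
## (2% of the 100 mAU apex height)
batch  <- simulate_batch(c(Perfect = 1, PerfectPartial = 1,
                           Simple = 1, Complex = 1),
                         noise_sd = 2, seed = 42)
report <- classify_batch(batch$layout, batch$traces)
report[, c("sample_id", "category", "n_peaks_intact",
           "n_peaks_reduced", "shift_detected")]
#>   sample_id       category n_peaks_intact n_peaks_reduced shift_detected
#> 1   SYN0001        Perfect              1               1           TRUE
#> 2   SYN0002 PerfectPartial              1               2           TRUE
#> 3   SYN0003         Simple              2               1          FALSE
#> 4   SYN0004        Complex              1               3          FALSE
```

Each row is one intact/reduced pair after blank subtraction: `SYN0001`
kept a single peak whose apex moved by more than `overlap_tol` under DTT
(disulfides formed and reduced — `Perfect`); `SYN0002`'s reduced trace
split into an overlapping and a shifted peak (`PerfectPartial`);
`SYN0003` shows two intact peaks (at the `-Classification` bound, so
`Simple`); `SYN0004` has three reduced peaks (`Complex`).

```r
## in-silico properties of a 6-cysteine peptide (3 disulfides assumed)
peptide_properties(c(hitchhiker = "GCGSGCGKCWDECCK"))[
  , c("id", "average_mass", "monoisotopic_mass", "net_charge",
      "hydrophobicity")]
#>           id average_mass monoisotopic_mass net_charge hydrophobicity
#> 1 hitchhiker      1531.73           1530.48  -0.132759      -0.373333

## WBA: fit the standard line and transform tissue signals to dpm
curve <- fit_standard_curve(data.frame(raw_signal = c(10, 50, 120, 400),
                                       known_dpm  = c(210, 1010, 2410, 8010)))
curve
#> <cdp_standard_curve> dpm = 20 * raw + 10 (r2 = 1.0000, n = 4)
to_dpm(data.frame(tissue = c("brain", "tumor", "blood"),
                  raw_signal = c(35, 260, 4)), curve)
#>   tissue raw_signal  dpm flag
#> 1  brain         35  710
#> 2  tumor        260 5210
#> 3  blood          4   90
```

The masses include the −2 m_H-per-disulfide correction; the net charge is
the pH 7.4 Henderson–Hasselbalch sum with the three bonded cystine pairs
excluded from the acidic set; hydrophobicity is the mean Kyte–Doolittle
value (negative = hydrophilic).

## Command line

A launcher ships at `system.file("scripts", "cdpqc", package = "cdpqc")`:

```sh
cdpqc simulate --out-dir batch1 --per-class 2 --seed 7
cdpqc classify --manifest batch1/manifest.csv \
      -SN 10 -MinRTForPeak 5 -MaxRTForPeak 12 -Classification 2 \
      --out batch1/report.csv
cdpqc props --fasta peptides.fasta --ph 7.4 --out properties.csv
cdpqc wba --standards standards.csv --tissues tissues.csv --out dpm.csv
```

The historical single-dash flags (`-SN`, `-MinRTForPeak`, `-MaxRTForPeak`,
`-Classification`) are accepted as aliases of the long spellings.

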