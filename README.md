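# cherryS

S-allele and MGST genotyping for sweet cherry (*Prunus avium*) from
capillary fragment analysis.

## The problem

Sweet cherry is gametophytically self-incompatible: pollen carrying an
S-allele that matches either pistil S-allele is rejected, so growers need
compatible pollinizer pairings and breeders select for the self-compatible
(SC) mutant alleles S3′, S4′ and S5′ or for the MGST promoter insertion
associated with partial self-compatibility. A one-tube 27-primer multiplex
PCR read on a four-dye capillary resolves all of this in a single run:
universal S-RNase intron-1 fragments plus SC-discriminating SFB markers in
the blue channel, allele-specific confirmation fragments in red, the three
MGST promoter alleles in green, and a single-copy *PaveIF-1A* control in
yellow.

`cherryS` is that assay as software, for anyone who has the peak tables. It
ships the panel constants (primers, dye-channel fragment bins, dosage
calibrations), bins peaks to fragments at 0.45 nt tolerance (tight enough to
split the 1-nt S5/S5′ pair), applies the interpretation matrix for 14
self-incompatible allele classes, 3 SC alleles and 3 MGST alleles, and flags
everything it cannot prove.

The quantitative core handles the cases presence/absence cannot: a genotype
showing only S3, S3′, S4′ or S5′ may hide a second allele invisible to the
universal primers. With the diploid control fixed at two copies, the
control-normalized peak height indicates fragment copy number; each
calibrated ratio is scored as a z-value against the published two-copy and
one-copy group statistics (e.g. PaveIF-1A/227 = 1.17 ± 0.21 for S3S3′ vs
2.12 ± 0.25 for S3Sx), z-values are combined by root mean square, and the
nearest hypothesis within 3 combined SDs wins.

Also included: an in-silico multiplex PCR engine (IUPAC-degenerate binding
site search with a protected 3′ window, amplicon and dye-channel
prediction), a seeded peak-table simulator implementing the copy-number
height model, and a command line (`exec/cherryS`) wrapping it all.

## Worked example

Simulate a cultivar whose pattern shows only the S3 allele (the S3S3′
masking case), then call it:

```r
library(cherryS)
panel <- load_default_panel()

run <- simulate_run(c("S3", "S3p"), c("MGSTwt", "MGSTwt"),
                    sim_params(cv = 0.08, size_sd = 0.05, seed = 11),
                    panel, "cv-123")
run
#> <sample_run> cv-123: 4 peaks
#>  channel     size   height
#>        B 122.0589 1100.884
#>        B 226.9533 1724.915
#>        G 140.0662 2019.437
#>        Y 118.0312 1788.038

x <- call_genotype(run, panel, mgst_dosage = TRUE)
x
#> <genotype_call> cv-123
#>   S-genotype: S3S3' (dosage: homozygous_sc)
#>   MGST: MGSTwt/MGSTwt (determined)
#>   interpretation: self_compatible

x$dosage
#> <dosage_decision> S3_only: homozygous_sc -> (S3, S3')
#>   z_homo = 0.46, z_het = 3.93
#>         ratio_id  num  den    value
#>      ctrl_sfb122 Y118 B122 1.624184
#>    ctrl_rnase227 Y118 B227 1.036595
#>  rnase227_sfb122 B227 B122 1.566845
```

Only two blue peaks are present (122 + 227: an S3 pattern), yet the
control/227 ratio of 1.04 sits at the two-copy group mean (z = 0.46) and
almost four SDs from the one-copy mean — the 227 nt S-RNase fragment is
present in two copies, so the hidden second allele is S3′ and the tree is
self-compatible. `genotype_table()` flattens calls to one row per sample for
TSV export, and `genotype_report()` writes the full evidence as JSON.

Real peak tables come in the same way via `read_peak_table()` (simple
CSV/TSV or the tab-delimited genotypes-table export of common
fragment-analysis software), or through the command line:

```sh
cherryS call --in peaks.csv --report evidence.json > genotypes.tsv
```

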