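# barcodeaudit

Audit a DNA barcode reference library for species identification.

Regional barcode libraries — aligned mitochondrial COI fragments (typically
658 bp) tied to expert-identified voucher specimens — exist to answer one
question: *which species can a barcode identify reliably?* `barcodeaudit` is
for the people who build and curate such libraries (museum and monitoring
projects, conservation agencies, taxonomists). It runs the standard audit
end-to-end and reports, per species, whether the barcode is diagnostic,
why it fails when it fails, and how much adding morphology recovers.

## What it computes

* **K2P distances** with pairwise deletion of ambiguous/gap sites:
  `d = -½·ln((1−2P−Q)·√(1−2Q))`, with `P` the transition and `Q` the
  transversion proportion over the sites comparable in each pair. Saturated
  pairs are `NA`, never clamped.
* **Neighbor-joining trees** (Saitou–Nei Q-criterion, deterministic
  lexicographic tie-breaking), nonparametric **bootstrap support** over
  resampled alignment columns, and **midpoint rooting**.
* **Per-species audit**: max/mean intraspecific divergence, nearest
  non-conspecific neighbor, shared (identical) barcodes, monophyly status
  (monophyletic / paraphyletic / polyphyletic / singleton), two
  diagnosability criteria (barcode-cluster and species-specific-haplotype),
  cryptic-diversity flags at 2% and 3%, and nearest-match query
  identification with tie handling.
* **Integrative identification rates**: confusability graphs per evidence
  channel (barcode, male morphology, female morphology), edge-wise
  intersection for the integrated channels, and species-level
  "identification always possible" percentages.
* **A ground-truth simulator** (species clusters under an exact K2P
  substitution process on a coalescent-shaped species tree, singletons,
  mitochondrial introgression) so the whole pipeline is testable offline.

## Worked example

Simulate a small library with one introgression event (species002 donates a
haplotype to species006) and audit it:

```r
library(barcodeaudit)
sim <- simulate_library(sim_config(
  n_species = 8, specimens_per_species = c(4, 4, 3, 3, 3, 2, 2, 1),
  introgression_events = data.frame(donor = 2, recipient = 6, n_specimens = 1),
  seed = 42))
aud <- species_audit(sim$library)
aud
#> Barcode library audit: 8 species, 22 specimens
#>   monophyletic 5 | paraphyletic 1 | polyphyletic 1 | singleton 1
#>   cluster-diagnostic: 6 (75.0%); haplotype-diagnostic: 6 (75.0%)
aud$assessments[, c("species", "n_specimens", "max_intra", "nn_distance", "monophyly")]
#>              species n_specimens max_intra nn_distance    monophyly
#> 1 Simulia species001           4     1.227        3.12 monophyletic
#> 2 Simulia species002           4     1.381        0.00 paraphyletic
#> ...
#> 6 Simulia species006           2     7.031        0.00 polyphyletic
#> 8 Simulia species008           1        NA        6.52    singleton
```

The donor/recipient pair shows exactly the signature the audit is built to
catch: nearest-neighbor distance 0.00% (a shared barcode), para/polyphyly on
the NJ tree, and both diagnosability criteria false — while the clean
species, including the singleton with a unique haplotype at 6.5% from
anything else, stay diagnostic.

The packaged Swiss accounting fixture (217 sequenced resident species; ten
barcode-problematic groups, eight male-morphology pairs, eight
female-morphology groups) reproduces the published identification-rate
table:

```r
fx <- swiss_fixture()
g <- channel_graphs(fx$groups)
identification_rates(g$barcode, g$male_morphology, g$female_morphology, fx$n_species)
#>             channel n_difficult rate_always_exact rate_always rate_difficult
#> 1           barcode          22          89.86175        89.9           10.1
#> 2   male_morphology          16          92.62673        92.6            7.4
#> 3 female_morphology          18          91.70507        91.7            8.3
#> 4   integrated_male           4          98.15668        98.2            1.8
#> 5 integrated_female           8          96.31336        96.3            3.7
```

Reading: the barcode alone identifies 89.9% of species; combining it with
male morphology raises the rate to 98.2% because the two channels fail on
almost disjoint species pairs. Under the species-specific-haplotype
criterion (para/polyphyletic species whose haplotypes are still unique to
one species count as diagnosable) the barcode-alone rate is 93.5%.

## Command line

A thin CLI wraps the same functions:

```sh
inst/exec/barcode-audit audit --fasta lib.fasta --metadata lib.tsv --out out/ \
    --replicates 100 --seed 1 [--morphology groups.tsv --universe 217]
inst/exec/barcode-audit simulate --out sim/ --species 20 --seed 7
inst/exec/barcode-audit rates --groups groups.tsv --universe 217
inst/exec/barcode-audit coverage --fasta lib.fasta --metadata lib.tsv --reference species.txt
```

Input formats: plain FASTA (pre-aligned, equal length); metadata as UTF-8
TSV with columns `specimen_id`, `species` (optional `sex`, `region`);
confusable groups as TSV with `channel`, semicolon-separated `species`, and
`shares_barcode` for barcode groups. See
`vignettes/barcode-library-audit.Rmd` for the methods and the reasoning
behind every numerical convention.
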