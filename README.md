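# endofish

Design taxon-specific FISH probes and quantify endohyphal bacteria in
fluorescence micrographs.

Bacterial endosymbionts such as *Mycoavidus* live inside the hyphae of
Mortierellaceae fungi (e.g. *Podila verticillata*).  Visualizing and
counting them requires (1) oligonucleotide probes that bind the
endosymbiont's 16S rRNA (and the host's 18S rRNA) with no off-target
binding anywhere in the host material, and (2) an objective way to turn
multi-channel confocal images into bacterial densities that can be
compared across culture conditions.  `endofish` implements both as one
reusable R package, plus deterministic synthetic-data generators that make
every step testable without any external data.

## The two methods

**Probe design** (`design_probes()`).  Every 25-mer of the target rRNA is
screened through sequential filters:

1. uniqueness — the k-mer occurs once in the target and never in the host
   rRNA or background contigs (both strands of background DNA);
2. melting temperature — probe `Tm` within `[tm_low, tm_high]`
   (Wallace rule `2(A+T) + 4(G+C)` by default; SantaLucia nearest-neighbor
   model available);
3. edit-distance off-target screen — the final 18 nt of the target site
   must have Levenshtein distance **> 6** to every non-self 18-nt window
   of the input sequences, catching indel-shifted near-matches;
4. probe assembly — the probe is the reverse complement of the target
   site;
5. structure — probes with self-complementary 4-mer pairs (two distinct
   positions) or a canonical G-quadruplex motif (four runs of ≥3 G,
   loops 1–7 nt) are rejected.

**Image quantification** (`quantify_stack()`).  For each TIFF stack with
16S/18S channel roles and a pixel size: maximum-intensity Z projection →
joint min–max normalization of the projections → adaptive-threshold
mycelial mask from the 18S channel (local mean + offset, small objects
removed) → difference-of-Gaussian spot detection on the 16S channel →
spots inside the mask per 100 µm² of mycelium:

    density = count / (area_um2 / 100)

Conditions are compared with two-sided Welch's *t*-tests
(`welch_t_test()`, `compare_density_groups()`), and spatial gradients
along hyphal bundles with `transect_counts()`.

## Worked example

```r
library(endofish)

## probe design on a ground-truthed synthetic input set
fixture <- generate_sequences(seq_fixture_spec(seed = 0))
probes  <- design_probes(fixture$records)
probes
#> FISH probe set (k = 25 )
#> stage survivors: kmerize=426, unique=426, tm=426, levenshtein=1, structure=1
#> accepted probes:
#>      source_id position            probe_sequence tm_c min_suffix_lev
#> 213 target_16S      237 CCCGCGCCCCACTGCCGGATGTGTC   88              8
```

The generator planted exactly one probe-compliant 25-mer site; the
pipeline rediscovers it at position 237, reports its Wallace `Tm` (88 °C)
and its minimum suffix edit distance to all non-self windows (8 > 6); 425
other unique candidates fail the off-target screen.

```r
## quantify a synthetic two-channel micrograph (25 planted bacteria)
img <- generate_image(image_fixture_spec(seed = 1, noise_sigma = 0))
q <- quantify_stack(img$stack)
sprintf("count = %d, area = %.1f um^2, density = %.2f per 100 um^2",
        q$density$count, q$density$area_um2, q$density$density_per_100um2)
#> "count = 25, area = 164.0 um^2, density = 15.24 per 100 um^2"

## compare per-image densities across two culture media
welch_t_test(c(18.2, 22.4, 21.1, 19.6, 20.3),   # condition A
             c(28.9, 31.4, 30.2, 29.5, 32.1))   # condition B
#> Welch's t-test: t = -10.9757, dof = 7.763, p (two-sided) = 5.324e-06
```

All 25 planted spots are recovered inside the mycelial mask, and the
density follows as count over masked area.

## Command line

A thin front-end wraps the same functions:

```sh
endofish simulate sequences --seed 0 --out sim/
endofish design --target sim/target.fasta --host sim/host.fasta \
        --background sim/background.fasta --out design/
endofish quantify img.tif --ch-16s 1 --ch-18s 2 --pixel-size-um 0.1 --out q/
endofish compare pd.csv r2a.csv me.csv --out compare.csv
```

Outputs are TSV/CSV tables, FASTA probe files, mask TIFFs and a
`manifest.json` recording inputs, digests, resolved configuration and
stage survivor counts.  Exit codes: 0 success, 2 usage/input error,
1 internal error.

## Documentation

The methods vignette (`vignettes/endofish-methods.Rmd`) documents the
screening model, the mask/detector parameters and their defaults, what the
synthetic generators do and do not emulate, numerical choices and known
limitations.
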