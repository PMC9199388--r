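---
title: "Methods: probe design and endobacteria quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe design and endobacteria quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endofish)
```

`endofish` implements two computational methods used to visualize and
quantify bacterial endosymbionts (e.g. *Mycoavidus*) living inside fungal
hyphae (Mortierellaceae such as *Podila verticillata*): a taxon-specific
FISH probe designer working from rRNA and genome assembly sequences, and an
image-quantification pipeline converting multi-channel micrographs into
bacterial densities and statistical comparisons.  This vignette documents
the models, parameters, numerical choices and limitations.

## Probe design

### The screening pipeline

Given a *target* rRNA sequence (here bacterial 16S), a *host* rRNA sequence
(fungal 18S) and any number of host *background* contigs, candidate probes
are derived from target sites of length $k = 25$ nt in five sequential
stages:

1. **k-merization.** Every 25-mer of the target is enumerated (0-based,
   half-open coordinates).  K-mers containing `N` (assembly ambiguities)
   are excluded from candidacy — gaps must not generate probes.
2. **Uniqueness.** A k-mer survives iff it occurs exactly once within the
   union of target sequences and never in any host/background sequence.
   By default both strands of non-target sequences are screened
   (`screen_revcomp_background`): the probe hybridizes to single-stranded
   rRNA, but background contigs represent double-stranded genomic DNA.
3. **Melting temperature.** The assembled probe's $T_m$ must lie in
   `[tm_low, tm_high]`.  The default method is the Wallace rule
   $T_m = 2(A{+}T) + 4(G{+}C)$ — exact, fast and adequate for a window
   screen; a SantaLucia & Hicks (2004) nearest-neighbour model (25 nM
   strands, 50 mM Na⁺, entropy salt correction) is available via
   `tm_method = "nearest_neighbor"`.  The lower bound defaults to 37 °C,
   the hybridization temperature of the FISH protocol; the upper bound
   (90 °C) is a permissive cap, because the ligation-step temperature is
   protocol-specific.  Both are configurable and should be tightened to
   the actual hybridization/ligation conditions.
4. **Edit-distance (Levenshtein) off-target screen.** The final 18 nt of
   each surviving target site — the segment whose probe complement anchors
   hybridization at the probe's 3' end — is compared against every 18-nt
   window of the input sequences; the candidate survives iff the minimum
   edit distance strictly exceeds 6.  Insertions and deletions are
   counted, so near-matches shifted by indels are caught, unlike a pure
   Hamming screen.
5. **Probe assembly and structural filters.**  The probe is the reverse
   complement of the target site.  Probes containing a 4-mer and its
   reverse complement at two *distinct* positions are rejected
   (self-complementarity → hairpins/dimers), as are probes matching the
   canonical G-quadruplex motif (four runs of ≥3 G separated by loops of
   1–7 nt).

Every candidate row retains its metrics and flags; stage survivor counts
are recorded and are non-increasing by construction.  The pipeline is
fully deterministic.

### The "non-self" windows of the edit-distance screen

Which windows count as *non-self* is the one genuinely open design point.
Excluding only the candidate's own window is degenerate: the window shifted
by one position always lies within edit distance 2, so no candidate could
ever pass a threshold of 6.  `endofish` therefore excludes every window
that **overlaps an exact occurrence of the candidate k-mer** — windows
sharing even one base with the candidate's own site mostly restate its own
content and say nothing about off-target risk.  All other windows of all
input sequences are screened (`lev_scope = "all"`); restricting the screen
to the target sequences alone (`lev_scope = "target"`) is available.

### Self-complementarity: why two distinct positions

A single occurrence of a palindromic 4-mer (e.g. `ACGT`, its own reverse
complement) cannot base-pair with itself, so it is not grounds for
rejection; requiring a 4-mer and its reverse complement at two distinct
positions is the weakest rule consistent with accepted rRNA probes that
begin with palindromes.  This is checked by exhaustive pair scan over all
4-mers of the probe.

## Image quantification

### Pipeline

For each multi-channel confocal stack (channels: 16S probe signal, 18S
probe signal, optional nuclei; pixel size in µm supplied by the user):

1. **Maximum-intensity Z projection** per channel.
2. **Set-wise min–max normalization**: the projections are rescaled
   together so the global minimum maps to 0 and the global maximum to 1.
   Normalization is never per image: per-image scaling would destroy
   cross-condition intensity comparability.  A constant set normalizes to
   zeros with a warning.
3. **Mycelial masking** of the 18S image by adaptive thresholding: a pixel
   is foreground iff its intensity exceeds the mean of its
   `block_size × block_size` neighbourhood (exact box mean via integral
   images; reflection padding at borders) by more than `offset`.
   Components smaller than `min_object_px` under 8-connectivity are
   removed.  Defaults: block 51 px, offset 0.01 (normalized units — on a
   [0, 1] scale an absolute offset of several 8-bit counts would blank or
   saturate the mask), minimum object 64 px.  The positive margin makes a
   featureless (e.g. all-background) image produce an empty mask rather
   than a full one.
4. **Spot detection** on the 16S image by difference of Gaussians:
   Gaussian blurs at geometrically spaced scales
   $\sigma_1 < \dots < \sigma_n$ (defaults 1–4 px, 5 scales), adjacent
   differences normalized by $(\sigma_{i+1}/\sigma_i - 1)$, strict local
   maxima over the 3×3×3 (y, x, scale) neighbourhood above
   `response_threshold`, then greedy removal of detections whose discs
   (radius $\sqrt{2}\sigma$) overlap a stronger detection by more than
   `overlap_fraction` (default 0.5) of the smaller disc.
5. **Mask filtering and density.**  Spots whose integer-rounded centers
   fall inside the mycelial mask are counted and divided by the masked
   area: `density = count / (area_um2 / 100)` — cells per 100 µm² of
   mycelium, the unit used for cross-condition comparison.
6. **Comparison** across conditions (e.g. culture media) by two-sided
   Welch's *t*-test on per-image densities, pairwise over groups.  Raw
   p-values are reported by default (a Holm flag is available) because
   the comparisons of interest are typically few and pre-planned.

Per-image densities are reported and compared; a pooled-area mode is a
possible alternative reading of "density over aggregated area" but couples
images of unequal mycelial content, so the per-image mean is the default.

### Choice of the DoG response threshold

The detector's operating point targets diffraction-scale bacteria
(~0.5–1 µm) at ~0.1 µm/px sampling on normalized images.  With the scale
normalization above, a Gaussian spot of peak amplitude ~0.8 yields a DoG
response of ~0.26–0.38 at the matched scale, while Gaussian noise up to
one fifth of the spot amplitude produces spurious maxima no stronger than
~0.17.  The default `response_threshold = 0.2` sits between the two
populations: roughly 60 % of a bright spot's response and well above the
noise floor at signal-to-noise ≥ 5.  Dimmer spots require lowering the
threshold (and accepting noise-limited precision).

### Transect counting

`transect_counts()` counts detections inside an ordered list of
non-overlapping rectangles — windows placed along a hyphal bundle from the
inoculation point (proximal) toward the hyphal tips (distal).  ROIs are
0-based, half-open pixel rectangles; `default_transect_rois()` splits an
image into equal-width bands for roughly axis-aligned bundles.

## Synthetic data generators

Both pipelines are validated against deterministic generators with
machine-readable ground truth; all randomness flows through a single
explicitly seeded generator whose state is restored after use.

**Sequences** (`generate_sequences()`): an AT-rich scaffold (GC 0.25, in
line with AT-rich Mortierellaceae genomes) of one target (default 500 nt),
one host (600 nt) and six background contigs (1200 nt each) — desk-scale
stand-ins for a 16S (~1.5 kb)/18S (~1.8 kb) + contig set.  Planted probe
sites are drawn with GC-rich 18-nt suffixes: because every edit operation
can remove at most one A/T, the edit distance from a GC-rich suffix to any
AT-rich window is bounded below by the window's A/T count, giving planted
sites a guaranteed margin under the >6 screen while ordinary candidates
fail it.  Sites are rejection-sampled until they satisfy every filter
(uniqueness, $T_m$ window, structure, screen margin) and are delimited by
single `N` bases so that k-mers straddling a planted locus — which would
otherwise inherit its screen margin — are excluded from candidacy as
gap-containing.  A decoy copy of a non-planted suffix, mutated at exactly
`mutation_distance` positions, is planted in a background contig to
exercise the screen.  The generator finally *verifies* its construction by
running `design_probes()` and requiring the accepted set to equal the
planted set, deterministically resampling the scaffold otherwise.

**Images** (`generate_image()`): hyphae are roughly horizontal random-walk
centerlines with bounded turning angle, dilated to `tube_width_um`
(default 3 µm) — mimicking procumbent single hyphae while staying
trivially maskable.  Bacterial spots are isotropic Gaussians
(`spot_sigma_um` 0.2 µm, amplitude 0.8) placed at least one spot radius
inside the tube and at least $3\sigma$ apart so exact-count assertions are
well defined; outside spots are kept clear of the tube.  Channels share a
constant autofluorescence floor (0.1), an optional linear gradient and
i.i.d. Gaussian noise (default σ 0.05), clamped to [0, 1];
`density_profile = "linear_decay"` thins spot placement toward the distal
end to emulate the proximal-to-distal decline of endobacteria.  Default
problem sizes (256×256 px, 25 spots; 10 replicates for stochastic
properties) keep the whole validation suite desk-scale.

What the generators deliberately do **not** model: optics (no PSF,
photon/Poisson statistics, defocus), 3-D structure (single z slice;
projection is exercised separately), hyphal branching and crossing
networks, autofluorescent debris, and sequence evolution (no homology
structure beyond the planted sites).  Passing tests therefore demonstrate
algorithmic correctness and recoverability under controlled conditions,
not performance on real micrographs, where masking and detector thresholds
must be tuned to the instrument.

## Numerical and engineering choices

- Edit distances: `utils::adist` for single comparisons; the window screen
  uses a banded dynamic program capped at the running minimum (exact
  minima, early abandon) implemented in C++.
- Gaussian blur uses banded convolution matrices with half-sample
  symmetric reflection; box means use integral images on
  reflection-padded arrays: results are exact and deterministic, with no
  FFT wrap-around at borders.
- Connected components use 8-connectivity (diagonal contact joins).
- Strict local maxima: a scale-space voxel must exceed *every* in-bounds
  neighbour; border voxels may be maxima.  Plateaus (exact ties) yield no
  detection, which is irrelevant for continuous-valued images.
- Degenerate inputs: constant image sets normalize to zeros with a
  warning; zero mycelial area makes density undefined (error in
  `density_per_100um2()`, `NA` row in the command-line output); a
  vacuously satisfied screen (no eligible window) reports `Inf` and
  passes.
- Coordinates: image (row = y, col = x) and sequence positions are
  0-based (half-open intervals); FASTA headers of accepted probes use
  1-based inclusive coordinates for readability.
- File outputs are written atomically (temp file + rename).

## Limitations

- The probe screen is exact/edit-distance based; it does not replace an
  alignment-based (BLAST) off-target confirmation against databases of
  non-host organisms.
- No fluorophore assignment, HCR initiator design, image stitching,
  deconvolution or 3-D detection.
- Absolute densities from real images depend on masking and detector
  parameters that the micrograph, not the package, dictates; cross-
  condition comparisons on identically processed image sets are the
  supported inference.
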