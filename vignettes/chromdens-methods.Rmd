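---
title: "Windowed feature densities along chromosomes: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed feature densities along chromosomes: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromdens)
```

## The procedure

`chromdens` turns a genome annotation into chromosome-scale density
maps. For each requested feature type the pipeline is:

1. **Parse and filter.** GFF records whose column-3 type matches the
   request are kept; everything else, including all of column 9, is
   ignored. One tolerant parser covers GFF2, GFF2.5 and GFF3, since the
   dialects differ only in attribute syntax this tool never reads.
2. **Split into strand tracks.** `minus` and `plus` keep one strand
   each; `both` draws the two side by side; `fused` pools both strands
   *and* unstranded records into one track; `all` draws minus, plus and
   fused. Unstranded records (GFF strand `.`, `?` or empty) carry no
   strand information, so they can only contribute to fused tracks; a
   warning is raised when another mode would drop them.
3. **Merge.** The intervals of a track are sorted by start and merged
   into their union, so a base covered by five overlapping exons counts
   once. Book-ended intervals ([1,5], [6,9]) are merged too — coverage
   is identical either way; merging gives a canonical form.
4. **Tile.** Windows `[1, W], [W+1, 2W], ...` cover the chromosome (or
   the BED region) exactly; only the last window may be shorter.
5. **Score.** density = 100 × (covered bases in window) / (window span),
   rounded to an integer, and mapped to a colour through the track's
   colour scale.

The density is coverage-based, not count-based: it answers "what
fraction of this megabase is exonic", not "how many exons start here".

### Tunable parameters

| parameter | unit | default | role |
|---|---|---|---|
| `scale_factor` (W) | bp | — | tiling-window length |
| `auto_scale_factor` | px | 1000 | picture-height budget from which W is derived |
| `rounding_method` | — | `floor` | integer rounding of raw percentages |
| `colour_scale` | id | 1 | global density→colour mapping |
| `gc` | id | off | adds a GC% track using that scale |
| `strand_width` / `strand_space` / `space_chr` | px | 20 / 10 / 30 | column geometry |
| `win_size` | px | — | fixes the drawn height without changing W |

`floor` is the right default for dense features; `ceil` exists for
sparse ones (helitrons, ncRNAs): it rounds every non-zero coverage in
(0, 1)% up to 1%, so rare features remain visible instead of vanishing
into the 0% bin.

When both `scale_factor` and `auto_scale_factor` are given, the fixed
window length wins with a warning: an explicit W is the more specific
intent. Auto sizing chooses `W = ceiling(max_len / available_px)` with
`available_px` the height budget minus the fixed chrome (margins, title,
labels), which guarantees the longest chromosome fits at one window per
pixel. The chosen W is echoed to the log and into the density table's
`# window_size=` comment line.

## Numerical and boundary choices

* **Final partial window.** The denominator is the *actual* span, not
  the nominal W. Dividing by W would report a fully covered final
  window as, say, 40% — and break the invariant density ≤ 100.
* **Exactness.** Covered bases are integers computed by interval
  arithmetic (IRanges coverage/Views), not floating-point accumulation;
  `100 * covered / span` at these magnitudes is exact enough that floor
  and ceiling are unambiguous.
* **Coordinates.** GFF is 1-based inclusive; BED is 0-based half-open
  and converted on ingest, so all internal arithmetic is 1-based
  inclusive. Window coordinates in the CSV match GFF.
* **Sequence lengths.** Precedence: `##sequence-region` pragma > FASTA
  sequence length > max feature end. A pragma contradicting the FASTA
  length is an error; features overhanging the declared length are
  clipped with a warning (truncated annotations are common; an error
  would be hostile).
* **GC denominator.** Ambiguous bases (N) are excluded; an all-N window
  reports 0, not NaN — grey on the GC scale, which is what an assembly
  gap should look like.
* **Degenerate windows.** W larger than the sequence degrades to a
  single whole-sequence window with a warning, not an error.

## Colour scales

A scale is an ordered set of inclusive integer bins covering 0–100,
addressed by number; the catalog ships as an editable TSV
(`inst/extdata/colour_scales.tsv`, replaceable via `--scale_file`).
Scale 1 (default) steps blue→red every 10%. Scale 10 targets sparse
features: 0% grey, 1–9% a per-percent blue→red gradient, ≥10% dark red.
Scale 12 targets GC content: <30% grey, 30–49% green→red, ≥50% dark
red — centred on the 30–50% band where most genomes live. Bin
boundaries are integer-inclusive ([0,0], [1,9], [10,100] for scale 10),
matching the rounding of densities to integers. Remaining ids are
gradient variants; a per-type override (`"CDS = fused = 10"`) beats the
global `-c` scale. No perceptual-uniformity claim is made.

## Figure geometry

Chromosomes are vertical columns left→right, windows top→bottom with a
Mbp ruler; each (type, strand track) is a sub-column of `strand_width`
px. The layout is a pure function of tracks and options, and the SVG
emitter writes plain, deterministically formatted markup — two runs on
the same inputs are byte-identical, which makes figures diffable and
cacheable. With `win_size` set, cell heights become fractional pixels
(SVG handles these exactly); one window is always one drawn cell —
cells are rescaled geometrically rather than densities being recomputed
per output pixel. The computed picture size is printed before drawing;
interactive sessions must confirm it (`--force` auto-answers yes),
non-interactive runs proceed after reporting, so scripted pipelines
never hang on a prompt.

## The synthetic-annotation generator

`generate_gff_fixture()` emulates the inputs the tool is built for:
multi-sequence GFF3 with pragmas, uniformly placed features of several
types (lengths uniform on 50–2000 bp, the span of typical exons through
short genes), strands drawn 0.48/0.48/0.04 plus/minus/unstranded, and
an i.i.d. nucleotide sequence with a requested GC fraction. It is
deliberately unlike real genomes in ways that do not matter to the
statistic: no clustering of features, no feature hierarchies, no
chromosome-scale GC gradients, no repeats of the literal same interval.
Tests passing on these fixtures therefore validate the *bookkeeping* —
parsing, merging, tiling, clipping, rounding, rendering — not any
biological claim about where features sit. That is the right scope: the
per-window statistic is elementary once the bookkeeping is right.

Test problem sizes were chosen to probe the code, not the hardware:
oracle sweeps use 200 seeded fixtures of up to 100 kb and 1,000
features, checked base-for-base against a naive bitmap; the scalability
check runs one million features across five 2-Mb sequences through the
whole pipeline.

## Known limitations

* Windows are non-overlapping and fixed-length; no sliding windows, no
  per-base wiggle output, no count-based densities.
* Column 9 is never parsed: no feature hierarchies (gene→mRNA→exon) and
  no GTF support. Filtering is by column 3 verbatim.
* One global window length per run; regions from a BED file share it.
* Output is SVG 1.1 only; convert externally for raster formats.
* The ruler is a single global scale anchored at the top of the
  columns; with BED regions of different starts it reads as distance
  into the region, not absolute position.
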