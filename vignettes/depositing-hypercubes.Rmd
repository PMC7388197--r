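---
title: "From plane directories to annotated OME-TIFF datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From plane directories to annotated OME-TIFF datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omeDeposit)
```

## The problem

Multi-position time-lapse microscopy produces large collections of 2D
raster planes: an acquisition that images, say, 25 stage positions in 3
optical channels over 5 z-sections and 240 timepoints leaves 90,000
individual files on disk, organised only by a directory-and-filename
convention. Image repositories, by contrast, want each position as one
five-dimensional image — space (X, Y), z-section, channel and time in a
single object — together with the experimental metadata (strains, medium,
exposure settings, free-text context) that was captured in the lab's log
files at acquisition time.

`omeDeposit` closes that gap. It scans a directory tree laid out as

1. one subdirectory `pos{xxx}` per microscope position, `{xxx}` a numeric
   identifier of any digit width;
2. within each, one image file per (timepoint, channel, z-section)
   combination;
3. each file named `{prefix}_{timepoint}_{channel}_{z}.{ext}`, where
   `{prefix}` is arbitrary and may itself contain underscores;

assembles one (T, C, Z, Y, X) hypercube per position, extracts a
four-field metadata record (description, tags, key-value pairs, named
tables) from semi-structured text logs, and deposits everything through a
broker abstraction. The shipped sink writes local OME-TIFF files with
embedded OME-XML, one HDF5 attachment per table, and a JSON manifest that
records the dataset's annotations and every image's dimensions.

## Pipeline and contracts

The pipeline is deliberately split at two pluggable seams, because no
fixed parser can cover the variety of lab log formats, and no fixed image
transformation suits every deposition:

* **Metadata parsers** implement one generic, `extractMetadata(parser,
  source) -> MetadataBundle`. The default is `MetadataAggregator`, which
  locates an acquisition file (`*Acq.txt`) and a log file (`*log.txt`) at
  the tree root, parses each with a leaf parser, and merges the results.
  Any object with an `extractMetadata` method — or a plain R function
  loaded through `loadPlugin()` — substitutes at runtime.
* **Image processors** implement `processImage(processor, broker, path,
  dataset)`. The default scans positions, validates each plane index,
  assembles one hypercube per position and writes it through the broker.
  A custom processor could, for example, crop, denoise or segment before
  writing.

The broker itself is a third contract (`createDataset`,
`writeHypercube`, `annotateDataset`). Only the filesystem sink is
implemented; a server-backed transport would slot in behind the same
generics, which is why the orchestration (`launchUpload()`) takes
credentials it currently ignores.

## Scanning and rank coordinates

Filenames are tokenised **from the right**: the last underscore-separated
token is the z-section, the second-last the channel, the third-last the
timepoint, and everything left is the prefix. This is what lets the
prefix contain underscores. Timepoint and z must parse as non-negative
integers; the channel token is kept verbatim, since labs use both numeric
(`1`, `2`) and named (`GFP`, `BF`) channels.

Raw tokens are never used as array coordinates directly. Instead each
position's distinct tokens are sorted — numerically for timepoint and z,
numerically for channels when every token is an integer and
lexicographically otherwise — and mapped to dense 0-based ranks. This
tolerates 0- or 1-based conventions and gaps (timepoints `{1, 3, 5}`
simply become ranks 0..2) without guessing the acquisition software's
origin convention. The chosen channel order is recorded in the index so
channel names downstream are reproducible.

Validation is a value, not a crash: the scanner reports missing grid
cells, duplicate (t, c, z) coordinates and non-conforming filenames per
position, and the index construction is provably independent of
filesystem enumeration order (rows are canonically sorted by coordinate,
ties broken by path).

## Assembly and fill policy

`assembleCube()` reads every indexed plane exactly once into a
`(SizeT, SizeC, SizeZ, SizeY, SizeX)` integer array. All planes of a
position must agree in height, width and bit depth; disagreement is an
error naming both files, with no implicit promotion, because silent
up-casting changes pixel semantics.

Missing grid cells are governed by the fill policy. The default,
`"error"`, aborts and lists the absent cells: an acquisition gap should
be a conscious decision, not a silent zero. `"zero"` is the opt-in
alternative that substitutes all-zero planes — useful for interrupted
acquisitions — and is exposed on the command line as `--fill zero`.
Zero-filled cells are absent from the cube's provenance table, so they
remain identifiable.

## The on-disk dataset

In memory the axis order is fixed at (T, C, Z, Y, X); on disk the
OME-TIFF writer declares `DimensionOrder="XYZCT"` and emits pages
accordingly (z varies fastest, then channel, then time; page index
`z + SizeZ*(c + SizeC*t)`). One canonical in-memory order plus an
explicit conversion at the sink boundary avoids silent transposition.

The writer produces baseline multi-page TIFF — uncompressed,
little-endian, grayscale, 8- or 16-bit unsigned, one strip per page —
with the OME-XML block in the first page's `ImageDescription`, as the
OME-TIFF specification requires. Writing the container directly (rather
than through a TIFF library) is what allows the metadata block to be
embedded; the corresponding risk is controlled by round-trip tests that
re-read every written file with libtiff, an entirely independent
implementation, and require bit-exact pixels and matching OME-XML sizes.

Tables are attached as one HDF5 file per table: a single group named
after the table, one string dataset per column, and a `columns`
attribute preserving column order. Tags, key-value pairs, the
description and the image inventory land in `manifest.json`, the
machine-readable stand-in for a repository's annotation objects. The
manifest contains no timestamps, so identical inputs produce
byte-identical manifests — a property the tests rely on.

## Metadata dialect

Logs are parsed by three line-level rules, held in a `parserRules()`
record so a lab can override patterns without code changes:

* **Key-value pairs**: any line containing a colon, split at the *first*
  colon, key and value trimmed. First-colon splitting keeps clock times
  (`Start time: 12:30:00`) intact as values.
* **Tags**: the lines between a `tags:` header (case-insensitive) and
  the first blank line.
* **Tables**: a maximal run of at least two consecutive lines, each with
  at least one tab and a constant tab count; the first line is the
  header. A non-blank, non-tabbed line immediately preceding the block
  names it, otherwise blocks are named `table_1`, `table_2`, ... Ragged
  blocks are skipped with a warning rather than failing the upload.

Precedence matters: the tag block is segmented first, then table blocks
(including their name lines), and only the remaining lines feed the
key-value rule — otherwise the `tags:` header and tab-separated rows
containing colons would leak into the key-value pairs. The description
is taken from a `Description` key when present (and consumed from the
key-value list); the key name is configurable.

Aggregation across files joins descriptions with a blank line, takes the
order-preserving union of tags, concatenates key-value pairs dropping
only *exact* duplicate pairs (the same key with two different values is
genuine information and both are kept), and disambiguates colliding
table names with `_2`, `_3`, ... suffixes. These rules make aggregation
associative, which the test suite checks explicitly.

## The fixture generator

Real acquisitions are tens of gigabytes; the package instead ships a
first-class generator that emulates the *structure* of such data exactly
— the `pos{xxx}` layout, the filename convention, arbitrary token sets
with gaps, 8-/16-bit TIFF or 8-bit PNG planes, and metadata files in the
dialect above. Every plane is constant-valued at

```
encodePixel(p, t, c, z) = ((p*7 + t)*5 + c)*11 + z + 1,
```

reduced to the band `1..max` of the pixel type as `1 + (v-1) mod max`
(ranks 0-based). The multipliers make the value injective over small
rank combinations, so a plane placed at the wrong coordinate changes a
cube voxel detectably; keeping 0 out of the range means a zero-filled
gap plane can never be mistaken for generated content. Position
directories are written zero-padded to three digits, but the scanner
accepts any digit width.

What the generator does *not* emulate — realistic pixel textures, vendor
metadata, compressed containers, corrupted files, the exact section
headers of any particular lab's log — bounds what the passing tests
show: they demonstrate that structure-preserving transport is correct,
not that arbitrary real-world logs will parse meaningfully. The paper
trail for a real lab is the `parserRules()` override point and the
parser plug-in seam.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run three reference layouts,
chosen as this package's standard demonstration scales: the 3-position x
3-timepoint x 3-channel x 1-z tree of 16x16 planes (27 files, the worked
example everywhere in the documentation); a names-only enumeration of
the full 25 x 240 x 3 x 5 census (90,000 planes) which exercises the
combinatorics without touching pixels; and a 25-position deposition at 2
x 2 x 2 of 32x32 planes (200 planes), which keeps the one-image-per-
position property observable in seconds. Pixel values are exact
integers throughout — there is no floating-point tolerance anywhere in
the pipeline; every comparison in the tests is bit-exact.

Degenerate inputs have defined behaviour: an empty tree uploads as zero
images plus a warning (exit code 0 from the CLI — an empty experiment is
not a failure); an empty position directory is an assembly-time error; an
empty metadata file yields the empty four-field bundle; unknown file
extensions and malformed names are reported per file, never fatal to the
scan.

## Design choices on genuinely open points

* **One image per position**, never merged across positions: positions
  are independent fields of view and merging would fabricate a spatial
  relationship the data does not contain.
* **uint16 requires TIFF** in the generator: the PNG writer here emits
  8-bit samples, and silently quantising 16-bit fixtures would defeat
  their purpose as oracles.
* **Duplicate plane coordinates always abort a deposition** (they are
  reported, with both paths, by validation first): there is no principled
  way to pick between two files claiming the same (t, c, z).
* **Credentials** are accepted for interface compatibility and unused by
  the local sink; a `--password-env` variable avoids prompts in scripts,
  and `-y` suppresses interaction entirely.
* **The CLI's `-s` flag doubles as the sink directory** for the local
  sink, with `--sink local:<dir>` as the explicit form, so the
  documented flag order of scripted invocations keeps working while
  anything that looks like a server hostname is refused with a clear
  message (no remote transport is implemented).

## Known limitations

* No server transport: `RemoteBroker` declares the shape, nothing
  implements it. The manifest is the local stand-in for repository-side
  annotation objects.
* The metadata dialect is this package's own fixed convention; real lab
  logs will usually need a `parserRules()` override or a custom parser.
* The OME-TIFF writer emits uncompressed baseline TIFF only — no
  pyramids, no BigTIFF, so single images are limited to 4 GiB.
* PNG planes are read as 8-bit grayscale; multi-sample (RGB) planes are
  reduced to their first channel.
* Plane files are held one at a time but a whole cube must fit in
  memory: positions of several gigabytes need more RAM than a laptop.
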