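# omeDeposit

Turn directory trees of 2D microscopy planes into annotated,
five-dimensional OME-TIFF datasets.

## The problem

Multi-position time-lapse experiments leave their output on disk as tens
of thousands of individual 2D raster files — one subdirectory `pos{xxx}`
per microscope stage position, one file per (timepoint, channel,
z-section) named `{prefix}_{timepoint}_{channel}_{z}.{ext}` — plus
semi-structured text logs holding the experimental context. Image
repositories want the opposite shape: one 5D "hypercube" image
(T, C, Z, Y, X) per position, with the metadata attached as structured
annotations.

`omeDeposit` is for the researchers and data curators who deposit such
data routinely. It scans the tree, validates and assembles one hypercube
per position, extracts a four-field metadata record — description, tags,
key-value pairs, named tables — from `*Acq.txt` / `*log.txt` files, and
deposits everything through a broker abstraction. The shipped local sink
writes:

* one `pos{NNN}.ome.tiff` per position — a multi-page TIFF with the
  OME-XML block (`DimensionOrder="XYZCT"`, sizes, channel names)
  embedded in its header;
* one `.h5` (HDF5) attachment per metadata table;
* a `manifest.json` recording the dataset's description, tags, key-value
  pairs, attachments and every image's dimensions.

Both the metadata parser and the image processor are pluggable
contracts (`extractMetadata(parser, source)` and
`processImage(processor, broker, path, dataset)`): custom
implementations substitute at runtime, from code or via `--parser` /
`--processor` plug-in scripts on the command line. A deterministic
fixture generator (`LayoutSpec()` / `generateTree()`) produces
conforming trees with known pixel encodings, so the entire pipeline is
testable without any real acquisition.

## Worked example

Generate the demonstration layout — 3 positions, 3 timepoints, 3
channels, 1 z-section of 16×16 planes, with metadata files — and upload
it into a local sink:

```r
library(omeDeposit)

bundle <- MetadataBundle(
  description = "diel growth run, strain FY4",
  tags = c("timelapse", "yeast"),
  kvps = c(Microscope = "Nikon Ti", `Start time` = "12:30:00"),
  tables = list(exposure = data.frame(channel = c("1", "2", "3"),
                                      ms = c("50", "100", "150"))))

spec <- LayoutSpec(3, timepoints = 1:3, channels = 1:3, zSections = 1)
tree <- generateTree(spec, "demo_tree", bundle = bundle)

report <- launchUpload("USER", "", "demo_sink", "my_first_dataset",
                       tree@root)
show(report)
#> Upload report
#>   dataset: my_first_dataset (id my_first_dataset)
#>   images deposited: 3
#>   planes written:   27
#>   annotations: 2 tag(s), 2 key-value pair(s), 1 table(s)
```

Three hypercubes were deposited — one per position, each carrying all 9
planes of its position (3 timepoints × 3 channels × 1 z). The manifest
confirms the dimensions:

```r
man <- readManifest("demo_sink/my_first_dataset")
man@images[, c("positionId", "file", "sizeT", "sizeC", "sizeZ")]
#>   positionId            file sizeT sizeC sizeZ
#> 1          1 pos001.ome.tiff     3     3     1
#> 2          2 pos002.ome.tiff     3     3     1
#> 3          3 pos003.ome.tiff     3     3     1
```

and any written file reads back as a full 5D image:

```r
cube <- readOmeTiff("demo_sink/my_first_dataset/pos002.ome.tiff")
show(cube)
#> HyperCube: position 2, T=3 C=3 Z=1 Y=16 X=16 (uint8), channels: 1, 2, 3
```

Because fixture planes are constant-valued at a known encoding, plane
placement is verifiable voxel by voxel:
`pixelArray(cube)[2, 3, 1, 1, 1]` is `208`, which equals
`encodePixel(1, 1, 2, 0)` — position rank 1, timepoint rank 1, channel
rank 2, z rank 0.

The same upload from a shell (the script ships in `inst/scripts/`):

```sh
Rscript inst/scripts/upload_cli.R -d demo_tree -n my_first_dataset \
    -u USER -s demo_sink -y
```

Useful variants: `--dry-run` (scan, validate and parse metadata, write
nothing), `--fill zero` (zero-fill missing planes instead of aborting),
`--no-metadata`, and `--parser`/`--processor` for plug-in scripts.

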