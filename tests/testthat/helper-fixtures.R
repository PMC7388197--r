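# Shared fixture builders. All trees are generated fresh under tempdir()
# by the package's own fixture module; nothing is read from disk fixtures.

# the canonical small layout: 3 positions x 3 timepoints x 3 channels x 1 z
smallSpec <- function(...) {
  LayoutSpec(3, timepoints = 1:3, channels = 1:3, zSections = 1,
             planeHeight = 16L, planeWidth = 16L, ...)
}

# a richer bundle exercising every metadata feature
richBundle <- function() {
  MetadataBundle(
    description = "diel growth run, strain FY4",
    tags = c("timelapse", "yeast", "glucose"),
    kvps = list(c("Microscope", "Nikon Ti"),
                c("Start time", "12:30:00"),
                c("Interval", "2.5 min")),
    tables = list(
      exposure = data.frame(channel = c("1", "2", "3"),
                            ms = c("50", "100", "150"),
                            stringsAsFactors = FALSE),
      positions = data.frame(x = c("10.5", "20.0"), y = c("-3", "7"),
                             stringsAsFactors = FALSE)))
}

makeTree <- function(spec = smallSpec(), bundle = NULL,
                     dest = tempfile("tree")) {
  generateTree(spec, dest, bundle = bundle)
}
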