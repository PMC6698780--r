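Package: screencomposer
Title: Declarative Screen Composition for Behavioral Experiment Paradigms
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Build experiment screens (stimulus displays for behavioral and
    neuroimaging paradigms) as declarative render trees: layouts divide the
    available space among their children, wrappers modify a single child's
    area, and primitives draw text, shapes, or images into whatever space
    they are given. A recursive compose pass assigns every node an integer
    pixel rectangle, draws into a deterministic in-memory raster, and records
    a geometry trace so that every layout decision is testable without a
    display. Includes a poll-based event listener with timeouts and handler
    chains, session helpers (slide shows, text-entry buffer editing), scalar
    field rendering, and a trial/block harness that captures stimulus onsets
    and reaction times and writes TSV results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    digest,
    png,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
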