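---
title: "Declarative screen composition: model, guarantees, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Declarative screen composition: model, guarantees, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screencomposer)
```

## The model

A stimulus screen is a tree of rendering instructions, not pixel data. The
`compose()` pass walks the tree once, top-down: the root receives the full
target rectangle; each **layout** partitions its rectangle among its
children; each **wrapper** derives a (usually smaller) rectangle for its
single child; each **primitive** draws into whatever rectangle it was
given, using as much of it as possible. Because space flows down as
*proportions of the parent*, the same tree renders sensibly at any
resolution — the property that makes screens portable across lab displays.

Two deliberate restrictions shape everything else:

* **All public geometry is integer pixels.** Fractional inputs (padding
  fractions, layout weights, aspect ratios) are resolved to integers at
  each operation and never propagated, so there is exactly one place where
  rounding can happen per decision, and traces are exactly reproducible.
* **Compositing is opaque.** Later draws overwrite earlier ones; `overlay()`
  order is draw order. No alpha blending — stimulus screens rarely need it,
  and its absence makes pixel-level assertions exact.

## Integer arithmetic and rounding

Three rounding decisions determine every rectangle, and each is applied
uniformly:

1. **Interval splitting** uses cumulative-boundary rounding: boundary
   `k` of an interval of length `L` under weights `w` is
   `round_half_up(L · Σ_{j≤k} w_j / Σw)`, and segment `i` is the difference
   of consecutive boundaries. Rounding each segment independently could
   create or destroy pixels; the cumulative rule conserves length exactly,
   which is the tiling invariant the tests enforce. Consequences: segments
   are proportional to their weights within 1 px, and equal weights with a
   divisible length give exactly equal segments.
2. **Fractional insetting** (padding) moves the origin by
   `round_half_up(left · w)` and sets the extent to
   `round_half_up((1 − left − right) · w)`, clamped into the parent.
3. **Centering remainders** use `offset = (outer − inner) %/% 2`: an odd
   leftover pixel goes to the right/bottom. We considered round-half-up
   here (extra pixel at top/left) and chose floor so that content never
   sits above/left of true center; one rule is used for letterboxing,
   primitive centering, and text-block centering alike.

Image placement computes a scale `s = min(W/w_img, H/h_img)`, capped at 1
unless upscaling is explicitly allowed — images are scaled *down* to the
biggest distortion-free rectangle, and centered rather than enlarged when
the area is bigger than the image. `rectangle_shaper()` is the same
operation with upscaling allowed, since pure proportions carry no native
resolution.

## The drawing surface and headless determinism

`compose()` draws into a `pixel_buffer()`: an `h × w × 3` integer raster
with fill-rect, scaled-blit, circle, and line operations. This single
raster implementation *is* the drawing surface; the windowed/headless
distinction lives one level up, at presentation time (`display_show()`
either pushes the raster to a graphics device or appends a content digest
to the context's frame log). Compose output is therefore byte-identical
whether or not a window exists, which is what makes golden-trace and
golden-pixel regression tests meaningful.

Text is rendered with a **synthetic fixed-advance font**: glyph advance
`ceil(0.6 · size)` px, line height `round(1.2 · size)` px, glyphs drawn as
solid ink blocks (bold fills the full advance, regular leaves a 1 px gap).
This is a deliberate trade: platform font stacks produce different pixels
on different systems, and no preinstalled R package rasterizes fonts
deterministically. The synthetic font keeps every metric and pixel
platform-independent. What a green text test establishes is *placement* —
alignment, clipping, line stacking, vertical centering — not typographic
appearance. Text never rescales to fit; overflow clips to the assigned
area.

Smooth image scaling is an area-averaging box filter (each source pixel
contributes to the target bin its center falls in), appropriate for the
dominant use case of scaling stimuli down; upscaling and
`smooth_scale = FALSE` use nearest-neighbor.

## Events, clocks, and what "exact" means

The listener never blocks on hardware. It polls an **event source**
(`poll()` returns pending events, each delivered at most once, in order)
and tells time through a **clock** (`now()`/`sleep()`). Handler chains run
permanent handlers (installed at listener construction) before call-site
handlers, in order; the first non-`NULL` result ends the wait. Unconsumed
events are dropped — a fidelity risk worth naming: a retained-event design
would let one wait's leftovers satisfy the next, and we chose the simpler
semantics and documented it.

Defaults: 1 ms poll interval; a timeout of `NULL` (or ≤ 0) waits
indefinitely; the timeout sentinel is a distinguished object
(`is_timeout()`), never a valid key or character. With a silent source and
timeout `T`, a wait ends after simulated time in `[T, T + poll_interval]`.

Reaction times are computed from *event timestamps*, not from the moment
the poll loop happened to observe the event: `rt = t_event − t_onset`. On a
simulated clock with a scripted source this makes latency recovery exact
(zero jitter), which is the calibration check `run_block()` is tested
against. On a real clock, accuracy is bounded by the OS and display
pipeline; no input- or display-latency calibration is attempted, so the
package is not suitable for paradigms that need guaranteed
millisecond-exact presentation (e.g. subliminal priming).

One numerical guard: the scripted source releases events whose timestamp is
within 1 ns above the clock, because a clock that accumulates thousands of
floating-point sleeps can land an ulp below a timestamp that lies exactly
on a poll tick.

## The trial harness

`run_block()` is the canonical trial loop: compose and present the
stimulus, store the onset (seconds since session start), wait for one of
the trial's valid keys, store the reaction time, then wait out the
inter-trial interval. By convention the last trial's ITI is zero (there is
no next trial to wait for); a nonzero value is a warning, not an error,
because truncated ITI lists are a common and harmless scripting slip. A
quit event aborts the session but the completed records are attached to
the raised condition, so partial data is never silently lost. Results are
TSV (`subject, block, trial, onset, response, rt`), seconds to 6 decimal
places, `NA` for timed-out trials — the format round-trips through
`read_results()` to within 1 µs.

Response timeouts are absent by default (the loop waits indefinitely), and
all session timestamps come from the injected clock; wall-clock time never
enters a record.

## The example fixtures

`build_example()` builds the three screen archetypes used throughout the
tests: (1) a two-alternative inter-temporal choice screen — horizontal
split, each side padded to 80% and filled with a bordered amount/delay box
at weights 2:1, both texts at font size 50 with the amount bold; (2) a
symbol-match screen whose symbol row interleaves three empty spacer slots
with the two symbols, plus one trailing spacer that shifts the content up;
(3) a Stroop training screen of three equal vertical rows (caption,
training stimulus, color-to-key mapping row built from per-color
sublayouts with spacers on their outsides). Defaults mirror the narrative
the fixtures come from (10€ now vs 20€ in 30 days; green target; four
color–key mappings). The choice of specific colors, key names, and symbol
shapes for examples 2 and 3 is this package's own — the fixtures pin
*structure* (counts, proportions, equal rows), which is what the
acceptance tests assert.

## What the tests do and do not establish

The property suites run on randomized trees, weights, and event streams
under fixed seeds: interval conservation and 1 px proportionality,
containment of every traced rect in its parent, the no-upscale and
exact-aspect contracts, overlay draw order, byte-identical re-composition,
listener timeout bounds, text-entry round-trips, and exact scripted
latency recovery. These establish the *geometry and timing contracts* of
the engine. They do not establish anything about real hardware: font
rendering fidelity, GPU or window-system behavior, real keyboard latency,
or display synchronization are all outside the tested surface, and the
windowed backend is a thin presentation path over the same raster, not a
timing instrument.

## Known limitations

* One display context per process; no multi-window support.
* No alpha compositing, rotation, or sub-pixel geometry.
* Keyboard and mouse only; no joystick or serial-port devices.
* The synthetic font is a placement model, not a typeface; windowed demos
  show block glyphs.
* BMP support covers the common uncompressed 24-bit form only.
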