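# screencomposer

Declarative screen composition for behavioral and neuroimaging experiment
paradigms, in R.

A paradigm confronts a subject with a sequence of stimulus screens — text,
shapes, images — and records behavior: which key was pressed, and how fast.
Most tooling in this space positions stimuli with absolute (x, y)
coordinates, which couples every screen to one display resolution.
`screencomposer` instead describes a screen as a **render tree**:

* **layouts** divide their space among their children — `lin_layout()`
  (horizontal/vertical line, proportional slots via `ll_item()`),
  `grid_layout()`, `overlay()`;
* **wrappers** modify the area of a single child — `padding()` /
  `padding_scale()`, `border()`, `fill()`, `rectangle_shaper()`,
  `mouse_area()`, and automatic wrapping of raw images;
* **primitives** draw into whatever rectangle they are given —
  `text_element()`, `circle()`, `cross()`, `line_element()`, images, and
  `fill()` with no child as the rectangle primitive.

A recursive `compose()` pass assigns every node an integer pixel rectangle
and draws into an in-memory RGB raster (`pixel_buffer()`). The core layout
arithmetic is exact integer work: an interval of `L` pixels split among
weights `w` places boundary `k` at `round(L · Σ_{j≤k} w_j / Σ w)`
(cumulative rounding, so no pixel is ever lost or created), and images are
letterboxed with scale `s = min(W/w_img, H/h_img)`, capped at 1 unless
upscaling is allowed. Every compose also returns a **layout trace** — the
rect each node received, in draw order — so layout behavior is testable
headlessly and deterministically (byte-identical pixels across runs).

Input is a poll-based **event listener** over injectable clock and
event-source contracts: `wait_for_keys()`, `wait_for_unicode_char()`,
`wait_for_seconds()`, and raw `listen()` with handler chains and timeouts.
Tests and replays use `simulated_clock()` + `scripted_event_source()`, so
timing contracts are exact. A trial/block harness (`trial_spec()`,
`run_block()`) captures stimulus onsets and reaction times
(`rt = response time − onset`) and writes TSV results (`write_results()`).

Display-latency calibration and v-sync synchronization are explicitly out of
scope: onsets and RTs are as good as the injected clock.

## Worked example

An inter-temporal choice screen — choose between 10€ now and 20€ in 30
days. Each screen half is scaled down to 80% and filled with a bordered
offer box in which the bold amount gets twice the height of the delay:

```r
library(screencomposer)

screen <- lin_layout("h",
  padding_scale(0.8, border(lin_layout("v",
    ll_item(2, text_element("10€", font_size = 50, bold = TRUE)),
    ll_item(1, text_element("now", font_size = 50))))),
  padding_scale(0.8, border(lin_layout("v",
    ll_item(2, text_element("20€", font_size = 50, bold = TRUE)),
    ll_item(1, text_element("in 30 days", font_size = 50))))))
# equivalently: screen <- build_example(1)

out <- compose_to_buffer(screen, 1000, 1000)
subset(as.data.frame(out$trace), kind == "border")
#>         path   kind   x   y   w   h
#> 4     /1/1/1 border  50 100 400 800
#> 12    /2/1/1 border 550 100 400 800
```

Each offer box is 400×800 px — exactly 80% of its 500×1000 half-screen cell
in both dimensions. Inside, the amount/delay regions are 532 and 266 px
tall (the bordered interior is 798 px, split 2:1 exactly).

Running a scripted block and recovering reaction times:

```r
clock <- simulated_clock()
events <- list(key_down_event("F", 0.3), key_down_event("J", 2.8))
listener <- event_listener(scripted_event_source(events, clock), clock)
display_init(c(100, 100), backend = "headless")
rec <- run_block(list(
  trial_spec(build_example(1), c("F", "J"), iti = 2),
  trial_spec(build_example(1), c("F", "J"), iti = 0)), listener)
rec
#>   block trial onset response  rt
#> 1     1     1   0.0        F 0.3
#> 2     1     2   2.3        J 0.5
write_results(rec, subject = "s01", "results.tsv")
```

The second onset is 2.3 s (first response at 0.3 s plus the 2 s inter-trial
interval) and both latencies are recovered exactly on the simulated clock.

## Command line

```sh
Rscript inst/scripts/screencompose render --example 1 --size 1000x1000 \
    --out screen.png --trace trace.json
Rscript inst/scripts/screencompose render --scene scene.json --size 800x600 --out s.png
Rscript inst/scripts/screencompose simulate-block --events events.jsonl --out results.tsv
```

`--scene` takes a JSON tree (`{"kind": "lin_layout", "children": [...]}`,
colors as `"#RRGGBB"`); `--events` takes JSON lines
(`{"t": 0.25, "kind": "key_down", "key": "F"}`).

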