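---
title: "lochip: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lochip: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lochip)
```

`lochip` is a desk-scale control stack for internet-operated lifting-gate
lab-on-a-chip (LoC) devices: a valve-sequencing language and interpreter, a
digital twin of the fluidics, a synthetic single-particle fluorescence
pipeline, and a message-driven remote-control layer. This vignette documents
the models behind each layer, the parameters that matter, and the places
where the design was genuinely open and a choice had to be made.

## The scripting language

The physical device exposes fifteen pneumatic valves; an experiment is a
timed sequence of open/close actuations. The language therefore has exactly
three single-character commands — `o <valve>` (open), `c <valve>` (close),
`w <milliseconds>` (wait) — plus `call <name>` for user-defined functions,
and nothing else: no variables, arithmetic, loops or conditionals. The point
of the language is to be learnable in minutes by people with no programming
background, and every feature it lacks is a feature a novice cannot misuse
while holding real hardware.

The published description of the language names the commands and the
main-block/function structure but not the concrete line syntax, so the
grammar here is an independent concretization, chosen to make the structure
statically checkable:

* one instruction per line, whitespace-separated tokens;
* explicit block delimiters `main:` … `end` and `def <name>:` … `end`;
* function definitions must follow the main block (enforced as the
  `E_DEF_BEFORE_MAIN` error);
* `#` comments to end of line; lowercase commands only;
* `w` takes non-negative integers (milliseconds) — no fractional waits;
* unknown commands are hard errors, never warnings: in a device-control
  language a silently skipped line can flood a chip.

Valve numbering is **1-based** (`o 1` … `o 15`), matching laboratory labels.

`validate_script()` performs all static checks (valve range against a
topology, `call` resolution, cycle detection by depth-first search over the
call graph, unused-function warnings) and returns diagnostics from a closed
code set (`LOC_DIAGNOSTIC_CODES`) rather than raising; an empty diagnostic
list is the definition of "runnable". Recursion is prohibited statically:
the interpreter's semantics are straight-line expansion, and a recursive
`call` could only mean an infinite actuation sequence.

## The interpreter

`run_script()` walks the call-expanded instruction list sequentially,
forwarding actuations to a pluggable backend and advancing a clock on
waits. Two clock modes exist: `"virtual"` (waits advance the clock
instantaneously, so a 20-minute protocol simulates in milliseconds) and
`"realtime"` (waits sleep, for hardware or transport backends). Whether
calls are expanded ahead of time or interpreted lazily is unobservable in
the actuation sequence; the tested contract is equivalence of the ordered
(action, valve) sequence with an independently written lazy reference
executor, over thousands of randomly generated valid scripts.

Re-opening an open valve (or re-closing a closed one) is forwarded and
logged but is not an error: the solenoids are level-driven and the physical
device tolerates it. On a backend error the partial trace is preserved in
the raised condition — no rollback, since a physical chip cannot roll back
either.

`dry_run()` computes total scheduled duration, per-valve actuation counts,
peak simultaneously-open valves, and per-function wait subtotals without
touching any backend (verified with a spy backend in the tests). The
per-function subtotal is what lets a reviewer confirm that, e.g., a staining
script's `incubate` block schedules exactly the 20 minutes the staining
chemistry requires.

## The digital twin

Lifting-gate semantics: negative pressure lifts a PDMS membrane, opening an
exchange volume between adjacent channels; positive pressure closes it and
expels the contained liquid toward adjacent open valves. The twin maps this
onto a graph state machine over discrete fluid parcels:

* a parcel is a named vector of per-reagent volumes (nanoliters), so
  per-reagent conservation is a sum identity, not a numerical approximation;
* **open** marks the valve open and draws fluid from adjacent inlet
  reservoirs up to the valve's internal capacity;
* **close** expels the valve's parcel, partitioned **equally by volume**
  among adjacent open nodes; merging parcels combine volume-additively with
  volume-weighted composition averaging.

Open design points and the choices made:

* *Partitioning.* The published description says expelled liquid moves
  "towards adjacent open valves" without giving a rule; equal split is the
  symmetric choice and is implemented exactly (each of `k` recipients gets
  `V/k`).
* *Reservoirs always accept.* Closing an inlet valve pushes half its parcel
  back up the inlet — physically realistic and conservation-preserving.
* *No open neighbor.* The parcel is flagged "trapped" in an audit field with
  a `W_TRAPPED` warning rather than destroyed; a real device would
  backpressure, and destroying fluid would break the conservation invariant
  that the whole model is built on.
* *Capacity.* Valve internal capacity defaults to 10 nL and is configurable
  in the topology file. Exceeding it (by merging expelled parcels) records a
  `W_CAPACITY` audit entry, not an error: the physical analogue is fluid
  extending into the channel segments around a valve, which the model does
  not resolve. The bundled staining run records such entries while the
  pooled 15 nL parcel transits single valves; on the physical chip that
  volume is spread across the three central mixing valves.
* *Mixing is instantaneous and perfect* on merge; incubation time moves only
  the clock. Diffusion kinetics, Taylor dispersion, pressure/flow physics
  and PDMS mechanics are out of scope by design — the twin is a routing and
  accounting model, not a CFD code.

The default topology (15 valves, 6 reservoirs) is a serial mixing chain:
inlet reservoirs R1–R3 feed inlet valves V1–V3, which converge on central
mixing valves V4–V6; a transport chain V7–V13 leads to the detection valve
V14 and the output valve V15, which adjoins outlet reservoirs R4–R6. The
exact adjacency of the physical chip is not published; this is a schematic
stand-in with the same node counts, roles and reachability, and alternate
architectures are drop-in YAML files (`chip_topology("my_chip.yaml")`).

The bundled reference protocol loads three inlets — 2 µL *E. coli*
suspension in 1X PBS, 2 µL 1X SYBR Gold, 5 µL 1X PBS — and the bundled
`staining.loc` script draws them into the mixers, homogenizes by rotating
the parcel through V4–V6, waits 20 minutes, and hands the parcel valve by
valve to V14. "Delivered" fluid is accounted as the cumulative parcel that
enters the detection node during a run.

```{r}
run <- run_protocol(parse_script(reference_script("staining")))
run
mass_balance(run$state)
```

## Synthetic fluorescence video and burst detection

On hardware, stained bacteria crossing the excitation volume (488 nm laser
in a solid-core waveguide, 532 nm emission filter) produce intensity bursts
recorded by a high-frame-rate camera; the video is reduced frame by frame to
an integrated region-of-interest (ROI) trace, and events are called on that
trace with a 5 ms confirmation window cropped around each peak.

The generator (`generate_video()`) emulates the minimal physics that
reproduces this trace morphology: each particle crosses the ROI at constant
velocity, depositing a normalized 2-D Gaussian spot (point-spread σ, default
1.5 px) whose total intensity follows a Gaussian temporal envelope (dwell
2 ms) peaking at `amplitude` photons, over a flat background with Poisson
shot noise (optionally Gaussian or none). Amplitudes can be log-normal to
mimic staining variability. All randomness derives from the spec's seed.

What it deliberately does **not** emulate: camera read noise and hot pixels,
focus drift, flow-rate fluctuation, coincident particles in the excitation
volume, photobleaching, and the dye's spectral behavior beyond an amplitude
scale. Detector performance on this synthetic data therefore demonstrates
the correctness of the pipeline and its calibration on well-separated,
high-SNR bursts — not performance on real chip video.

Defaults, and why: the camera's true frame rate and ROI are not published.
Frame rate defaults to 2000 Hz so the 5 ms window spans 10 frames; frames
are 32×32 px with a 16×8 px ROI; background is 5 counts/px and amplitude
2000 photons, giving a trace noise scale of about `sqrt(5·128) ≈ 25` counts
— bursts ~80× the noise, comfortably inside the ≥10× regime the detector is
specified for. Transit times default to even spacing with ±12.5% jitter,
guaranteeing pairwise separation (a dilute sample); 100 particles over 2 s.

The detector (`detect_events()`) uses a median baseline and a
`1.4826·MAD` noise scale — both robust to the bursts themselves, which can
occupy ~10% of frames — and accepts local maxima above
`baseline + k·noise` (default `k = 5`) greedily by height under a minimum
separation (default one event window). The thresholding rule used in the
original analysis is not published; median/MAD was chosen over mean/SD
because bursts are extreme outliers that would inflate a non-robust scale
estimate. Two invariants pin the design: detection is invariant to adding a
constant to the trace, and raising `k` never increases the event count.
Edge events get truncated (never padded) windows, flagged as such.

## The remote-control layer

The hardware platform is driven over MQTT; here an in-process
publish/subscribe bus reproduces the contract — MQTT-style hierarchical
topics (`device/<id>/command`, `device/<id>/status`, `+`/`#` wildcards),
JSON payloads (round-tripped through JSON in transit, so handlers see
exactly what a real broker would deliver), synchronous per-topic FIFO
delivery, and an acknowledged-delivery rule: every command yields at least
one status message referencing its id, with `timeout` statuses for absent
devices. The three operation modes of the original GUI map to
`manual_valve_command()`, `run_saved_script()` and `upload_script()`; the
GUI itself is not reproduced — the functions and the `inst/cli/loc.R`
command-line tool cover the modes. Authentication and user management are
deployment concerns, out of scope. A real-broker adapter can be layered on
the same message shape but is never required by anything in the package.

Uploads are parsed and validated **on the device** before storage; a
rejected upload carries the full diagnostics, which is the feedback path for
remotely submitted scripts (e.g. student homework on a teaching deployment).

## Numerical choices and problem sizes

* Wait durations and the virtual clock are integer milliseconds summed in
  doubles; no rounding occurs below 2^53.
* Parcel arithmetic is plain double addition/scaling; the conservation
  invariant is tested to 1e-9 relative error but in practice holds to
  machine precision because every operation is a reassignment of the same
  summands.
* Equal splits compute `V/k` once and deposit the identical share `k`
  times.
* Event windows of `w` frames place `floor((w-1)/2)` frames before the
  peak; ties between equal-height candidate peaks are broken by index order.
* The test suite exercises 1000 random scripts against the reference
  executor, 1000 random 30-actuation sequences for conservation, and three
  seeded 100-particle videos (2 s at 2000 Hz, 32×32 px) for detector recall
  and precision; the whole suite runs in well under a minute on one core.

## Known limitations

* The fluid model cannot represent partial valve actuation, channel
  dead-volume, or flow driven by anything other than valve displacement.
* Scripts are untimed beyond `w`; there is no feedback from the chip state
  into control flow (by design — the language has no conditionals).
* The synthetic video is a calibration instrument, not a camera model; see
  above for what passing detector tests does and does not show.
* The bus is single-process and synchronous; ordering guarantees across
  multiple real brokers are out of scope.
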