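---
title: "Detecting and tracking biological targets in surveillance-radar scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and tracking biological targets in surveillance-radar scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeroscan)
```

## The data model

A marine surveillance radar sweeps a narrow beam through 360 degrees and, for
each transmitted pulse, digitizes the returned echo into a fixed number of
samples. One full rotation is a **scan**: an unsigned-integer matrix whose
columns are pulses (in rotation order) and whose rows are **range cells** —
sample `i` (0-based) of any pulse covers slant range `[i*dr, (i+1)*dr)` with
`dr = c / (2 * rate)`. A 12-bit digitizer yields samples in 0–4095; typical
cards digitize at 5–60 Msamples/s with a budget of about 4 million samples
per scan, and `validate_scan()` reports violations of exactly these three
constraints (sample range, budget, rate) as return values rather than errors,
so a pipeline can log and continue.

Geometry conventions, fixed once and used everywhere: azimuth is measured in
degrees clockwise from true north (pulse 0 points at `heading_deg`); cell
centers are used for all projections; `polar_to_xyz()` maps slant range and
azimuth to a local east/north/up frame using the beam-center elevation only —
a single fan-beam radar has no height resolution within the beam, so the `z`
coordinate is the beam-center approximation. The speed of light is fixed at
299,792,458 m/s and no atmospheric refraction is applied.

`scan_to_ppi()` renders the classical plan position indicator by
nearest-sample lookup: each pixel center inside the display radius is mapped
to the polar cell that contains it. Out-of-range pixels are carried in a
separate logical mask (and `NA` in the value matrix) so the raster itself
holds pure sample values; `write_pgm()` emits a portable 8-bit P5 image.

## Blip extraction

Detection is deliberately simple and transparent, operating against an
adaptive background:

1. **Learn.** For a user-chosen number of scans `L`, pool every sample inside
   each *stats cell* (a window of `cell_rows` samples by `cell_cols` pulses;
   the last cell in each direction absorbs any remainder) across all `L`
   scans, and store the pooled mean `m` and mean absolute deviation `d`.
   Pooling both spatially and temporally keeps `d` stable even for small `L`.
   "Deviation" here is the mean absolute deviation about the mean; a standard
   deviation estimator is available via `estimator = "sd"` for users who
   prefer a variance-based z-score, without any claim about which is more
   faithful to earlier systems.
2. **Score.** Each sample gets `z = (x - m) / d` against its cell statistics.
   A degenerate cell with `d = 0` scores `+Inf` above the mean, `-Inf` below,
   `0` at it — so any echo above a perfectly constant background is hot at
   any finite threshold. A sample is **hot** when `z` strictly exceeds
   `z_thresh`.
3. **Group.** Hot samples join into **patches** by 8-connectivity; the first
   and last pulse columns are adjacent (azimuth wraps) but range does not
   wrap. Components are returned sorted by (min row, min unwrapped column)
   so downstream processing is deterministic.
4. **Summarize.** `blip_properties()` computes, per patch: sample count,
   polar-area (`sum of r_i * dtheta * dr` over cells), perimeter (cells with
   at least one 4-neighbour outside the patch), mean/max intensity, angular
   and radial span, an intensity-weighted centroid in x/y, and a timestamp
   interpolated by pulse column within the rotation (the scan only stores
   the rotation start time, but a blip at azimuth 180 degrees was observed
   half a rotation later — this matters for speed estimates).
5. **Filter.** Patches that satisfy all closed bounds (and an optional user
   predicate) become **blips**. Sector rules can discard whole wedges of the
   scanned volume or re-filter blips inside a wedge with different bounds;
   when override sectors overlap, the first listed wins.
6. **Update.** The background follows the scene with an exponential update:
   `m <- (1-alpha) m + alpha m_scan` (same for `d`), using the single scan's
   cell statistics. Hot samples are included by default — the simplest
   contract, and with small `alpha` the contamination of a moving target is
   negligible; `exclude_hot = TRUE` masks them out for stationary-clutter
   regimes.

Raising `z_thresh` can only shrink the hot mask, so hot-sample and blip
counts are non-increasing in the threshold; the test suite checks this
monotonicity alongside brute-force oracles for the pooled statistics, the
hot mask and the connected components.

## Track building

Blips are linked across scans by one of two track-while-scan models.

**Nearest neighbour (NN).** For every active track and every new blip, the
candidate extension is scored by speed, turning angle and relative change in
blip area (or mean intensity); candidates outside the user bounds are
infeasible. Among feasible pairs, blips are assigned to tracks by a
maximum-cardinality matching that minimizes the total 3-D *extension
distance*, computed as an optimal rectangular bipartite assignment; exact
ties are broken by a seeded permutation (the "coin toss"), so runs are
reproducible given the seed. Unmatched blips wait in a pool and may seed new
two-blip tracks on later scans until they expire; tracks unextended for more
than `expiry_scans` scans are declared complete.

**Multiframe correspondence (MFC).** After an NN bootstrap on the first two
scans, each extension candidate is scored by a gain on a log scale,

    gain = -w_prox * ln(1 + d / sigma_p) - w_vel * ln(1 + dv / sigma_v)

where `d` is the distance from the blip to the position predicted by the
track's last velocity (constant-velocity prediction) and `dv` is the change
in velocity implied by accepting the blip. The gain is at most 0 (a blip
exactly at the prediction with unchanged velocity) and is replaceable by a
user hook. Candidates include *breaking* an existing link within the sliding
window of the last `k` scans and re-attaching the track prefix to a new
blip; links older than `k` scans are frozen. Candidates are accepted
greedily in rank order without conflicts; broken-off multi-blip tails become
new tracks and enter a second matching phase together with unmatched blips,
while single orphaned blips return to the seeding pool.

Two ranking terms beyond the raw gain proved necessary, and both are design
choices of this implementation (the published description of the greedy
multiframe scheme fixes neither):

- **Gap penalty** (`gap_penalty`, default 0.5 log-gain units per skipped
  scan). A candidate link that jumps over a scan — after a missed detection,
  or because it orphans a trailing blip — is smoother than an honest
  one-scan extension simply because its velocity is averaged over a longer
  baseline; without a penalty, centroid noise alone makes "break and skip"
  profitable roughly half the time and tracks shed blips continually.
- **Link reward** (`link_reward`, default 1.0). Because the gain is bounded
  above by 0, removing any link never decreases a naive total gain, so pure
  total-gain maximization degenerates. Extensions are therefore ranked at
  `link_reward + gain`, while a break is ranked by its *net* effect
  `gain_new - gain_old` (the reward of the broken and remade link cancels).
  An existing link is broken only when it is worse than its replacement by
  more than the reward — which is exactly the situation in a mistaken
  crossing assignment, where the wrong link's gain is far below its
  correction's.

With these defaults the tracker resolves the constructed crossing instance
(two constant-velocity targets whose paths intersect at a shallow angle)
that the NN model provably swaps, and it does not fragment clean
single-target tracks; both behaviors are locked in by tests.

`evaluate_tracks()` scores a recovered tracking against simulated ground
truth: a link (two consecutive blips of one track) is correct when both
blips fall within a match radius of the same truth target and those truth
detections are consecutive; precision is correct/claimed (1.0 when nothing
is claimed), recall is correct/truth links, and purity is each track's
majority-target fraction averaged over tracks.

## The synthetic scene generator

Scenes are the package's test bed and define its study conditions. The
noise model is a shifted exponential — `round(clip(noise_mean +
Exp(noise_scale)))` per sample — chosen over a Gaussian because echo
intensity is one-sided and heavy-tailed the way sea and rain clutter are;
an azimuth wedge can scale the exponential (sea state) and a ground-plane
disc can lift the floor (a rain cell). Targets fly straight lines or
constant-turn arcs at constant speed and are rendered as Gaussian
point-spread blobs in (range, azimuth) with wraparound at the 0/360 seam.
Two fidelity choices matter for interpretation:

- Target amplitude is constant with range by default (no radar-equation
  `1/r^4` falloff; an optional power-law exponent exists). Detection tests
  therefore probe the statistics of the background model, not radiometry.
- Targets are evaluated at *each pulse's own transmit time*, so fast targets
  smear across azimuth exactly as a rotating antenna sees them. The ground
  truth records the position at the moment the beam crosses the target
  (solved by a short fixed-point iteration), which is the position the blip
  actually images; a scan-start or scan-center convention would bias the
  truth by up to half a rotation's worth of target motion.

What the generator does *not* emulate: antenna sidelobes, multipath,
beam-height-dependent detectability, second-trace echoes, or correlated
clutter textures. Passing the recovery tests shows the detector and trackers
are correct under the stated noise model, not that they are calibrated for
any particular radar site.

One RNG stream per scene is seeded explicitly; per-scan sub-streams are
derived deterministically from the scene seed and scan index, so identical
seeds give bitwise-identical scans and different seeds change the noise but
not the truth.

## Archives and exports

Blipmovies (per-scan metadata plus retained blips with their raw cells) and
raw scan archives are gzip-compressed streams of newline-delimited records
in a canonical JSON serialization: keys sorted lexicographically, no
insignificant whitespace, full-precision numbers. The container is
self-describing — line 1 is a header with format name and version — and
unknown keys at any level survive a read/write cycle, which is the
forward/backward-compatibility contract (readers warn on newer versions and
parse best-effort; malformed lines fail with their line number). Sample
matrices are stored as base64 little-endian unsigned 16-bit values
(headroom over the 12-bit card, with the true bit depth in the metadata);
a threshold switches to sparse (row, col, value) triples, and an azimuth
sector restriction stores only the selected pulse columns along with their
original column indices. This is a fresh container design against the
stated compatibility contract, not a byte-level reader for any existing
archive format. Blip and track tables are exported as RFC 4180 CSV with
fixed column orders; tracked blips carry dense positive track ids in order
of track creation.

## The processing pipeline

`run_pipeline()` drives source → background → blips → tracks → sinks with
named hook points between stages (`SCAN_META`, `SCAN_DATA`, `POST_STATS`,
`POST_HOT`, `POST_PATCHES`, `POST_BLIPS`, `POST_TRACK_STEP`,
`TRACK_COMPLETE`, `SCAN_DONE`). Hooks receive the stage payload and return
a replacement; with none registered the pipeline is the identity composition
of the module functions, a property the tests check directly. A failing hook
logs and leaves the payload unchanged unless `strict_hooks` is set — in a
field deployment a broken user plugin should not abort a recording session.
Configurations are plain JSON or YAML files; `run_batch()` processes several
with isolated state and a nonzero exit status if any job failed. The first
`learn_scans` scans initialize the background and emit no blips. A thin
command-line wrapper (`inst/exec/aeroscan`) exposes run/batch/simulate/
export/render verbs over these functions.

## The reference study and problem sizes

`run_benchmark()` fixes the validation scenario: a 1024 x 512 polar grid
(50 Msamples/s, 2.5 s rotation), noise floor 100 with scale 10, three
constant-velocity targets at 13 m/s with amplitude 100 — ten times the
noise scale — background learned on 4 scans and 20 scans scored, detection
at `z_thresh = 4` with a minimum blip size of 8 samples, tracking with MFC
at `k = 3`. At `z = 4` the exponential tail still makes roughly 2% of
noise samples hot (about 10,000 per scan), so the minimum-size filter is
what separates point targets (around 30 cells above threshold with the
default point spread) from noise clusters, whose size distribution decays
too fast to reach 8 cells. Typical results: every scored (scan, target)
pair has a blip centroid within one cell diagonal of truth, exactly three
blips on at least 95% of scans, link recall above 0.93, track purity 1.0,
and mean track speed within a fraction of a percent of the simulated
13 m/s. These sizes keep a full run around half a minute on one CPU while
remaining large enough that the noise statistics behave asymptotically.

## Numerical and degenerate-input choices

- Hot requires strict `z > z_thresh`; filter bounds are closed intervals.
- `d = 0` cells use the signed-infinity z-score rule above.
- Assignment ties and MFC ranking ties resolve by (gain rounded to 1e-9,
  pure-extension-before-break, track id, blip azimuth, seeded coin toss).
- A blip whose interpolated timestamp does not strictly follow a track's
  last blip (possible for seam-adjacent detections) is simply not a
  candidate for that track.
- Straightness of an out-and-back track is 0 (net displacement zero);
  1-blip tracks are excluded from track summaries by default.
- `alpha = 0` leaves the background untouched; `alpha = 1` replaces it with
  the single-scan statistics; updating with the learning population's own
  statistics is a fixed point for any `alpha`.

## Known limitations

Detection is per-sample thresholding with connectivity — no CFAR, no
matched filtering, no physical power calibration (samples stay in digitizer
units throughout). Tracking assumes constant velocity between scans and
offers no multiple-hypothesis reasoning; crossing targets closer than the
centroid noise cannot be disambiguated by any gain function. The archive
format is this package's own; it does not read legacy binary archives.
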