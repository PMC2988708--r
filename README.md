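# aeroscan

Headless R toolkit for **radar aeroecology**: detecting putative biological
targets ("blips") in digitized marine surveillance-radar scans and linking
them into tracks, with archival formats, delimited exports, and a seeded
synthetic-scene simulator so the whole chain is testable without radar
hardware.

A scan is a matrix of unsigned-integer echo intensities — rows are range
cells (depth `dr = c / (2 * rate)`), columns are pulses around one antenna
rotation. Processing follows the classical adaptive-background scheme:

1. **Background.** Per *stats cell* (a window of samples x pulses), learn the
   pooled mean `m` and mean absolute deviation `d` over the first `L` scans;
   afterwards update exponentially, `m <- (1 - alpha) m + alpha m_scan`.
2. **Hot samples.** A sample is hot when its z-score `(x - m) / d` exceeds a
   user threshold.
3. **Blips.** Hot samples group into 8-connected patches (azimuth wraps at
   the 0/360 seam); patches passing user bounds on sample count, PPI area,
   angular and radial span become blips, summarized by intensity-weighted
   centroid, perimeter, intensity statistics and a pulse-interpolated
   timestamp.
4. **Tracks.** Blips link across scans either by nearest-neighbour
   assignment — a maximum-cardinality matching minimizing total extension
   distance, ties broken by a seeded coin toss — or by a greedy multiframe
   correspondence (MFC) over a sliding window of `k` scans that ranks
   candidate links by the gain
   `-w_p ln(1 + d/sigma_p) - w_v ln(1 + dv/sigma_v)`
   (proximity to the constant-velocity prediction, and velocity
   homogeneity), and may retroactively break and re-attach links within the
   window.

## Worked example

Simulate a small scene with one 8 m/s target in exponential clutter, learn
the background on three scans, extract blips from the rest and track them:

```r
library(aeroscan)

meta  <- scan_meta(n_pulses = 64, n_samples = 128, rate_hz = 50e6,
                   duration_s = 2.5)
tg    <- target_spec("A", x0 = 100, y0 = 50, vx = 8, vy = 0,
                     amplitude = 400, psf_sigma_r_m = 6, psf_sigma_az_deg = 6)
scene <- scene_config(meta, n_scans = 10, targets = list(tg),
                      clutter = clutter_spec(noise_mean = 100,
                                             noise_scale = 10), seed = 5)

cfg <- pipeline_config(
  source     = scene,
  extraction = extraction_params(z_thresh = 4, learn_scans = 3,
                                 filters = blip_filters(min_samples = 6)),
  tracker    = "mfc",
  tracker_params = tracker_params(max_speed_mps = 60),
  sinks      = list(blip_csv  = "blips.csv",
                    track_csv = "tracks.csv"),
  seed = 5)

out <- run_pipeline(cfg)
out$tracks_completed
#> [1] 1
read.csv("tracks.csv")
#>   id n_blips  t_start    t_end mean_speed_mps net_heading_deg straightness
#> 1  1       7 8.001803 23.05122       7.965636        89.99918    0.9928822
```

One track: seven blips (ten scans minus three learning scans), recovered
speed 7.97 m/s against the simulated 8 m/s, heading 90.0 degrees matching the
true due-east course, and straightness ~1 for a straight flight. `blips.csv`
holds one row per blip (`ts, x_m, y_m, z_m, n_samples, area_m2,
perimeter_cells, int_mean, int_max, angular_span_deg, radial_span_m,
track_id`).

The same run is available from a shell via the thin CLI:

```sh
Rscript inst/exec/aeroscan run job.json     # or .yml
Rscript inst/exec/aeroscan render scans.raw -o ppi/ --npix 512
```

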