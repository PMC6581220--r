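# awakepet

Brain PET of awake, freely moving mice — simulation, radioactive
point-source head tracking, event-by-event motion-corrected list-mode
reconstruction, and test–retest / pharmacological-challenge quantification,
in one R package.

Mouse-brain PET is usually acquired under anesthesia, which itself alters
the tracer uptake being measured. The alternative implemented here lets the
animal move on a platform inside the scanner: four ~1-mm radioactive point
sources (296–370 kBq) glued to the head are localised in 32-ms list-mode
reconstruction frames; the four detected sources whose six pairwise
distances best match a rigid marker model (exhaustive search, geometric
similarity score) give the head pose by a Kabsch least-squares fit; frames
with any marker farther than 2 mm from the rigid model are discarded.
Every coincidence event's line of response is then transformed by the
inverse of the pose interpolated at the event time, and list-mode OSEM
(16 subsets, 8 iterations, image-space Gaussian resolution model)
reconstructs in the head frame, with attenuation from a body-outline mask
(soft tissue, 0.097 cm⁻¹) and an exposure-weighted moving sensitivity.

Because no scanner data ships with the package, a full list-mode simulator
(`simulate_listmode`) generates coincidence streams from a digital
mouse-head phantom (five labelled brain regions in an attenuating body)
under bounded random head trajectories with rest/move bouts — so every
stage, from raw events to regional SUV statistics (coefficient of
variation, ICC, Bland–Altman, time–activity-curve slope tests, challenge
percent change), is testable against ground truth.

## Worked example

```r
library(awakepet)

phantom <- make_head_phantom()          # activity + mu-map + atlas, head frame
markers <- default_marker_model()      # 4 fiducials on the head surface
geom    <- scanner_preset("desk")      # 288 x 12 crystals, r = 80 mm

# a 20-s scan of a mouse exploring at ~2 cm/s
traj <- sample_trajectory(20000, mean_speed = 2, seed = 1)
sim  <- simulate_listmode(phantom$activity, markers, traj, geom,
                          duration_ms = 20000, rate_cps = 6e5, seed = 2)
sim$events
#> <event_stream> 945345 events over 20.0 s (geometry 'desk')

trk <- track_events(sim$events, markers, geom)
mean(trk$trajectory$accepted)
#> [1] 0.9248
sd <- speed_and_distance(head_track(trk$trajectory, markers))
sd$speed_cms; sd$distance_m
#> [1] 2.502731
#> [1] 0.4629051

# motion-corrected reconstruction of the moving scan, compared with a
# plain reconstruction of a matched static scan of the same phantom
img <- motion_corrected_recon(sim$events, trk$trajectory, geom,
                              phantom$activity$grid,
                              recon_config(4, 2, psf_sigma_mm = 0.86))
traj0 <- sample_trajectory(20000, 0, rotation_scale = 0, seed = 1)
sim0  <- simulate_listmode(phantom$activity, markers, traj0, geom,
                           duration_ms = 20000, rate_cps = 6e5, seed = 2)
static <- osem_listmode(sim0$events, geom, phantom$activity$grid,
                        recon_config(4, 2, psf_sigma_mm = 0.86))
round(100 * (regional_means(img, phantom$atlas) -
             regional_means(static, phantom$atlas)) /
        regional_means(static, phantom$atlas), 1)
#>          cortex caudate_putamen        thalamus     hippocampus      cerebellum
#>             3.5             2.8             2.7             2.5            -2.3
```

92% of the 32-ms frames yield a validated pose. The measured head speed
(2.5 cm/s against the trajectory's 2.0 cm/s target) is slightly inflated
because per-frame pose noise adds path length — the track is deliberately
not smoothed before the distance sum. The last line is the package's
central claim in one number per region: after event-by-event motion
correction, the regional means of the moving scan agree with a matched
motion-free scan to within a few percent. `run_experiment()` chains three
such scans (test, retest, locomotor challenge) into SUV tables,
behavioural metrics and heat maps; `reference_suv_means()` ships a
published-scale group-mean SUV table whose challenge contrast evaluates to
+63.7% (awake) vs +24.0% (anesthetized) via `memantine_percent_change()`.

A thin command-line wrapper over these functions is installed at
`inst/cli/awakepet.R` (subcommands `simulate`, `track`, `reconstruct`,
`behavior`, `stats`).

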