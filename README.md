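# nightwatch

Event-driven nighttime monitoring for ambient assisted living (AAL),
in R. The package is aimed at researchers and engineers building
sensor-based home monitoring for older adults living alone: it
re-creates, in-process, the *active database* pattern — sensor streams
inserted into tables, event-condition-action (ECA) triggers reacting to
every insert, services notified over publish/subscribe channels — and
implements three nighttime services on top of it, together with a
fully seeded night simulator so everything can be tested against known
ground truth.

## What it computes

**Bed presence from a load cell.** An 80 Hz ADC stream from a
strain-gauge cell under one bed leg is converted to kilograms
(`weight = adc_out / ratio`, ratio −41943 counts/kg) and summarised
over non-overlapping 40-sample windows — one per half second. A window
counts as occupied iff

    Presence = (σ_w ≥ O_σw) AND (m_w ≥ O_mw)

where `m_w` and `σ_w` are the window median and standard deviation and
the thresholds are calibrated per resident by the Otsu algorithm
(the cut maximising between-class variance `ω₀ω₁(μ₀−μ₁)²`). State
changes emit bed-exit (`Bout`) / bed-entrance (`Bin`) events.

**Transition mining.** Over the event alphabet
{Ba, K, H, L, I, D, Bin, Bout} (bathroom, kitchen, hallway, living
room, inactivity, door, bed in/out), the miner maintains online the
first-order confidence matrix `P(e_j | e_i)` and Welford mean/sd of the
inter-event transition time per pair, and exports the graph of edges
above a confidence threshold (default 0.2) as DOT.

**Early-night classification.** A 20-minute window slid over each
night yields 15 features (last four event symbols, three inter-event
times, eight event-type counts) labelled `TPI` (10 p.m.–midnight) or
`!TPI` (midnight–6 a.m.); a from-scratch C4.5 tree (gain-ratio splits
with Quinlan's mean-gain filter) discriminates the two, evaluated by
stratified 10-fold cross-validation.

**Simulator.** A semi-Markov resident over {Bed, Ba, K, H, L} with a
planted transition matrix, truncated-normal dwells and transit gaps
(7 ± 7 min out of bed), a bimodal load-cell emission model, and an
Emfit-style bed sensor that misses ~60% of exits. Every stream is
reproducible from one seed, with full ground truth.

## Worked example

```r
library(nightwatch)

cfg <- night_scenario(seed = 42)          # 14 nights, 10 p.m.-6 a.m.
rec <- simulate_night(cfg, 1, loadcell = TRUE)

w   <- loadcell_windows(adc_to_weight(rec$loadcell$adc_out), rec$loadcell$ts)
thr <- calibrate_thresholds(w)
#> Bed-presence thresholds (Otsu-calibrated)
#>   O_m_w     = 10.3502 kg  (separability 0.999)
#>   O_sigma_w = 0.0603 kg  (separability 0.948)
#>   calibrated on 57600 windows

ev <- detect_bed_events(w, thr)
head(ev, 2)
#>                    ts symbol
#> 1 2024-01-01 22:43:02    Bin
#> 2 2024-01-01 22:48:01   Bout
event_f1(ev, rec$true_bed_events)$f1
#> [1] 1
```

The thresholds land in the gap between the empty-bed and occupied-bed
clusters of each statistic, and on simulated nights the detected
Bin/Bout events match the ground truth exactly (F1 = 1 here).

```r
m <- transition_model()
for (r in simulate_nights(cfg)) m <- observe_events(m, night_events(r))
transition_probability(m, "Bout", "Ba")
#> [1] 0.757
transition_time_stats(m, "Bout", "Ba")   # seconds
#> $n 53   $mean 557.3   $sd 377.9
```

After a bed exit the most likely next event is a bathroom visit
(planted confidence 0.7, recovered 0.757 from 14 nights), taking on
average 9.3 min — the mean of the planted 7 ± 7 min transit law after
truncation at zero.

```r
ds <- build_dataset(do.call(rbind,
        lapply(simulate_nights(cfg), night_events, bed = "true")))
nrow(ds); sum(ds$label == "TPI")
#> [1] 336
#> [1] 84
crossval_c45(ds, k = 10, seed = 1)
#> 10-fold CV (seed 1): mean accuracy 0.852 (sd 0.062)
```

14 nights × 24 non-overlapping 20-minute windows give 336 labelled
observations (84 early-night); the tree recovers the planted
early-night structure well above the 0.75 majority baseline.

`run_pipeline(out_dir, scenario = cfg)` chains all of the above
(simulate → calibrate → detect → mine → train → cross-validate) and
writes the event logs, thresholds, transition table/graph, dataset,
tree and a `metrics.json` that is byte-identical across runs with the
same scenario and seed.

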