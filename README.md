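# demeflow

Social structure from RFID movement records: multilayer map-equation
modules, compression-rate modularity, and pedigree-supported demes.

House mice and other small mammals organise into demes — small
reproductive units, typically one dominant male with several females and
subordinates — that leave a clear trace in who shares a nest box with
whom. `demeflow` is for researchers running RFID-instrumented enclosure
(or nest-box field) studies who want to go from raw antenna logs to a
quantitative account of that structure: how tightly the population is
partitioned, how the partition evolves in time and space, and which
social clusters actually reproduce together.

## The method in brief

1. **Visits.** Paired outer/inner antenna reads are parsed into credible
   nest-box visits; equivocal signal patterns are dropped and counted.
   Records around enclosure checks are censored to the following
   midnight.
2. **Time layers.** The record is cut at enclosure-wide silent gaps
   (> 1 h) and into ≤ 48 h fragments; layers spanning < 24 h merge into
   their nearest neighbour. Each layer yields a weighted network whose
   edge `A[i, j]` is the co-occupancy time of `i` and `j` in any box.
3. **Multilayer clustering.** Layers are coupled into a state network:
   intra-layer links weighted by `(1 - r)`, cross-layer links by the
   relax rate `r` times the similarity of an individual's neighbourhood
   between layers (overlap coefficient of normalised neighbour weights).
   Modules minimise the two-level map equation

   `L = q H(Q) + sum_m p_m H(P_m)`  (bits per step of a random walk),

   with codewords shared per individual within a module, via a Louvain
   search. Structure is summarised by the compression-rate modularity

   `M = L_before / L_after  (>= 1)`,

   the one-module codelength over the partitioned codelength.
4. **Diagnostics.** Relax-rate selection by normalized mutual information
   across a 21-value grid; robustness by a visit-reordering bootstrap
   that conserves every individual's per-box time budget while disturbing
   synchrony; module distinctiveness; a spatial-separation index of box
   possession; period-summary networks.
5. **Demes.** With a resolved pedigree: multiple paternity, family-bond
   persistence across layers, and per-module deme support — the effective
   number of parental pairs whose gestation windows both parents spent in
   the module where the litter was conceived.

A built-in continuous-time simulator emits reader events, metadata,
check schedules, pedigrees and a planted truth partition, so the whole
pipeline is testable end to end without any external data.

## Worked example

```r
library(demeflow)

run <- simulate_run(sim_config(duration_days = 45, mixing = 0.05,
                               birth_rate = 0.06), seed = 42)
run
#> sim_run: 45 individuals, 42732 reads over 45 days; 2 planted modules

out <- deme_pipeline(run$events, run$checks, run_config(rng_seed = 42), r = 0.6)
out$fit
#> Multilayer map-equation module fit
#>   state nodes: 277  layers: 18  modules: 2
#>   relax rate r = 0.60, teleportation tau = 0.01
#>   codelength: 4.3339 -> 3.6612 bits/step  (modularity M = 1.184)
```

The fit found two modules that persist across all 18 layers (48-h
snapshots): a random walk over the co-occupancy network can be described
in 3.66 bits per step once partitioned, against 4.33 bits unpartitioned —
a compression rate of 1.18. The recovered partition matches the planted
one exactly:

```r
nmi(out$fit$partition, planted_partition(run, out$fit$partition))
#> [1] 1
```

Per-layer descriptive statistics and the pedigree link:

```r
head(out$metrics, 3)
#>   layer_index distinctiveness distinctiveness_pooled spatial_separation
#> 1           1           0.951                  0.952              0.947
#> 2           2           0.963                  0.961              0.918
#> 3           3           0.987                  0.987              0.961

deme_support(run$pedigree, out$fit$partition, out$layers)
#> Deme support (effective parental pairs per module):
#>  module_id effective_pairs is_deme
#>          1           4.000    TRUE
#>          2           2.625    TRUE

multiple_paternity(run$pedigree)
#> [1] 0
```

Individuals spent 95–99% of their interaction time with members of their
own module (distinctiveness), modules near-monopolised their boxes
(spatial separation ~0.95), both modules carry positive reproductive
support — both are demes — and with the simulator's full dominant-male
control every litter is single-sired, so multiple paternity is 0.

`plot(out$fit, layers = out$layers)` draws the module-membership raster
(individuals × layers, coloured by module). `select_relax_rate()`,
`bootstrap_modularity()`, `modularity_for_subgraph()` (sex-specific M),
`summary_network()`, `box_occupancy()` and `bond_persistence()` cover the
rest of the analysis; see the vignette in `vignettes/` for the models,
parameter meanings and design decisions.

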