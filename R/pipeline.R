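#' Run the full movement-network pipeline
#'
#' Convenience wrapper chaining the stages: censor events around enclosure
#' checks, reconstruct credible visits, clip them outside check windows,
#' discretise the record into time layers, build per-layer co-occupancy
#' networks, fit the multilayer module partition at the requested relax
#' rate, and compute per-layer distinctiveness and spatial separation.
#'
#' @param events reader events (see [read_events()]).
#' @param checks check schedule (may be NULL).
#' @param config a [run_config()].
#' @param r relax rate (default 0.6).
#' @return list: \code{visits}, \code{layers}, \code{networks},
#'   \code{fit} (a \code{demefit}), \code{metrics} (per-layer table).
#' @export
deme_pipeline <- function(events, checks = NULL, config = run_config(),
                          r = 0.6) {
  ev <- if (!is.null(checks)) censor_checks(events, checks) else events
  visits <- extract_visits(ev)
  if (!is.null(checks)) visits <- clip_visits_to_checks(visits, checks)
  layers <- build_time_layers(ev,
                              gap_max_hours = config$gap_max_hours,
                              layer_max_hours = config$layer_max_hours,
                              min_hours = config$layer_min_hours_for_merge)
  networks <- co_occupancy_networks(visits, layers)
  fit <- fit_demes(networks, r = r, tau = config$tau, seed = config$rng_seed)
  metrics <- layer_metrics(networks, visits, layers, fit$partition)
  list(visits = visits, layers = layers, networks = networks, fit = fit,
       metrics = metrics)
}
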