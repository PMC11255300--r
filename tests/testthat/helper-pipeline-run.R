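# One full-scale synthetic run shared by the recovery tests: simulated once
# per session and cached. Sized so that the initiation-aligned RMSD rests on
# well over 457 trajectories and the event set on > 300 cell cycles.
.run_cache <- new.env(parent = emptyenv())

full_pipeline_run <- function() {
  if (!is.null(.run_cache$full)) return(.run_cache$full)
  cfg <- sim_config(sim = list(n_lineages = 48),
                    schedule = list(duration = 330))
  ds <- simulate_dataset(cfg, seed = 20250924)
  linked <- link_foci(ds$observations)
  events <- detect_initiation(linked[linked$channel == "replisome", ], ds$cells)
  aligned <- align_on_initiation(linked[linked$channel == "replisome", ],
                                 events, ds$cells, window = 20)
  corrected <- subtract_net_drift(aligned)
  curve <- rmsd_curve(corrected)
  .run_cache$full <- list(ds = ds, linked = linked, events = events,
                          aligned = aligned, corrected = corrected,
                          curve = curve)
  .run_cache$full
}

# per-locus run for displacement-minimum recovery
locus_run <- function(alpha, seed) {
  key <- sprintf("locus_%s", alpha)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  cfg <- sim_config(sim = list(n_lineages = 12),
                    schedule = list(duration = 300),
                    locus = list(name = sprintf("alpha%.2f", alpha),
                                 alpha = alpha, ter_anchor = alpha >= 0.95))
  ds <- simulate_dataset(cfg, seed = seed)
  tr <- fit_channel_transform(ds$landmarks)
  obs <- dplyr::bind_rows(
    ds$observations[ds$observations$channel == "replisome", ],
    apply_channel_transform(ds$observations[ds$observations$channel == "locus", ], tr)
  )
  rec <- compute_displacements(obs, ds$cells)
  .run_cache[[key]] <- list(ds = ds, records = rec, transform = tr)
  .run_cache[[key]]
}
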