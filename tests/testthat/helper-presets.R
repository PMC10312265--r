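# Shared cache of full-size preset runs for the acceptance suite: stores
# scalar metrics and the probe-neuron trace of each preset (never the full
# trace container) so thresholds and filters can be re-applied without
# re-simulating.
.presetCache <- new.env(parent = emptyenv())

presetRun <- function(name, T = 2, dt = 5e-4) {
  key <- paste0(name, "_", T, "_", dt)
  if (!is.null(.presetCache[[key]])) return(.presetCache[[key]])
  t0 <- proc.time()
  out <- runPreset(name, T = T, dt = dt, keepResult = TRUE)
  elapsed <- unname((proc.time() - t0)[3])
  probe <- stiTable(out$report)$population[1]
  entry <- list(
    sti = stiTable(out$report)$sti[1],
    probe = probe,
    trace = neuronTrace(out$result, probe, 100),
    latencies = out$report@latencies,
    elapsed = elapsed)
  .presetCache[[key]] <- entry
  entry
}

presetSTI <- function(name) presetRun(name)$sti
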