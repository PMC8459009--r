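#' SpikeRaster: spike events of one simulation run
#'
#' @slot events data.frame with `neuron_id` (integer) and `time` (ms, a
#'   multiple of the step size), time-ordered.
#' @slot t_end run duration, ms.
#' @slot dt integration step, ms.
#' @slot traces data.frame of recorded membrane potentials (1 kHz, column
#'   `time` plus one column per recorded neuron); empty if none requested.
#' @slot delivered total number of delayed synaptic deliveries performed
#'   (event-accounting diagnostic).
#' @exportClass SpikeRaster
setClass("SpikeRaster",
         representation(events = "data.frame", t_end = "numeric",
                        dt = "numeric", traces = "data.frame",
                        delivered = "numeric"))

setValidity("SpikeRaster", function(object) {
  ev <- object@events
  msgs <- character(0)
  if (!all(c("neuron_id", "time") %in% names(ev))) {
    msgs <- c(msgs, "events needs columns neuron_id, time")
  } else if (nrow(ev)) {
    if (min(ev$time) < 0 || max(ev$time) > object@t_end + 1e-9) {
      msgs <- c(msgs, "event times outside [0, t_end]")
    }
    steps <- ev$time / object@dt
    if (any(abs(steps - round(steps)) > 1e-6)) {
      msgs <- c(msgs, "event times must be multiples of dt")
    }
    if (anyDuplicated(ev[, c("neuron_id", "time")])) {
      msgs <- c(msgs, "at most one spike per neuron per step")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SpikeRaster-class compact description.
#' @param object a `SpikeRaster`.
#' @export
setMethod("show", "SpikeRaster", function(object) {
  cat("SpikeRaster:", nrow(object@events), "spikes from",
      length(unique(object@events$neuron_id)), "neurons over",
      object@t_end, "ms (dt =", object@dt, "ms)\n")
  invisible(NULL)
})

#' Spike events of a raster
#' @param raster a [SpikeRaster-class] object.
#' @return data.frame with `neuron_id`, `time` (ms).
#' @export
spikeEvents <- function(raster) raster@events

#' Recorded voltage traces of a run
#' @inheritParams spikeEvents
#' @return data.frame (`time` plus one column per recorded neuron), possibly
#'   empty.
#' @export
voltageTraces <- function(raster) raster@traces

#' Simulation protocol
#'
#' @param duration run length, ms (a multiple of `dt`).
#' @param dt integration step, ms; 0.05 ms is the reference value.
#' @param stimulus a [stimulusProtocol()] object, or `NULL` for an
#'   unstimulated run.
#' @param record_traces neuron ids whose membrane potential is recorded at
#'   1 ms resolution.
#' @param canonical_exp_term use the canonical `g_L * Delta_T` prefactor of
#'   the exponential spike-initiation term (sensitivity switch; off by
#'   default).
#' @param exp_clamp clamp on the exponent of the spike-initiation term.
#' @return list of class `"simulationProtocol"`.
#' @export
simulationProtocol <- function(duration = 300, dt = 0.05, stimulus = NULL,
                               record_traces = integer(0),
                               canonical_exp_term = FALSE, exp_clamp = 10) {
  stopifnot(dt > 0, duration > 0,
            abs(duration / dt - round(duration / dt)) < 1e-9)
  structure(list(duration = duration, dt = dt, stimulus = stimulus,
                 record_traces = as.integer(record_traces),
                 canonical_exp_term = canonical_exp_term,
                 exp_clamp = exp_clamp),
            class = "simulationProtocol")
}

#' Run a column simulation
#'
#' Time-stepped co-simulation of all neurons and synapses. Per step the
#' engine (i) delivers due delayed spikes to the postsynaptic conductance
#' accumulators, applying the short-term-plasticity efficiency computed at
#' the presynaptic spike time, (ii) evaluates the conductance-based currents
#' at the current membrane potentials, (iii) advances all neurons one
#' forward-Euler step, (iv) applies the threshold/reset rule, recording
#' spikes at `t + dt`, and (v) enqueues new spikes with their transmission
#' delays (delays shorter than `dt` round up to one step). Neurons start at
#' `V = E_L`, `w = 0`. Identical inputs reproduce identical rasters; the
#' engine itself draws no random numbers.
#'
#' @param network a fully parameterized [ColumnNetwork-class] (see
#'   [assignParameters()]).
#' @param protocol a [simulationProtocol()] object.
#' @return a [SpikeRaster-class] object.
#' @examples
#' \donttest{
#' cfg <- defaultColumnConfig()
#' net <- assignParameters(buildColumn(cfg, seed = 1),
#'                         speciesTable(cfg, "rodent"),
#'                         cfg$background_currents)
#' ras <- runSimulation(net, simulationProtocol(duration = 100))
#' }
#' @export
runSimulation <- function(network, protocol = simulationProtocol()) {
  neu <- network@neurons
  if (anyNA(neu$C) || anyNA(neu$I_bg)) {
    stop("network is not fully parameterized; run assignParameters() first")
  }
  syn <- network@synapses
  if (abs(syn$AMPA$tau_D - syn$NMDA$tau_D) > 1e-9) {
    stop("AMPA and NMDA transmission delays must agree: both receptors are ",
         "driven by the same presynaptic release event")
  }
  dt <- protocol$dt
  nSteps <- as.integer(round(protocol$duration / dt))
  segs <- if (is.null(protocol$stimulus)) {
    data.frame(neuron = integer(0), step_on = integer(0),
               step_off = integer(0), amp = numeric(0))
  } else {
    makeStimulus(protocol$stimulus, dt)
  }
  res <- .run_column_cpp(
    neu$C, neu$g_L, neu$E_L, neu$V_r, neu$V_th, neu$Delta_T, neu$tau_w,
    neu$a, neu$b, neu$I_bg, neu$excitatory,
    network@pre, network@post,
    unclass(syn$AMPA), unclass(syn$NMDA), unclass(syn$GABAA),
    network@stp,
    as.integer(segs$neuron), as.integer(segs$step_on),
    as.integer(segs$step_off), as.numeric(segs$amp),
    dt, nSteps, isTRUE(protocol$canonical_exp_term), protocol$exp_clamp,
    protocol$record_traces, as.integer(round(1 / dt)))
  ev <- data.frame(neuron_id = res$neuron_id, time = res$time)
  ev <- ev[order(ev$time, ev$neuron_id), , drop = FALSE]
  rownames(ev) <- NULL
  traces <- if (length(protocol$record_traces)) {
    tr <- as.data.frame(res$traces)
    names(tr) <- paste0("n", protocol$record_traces)
    cbind(time = seq(0, by = 1, length.out = nrow(tr)), tr)
  } else {
    data.frame()
  }
  new("SpikeRaster", events = ev, t_end = protocol$duration, dt = dt,
      traces = traces, delivered = res$delivered)
}

#' Write a spike raster to CSV
#'
#' Two columns: `neuron_id`, `spike_time_ms`.
#' @inheritParams spikeEvents
#' @param path output file.
#' @export
writeRaster <- function(raster, path) {
  ev <- raster@events
  write.csv(data.frame(neuron_id = ev$neuron_id, spike_time_ms = ev$time),
            path, row.names = FALSE)
  invisible(path)
}

#' Write recorded voltage traces to CSV
#' @inheritParams writeRaster
#' @export
writeTraces <- function(raster, path) {
  write.csv(raster@traces, path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records what is needed to reproduce a run: a hash of the configuration,
#' the seeds and the durations.
#'
#' @param path output file.
#' @param config configuration list.
#' @param seeds named or unnamed seed vector/list.
#' @param durations named list/vector of durations, ms.
#' @export
writeRunManifest <- function(path, config, seeds, durations) {
  manifest <- list(config_hash = configHash(config), seeds = seeds,
                   durations = durations,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Deterministic hash of a configuration
#'
#' Polynomial checksum of the JSON serialization; identical configurations
#' give identical hashes across platforms.
#' @param config configuration list.
#' @return hex string.
#' @export
configHash <- function(config) {
  js <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                      force = TRUE))
  bytes <- utf8ToInt(js)
  h <- 0
  for (v in bytes) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}
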