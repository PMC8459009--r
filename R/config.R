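# Column configuration: architecture, aEIF tables, synapse/STP constants,
# connectivity and background currents, loaded from YAML with schema checks.

.LAYERS <- c("L2/3", "L5", "L6")
# PC: pyramidal cell (excitatory). LL-IN: local-layer interneuron.
# BPC: bipolar cell (cross-layer interneuron). LBC: large basket cell and
# MC: Martinotti cell (long-range interneurons). All non-PC classes are
# inhibitory; LBCs share the membrane parameters of the PCs of their layer.
.CLASSES <- c("PC", "LL-IN", "BPC", "LBC", "MC")
.AEIF_FIELDS <- c("C", "g_L", "E_L", "V_r", "V_th", "Delta_T", "tau_w",
                  "a", "b")

#' Population keys of the column
#'
#' A population is one (layer, cell class) combination; keys look like
#' `"L2/3 PC"`. The five classes are PC (pyramidal cell), LL-IN (local-layer
#' interneuron), BPC (bipolar cell, cross-layer), LBC (large basket cell) and
#' MC (Martinotti cell); only PCs are excitatory.
#'
#' @param layer layer label(s), subset of `"L2/3"`, `"L5"`, `"L6"`.
#' @param cell_class class label(s).
#' @return character vector of population keys.
#' @export
populationKey <- function(layer, cell_class) paste(layer, cell_class)

.allPopulations <- function() {
  as.vector(t(outer(.LAYERS, .CLASSES, populationKey)))
}

.checkKeys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(unknown, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Validate and complete an aEIF parameter table
#'
#' A parameter table holds one row per (layer, cell class) with the nine aEIF
#' membrane fields. Missing LBC rows default to the PC row of their layer
#' (basket cells share pyramidal-cell electrophysiology); missing BPC or MC
#' rows default to the LL-IN row of their layer. A missing PC or LL-IN row is
#' an error.
#'
#' @param table data.frame with columns `layer`, `cell_class` and the aEIF
#'   fields `C`, `g_L`, `E_L`, `V_r`, `V_th`, `Delta_T`, `tau_w`, `a`, `b`.
#' @return completed data.frame with one row per population (15 rows),
#'   ordered by layer then class.
#' @export
completeAeifTable <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("layer", "cell_class", .AEIF_FIELDS)
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("parameter table lacks column(s): ", paste(miss, collapse = ", "))
  }
  table$layer <- as.character(table$layer)
  table$cell_class <- as.character(table$cell_class)
  stopifnot(all(table$layer %in% .LAYERS),
            all(table$cell_class %in% .CLASSES))
  if (anyDuplicated(populationKey(table$layer, table$cell_class))) {
    stop("duplicate (layer, cell_class) rows in parameter table")
  }
  rows <- list()
  for (ly in .LAYERS) {
    sub <- table[table$layer == ly, , drop = FALSE]
    getRow <- function(cls) sub[sub$cell_class == cls, , drop = FALSE]
    for (cls in .CLASSES) {
      r <- getRow(cls)
      if (nrow(r) == 0L) {
        src <- switch(cls, "LBC" = "PC", "BPC" = "LL-IN", "MC" = "LL-IN",
                      stop(sprintf("parameter table lacks the %s %s entry",
                                   ly, cls)))
        r <- getRow(src)
        if (nrow(r) == 0L) {
          stop(sprintf("parameter table lacks the %s %s entry (needed for %s)",
                       ly, src, cls))
        }
        r$cell_class <- cls
      }
      rows[[populationKey(ly, cls)]] <- r[, need]
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # each row must form a valid aEIF parameter set
  for (i in seq_len(nrow(out))) {
    do.call(aeifParams, as.list(out[i, .AEIF_FIELDS]))
  }
  out
}

#' Import an aEIF parameter table from CSV
#'
#' Reads a parameter table in the standard layout: one row per layer x cell
#' class, columns `layer`, `cell_class`, `C`, `g_L`, `E_L`, `V_r`, `V_th`,
#' `Delta_T`, `tau_w`, `a`, `b`. The table is validated and completed with
#' [completeAeifTable()].
#'
#' @param path CSV file path.
#' @return completed parameter table (15 rows).
#' @export
importAeifTable <- function(path) {
  completeAeifTable(read.csv(path, check.names = FALSE))
}

.CONFIG_KEYS <- c("architecture", "allow_autapses", "background_currents",
                  "aeif_tables", "synapses", "stp", "connectivity",
                  "stimulus", "simulation")

#' Read and validate a column configuration file
#'
#' Parses a YAML column configuration with sections `architecture` (neuron
#' counts per layer and class), `aeif_tables` (one membrane-parameter block
#' per species), `synapses` (per-receptor kernel constants), `stp`
#' (Tsodyks-Markram constants), `connectivity` (source -> target connection
#' probabilities), `background_currents`, `stimulus` and `simulation`
#' defaults. Unknown keys anywhere are rejected.
#'
#' @param path YAML file path.
#' @return validated configuration list; aEIF tables are completed
#'   data.frames, connectivity a full numeric matrix over population keys.
#' @seealso [defaultColumnConfig()]
#' @export
readColumnConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  validateColumnConfig(raw)
}

#' Validate a column configuration list
#'
#' @param raw configuration list (as parsed from YAML).
#' @return normalized configuration list.
#' @export
validateColumnConfig <- function(raw) {
  .checkKeys(raw, .CONFIG_KEYS, "configuration")
  for (k in c("architecture", "background_currents", "aeif_tables",
              "synapses", "stp", "connectivity")) {
    if (is.null(raw[[k]])) stop("configuration lacks section: ", k)
  }
  cfg <- list()

  arch <- raw$architecture
  .checkKeys(arch, c("total", "counts"), "architecture")
  .checkKeys(arch$counts, .LAYERS, "architecture$counts")
  counts <- matrix(0L, nrow = length(.LAYERS), ncol = length(.CLASSES),
                   dimnames = list(.LAYERS, .CLASSES))
  for (ly in names(arch$counts)) {
    .checkKeys(arch$counts[[ly]], .CLASSES,
               paste0("architecture$counts$`", ly, "`"))
    for (cls in names(arch$counts[[ly]])) {
      n <- arch$counts[[ly]][[cls]]
      stopifnot(n >= 0, n == round(n))
      counts[ly, cls] <- as.integer(n)
    }
  }
  if (!is.null(arch$total) && sum(counts) != arch$total) {
    stop(sprintf("architecture counts sum to %d but total is %d",
                 sum(counts), arch$total))
  }
  cfg$architecture <- counts

  cfg$allow_autapses <- isTRUE(raw$allow_autapses)

  bg <- raw$background_currents
  .checkKeys(bg, c("excitatory", "interneuron"), "background_currents")
  stopifnot(is.numeric(bg$excitatory), is.numeric(bg$interneuron))
  cfg$background_currents <- list(excitatory = bg$excitatory,
                                  interneuron = bg$interneuron)

  cfg$aeif_tables <- lapply(raw$aeif_tables, function(tb) {
    completeAeifTable(do.call(rbind, lapply(tb, as.data.frame)))
  })

  .checkKeys(raw$synapses, c("AMPA", "NMDA", "GABAA"), "synapses")
  cfg$synapses <- lapply(names(raw$synapses), function(rc) {
    blk <- raw$synapses[[rc]]
    .checkKeys(blk, c("g_max", "E_rev", "tau_on", "tau_off", "tau_D"),
               paste0("synapses$", rc))
    do.call(synapseParams, c(list(receptor = rc), blk))
  })
  names(cfg$synapses) <- names(raw$synapses)
  if (!all(c("AMPA", "NMDA", "GABAA") %in% names(cfg$synapses))) {
    stop("synapses section must define AMPA, NMDA and GABAA blocks")
  }

  .checkKeys(raw$stp, c("U", "tau_facil", "tau_rec"), "stp")
  cfg$stp <- do.call(stpParams, raw$stp)

  pops <- .allPopulations()
  P <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  .checkKeys(raw$connectivity, pops, "connectivity")
  for (src in names(raw$connectivity)) {
    .checkKeys(raw$connectivity[[src]], pops,
               paste0("connectivity$`", src, "`"))
    for (dst in names(raw$connectivity[[src]])) {
      p <- raw$connectivity[[src]][[dst]]
      if (!is.numeric(p) || p < 0 || p > 1) {
        stop(sprintf("connection probability %s -> %s outside [0,1]",
                     src, dst))
      }
      P[src, dst] <- p
    }
  }
  cfg$connectivity <- P

  stimDefaults <- list(onset = 200, stim_duration = 100, mode = "poisson50",
                       pulse_amplitude = 4000, poisson_rate = 50,
                       pulse_width = 1)
  if (!is.null(raw$stimulus)) {
    .checkKeys(raw$stimulus, names(stimDefaults), "stimulus")
    stimDefaults <- modifyList(stimDefaults, raw$stimulus)
  }
  cfg$stimulus <- stimDefaults

  simDefaults <- list(duration = 300, dt = 0.05, canonical_exp_term = FALSE,
                      exp_clamp = 10)
  if (!is.null(raw$simulation)) {
    .checkKeys(raw$simulation, names(simDefaults), "simulation")
    simDefaults <- modifyList(simDefaults, raw$simulation)
  }
  cfg$simulation <- simDefaults
  cfg
}

#' Bundled default column configuration
#'
#' The package's default study conditions: a 2,000-neuron column with 900
#' L2/3 pyramidal cells, rodent and human membrane-parameter tables built
#' from the qualitative species contrasts (human L5/L6 pyramidal capacitance
#' about half the rodent value, human LL-IN capacitance about twice, human
#' reset and threshold potentials higher), unified synapse and
#' short-term-plasticity constants (U = 0.25, tau_facil = 500 ms,
#' tau_rec = 300 ms) and provisional connection probabilities. The numerical
#' values of the tables and probabilities are editable defaults, not
#' measurements; see the package vignette.
#'
#' @return validated configuration list (see [readColumnConfig()]).
#' @examples
#' cfg <- defaultColumnConfig()
#' sum(cfg$architecture)  # 2000
#' @export
defaultColumnConfig <- function() {
  readColumnConfig(system.file("extdata", "column_config.yaml",
                               package = "CortexColumn", mustWork = TRUE))
}

#' Species parameter table from a configuration
#'
#' @param config configuration list.
#' @param species species name present in `config$aeif_tables`.
#' @return completed aEIF parameter table.
#' @export
speciesTable <- function(config, species) {
  tb <- config$aeif_tables[[species]]
  if (is.null(tb)) {
    stop(sprintf("no aEIF table for species '%s' (available: %s)", species,
                 paste(names(config$aeif_tables), collapse = ", ")))
  }
  tb
}
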