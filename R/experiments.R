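# Scripted experiments: single-repeat assay, species comparison, single-
# parameter morphs, background and STD-recovery sweeps, noise robustness,
# and the quadratic response-surface regression.

#' AssayReport: per-repeat metrics with summaries
#'
#' @slot results data.frame, one row per repeat x pattern x condition with
#'   the four assay metrics (baseline and persistent-activity spike density,
#'   excited-neuron ratio, transfer accuracy) plus bookkeeping columns.
#' @slot summary data.frame of per-group means and SEMs.
#' @slot anova data.frame of one-way ANOVA results per compared quantity.
#' @slot condition experiment label.
#' @exportClass AssayReport
setClass("AssayReport",
         representation(results = "data.frame", summary = "data.frame",
                        anova = "data.frame", condition = "character"))

#' @describeIn AssayReport-class compact description.
#' @param object an `AssayReport`.
#' @export
setMethod("show", "AssayReport", function(object) {
  cat("AssayReport [", object@condition, "]: ", nrow(object@results),
      " repeats\n", sep = "")
  print(object@summary, row.names = FALSE, digits = 4)
  invisible(NULL)
})

#' Per-repeat results of a report
#' @param report an [AssayReport-class] object.
#' @return data.frame.
#' @export
assayResults <- function(report) report@results

#' Summary table of a report
#' @inheritParams assayResults
#' @return data.frame with group means and SEMs.
#' @export
assaySummary <- function(report) report@summary

#' Write an assay report to CSV
#'
#' Writes the tidy per-repeat table and a summary table (mean, SEM, n, and
#' the ANOVA p-values where computed).
#' @inheritParams assayResults
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the two file paths.
#' @export
writeAssayReport <- function(report, dir, prefix = report@condition) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, paste0(prefix, "_results.csv"))
  f2 <- file.path(dir, paste0(prefix, "_summary.csv"))
  write.csv(report@results, f1, row.names = FALSE)
  smry <- report@summary
  write.csv(smry, f2, row.names = FALSE)
  if (nrow(report@anova)) {
    write.csv(report@anova, file.path(dir, paste0(prefix, "_anova.csv")),
              row.names = FALSE)
  }
  invisible(c(f1, f2))
}

# derive independent child seeds (connectivity / stimulus / noise) from one
# repeat seed, so experiments can vary one randomness source while freezing
# the others
.childSeeds <- function(seed) {
  set.seed(as.integer(seed))
  s <- sample.int(2147483646L, 3L)
  list(connectivity = s[1L], stimulus = s[2L], noise = s[3L])
}

#' Run one repeat of the image assay
#'
#' Builds the column (connectivity redrawn from the repeat's connectivity
#' seed), assigns the given parameter table, encodes the (optionally
#' noise-corrupted) pattern as a stimulus at 200 ms, simulates 300 ms, and
#' computes the four assay metrics. The accuracy reference is always the
#' clean pattern; noise corrupts only the input image before encoding.
#'
#' @param config configuration list ([defaultColumnConfig()]).
#' @param table aEIF parameter table for the run.
#' @param pattern 30x30 binary input matrix.
#' @param seed repeat seed; child seeds for connectivity, stimulus and noise
#'   are derived from it.
#' @param noise salt-and-pepper proportion applied to the input, in [0, 1].
#' @param background list with `excitatory`/`interneuron` currents (pA);
#'   defaults to the configuration's values.
#' @param tau_rec optional override of the depression recovery time, ms.
#' @param stimulus named list overriding fields of the configuration's
#'   stimulus block (`onset`, `stim_duration`, `mode`, `pulse_amplitude`,
#'   `poisson_rate`).
#' @param return_raster also return the spike raster.
#' @return one-row data.frame of metrics (plus the raster when requested, as
#'   a list).
#' @export
runAssay <- function(config, table, pattern, seed, noise = 0,
                     background = config$background_currents,
                     tau_rec = NULL, stimulus = list(),
                     return_raster = FALSE) {
  seeds <- .childSeeds(seed)
  if (!is.null(tau_rec)) config$stp$tau_rec <- tau_rec
  net <- buildColumn(config, seeds$connectivity)
  net <- assignParameters(net, table, background)
  clean <- pattern
  if (noise > 0) pattern <- addSaltPepper(pattern, noise, seeds$noise)
  stim <- modifyList(config$stimulus, stimulus)
  targets <- encodeImage(pattern)
  proto <- simulationProtocol(
    duration = config$simulation$duration, dt = config$simulation$dt,
    stimulus = if (length(targets)) {
      stimulusProtocol(targets, onset = stim$onset,
                       stim_duration = stim$stim_duration, mode = stim$mode,
                       pulse_amplitude = stim$pulse_amplitude,
                       poisson_rate = stim$poisson_rate,
                       pulse_width = stim$pulse_width,
                       seed = seeds$stimulus)
    },
    canonical_exp_term = config$simulation$canonical_exp_term,
    exp_clamp = config$simulation$exp_clamp)
  ras <- runSimulation(net, proto)
  onset <- stim$onset
  base <- c(onset - 100, onset)
  pa <- c(onset, onset + 100)
  out <- data.frame(
    seed = as.integer(seed),
    pattern = if (is.null(attr(clean, "name"))) NA_character_ else
      attr(clean, "name"),
    noise = noise,
    spike_density_baseline = spikeDensity(ras, base),
    spike_density_pa = spikeDensity(ras, pa),
    excited_ratio = if (length(targets)) {
      excitedRatio(ras, targets, base, pa)
    } else NA_real_,
    accuracy = transferAccuracy(clean, decodeOutput(ras, c(onset + 2,
                                                           onset + 100))))
  if (return_raster) list(metrics = out, raster = ras) else out
}

# run n_repeats of the assay over a pattern list; one row per repeat x pattern
.assayRepeats <- function(config, table, patterns, seeds, label, ...) {
  if (is.null(names(patterns))) {
    names(patterns) <- vapply(patterns, function(p) {
      nm <- attr(p, "name"); if (is.null(nm)) "pattern" else nm
    }, character(1))
  }
  rows <- list()
  for (pn in names(patterns)) {
    for (i in seq_along(seeds)) {
      r <- runAssay(config, table, patterns[[pn]], seeds[i], ...)
      r$pattern <- pn
      r$repetition <- i
      r$group <- label
      rows[[length(rows) + 1L]] <- r
    }
  }
  do.call(rbind, rows)
}

#' Repeat seeds derived from a master seed
#'
#' @param seed master seed.
#' @param n_repeats number of repeats (default 9, the assay's standard).
#' @return integer vector of length `n_repeats`.
#' @export
repeatSeeds <- function(seed, n_repeats = 9) {
  set.seed(as.integer(seed))
  sample.int(2147483646L, n_repeats)
}

# group-wise summary of all four metrics + per-metric ANOVA across groups,
# computed within each pattern
.reportFrom <- function(results, condition,
                        metrics = c("spike_density_baseline",
                                    "spike_density_pa", "excited_ratio",
                                    "accuracy")) {
  sumRows <- list()
  anovaRows <- list()
  for (pn in unique(results$pattern)) {
    sub <- results[results$pattern == pn, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]]
      if (all(is.na(v))) next
      sp <- split(v, sub$group)
      for (g in names(sp)) {
        sumRows[[length(sumRows) + 1L]] <- data.frame(
          pattern = pn, metric = m, group = g, n = length(sp[[g]]),
          mean = mean(sp[[g]]),
          sem = sd(sp[[g]]) / sqrt(length(sp[[g]])))
      }
      if (length(sp) >= 2L && all(lengths(sp) >= 2L)) {
        an <- summarizeAssay(v, sub$group)$anova
        an <- cbind(pattern = pn, metric = m, an)
        anovaRows[[length(anovaRows) + 1L]] <- an
      }
    }
  }
  new("AssayReport", results = results,
      summary = do.call(rbind, sumRows),
      anova = if (length(anovaRows)) do.call(rbind, anovaRows) else
        data.frame(),
      condition = condition)
}

#' Species comparison experiment
#'
#' Runs the full image assay for two (or more) species tables under
#' identical architecture, connectivity and stimulation, with per-repeat
#' reseeding of connectivity and stimulus, and summarizes the four metrics
#' with one-way ANOVA across species per pattern.
#'
#' @inheritParams runAssay
#' @param species character vector of species names in
#'   `config$aeif_tables`.
#' @param patterns named list of 30x30 patterns; default the four bundled
#'   shapes.
#' @param n_repeats independent repeats per pattern x species (default 9).
#' @param seed master seed from which the repeat seeds are drawn; the same
#'   repeat seeds are used for every species (paired comparison).
#' @return an [AssayReport-class] object.
#' @export
runSpeciesComparison <- function(config, species = c("rodent", "human"),
                                 patterns = defaultPatterns(),
                                 n_repeats = 9, seed = 1, ...) {
  seeds <- repeatSeeds(seed, n_repeats)
  res <- do.call(rbind, lapply(species, function(sp) {
    .assayRepeats(config, speciesTable(config, sp), patterns, seeds, sp, ...)
  }))
  .reportFrom(res, "species_comparison")
}

#' The four bundled input patterns
#' @return named list of 30x30 matrices (star, circle, square, triangle).
#' @export
defaultPatterns <- function() {
  nm <- c("star", "circle", "square", "triangle")
  setNames(lapply(nm, loadPattern), nm)
}

#' Morph named parameters of one table toward another
#'
#' Clones `base` and replaces the single field `param` with the values of
#' `source`, either everywhere or only in the populations listed in `scope`.
#' All other fields stay bit-identical.
#'
#' @param base,source completed aEIF parameter tables.
#' @param param one of the nine aEIF field names (e.g. `"C"`, `"V_th"`).
#' @param scope character vector of population keys (e.g.
#'   `c("L2/3 LL-IN", "L5 LL-IN")`), or `NULL` for all populations.
#' @return morphed table.
#' @export
morphTable <- function(base, source, param, scope = NULL) {
  base <- completeAeifTable(base)
  source <- completeAeifTable(source)
  if (!param %in% .AEIF_FIELDS) {
    stop("unknown parameter name: ", param, " (expected one of ",
         paste(.AEIF_FIELDS, collapse = ", "), ")")
  }
  keys <- populationKey(base$layer, base$cell_class)
  rows <- if (is.null(scope)) seq_len(nrow(base)) else {
    bad <- setdiff(scope, keys)
    if (length(bad)) stop("unknown population(s): ", paste(bad, collapse = ", "))
    which(keys %in% scope)
  }
  base[[param]][rows] <- source[[param]][match(keys[rows],
                                               populationKey(source$layer,
                                                             source$cell_class))]
  base
}

#' Scale one parameter multiplicatively
#'
#' Probe used to push a parameter beyond either species' value (e.g.
#' "increase V_th by a further 25%": `factor = 1.25`). For negative-valued
#' potentials an increase toward depolarization means shrinking the
#' magnitude, so `V_th` and `V_r` are scaled as
#' `E_L + factor * (value - E_L)` (relative to leak reversal); all other
#' fields are scaled directly.
#'
#' @inheritParams morphTable
#' @param table completed aEIF parameter table.
#' @param factor multiplicative factor.
#' @return scaled table.
#' @export
scaleParameter <- function(table, param, factor, scope = NULL) {
  table <- completeAeifTable(table)
  keys <- populationKey(table$layer, table$cell_class)
  rows <- if (is.null(scope)) seq_len(nrow(table)) else which(keys %in% scope)
  if (param %in% c("V_th", "V_r")) {
    table[[param]][rows] <- table$E_L[rows] +
      factor * (table[[param]][rows] - table$E_L[rows])
  } else {
    table[[param]][rows] <- factor * table[[param]][rows]
  }
  table
}

#' Single-parameter morph experiment
#'
#' Replaces one named membrane parameter of the base species with the other
#' species' values (optionally only in a scoped population set) and runs the
#' full assay for both the base and the morphed table.
#'
#' @inheritParams runSpeciesComparison
#' @param base,source species names in `config$aeif_tables`.
#' @param param aEIF field to morph.
#' @param scope population keys to morph, or `NULL` for all.
#' @return an [AssayReport-class] with groups `base` and `morph`.
#' @export
morphSingleParam <- function(config, base = "rodent", source = "human",
                             param = "V_th", scope = NULL,
                             patterns = defaultPatterns(), n_repeats = 9,
                             seed = 1, ...) {
  seeds <- repeatSeeds(seed, n_repeats)
  baseTb <- speciesTable(config, base)
  morphTb <- morphTable(baseTb, speciesTable(config, source), param, scope)
  res <- rbind(
    .assayRepeats(config, baseTb, patterns, seeds, base, ...),
    .assayRepeats(config, morphTb, patterns, seeds,
                  paste0("morph_", param), ...))
  .reportFrom(res, paste0("morph_", param))
}

#' Background-current sweep
#'
#' Runs the assay at several (excitatory, interneuron) background pairs;
#' default levels are the standard 250/200 pA plus the raised 300/250 and
#' lowered 200/150 pA probes.
#'
#' @inheritParams runSpeciesComparison
#' @param species single species name.
#' @param levels list of `c(excitatory, interneuron)` pairs, pA.
#' @return an [AssayReport-class] with one group per level.
#' @export
sweepBackground <- function(config, species = "rodent",
                            levels = list(c(250, 200), c(300, 250),
                                          c(200, 150)),
                            patterns = defaultPatterns(), n_repeats = 9,
                            seed = 1, ...) {
  stopifnot(all(vapply(levels, function(l) all(l > 0), logical(1))))
  seeds <- repeatSeeds(seed, n_repeats)
  tb <- speciesTable(config, species)
  res <- do.call(rbind, lapply(levels, function(l) {
    .assayRepeats(config, tb, patterns, seeds,
                  sprintf("bg_%g_%g", l[1L], l[2L]),
                  background = list(excitatory = l[1L], interneuron = l[2L]),
                  ...)
  }))
  .reportFrom(res, "background_sweep")
}

#' Synaptic-depression recovery-time sweep
#'
#' Substitutes the depression recovery constant `tau_rec` globally and runs
#' the assay at each value. The default grid spans the fast-recovery
#' (144 ms) and slow-recovery (536 ms) regimes with intermediate points;
#' accuracy is not expected to vary monotonically along it.
#'
#' @inheritParams sweepBackground
#' @param tau_rec_values vector of recovery times, ms (> 0).
#' @return an [AssayReport-class] with one group per value.
#' @export
sweepStdRecovery <- function(config, species = "human",
                             tau_rec_values = c(100, 144, 200, 300, 400,
                                                536, 650),
                             patterns = defaultPatterns()["square"],
                             n_repeats = 9, seed = 1, ...) {
  stopifnot(all(tau_rec_values > 0))
  seeds <- repeatSeeds(seed, n_repeats)
  tb <- speciesTable(config, species)
  res <- do.call(rbind, lapply(tau_rec_values, function(tr) {
    .assayRepeats(config, tb, patterns, seeds, sprintf("taurec_%g", tr),
                  tau_rec = tr, ...)
  }))
  .reportFrom(res, "std_recovery_sweep")
}

#' Noise-robustness experiment
#'
#' Corrupts the input image with salt-and-pepper noise before encoding
#' (accuracy is always scored against the clean pattern) and runs the assay
#' per species x proportion.
#'
#' @inheritParams runSpeciesComparison
#' @param proportions noise proportions in [0, 1]; default 0/10/20/30%.
#' @param pattern single 30x30 input pattern (default the square).
#' @return an [AssayReport-class]; groups are `species_noiseX` labels.
#' @export
noiseRobustness <- function(config, species = c("rodent", "human"),
                            proportions = c(0, 0.1, 0.2, 0.3),
                            pattern = loadPattern("square"), n_repeats = 9,
                            seed = 1, ...) {
  stopifnot(all(proportions >= 0 & proportions <= 1))
  seeds <- repeatSeeds(seed, n_repeats)
  res <- do.call(rbind, lapply(species, function(sp) {
    tb <- speciesTable(config, sp)
    do.call(rbind, lapply(proportions, function(pr) {
      r <- .assayRepeats(config, tb, list(pattern), seeds,
                         sprintf("%s_noise%g", sp, 100 * pr), noise = pr, ...)
      r$species <- sp
      r
    }))
  }))
  .reportFrom(res, "noise_robustness")
}
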