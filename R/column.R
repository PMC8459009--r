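#' ColumnNetwork: a parameterized cortical column
#'
#' S4 container for one realization of the column: a neuron table (layer,
#' cell class, membrane parameters, background current), a directed synapse
#' list (presynaptic id, postsynaptic id; excitatory sources project
#' AMPA+NMDA, inhibitory sources GABA-A), the per-receptor synapse constants,
#' the short-term-plasticity constants and the construction seed.
#'
#' @slot neurons data.frame with one row per neuron: `id`, `layer`,
#'   `cell_class`, `population`, `excitatory`, the nine aEIF fields and
#'   `I_bg` (background current, pA; NA until [assignParameters()] runs).
#' @slot pre,post integer vectors: the directed synapse list.
#' @slot synapses named list of [synapseParams()] (AMPA, NMDA, GABAA).
#' @slot stp [stpParams()] constants shared by all connections.
#' @slot connectivity numeric matrix of connection probabilities used.
#' @slot seed integer construction seed.
#' @exportClass ColumnNetwork
setClass("ColumnNetwork",
         representation(neurons = "data.frame", pre = "integer",
                        post = "integer", synapses = "list", stp = "list",
                        connectivity = "matrix", seed = "integer"))

setValidity("ColumnNetwork", function(object) {
  n <- nrow(object@neurons)
  msgs <- character(0)
  if (!identical(object@neurons$id, seq_len(n))) {
    msgs <- c(msgs, "neuron ids must be 1..n in order")
  }
  if (length(object@pre) != length(object@post)) {
    msgs <- c(msgs, "pre and post must have equal length")
  }
  if (length(object@pre) &&
      (min(object@pre, object@post) < 1L || max(object@pre, object@post) > n)) {
    msgs <- c(msgs, "synapse endpoints out of range")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ColumnNetwork-class compact description.
#' @param object a `ColumnNetwork`.
#' @export
setMethod("show", "ColumnNetwork", function(object) {
  cat("ColumnNetwork:", nrow(object@neurons), "neurons,",
      length(object@pre), "synapses (seed", object@seed, ")\n")
  tab <- table(object@neurons$population)
  cat("  populations:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (all(is.na(object@neurons$C))) {
    cat("  membrane parameters: not yet assigned\n")
  }
  invisible(NULL)
})

#' Number of neurons in a column
#' @param network a [ColumnNetwork-class] object.
#' @return integer count.
#' @export
nNeurons <- function(network) nrow(network@neurons)

#' Neuron table of a column
#' @inheritParams nNeurons
#' @return the per-neuron data.frame.
#' @export
neuronTable <- function(network) network@neurons

#' Directed synapse list of a column
#' @inheritParams nNeurons
#' @return data.frame with columns `pre`, `post`.
#' @export
edgeList <- function(network) data.frame(pre = network@pre,
                                         post = network@post)

#' Neuron ids of one population
#' @inheritParams nNeurons
#' @param population population key, e.g. `"L2/3 PC"`.
#' @return integer vector of neuron ids (1-based, contiguous).
#' @export
populationIds <- function(network, population) {
  network@neurons$id[network@neurons$population == population]
}

#' Build the column network
#'
#' Lays out neurons population by population (layer 2/3 pyramidal cells
#' first, occupying ids 1..900 in the default architecture, in row-major
#' pixel order for the image mapping) and draws each ordered (pre, post) pair
#' as an independent Bernoulli trial with the configured probability for the
#' (source population, target population) pair. Autapses are excluded unless
#' the configuration allows them. Construction is deterministic for a fixed
#' seed. Membrane parameters and background currents are filled in by
#' [assignParameters()].
#'
#' @param config a configuration list from [readColumnConfig()] /
#'   [defaultColumnConfig()].
#' @param seed integer seed for the connectivity draw.
#' @return a [ColumnNetwork-class] object (parameters unassigned).
#' @examples
#' \donttest{
#' net <- buildColumn(defaultColumnConfig(), seed = 1)
#' nNeurons(net)  # 2000
#' }
#' @export
buildColumn <- function(config, seed) {
  counts <- config$architecture
  P <- config$connectivity
  stopifnot(all(P >= 0 & P <= 1))
  pops <- .allPopulations()
  neurons <- do.call(rbind, lapply(.LAYERS, function(ly) {
    do.call(rbind, lapply(.CLASSES, function(cls) {
      n <- counts[ly, cls]
      if (n == 0L) return(NULL)
      row <- data.frame(layer = ly, cell_class = cls,
                        population = populationKey(ly, cls),
                        excitatory = cls == "PC")
      row[rep(1L, n), , drop = FALSE]
    }))
  }))
  neurons <- cbind(id = seq_len(nrow(neurons)), neurons)
  rownames(neurons) <- NULL
  for (f in .AEIF_FIELDS) neurons[[f]] <- NA_real_
  neurons$I_bg <- NA_real_

  ids <- split(neurons$id, factor(neurons$population, levels = pops))
  set.seed(as.integer(seed))
  preL <- list()
  postL <- list()
  k <- 0L
  for (src in pops) {
    for (dst in pops) {
      p <- P[src, dst]
      nA <- length(ids[[src]])
      nB <- length(ids[[dst]])
      if (p <= 0 || nA == 0L || nB == 0L) next
      hit <- which(runif(nA * nB) < p)
      if (!length(hit)) next
      k <- k + 1L
      preL[[k]] <- ids[[src]][(hit - 1L) %% nA + 1L]
      postL[[k]] <- ids[[dst]][(hit - 1L) %/% nA + 1L]
    }
  }
  pre <- as.integer(unlist(preL))
  post <- as.integer(unlist(postL))
  if (!config$allow_autapses && length(pre)) {
    keep <- pre != post
    pre <- pre[keep]
    post <- post[keep]
  }
  new("ColumnNetwork", neurons = neurons, pre = pre, post = post,
      synapses = config$synapses, stp = unclass(config$stp),
      connectivity = P, seed = as.integer(seed))
}

#' Assign membrane parameters and background currents
#'
#' Writes a species parameter table into a built column: every neuron takes
#' the aEIF row of its (layer, cell class) population (large basket cells
#' default to the pyramidal-cell row of their layer, per
#' [completeAeifTable()]). Background currents are set by excitatory class:
#' pyramidal cells receive the excitatory level, all interneuron classes the
#' interneuron level (defaults 250 and 200 pA).
#'
#' @param network a [ColumnNetwork-class] object.
#' @param table aEIF parameter table (completed with [completeAeifTable()] if
#'   needed).
#' @param background list with `excitatory` and `interneuron` currents (pA).
#' @return the network with parameters filled in.
#' @export
assignParameters <- function(network, table,
                             background = list(excitatory = 250,
                                               interneuron = 200)) {
  tb <- completeAeifTable(table)
  rownames(tb) <- populationKey(tb$layer, tb$cell_class)
  neu <- network@neurons
  idx <- match(neu$population, rownames(tb))
  if (anyNA(idx)) {
    stop("parameter table lacks entries for population(s): ",
         paste(unique(neu$population[is.na(idx)]), collapse = ", "))
  }
  for (f in .AEIF_FIELDS) neu[[f]] <- tb[[f]][idx]
  neu$I_bg <- ifelse(neu$excitatory, background$excitatory,
                     background$interneuron)
  network@neurons <- neu
  validObject(network)
  network
}
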