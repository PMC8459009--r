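# Binary-image stimulus codec: 30x30 patterns onto the 900 L2/3 pyramidal
# cells (row-major), pulse/Poisson current generation, decoding, noise.

.PATTERN_DIM <- 30L
.N_L23PC <- 900L

.validatePattern <- function(pattern) {
  if (!is.matrix(pattern) || !all(dim(pattern) == .PATTERN_DIM)) {
    stop("a pattern must be a 30x30 matrix")
  }
  if (!all(pattern %in% c(0L, 1L))) stop("pattern pixels must be 0 or 1")
  invisible(TRUE)
}

#' Generate a named binary input pattern
#'
#' Deterministic 30x30 binary bitmaps of the four full-field shapes used by
#' the assay: a radius-10 disc (`circle`), a centered 20x20 block (`square`),
#' a filled isoceles triangle and a filled five-pointed star. Every pattern
#' has between 100 and 600 ON pixels. The same bitmaps ship as plain-text
#' PBM fixtures under `inst/extdata/patterns/`.
#'
#' @param name one of `"star"`, `"circle"`, `"square"`, `"triangle"`.
#' @return 30x30 integer matrix of 0/1 with attribute `name`.
#' @examples
#' sum(generatePattern("square"))  # 400 ON pixels
#' @export
generatePattern <- function(name = c("star", "circle", "square", "triangle")) {
  name <- match.arg(name)
  n <- .PATTERN_DIM
  ctr <- (n + 1) / 2 # 15.5: grid center, symmetric for even n
  rc <- expand.grid(r = seq_len(n), c = seq_len(n))
  on <- switch(name,
    square = rc$r >= 6 & rc$r <= 25 & rc$c >= 6 & rc$c <= 25,
    circle = (rc$r - ctr)^2 + (rc$c - ctr)^2 <= 10^2,
    triangle = {
      top <- 4; bot <- 27
      halfw <- 12 * (rc$r - top) / (bot - top)
      rc$r >= top & rc$r <= bot & abs(rc$c - ctr) <= halfw
    },
    star = {
      # five-pointed star: 10-vertex polygon, outer radius 13, inner 5.5,
      # one point upward; even-odd point-in-polygon test
      ang <- -pi / 2 + (0:9) * pi / 5
      rad <- rep(c(13, 5.5), 5)
      vx <- ctr + rad * cos(ang)
      vy <- ctr + rad * sin(ang)
      .pointInPolygon(rc$c, rc$r, vx, vy)
    })
  m <- matrix(0L, n, n)
  m[cbind(rc$r, rc$c)] <- as.integer(on)
  attr(m, "name") <- name
  m
}

# even-odd rule ray casting; vertices in order
.pointInPolygon <- function(x, y, vx, vy) {
  nV <- length(vx)
  inside <- logical(length(x))
  j <- nV
  for (i in seq_len(nV)) {
    cross <- ((vy[i] > y) != (vy[j] > y)) &
      (x < (vx[j] - vx[i]) * (y - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Read / write a 30x30 binary pattern as plain-text PBM (P1)
#'
#' @param path file path.
#' @return `readPBM` returns a 30x30 integer 0/1 matrix.
#' @export
readPBM <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^#", lines)])
  lines <- lines[nzchar(lines)]
  stopifnot(lines[1L] == "P1")
  dims <- as.integer(strsplit(lines[2L], "\\s+")[[1L]])
  vals <- as.integer(unlist(strsplit(paste(lines[-(1:2)], collapse = " "),
                                     "\\s+")))
  stopifnot(length(vals) == prod(dims))
  m <- matrix(vals, nrow = dims[2L], ncol = dims[1L], byrow = TRUE)
  .validatePattern(m)
  m
}

#' @rdname readPBM
#' @param pattern 30x30 binary matrix.
#' @param name comment written into the file header.
#' @export
writePBM <- function(pattern, path, name = attr(pattern, "name")) {
  .validatePattern(pattern)
  rows <- apply(pattern, 1L, paste, collapse = " ")
  writeLines(c("P1", if (!is.null(name)) paste("#", name),
               paste(.PATTERN_DIM, .PATTERN_DIM), rows), path)
  invisible(path)
}

#' Load a bundled pattern fixture
#'
#' @inheritParams generatePattern
#' @return 30x30 integer matrix.
#' @export
loadPattern <- function(name = c("star", "circle", "square", "triangle")) {
  name <- match.arg(name)
  m <- readPBM(system.file("extdata", "patterns", paste0(name, ".pbm"),
                           package = "CortexColumn", mustWork = TRUE))
  attr(m, "name") <- name
  m
}

#' Map a binary image to stimulated L2/3 pyramidal-cell ids
#'
#' Pixel (r, c) in row-major order maps to neuron id `30 (r - 1) + c`; the
#' returned set contains the ids of ON pixels.
#'
#' @param pattern 30x30 binary matrix.
#' @return sorted integer vector of target ids (subset of 1..900).
#' @examples
#' encodeImage(matrix(0L, 30, 30))  # integer(0)
#' @export
encodeImage <- function(pattern) {
  .validatePattern(pattern)
  tp <- t(pattern) # row-major order
  which(as.vector(tp) == 1L)
}

#' Decode the spiking output of the L2/3 pyramidal cells into an image
#'
#' Pixel k is 1 iff neuron id k (k = 1..900) fired at least once inside the
#' closed scoring window; the inverse of the [encodeImage()] mapping.
#'
#' @param raster a [SpikeRaster-class] object (or data.frame with
#'   `neuron_id`, `time`).
#' @param window closed scoring interval c(lo, hi), ms; default the
#'   post-stimulus window 202-300 ms.
#' @return 30x30 integer matrix.
#' @export
decodeOutput <- function(raster, window = c(202, 300)) {
  ev <- if (is(raster, "SpikeRaster")) raster@events else raster
  ids <- unique(ev$neuron_id[ev$time >= window[1L] & ev$time <= window[2L] &
                               ev$neuron_id <= .N_L23PC])
  v <- integer(.N_L23PC)
  v[ids] <- 1L
  matrix(v, .PATTERN_DIM, .PATTERN_DIM, byrow = TRUE)
}

#' Corrupt a pattern with salt-and-pepper noise
#'
#' Selects `round(proportion * 900)` distinct pixels uniformly at random and
#' flips each (`mode = "flip"`, the default, guaranteeing the stated
#' corruption level as a Hamming distance), or sets each selected pixel to 0
#' or 1 with equal probability (`mode = "extreme"`, the classic variant).
#' Deterministic for a fixed seed.
#'
#' @param pattern 30x30 binary matrix.
#' @param proportion fraction of pixels to corrupt, in [0, 1].
#' @param seed integer seed.
#' @param mode `"flip"` or `"extreme"`.
#' @return corrupted 30x30 matrix.
#' @export
addSaltPepper <- function(pattern, proportion, seed,
                          mode = c("flip", "extreme")) {
  .validatePattern(pattern)
  mode <- match.arg(mode)
  stopifnot(proportion >= 0, proportion <= 1)
  k <- round(proportion * length(pattern))
  if (k == 0L) return(pattern)
  set.seed(as.integer(seed))
  pick <- sample.int(length(pattern), k)
  out <- pattern
  if (mode == "flip") {
    out[pick] <- 1L - out[pick]
  } else {
    out[pick] <- as.integer(runif(k) < 0.5)
  }
  out
}

#' Stimulation protocol for the image assay
#'
#' Describes how target neurons are driven: `pulse` mode (the default)
#' injects one rectangular current of `pulse_amplitude` pA into every target
#' during `[onset, onset + stim_duration)`; `poisson50` mode draws, per
#' target, an independent Poisson train of 1-step current pulses at
#' `poisson_rate` Hz inside the window.
#'
#' @param targets integer ids of stimulated L2/3 pyramidal cells (1..900).
#' @param onset stimulus onset, ms.
#' @param stim_duration stimulus window length, ms.
#' @param mode `"pulse"` or `"poisson50"`.
#' @param pulse_amplitude pulse height, pA.
#' @param poisson_rate Poisson rate, Hz (poisson50 mode).
#' @param pulse_width width of each Poisson pulse, ms (poisson50 mode).
#' @param seed integer seed for the Poisson draws.
#' @return list of class `"stimulusProtocol"`.
#' @export
stimulusProtocol <- function(targets, onset = 200, stim_duration = 100,
                             mode = c("poisson50", "pulse"),
                             pulse_amplitude = 4000, poisson_rate = 50,
                             pulse_width = 1, seed = 1L) {
  mode <- match.arg(mode)
  targets <- as.integer(targets)
  stopifnot(all(targets >= 1L), all(targets <= .N_L23PC),
            onset >= 0, stim_duration >= 0, pulse_width > 0)
  structure(list(targets = targets, onset = onset,
                 stim_duration = stim_duration, mode = mode,
                 pulse_amplitude = pulse_amplitude,
                 poisson_rate = poisson_rate, pulse_width = pulse_width,
                 seed = as.integer(seed)),
            class = "stimulusProtocol")
}

#' Realize a stimulation protocol as current segments
#'
#' Converts a protocol into the per-neuron rectangular current contributions
#' the simulation engine consumes: one row per rectangle, applied during
#' simulation steps `[step_on, step_off)` (1-based; step k spans time
#' `[(k-1) dt, k dt)`).
#'
#' @param protocol a [stimulusProtocol()] object.
#' @param dt simulation step, ms.
#' @return data.frame with columns `neuron`, `step_on`, `step_off`, `amp`.
#' @export
makeStimulus <- function(protocol, dt) {
  if (length(protocol$targets) == 0L) {
    return(data.frame(neuron = integer(0), step_on = integer(0),
                      step_off = integer(0), amp = numeric(0)))
  }
  stepOn <- floor(protocol$onset / dt) + 1L
  nStepsWin <- max(1L, round(protocol$stim_duration / dt))
  if (protocol$mode == "pulse") {
    return(data.frame(neuron = protocol$targets, step_on = stepOn,
                      step_off = stepOn + nStepsWin,
                      amp = protocol$pulse_amplitude))
  }
  # poisson50: expected count per target = rate[Hz] * window[ms] / 1000
  set.seed(protocol$seed)
  lambda <- protocol$poisson_rate * protocol$stim_duration / 1000
  widthSteps <- max(1L, as.integer(round(protocol$pulse_width / dt)))
  segs <- lapply(protocol$targets, function(id) {
    nP <- rpois(1L, lambda)
    if (nP == 0L) return(NULL)
    pulseStep <- stepOn + floor(runif(nP) * nStepsWin)
    data.frame(neuron = id, step_on = pulseStep,
               step_off = pulseStep + widthSteps,
               amp = protocol$pulse_amplitude)
  })
  out <- do.call(rbind, segs)
  if (is.null(out)) {
    out <- data.frame(neuron = integer(0), step_on = integer(0),
                      step_off = integer(0), amp = numeric(0))
  }
  out
}

# dense per-step drive matrix (steps x neurons) of a segment table;
# test/diagnostic helper, quadratic in size so only for small problems
.stimulusDrive <- function(segments, nSteps, nNeurons) {
  drive <- matrix(0, nSteps, nNeurons)
  for (i in seq_len(nrow(segments))) {
    ks <- segments$step_on[i]:min(segments$step_off[i] - 1L, nSteps)
    drive[ks, segments$neuron[i]] <- drive[ks, segments$neuron[i]] +
      segments$amp[i]
  }
  drive
}
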