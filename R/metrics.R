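# Assay statistics: network spike density, excited-neuron ratio,
# signal-transfer accuracy, and repeat-level summaries (mean, SEM, ANOVA).

#' Network spike density
#'
#' Whole-network spike count in the half-open interval `[lo, hi)` divided by
#' the interval length in ms. The assay's two standard windows are
#' 100-200 ms (baseline) and 200-300 ms (persistent activity).
#'
#' @param raster a [SpikeRaster-class] object (or data.frame with
#'   `neuron_id`, `time`).
#' @param interval `c(lo, hi)`, ms, `hi > lo`.
#' @return spikes per ms.
#' @examples
#' r <- data.frame(neuron_id = 1:100, time = seq(100, 199, length.out = 100))
#' spikeDensity(r, c(100, 200))  # 1 spike/ms
#' @export
spikeDensity <- function(raster, interval) {
  ev <- if (is(raster, "SpikeRaster")) raster@events else raster
  len <- interval[2L] - interval[1L]
  if (len <= 0) stop("interval must have positive length")
  sum(ev$time >= interval[1L] & ev$time < interval[2L]) / len
}

#' Ratio of excited neurons
#'
#' Fraction (percent) of the stimulated neurons whose firing increased by at
#' least 50% from the pre-stimulus to the post-stimulus window. A stimulated
#' neuron counts as excited iff its post-window spike count is at least 1.5
#' times its pre-window count *and* strictly larger (so a neuron silent in
#' both windows is not excited, while a neuron silent before with any spike
#' after is).
#'
#' @inheritParams spikeDensity
#' @param stimulated integer ids of the neurons that received current
#'   stimulation (the ON-pixel targets).
#' @param pre,post equal-length comparison windows `c(lo, hi)`, ms (spikes
#'   counted in `[lo, hi)`); defaults 100-200 and 200-300 ms.
#' @return percent, in [0, 100].
#' @export
excitedRatio <- function(raster, stimulated, pre = c(100, 200),
                         post = c(200, 300)) {
  if (length(stimulated) == 0L) stop("stimulated set must not be empty")
  if (abs(diff(pre) - diff(post)) > 1e-9) {
    stop("pre and post windows must have equal length")
  }
  ev <- if (is(raster, "SpikeRaster")) raster@events else raster
  ev <- ev[ev$neuron_id %in% stimulated, , drop = FALSE]
  cnt <- function(win) {
    tab <- table(factor(ev$neuron_id[ev$time >= win[1L] & ev$time < win[2L]],
                        levels = stimulated))
    as.vector(tab)
  }
  nPre <- cnt(pre)
  nPost <- cnt(post)
  excited <- nPost >= 1.5 * nPre & nPost > nPre
  100 * sum(excited) / length(stimulated)
}

#' Signal-transfer accuracy
#'
#' Percent of the 900 layer-2/3 pyramidal-cell positions where the input and
#' output pixels agree (ON pixel and the neuron spiked, or OFF pixel and the
#' neuron stayed silent): `100 * (1 - normalized Hamming distance)`.
#'
#' @param input,output 30x30 binary matrices.
#' @return percent, in [0, 100].
#' @examples
#' p <- generatePattern("square")
#' transferAccuracy(p, p)  # 100
#' @export
transferAccuracy <- function(input, output) {
  .validatePattern(input)
  .validatePattern(output)
  100 * mean(input == output)
}

#' Summarize per-repeat metric values across groups
#'
#' Per-group mean and standard error of the mean (sd / sqrt(n)), plus a
#' standard one-way ANOVA across groups with significance stars at the
#' 0.05 / 0.01 / 0.0001 thresholds.
#'
#' @param values numeric vector of per-repeat metric values.
#' @param groups group labels, same length as `values` (>= 2 groups, >= 2
#'   values per group).
#' @return list with `summary` (data.frame: group, n, mean, sem),
#'   `anova` (data.frame: F, df_between, df_within, p, stars).
#' @examples
#' summarizeAssay(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
#' @export
summarizeAssay <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  if (length(unique(groups)) < 2L) stop("need at least 2 groups for ANOVA")
  nPer <- table(groups)
  if (any(nPer < 2L)) stop("need at least 2 values per group for the SEM")
  sp <- split(values, groups)
  summary <- data.frame(
    group = names(sp),
    n = lengths(sp),
    mean = vapply(sp, mean, numeric(1)),
    sem = vapply(sp, function(v) sd(v) / sqrt(length(v)), numeric(1)),
    row.names = NULL)
  if (var(values) == 0) { # degenerate: no variance anywhere
    Fv <- 0
    p <- 1
  } else {
    fit <- aov(values ~ factor(groups))
    tab <- summary(fit)[[1L]]
    Fv <- tab[["F value"]][1L]
    p <- tab[["Pr(>F)"]][1L]
    if (is.na(Fv)) {
      Fv <- 0
      p <- 1
    }
  }
  k <- length(sp)
  list(summary = summary,
       anova = data.frame(F = Fv, df_between = k - 1L,
                          df_within = length(values) - k, p = p,
                          stars = significanceStars(p)))
}

#' Significance stars at the assay's thresholds
#'
#' `"ns"` for p > 0.05, `*` below 0.05, `**` below 0.01, `***` below 0.0001.
#' @param p p-value(s).
#' @return character vector.
#' @export
significanceStars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "***" else if (pi < 0.01) "**" else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}
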