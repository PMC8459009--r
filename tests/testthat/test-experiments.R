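# Experiment drivers: reproducibility, morph semantics, sweep plumbing, and
# the quadratic response surface.

smallAssayConfig <- function() {
  # miniature column so experiment plumbing tests stay fast
  cfg <- defaultColumnConfig()
  counts <- cfg$architecture
  counts[] <- 0L
  counts["L2/3", "PC"] <- 900L # codec needs the full pixel layer
  counts["L2/3", "LL-IN"] <- 20L
  cfg$architecture <- counts
  cfg$simulation$duration <- 300
  cfg
}

test_that("one assay repeat is fully reproducible from its seed", {
  cfg <- smallAssayConfig()
  tb <- speciesTable(cfg, "human")
  p <- loadPattern("star")
  a <- runAssay(cfg, tb, p, seed = 123)
  b <- runAssay(cfg, tb, p, seed = 123)
  expect_identical(a, b)
  c <- runAssay(cfg, tb, p, seed = 124)
  expect_false(identical(a, c))
})

test_that("a zero-amplitude stimulus on a silent network scores the
           spontaneous output: all-zero input gives 100 percent", {
  cfg <- smallAssayConfig()
  # subthreshold table: nothing fires spontaneously
  tb <- tinyTable(V_th = -40) # rheobase 300 pA > 250 pA background
  blank <- matrix(0L, 30, 30)
  r <- runAssay(cfg, tb, blank, seed = 1,
                stimulus = list(pulse_amplitude = 0))
  expect_equal(r$accuracy, 100)
  expect_equal(r$spike_density_baseline, 0)
  expect_true(is.na(r$excited_ratio)) # no stimulated neurons
})

test_that("identical tables for both 'species' give identical reports", {
  cfg <- smallAssayConfig()
  cfg$aeif_tables$human <- cfg$aeif_tables$rodent
  rep <- runSpeciesComparison(cfg, n_repeats = 2, seed = 5,
                              patterns = defaultPatterns()["star"])
  res <- assayResults(rep)
  rodent <- res[res$group == "rodent", setdiff(names(res), "group")]
  human <- res[res$group == "human", setdiff(names(res), "group")]
  expect_equal(rodent, human, ignore_attr = TRUE)
})

test_that("morphing a parameter to its own value reproduces the base report
           and a scoped morph changes exactly the scoped entries", {
  cfg <- smallAssayConfig()
  cfg$aeif_tables$human <- cfg$aeif_tables$rodent # self-morph
  rep <- morphSingleParam(cfg, base = "rodent", source = "human",
                          param = "V_th", n_repeats = 2, seed = 3,
                          patterns = defaultPatterns()["star"])
  res <- assayResults(rep)
  base <- res[res$group == "rodent", c("spike_density_baseline",
                                       "spike_density_pa", "accuracy")]
  morph <- res[res$group == "morph_V_th", c("spike_density_baseline",
                                            "spike_density_pa", "accuracy")]
  expect_equal(base, morph, ignore_attr = TRUE)
})

test_that("morphing all five membrane fields equals a full species swap", {
  cfg <- defaultColumnConfig()
  rod <- speciesTable(cfg, "rodent")
  hum <- speciesTable(cfg, "human")
  m <- rod
  # threshold before reset: the human reset sits above the rodent threshold,
  # so the opposite order would create an invalid intermediate table
  for (f in c("C", "g_L", "E_L", "V_th", "V_r")) {
    m <- morphTable(m, hum, f)
  }
  expect_equal(m[, c("C", "g_L", "E_L", "V_r", "V_th")],
               hum[, c("C", "g_L", "E_L", "V_r", "V_th")])
})

test_that("background and recovery sweeps produce one report group per
           level and match baseline at the default level", {
  cfg <- smallAssayConfig()
  star <- defaultPatterns()["star"]
  bg <- sweepBackground(cfg, species = "rodent",
                        levels = list(c(250, 200), c(300, 250)),
                        patterns = star, n_repeats = 2, seed = 7)
  expect_setequal(unique(assayResults(bg)$group),
                  c("bg_250_200", "bg_300_250"))
  tr <- sweepStdRecovery(cfg, species = "rodent",
                         tau_rec_values = c(144, 300, 536),
                         patterns = star, n_repeats = 2, seed = 7)
  expect_setequal(unique(assayResults(tr)$group),
                  c("taurec_144", "taurec_300", "taurec_536"))
  # tau_rec equal to the configured value reproduces the plain assay
  plain <- runAssay(cfg, speciesTable(cfg, "rodent"), star[[1]],
                    repeatSeeds(7, 2)[1])
  swept <- assayResults(tr)
  swept <- swept[swept$group == "taurec_300" & swept$repetition == 1, ]
  expect_equal(swept$accuracy, plain$accuracy)
  expect_equal(swept$spike_density_pa, plain$spike_density_pa)
})

test_that("raised background does not lower the baseline spike density", {
  cfg <- smallAssayConfig()
  bg <- sweepBackground(cfg, species = "rodent",
                        levels = list(c(200, 150), c(250, 200), c(300, 250)),
                        patterns = defaultPatterns()["star"], n_repeats = 2,
                        seed = 11)
  s <- assaySummary(bg)
  dens <- s[s$metric == "spike_density_baseline", ]
  dens <- dens[order(dens$group), ] # bg_200_150, bg_250_200, bg_300_250
  expect_true(all(diff(dens$mean) >= 0))
})

test_that("noise at proportion zero equals the clean assay under the same
           seeds", {
  cfg <- smallAssayConfig()
  nr <- noiseRobustness(cfg, species = "human", proportions = c(0, 0.2),
                        n_repeats = 2, seed = 13)
  res <- assayResults(nr)
  clean <- runAssay(cfg, speciesTable(cfg, "human"), loadPattern("square"),
                    repeatSeeds(13, 2)[1])
  got <- res[res$group == "human_noise0" & res$repetition == 1, ]
  expect_equal(got$accuracy, clean$accuracy)
})

test_that("quadratic surface fit recovers exact coefficients from noiseless
           samples and the constant model", {
  set.seed(8)
  n <- 40
  X <- as.data.frame(matrix(runif(n * 5), n, 5))
  names(X) <- paste0("x", 1:5)
  beta <- c(70, 3.3, 0.1, 1.5, 1.4, 1.7)
  gam <- c(-0.8, -1.9, 2.0, 1.7, 2.2)
  X$accuracy <- beta[1] + as.matrix(X[, 1:5]) %*% beta[-1] +
    as.matrix(X[, 1:5])^2 %*% gam
  fit <- fitQuadraticResponse(X, paste0("x", 1:5))
  expect_equal(fit@intercept, 70, tolerance = 1e-8)
  expect_equal(fit@coefficients$linear, beta[-1], tolerance = 1e-8)
  expect_equal(fit@coefficients$quadratic, gam, tolerance = 1e-8)
  # iterative least squares started at all-ones lands on the same solution
  fit2 <- fitQuadraticResponse(X, paste0("x", 1:5), method = "iterative")
  expect_equal(fit2@coefficients, fit@coefficients, tolerance = 1e-8)
  # constant response: intercept only
  X$accuracy <- 81.5
  cfit <- fitQuadraticResponse(X, paste0("x", 1:5))
  expect_equal(cfit@intercept, 81.5, tolerance = 1e-8)
  expect_equal(max(abs(c(cfit@coefficients$linear,
                         cfit@coefficients$quadratic))), 0,
               tolerance = 1e-8)
})

test_that("rank-deficient designs are rejected", {
  X <- data.frame(x1 = rep(0.5, 12), x2 = runif(12))
  X$accuracy <- rnorm(12)
  expect_error(fitQuadraticResponse(X, c("x1", "x2")), "constant")
  expect_error(fitQuadraticResponse(data.frame(x1 = runif(2),
                                               accuracy = rnorm(2)), "x1"),
               "at least")
})

test_that("vertex form matches completing the square by hand", {
  x <- seq(0, 1, length.out = 21)
  d <- data.frame(x1 = x, accuracy = 74.3 + 2.0 * x^2 + 1.6 * x)
  fit <- fitQuadraticResponse(d, "x1")
  vf <- vertexForm(fit)
  expect_equal(vf$curvature, 2.0, tolerance = 1e-8)
  expect_equal(vf$vertex, -1.6 / (2 * 2.0), tolerance = 1e-7)
  expect_equal(attr(vf, "constant"), 74.3 - 1.6^2 / (4 * 2.0),
               tolerance = 1e-7)
  # prediction from the vertex form equals the raw polynomial
  expect_equal(predict(fit, d), d$accuracy, tolerance = 1e-8)
})

test_that("the fit is scale-consistent: affine predictor rescaling before
           normalization leaves fitted accuracies unchanged", {
  set.seed(15)
  raw <- data.frame(x1 = runif(30, 100, 300), x2 = runif(30, -80, -60))
  acc <- 70 + 0.01 * raw$x1 - 0.002 * (raw$x1 - 200)^2 / 100 + 0.1 * raw$x2
  norm01 <- function(v) (v - min(v)) / (max(v) - min(v))
  d1 <- data.frame(x1 = norm01(raw$x1), x2 = norm01(raw$x2), accuracy = acc)
  d2 <- data.frame(x1 = norm01(3 * raw$x1 + 7), x2 = norm01(-2 * raw$x2),
                   accuracy = acc)
  f1 <- fitQuadraticResponse(d1, c("x1", "x2"))
  f2 <- fitQuadraticResponse(d2, c("x1", "x2"))
  # same normalized design up to per-predictor reflection: fitted values match
  expect_equal(sort(f1@fitted), sort(f2@fitted), tolerance = 1e-8)
})

test_that("surface tables interpolate the five predictors between species
           and leave everything else at the base value", {
  cfg <- defaultColumnConfig()
  rod <- speciesTable(cfg, "rodent")
  hum <- speciesTable(cfg, "human")
  at0 <- surfaceTable(cfg, rep(0, 5))
  expect_equal(at0, rod)
  at1 <- surfaceTable(cfg, rep(1, 5))
  pick <- function(tb, ly, cl, f) tb[[f]][tb$layer == ly & tb$cell_class == cl]
  expect_equal(pick(at1, "L5", "PC", "C"), pick(hum, "L5", "PC", "C"))
  expect_equal(pick(at1, "L6", "PC", "C"), pick(hum, "L6", "PC", "C"))
  for (ly in c("L2/3", "L5", "L6")) {
    expect_equal(pick(at1, ly, "LL-IN", "V_th"),
                 pick(hum, ly, "LL-IN", "V_th"))
  }
  # untouched fields stay rodent
  expect_equal(pick(at1, "L2/3", "PC", "C"), pick(rod, "L2/3", "PC", "C"))
  expect_equal(pick(at1, "L5", "PC", "V_th"), pick(rod, "L5", "PC", "V_th"))
  mid <- surfaceTable(cfg, c(0.5, 0, 0, 0, 0))
  expect_equal(pick(mid, "L5", "PC", "C"),
               (pick(rod, "L5", "PC", "C") + pick(hum, "L5", "PC", "C")) / 2)
  # LBC rows track the morphed PC rows of their layer
  expect_equal(pick(at1, "L5", "LBC", "C"), pick(at1, "L5", "PC", "C"))
})

test_that("scaling a potential by 25 percent moves it relative to the leak
           reversal", {
  cfg <- defaultColumnConfig()
  hum <- speciesTable(cfg, "human")
  up <- scaleParameter(hum, "V_th", 1.25)
  i <- which(hum$layer == "L2/3" & hum$cell_class == "PC")
  expect_equal(up$V_th[i], hum$E_L[i] + 1.25 * (hum$V_th[i] - hum$E_L[i]))
  expect_gt(up$V_th[i], hum$V_th[i]) # depolarizing shift
})
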