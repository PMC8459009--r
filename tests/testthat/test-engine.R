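# Network engine: quiescence, delayed transmission, determinism,
# separability, event accounting, and agreement with the pure-R reference
# simulator on small random networks.

test_that("a network without synapses and below rheobase stays silent", {
  # rheobase g_L (V_th - E_L) = 200 pA > 150 pA background
  net <- handNet(genericParams(5), excitatory = rep(TRUE, 5), I_bg = 150)
  ras <- runSimulation(net, simulationProtocol(300))
  expect_equal(nrow(spikeEvents(ras)), 0)
  expect_s4_class(ras, "SpikeRaster")
})

test_that("in a two-neuron chain the postsynaptic conductance engages one
           transmission delay after the presynaptic spike", {
  p <- genericParams(2)
  # neuron 1 driven, neuron 2 passive (high threshold, no drive)
  p$V_th[2] <- -20
  net <- handNet(p, excitatory = c(TRUE, TRUE), pre = 1L, post = 2L,
                 I_bg = c(400, 0),
                 synapses = defaultSynapses(gA = 5, gN = 0, gG = 0))
  ras <- runSimulation(net, simulationProtocol(100, record_traces = 2L))
  ev <- spikeEvents(ras)
  t1 <- min(ev$time[ev$neuron_id == 1])
  # reference: isolated neuron 2 (no input) holds V = E_L exactly
  tr <- voltageTraces(ras)
  dev <- abs(tr$n2 - p$E_L[2])
  tFirstDev <- tr$time[min(which(dev > 1e-9))]
  tauD <- 1 # AMPA delay in defaultSynapses()
  # V first moves one step after the kernel turns on at t1 + tau_D
  expect_gte(tFirstDev, t1 + tauD)
  expect_lte(tFirstDev, t1 + tauD + 1.1) # trace resolution is 1 ms
})

test_that("identical seeds reproduce byte-identical rasters on the default
           column", {
  cfg <- defaultColumnConfig()
  run <- function() {
    net <- assignParameters(buildColumn(cfg, 3), speciesTable(cfg, "rodent"),
                            cfg$background_currents)
    runSimulation(net, simulationProtocol(150))
  }
  expect_identical(spikeEvents(run()), spikeEvents(run()))
})

test_that("with all conductances zero the network raster equals the union of
           independent single-neuron simulations", {
  set.seed(21)
  n <- 6
  p <- genericParams(n, C = runif(n, 120, 280), V_th = runif(n, -52, -45),
                     b = runif(n, 20, 90))
  Ibg <- runif(n, 250, 420)
  net <- handNet(p, excitatory = rep(c(TRUE, FALSE), 3),
                 pre = rep(1:n, each = n - 1),
                 post = unlist(lapply(1:n, function(i) setdiff(1:n, i))),
                 I_bg = Ibg, synapses = defaultSynapses(0, 0, 0))
  ras <- runSimulation(net, simulationProtocol(200))
  ev <- spikeEvents(ras)
  for (i in 1:n) {
    prm <- aeifParams(p$C[i], p$g_L[i], p$E_L[i], p$V_r[i], p$V_th[i],
                      p$Delta_T[i], p$tau_w[i], p$a[i], p$b[i])
    solo <- aeifSimulate(prm, Ibg[i], 200, dt = 0.05)$spike_times
    expect_equal(ev$time[ev$neuron_id == i], solo, tolerance = 1e-12)
  }
})

test_that("every presynaptic spike is delivered once per outgoing synapse", {
  cfg <- tinyConfig(nPC = 40, nIN = 10)
  net <- assignParameters(buildColumn(cfg, 9), tinyTable(),
                          cfg$background_currents)
  ras <- runSimulation(net, simulationProtocol(300))
  ev <- spikeEvents(ras)
  outDeg <- table(factor(net@pre, levels = 1:nNeurons(net)))
  # spikes within the last max-delay window have pending undelivered events
  maxDelay <- 1
  inWindow <- ev$time < 300 - maxDelay - 0.1
  expected <- sum(outDeg[ev$neuron_id[inWindow]])
  slack <- sum(outDeg[ev$neuron_id[!inWindow]])
  expect_gte(ras@delivered, expected)
  expect_lte(ras@delivered, expected + slack)
})

test_that("the compiled engine reproduces the pure-R direct-sum reference on
           small random networks", {
  set.seed(5)
  for (rep in 1:3) {
    n <- 5
    exc <- runif(n) < 0.6
    p <- genericParams(n, V_th = runif(n, -52, -46), b = runif(n, 20, 60))
    nSyn <- 8
    pre <- sample(1:n, nSyn, replace = TRUE)
    post <- vapply(pre, function(i) sample(setdiff(1:n, i), 1), numeric(1))
    net <- handNet(p, exc, pre, as.integer(post),
                   I_bg = runif(n, 180, 320),
                   synapses = defaultSynapses(gA = 2, gN = 3, gG = 4))
    proto <- simulationProtocol(150)
    fast <- spikeEvents(runSimulation(net, proto))
    slow <- spikeEvents(CortexColumn:::.referenceSimulate(net, proto))
    expect_equal(fast, slow, tolerance = 1e-9)
  }
})

test_that("halving dt changes the default-column spike count by less
           than 5 percent", {
  cfg <- defaultColumnConfig()
  net <- assignParameters(buildColumn(cfg, 7), speciesTable(cfg, "rodent"),
                          cfg$background_currents)
  n1 <- nrow(spikeEvents(runSimulation(net, simulationProtocol(300, dt = 0.05))))
  n2 <- nrow(spikeEvents(runSimulation(net, simulationProtocol(300, dt = 0.025))))
  expect_gt(n1, 1000) # tonically active baseline
  expect_lt(abs(n2 - n1) / n1, 0.05)
})

test_that("raster and trace writers produce well-formed CSV and the manifest
           records the configuration hash", {
  net <- handNet(genericParams(2), c(TRUE, TRUE), I_bg = c(400, 300))
  ras <- runSimulation(net, simulationProtocol(100, record_traces = 1:2))
  d <- withr::local_tempdir()
  writeRaster(ras, file.path(d, "raster.csv"))
  back <- read.csv(file.path(d, "raster.csv"))
  expect_named(back, c("neuron_id", "spike_time_ms"))
  expect_equal(nrow(back), nrow(spikeEvents(ras)))
  writeTraces(ras, file.path(d, "traces.csv"))
  tr <- read.csv(file.path(d, "traces.csv"))
  expect_equal(nrow(tr), 101) # 1 ms resolution including t = 0
  cfg <- tinyConfig()
  writeRunManifest(file.path(d, "manifest.json"), cfg, seeds = c(1, 2),
                   durations = list(run = 100))
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(man$config_hash, configHash(cfg))
})
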