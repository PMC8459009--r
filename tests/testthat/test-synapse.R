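# Conductance kernels, NMDA gate, short-term plasticity recursion and its
# limits, and the equivalence of the two conductance bookkeeping schemes.

test_that("NMDA gate follows the magnesium-block sigmoid; other receptors
           are ungated", {
  expect_equal(nmdaGate(-65.3, "AMPA"), 1)
  expect_equal(nmdaGate(12.7, "GABAA"), 1)
  expect_equal(nmdaGate(0, "NMDA"), 1.08 / 1.19, tolerance = 1e-12)
  expect_lt(nmdaGate(-200, "NMDA"), 1e-4) # gate closes when hyperpolarized
  V <- seq(-90, 20, by = 0.5)
  expect_equal(nmdaGate(V, "NMDA"),
               1.08 / (1 + 0.19 * exp(-0.064 * V)), tolerance = 1e-14)
  expect_true(all(diff(nmdaGate(V, "NMDA")) > 0)) # monotone opening
})

test_that("first spike initializes utilization and resources at (U, 1 - U)", {
  res <- stpOnSpike(stpInit(), 5, stpParams(U = 0.25))
  expect_equal(res$state$u, 0.25)
  expect_equal(res$state$R, 0.75)
  expect_equal(res$a, 0.1875)
})

test_that("the recursion matches a hand evaluation on random trains", {
  prm <- stpParams(U = 0.25, tau_facil = 500, tau_rec = 300)
  set.seed(3)
  for (rep in 1:10) {
    times <- cumsum(runif(25, 2, 120))
    hand <- stpHandSequence(times, prm$U, prm$tau_facil, prm$tau_rec)
    st <- stpInit()
    for (i in seq_along(times)) {
      res <- stpOnSpike(st, times[i], prm)
      st <- res$state
      expect_equal(st$u, hand$u[i], tolerance = 1e-12)
      expect_equal(st$R, hand$R[i], tolerance = 1e-12)
      expect_equal(res$a, hand$a[i], tolerance = 1e-12)
    }
  }
})

test_that("second spike after 500 ms reproduces the explicit recursion value", {
  prm <- stpParams(U = 0.25, tau_facil = 500, tau_rec = 300)
  s1 <- stpOnSpike(stpInit(), 0, prm)
  s2 <- stpOnSpike(s1$state, 500, prm)
  u2 <- 0.25 * exp(-1) + 0.25 * (1 - 0.25 * exp(-1))
  expect_equal(s2$state$u, u2, tolerance = 1e-12)
  R2 <- 0.75 * (1 - u2) * exp(-500 / 300) + 1 - exp(-500 / 300)
  expect_equal(s2$state$R, R2, tolerance = 1e-12)
})

test_that("out-of-order presynaptic spikes are rejected", {
  prm <- stpParams()
  st <- stpOnSpike(stpInit(), 10, prm)$state
  expect_error(stpOnSpike(st, 5, prm), "order")
})

test_that("limits: long intervals recover (u, R) -> (U, 1); fast facilitation
           decay reduces to pure depression; fast recovery cancels depression", {
  prm <- stpParams(U = 0.25, tau_facil = 500, tau_rec = 300)
  st <- stpOnSpike(stpInit(), 0, prm)$state
  res <- stpOnSpike(st, 1e6, prm)
  expect_equal(res$state$u, prm$U, tolerance = 1e-9)
  expect_equal(res$state$R, 1, tolerance = 1e-9)
  expect_equal(res$a, prm$U, tolerance = 1e-8)
  # tau_facil -> 0: u stays at U on every spike
  fast <- stpParams(U = 0.25, tau_facil = 1e-9, tau_rec = 300)
  st <- stpInit()
  for (t in seq(0, 100, by = 10)) {
    r <- stpOnSpike(st, t, fast)
    st <- r$state
    expect_equal(st$u, 0.25, tolerance = 1e-9)
  }
  # tau_rec -> 0: resources recover fully between spikes
  rec <- stpParams(U = 0.25, tau_facil = 500, tau_rec = 1e-9)
  st <- stpOnSpike(stpInit(), 0, rec)$state
  r <- stpOnSpike(st, 10, rec)
  expect_equal(r$state$R, 1, tolerance = 1e-9)
})

test_that("efficiency stays in (0, 1) and a periodic train converges
           geometrically to the algebraic fixed point", {
  prm <- stpParams(U = 0.25, tau_facil = 500, tau_rec = 300)
  set.seed(11)
  for (rep in 1:5) {
    times <- cumsum(runif(60, 1, 80))
    st <- stpInit()
    for (t in times) {
      r <- stpOnSpike(st, t, prm)
      st <- r$state
      expect_gt(r$a, 0)
      expect_lt(r$a, 1)
    }
  }
  isi <- 20
  fp <- stpFixedPoint(isi, prm)
  st <- stpInit()
  gaps <- numeric(60)
  for (i in 1:60) {
    r <- stpOnSpike(st, i * isi, prm)
    st <- r$state
    gaps[i] <- abs(r$a - fp$a)
  }
  expect_lt(gaps[60], 1e-11)
  # geometric contraction: an order of magnitude every 20 spikes
  expect_lt(gaps[40], 0.1 * gaps[20])
  expect_lt(gaps[60], 0.1 * gaps[40])
})

test_that("synaptic current: empty sum is zero, the kernel vanishes at the
           delivery instant, and a single event matches the closed form", {
  prm <- synapseParams("AMPA", g_max = 2, E_rev = 0, tau_on = 0.5,
                       tau_off = 2.5, tau_D = 1)
  none <- list(time = numeric(0), a = numeric(0))
  expect_identical(synapticCurrent(none, prm, V = -60, t = 50), 0)
  one <- list(time = 10, a = 1)
  expect_equal(synapticCurrent(one, prm, V = -60, t = 11), 0)
  tGrid <- seq(11, 30, by = 0.05)
  got <- vapply(tGrid, function(t) synapticCurrent(one, prm, -60, t),
                numeric(1))
  el <- tGrid - 10 - 1
  want <- 2 * 1 * (exp(-el / 2.5) - exp(-el / 0.5)) * (-60 - 0)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("GABA-A current is hyperpolarizing above its reversal and AMPA
           depolarizing below its reversal under the sign convention", {
  ev <- list(time = 0, a = 1)
  gaba <- synapseParams("GABAA", 1, -75, 0.5, 6, tau_D = 0)
  ampa <- synapseParams("AMPA", 1, 0, 0.5, 2.5, tau_D = 0)
  # returned current is subtracted from the drive
  expect_gt(synapticCurrent(ev, gaba, V = -60, t = 3), 0)
  expect_lt(synapticCurrent(ev, ampa, V = -60, t = 1), 0)
})

test_that("kernel peak occurs at the closed-form time", {
  prm <- synapseParams("AMPA", 1, 0, tau_on = 0.7, tau_off = 4, tau_D = 2)
  ev <- list(time = 0, a = 1)
  tGrid <- seq(2, 20, by = 1e-3)
  kern <- conductanceSeries(ev, prm, tGrid, method = "direct")
  expect_equal(tGrid[which.max(kern)], kernelPeakTime(prm), tolerance = 2e-3)
})

test_that("auxiliary-decay bookkeeping equals the direct kernel sum on
           random event trains", {
  set.seed(7)
  for (rep in 1:10) {
    prm <- synapseParams("AMPA", 1, 0, tau_on = runif(1, 0.3, 3),
                         tau_off = runif(1, 4, 120),
                         tau_D = sample(c(0, 0.5, 1), 1))
    dt <- 0.05
    times <- seq(0, 150, by = dt)
    nEv <- sample(3:25, 1)
    ev <- list(time = sort(sample(seq(0, 100, by = dt), nEv)),
               a = runif(nEv, 0.05, 1))
    direct <- conductanceSeries(ev, prm, times, method = "direct")
    recursive <- conductanceSeries(ev, prm, times, method = "recursive")
    expect_equal(recursive, direct, tolerance = 1e-9)
  }
})
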