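# Shared fixtures: tiny parameter tables, miniature configurations and
# hand-built networks, plus the high-order reference integrator used as the
# single-neuron oracle.

# one generic cell class replicated over all layers/classes
tinyTable <- function(C = 200, g_L = 10, E_L = -70, V_r = -60, V_th = -50,
                      Delta_T = 2, tau_w = 100, a = 2, b = 50) {
  completeAeifTable(do.call(rbind, lapply(c("L2/3", "L5", "L6"), function(ly) {
    do.call(rbind, lapply(c("PC", "LL-IN"), function(cl) {
      data.frame(layer = ly, cell_class = cl, C = C, g_L = g_L, E_L = E_L,
                 V_r = V_r, V_th = V_th, Delta_T = Delta_T, tau_w = tau_w,
                 a = a, b = b)
    }))
  })))
}

defaultSynapses <- function(gA = 0.5, gN = 1, gG = 2) {
  list(AMPA = synapseParams("AMPA", gA, 0, 0.5, 2.5, tau_D = 1),
       NMDA = synapseParams("NMDA", gN, 0, 2, 100, tau_D = 1),
       GABAA = synapseParams("GABAA", gG, -75, 0.5, 6, tau_D = 0.5))
}

# a minimal validated configuration with given counts in L2/3 only
tinyConfig <- function(nPC = 30, nIN = 10, pEE = 0.2, pEI = 0.2, pIE = 0.3,
                       table = tinyTable()) {
  counts <- matrix(0L, 3, 5, dimnames = list(c("L2/3", "L5", "L6"),
                                             c("PC", "LL-IN", "BPC", "LBC",
                                               "MC")))
  counts["L2/3", "PC"] <- as.integer(nPC)
  counts["L2/3", "LL-IN"] <- as.integer(nIN)
  pops <- as.vector(t(outer(rownames(counts), colnames(counts), paste)))
  P <- matrix(0, 15, 15, dimnames = list(pops, pops))
  P["L2/3 PC", "L2/3 PC"] <- pEE
  P["L2/3 PC", "L2/3 LL-IN"] <- pEI
  P["L2/3 LL-IN", "L2/3 PC"] <- pIE
  list(architecture = counts, allow_autapses = FALSE,
       background_currents = list(excitatory = 250, interneuron = 200),
       aeif_tables = list(test = table), synapses = defaultSynapses(),
       stp = stpParams(), connectivity = P,
       stimulus = list(onset = 200, stim_duration = 100, mode = "poisson50",
                       pulse_amplitude = 4000, poisson_rate = 50,
                       pulse_width = 1),
       simulation = list(duration = 300, dt = 0.05,
                         canonical_exp_term = FALSE, exp_clamp = 10))
}

# hand-built network from explicit neuron parameters and edge list
handNet <- function(params, excitatory, pre = integer(0), post = integer(0),
                    I_bg = 0, synapses = defaultSynapses(),
                    stp = stpParams()) {
  n <- length(excitatory)
  neu <- data.frame(id = seq_len(n), layer = "L2/3",
                    cell_class = ifelse(excitatory, "PC", "LL-IN"),
                    population = ifelse(excitatory, "L2/3 PC", "L2/3 LL-IN"),
                    excitatory = excitatory)
  for (f in names(params)) neu[[f]] <- params[[f]]
  neu$I_bg <- rep(I_bg, length.out = n)
  new("ColumnNetwork", neurons = neu, pre = as.integer(pre),
      post = as.integer(post), synapses = synapses, stp = unclass(stp),
      connectivity = matrix(0, 0, 0), seed = 0L)
}

genericParams <- function(n, C = 200, g_L = 10, E_L = -70, V_r = -60,
                          V_th = -50, Delta_T = 2, tau_w = 100, a = 2,
                          b = 50) {
  lapply(list(C = C, g_L = g_L, E_L = E_L, V_r = V_r, V_th = V_th,
              Delta_T = Delta_T, tau_w = tau_w, a = a, b = b),
         rep, length.out = n)
}

# adaptive high-order integration of the two aEIF equations with exact event
# location at the threshold crossing (deSolve root finding); independent of
# the package's Euler path
aeifReferenceSpikes <- function(p, I, duration, V0 = p$E_L, w0 = 0,
                                maxSpikes = 200) {
  rhs <- function(t, y, parms) {
    d <- aeifDrift(y[1], y[2], I, p)
    list(c(d$dV, d$dw))
  }
  root <- function(t, y, parms) y[1] - p$V_th
  spikes <- numeric(0)
  t0 <- 0
  y <- c(V = V0, w = w0)
  for (it in seq_len(maxSpikes)) {
    out <- deSolve::lsoda(y, seq(t0, duration, by = 0.1), rhs, NULL,
                          rootfunc = root, rtol = 1e-10, atol = 1e-10)
    tr <- attributes(out)$troot
    if (is.null(tr) || length(tr) == 0L) break
    spikes <- c(spikes, tr[1L])
    y <- c(V = p$V_r, w = out[nrow(out), 3L] + p$b)
    t0 <- tr[1L]
    if (t0 >= duration) break
  }
  spikes
}

# step-by-step evaluation of the facilitation/depression recursion,
# independent of stpOnSpike
stpHandSequence <- function(times, U, tau_facil, tau_rec) {
  u <- R <- a <- numeric(length(times))
  for (i in seq_along(times)) {
    if (i == 1L) {
      u[i] <- U
      R[i] <- 1 - U
    } else {
      dt <- times[i] - times[i - 1L]
      uDec <- u[i - 1L] * exp(-dt / tau_facil)
      u[i] <- uDec + U * (1 - uDec)
      R[i] <- R[i - 1L] * (1 - u[i]) * exp(-dt / tau_rec) +
        1 - exp(-dt / tau_rec)
    }
    a[i] <- u[i] * R[i]
  }
  list(u = u, R = R, a = a)
}
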