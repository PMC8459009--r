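# Pure-R reference simulator for small networks. Uses direct per-event
# double-exponential sums (no auxiliary-decay bookkeeping) and the same
# update order as the compiled engine; quadratic in events, so only suitable
# for a handful of neurons. Internal: this is the oracle the engine is
# tested against, not a user-facing code path.

.referenceSimulate <- function(network, protocol) {
  neu <- network@neurons
  n <- nrow(neu)
  syn <- network@synapses
  stp <- network@stp
  dt <- protocol$dt
  nSteps <- as.integer(round(protocol$duration / dt))
  segs <- if (is.null(protocol$stimulus)) {
    data.frame(neuron = integer(0), step_on = integer(0),
               step_off = integer(0), amp = numeric(0))
  } else {
    makeStimulus(protocol$stimulus, dt)
  }
  drive <- .stimulusDrive(segs, nSteps, n)

  out <- lapply(seq_len(n), function(i) network@post[network@pre == i])
  delayStepsExc <- max(1L, as.integer(round(syn$AMPA$tau_D / dt)))
  delayStepsInh <- max(1L, as.integer(round(syn$GABAA$tau_D / dt)))

  # delivered events per neuron per receptor: delivery time and efficiency
  ev <- replicate(n, list(
    AMPA = list(time = numeric(0), a = numeric(0)),
    NMDA = list(time = numeric(0), a = numeric(0)),
    GABAA = list(time = numeric(0), a = numeric(0))), simplify = FALSE)
  # pending deliveries keyed by step
  pending <- vector("list", nSteps + max(delayStepsExc, delayStepsInh) + 1L)
  stpState <- replicate(n, stpInit(), simplify = FALSE)

  V <- neu$E_L
  w <- rep(0, n)
  paramsList <- lapply(seq_len(n), function(i) {
    do.call(aeifParams, as.list(neu[i, .AEIF_FIELDS]))
  })
  spikes <- list()
  kernAt <- function(events, params, t) {
    if (!length(events$time)) return(0)
    el <- t - events$time
    sum(events$a * (exp(-el / params$tau_off) - exp(-el / params$tau_on)))
  }
  for (k in seq_len(nSteps)) {
    tNow <- (k - 1) * dt
    for (d in pending[[k]]) {
      rcs <- if (d$exc) c("AMPA", "NMDA") else "GABAA"
      for (tg in out[[d$src]]) {
        for (rc in rcs) {
          ev[[tg]][[rc]]$time <- c(ev[[tg]][[rc]]$time, tNow)
          ev[[tg]][[rc]]$a <- c(ev[[tg]][[rc]]$a, d$a)
        }
      }
    }
    for (i in seq_len(n)) {
      Isyn <- 0
      for (rc in c("AMPA", "NMDA", "GABAA")) {
        pm <- syn[[rc]]
        kern <- kernAt(ev[[i]][[rc]], pm, tNow)
        Isyn <- Isyn + pm$g_max * nmdaGate(V[i], rc) * kern *
          (V[i] - pm$E_rev)
      }
      p <- paramsList[[i]]
      st <- aeifStep(list(V = V[i], w = w[i], last_spike_time = NA_real_), p,
                     neu$I_bg[i] + drive[k, i] - Isyn, dt, tNow,
                     canonicalExp = isTRUE(protocol$canonical_exp_term),
                     expClamp = protocol$exp_clamp, id = i)
      V[i] <- st$state$V
      w[i] <- st$state$w
      if (st$spiked) {
        tSp <- k * dt
        spikes[[length(spikes) + 1L]] <- data.frame(neuron_id = i,
                                                    time = tSp)
        up <- stpOnSpike(stpState[[i]], tSp, stp)
        stpState[[i]] <- up$state
        dl <- if (neu$excitatory[i]) delayStepsExc else delayStepsInh
        slot <- k + 1L + dl
        pending[[slot]] <- c(pending[[slot]],
                             list(list(src = i, a = up$a,
                                       exc = neu$excitatory[i])))
      }
    }
  }
  evd <- if (length(spikes)) do.call(rbind, spikes) else
    data.frame(neuron_id = integer(0), time = numeric(0))
  evd <- evd[order(evd$time, evd$neuron_id), , drop = FALSE]
  rownames(evd) <- NULL
  new("SpikeRaster", events = evd, t_end = protocol$duration, dt = dt,
      traces = data.frame(), delivered = 0)
}
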