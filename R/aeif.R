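#' aEIF membrane parameter set
#'
#' Bundles the nine membrane parameters of one cell class of the adaptive
#' exponential integrate-and-fire (aEIF) model. Units are fixed package-wide:
#' pF (capacitance), nS (conductances), mV (potentials), ms (times),
#' pA (currents); these are self-consistent (pA/pF = mV/ms).
#'
#' @param C membrane capacitance, pF.
#' @param g_L leak conductance, nS.
#' @param E_L leak reversal potential, mV.
#' @param V_r reset potential, mV.
#' @param V_th spike threshold, mV.
#' @param Delta_T slope factor of the exponential spike-initiation term, mV.
#' @param tau_w adaptation time constant, ms.
#' @param a subthreshold adaptation conductance, nS.
#' @param b spike-triggered adaptation increment, pA.
#' @return A named list of class `"aeifParams"`.
#' @examples
#' p <- aeifParams(C = 170, g_L = 10, E_L = -70, V_r = -60, V_th = -50,
#'                 Delta_T = 2, tau_w = 150, a = 2, b = 50)
#' @export
aeifParams <- function(C, g_L, E_L, V_r, V_th, Delta_T, tau_w, a, b) {
  p <- list(C = C, g_L = g_L, E_L = E_L, V_r = V_r, V_th = V_th,
            Delta_T = Delta_T, tau_w = tau_w, a = a, b = b)
  p <- lapply(p, as.numeric)
  stopifnot(
    "C must be > 0" = p$C > 0,
    "g_L must be > 0" = p$g_L > 0,
    "tau_w must be > 0" = p$tau_w > 0,
    "Delta_T must be > 0" = p$Delta_T > 0,
    "V_r must not exceed V_th" = p$V_r <= p$V_th,
    "all parameters must be finite" = all(vapply(p, is.finite, logical(1)))
  )
  structure(p, class = "aeifParams")
}

#' @export
print.aeifParams <- function(x, ...) {
  cat("aEIF parameters: C=", x$C, " pF, g_L=", x$g_L, " nS, E_L=", x$E_L,
      " mV, V_r=", x$V_r, " mV, V_th=", x$V_th, " mV,\n  Delta_T=", x$Delta_T,
      " mV, tau_w=", x$tau_w, " ms, a=", x$a, " nS, b=", x$b, " pA\n",
      sep = "")
  invisible(x)
}

#' Membrane-equation drift of the aEIF model
#'
#' Right-hand sides of the coupled voltage/adaptation equations,
#' \deqn{C\,dV/dt = -g_L (V - E_L) + g_L \exp((V - V_{th})/\Delta_T) + I - w}
#' \deqn{\tau_w\,dw/dt = a (V - E_L) - w.}
#' The exponential term carries a bare `g_L` prefactor (the form used
#' throughout this package); `canonicalExp = TRUE` switches to the canonical
#' aEIF prefactor `g_L * Delta_T` for sensitivity checks. The exponent is
#' clamped at `expClamp` to avoid overflow in the same step the reset fires.
#'
#' @param V membrane potential, mV.
#' @param w adaptation current, pA.
#' @param I_total total injected current (background + synaptic + stimulus), pA.
#' @param params an [aeifParams()] object.
#' @param canonicalExp use the canonical `g_L * Delta_T` prefactor.
#' @param expClamp upper clamp on the exponent `(V - V_th)/Delta_T`.
#' @return list with `dV` (mV/ms) and `dw` (pA/ms).
#' @export
aeifDrift <- function(V, w, I_total, params, canonicalExp = FALSE,
                      expClamp = 10) {
  pref <- if (canonicalExp) params$g_L * params$Delta_T else params$g_L
  arg <- pmin((V - params$V_th) / params$Delta_T, expClamp)
  dV <- (-params$g_L * (V - params$E_L) + pref * exp(arg) + I_total - w) /
    params$C
  dw <- (params$a * (V - params$E_L) - w) / params$tau_w
  list(dV = dV, dw = dw)
}

#' One forward-Euler step of the aEIF model
#'
#' Advances the state `(V, w)` by one explicit Euler step of length `dt` and
#' applies the threshold/reset rule: if the stepped voltage exceeds `V_th`, a
#' spike is recorded at `t + dt`, the voltage is set to `V_r` and the
#' adaptation current is incremented by `b`.
#'
#' @param state list with numeric `V` (mV), `w` (pA), and optionally
#'   `last_spike_time` (ms or `NA`).
#' @param params an [aeifParams()] object.
#' @param I_total total injected current at time `t`, pA.
#' @param dt step size, ms (> 0).
#' @param t current time, ms.
#' @inheritParams aeifDrift
#' @param id neuron identifier used in error messages.
#' @return list with `state` (updated) and `spiked` (logical).
#' @examples
#' p <- aeifParams(170, 10, -70, -60, -50, 2, 150, 2, 50)
#' s <- list(V = -70, w = 0, last_spike_time = NA_real_)
#' aeifStep(s, p, I_total = 400, dt = 0.05, t = 0)
#' @export
aeifStep <- function(state, params, I_total, dt, t,
                     canonicalExp = FALSE, expClamp = 10, id = NA) {
  stopifnot(dt > 0)
  d <- aeifDrift(state$V, state$w, I_total, params, canonicalExp, expClamp)
  V <- state$V + dt * d$dV
  w <- state$w + dt * d$dw
  if (!is.finite(V) || !is.finite(w)) {
    stop(sprintf(
      "aEIF state became non-finite for neuron %s at t = %.4f ms (V=%g, w=%g)",
      as.character(id), t + dt, V, w))
  }
  spiked <- V > params$V_th
  if (spiked) {
    V <- params$V_r
    w <- w + params$b
    state$last_spike_time <- t + dt
  }
  state$V <- V
  state$w <- w
  list(state = state, spiked = spiked)
}

#' Simulate one isolated aEIF neuron
#'
#' Euler integration of a single neuron under a time-varying injected current,
#' starting from the standard initial conditions `V(0) = E_L`, `w(0) = 0`
#' (overridable). Mainly used for protocol design and as a building block of
#' test oracles; the network engine has its own compiled loop.
#'
#' @param params an [aeifParams()] object.
#' @param I either a single current (pA) or a function of time `I(t)` (ms).
#' @param duration total simulated time, ms.
#' @param dt step size, ms.
#' @param V0,w0 initial conditions; default `E_L` and 0.
#' @inheritParams aeifDrift
#' @return list with `spike_times` (ms), `time`, `V`, `w` vectors sampled at
#'   every step (time 0 included).
#' @export
aeifSimulate <- function(params, I, duration, dt = 0.05,
                         V0 = params$E_L, w0 = 0,
                         canonicalExp = FALSE, expClamp = 10) {
  nSteps <- round(duration / dt)
  Ifun <- if (is.function(I)) I else function(t) I
  V <- numeric(nSteps + 1L)
  w <- numeric(nSteps + 1L)
  V[1L] <- V0
  w[1L] <- w0
  state <- list(V = V0, w = w0, last_spike_time = NA_real_)
  spikes <- numeric(0)
  for (k in seq_len(nSteps)) {
    t <- (k - 1L) * dt
    res <- aeifStep(state, params, Ifun(t), dt, t, canonicalExp, expClamp)
    state <- res$state
    if (res$spiked) spikes <- c(spikes, k * dt)
    V[k + 1L] <- state$V
    w[k + 1L] <- state$w
  }
  list(spike_times = spikes, time = seq(0, by = dt, length.out = nSteps + 1L),
       V = V, w = w)
}
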