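#' Synaptic receptor parameter set
#'
#' Constants of one conductance-based receptor channel: a double-exponential
#' kernel with onset/offset time constants, a reversal potential, a peak
#' conductance and a fixed transmission delay.
#'
#' @param receptor one of `"AMPA"`, `"GABAA"`, `"NMDA"`.
#' @param g_max peak conductance, nS (>= 0).
#' @param E_rev reversal potential, mV.
#' @param tau_on,tau_off onset and offset time constants, ms
#'   (`tau_off > tau_on > 0`).
#' @param tau_D transmission delay between presynaptic spike and conductance
#'   onset, ms (>= 0).
#' @return A named list of class `"synapseParams"`.
#' @export
synapseParams <- function(receptor = c("AMPA", "GABAA", "NMDA"),
                          g_max, E_rev, tau_on, tau_off, tau_D = 0) {
  receptor <- match.arg(receptor)
  stopifnot(
    "tau_off must exceed tau_on" = tau_off > tau_on,
    "tau_on must be > 0" = tau_on > 0,
    "tau_D must be >= 0" = tau_D >= 0,
    "g_max must be >= 0" = g_max >= 0
  )
  structure(list(receptor = receptor, g_max = as.numeric(g_max),
                 E_rev = as.numeric(E_rev), tau_on = as.numeric(tau_on),
                 tau_off = as.numeric(tau_off), tau_D = as.numeric(tau_D)),
            class = "synapseParams")
}

# NMDA magnesium-block constants; frozen, not configurable.
.NMDA_SCALE <- 1.08
.NMDA_COEF <- 0.19
.NMDA_SLOPE <- 0.064 # per mV

#' Voltage gate of the NMDA receptor
#'
#' The sigmoidal voltage dependence of the NMDA conductance (magnesium-block
#' phenomenology): `s(V) = 1.08 / (1 + 0.19 exp(-0.064 V))` for NMDA and
#' exactly 1 for AMPA and GABA-A.
#'
#' @param V membrane potential, mV (vectorized).
#' @param receptor receptor kind.
#' @return gate value(s), dimensionless.
#' @examples
#' nmdaGate(0, "NMDA")    # 1.08/1.19
#' nmdaGate(-65, "AMPA")  # 1
#' @export
nmdaGate <- function(V, receptor = c("AMPA", "GABAA", "NMDA")) {
  receptor <- match.arg(receptor)
  stopifnot(all(is.finite(V)))
  if (receptor != "NMDA") return(rep(1, length(V)))
  .NMDA_SCALE / (1 + .NMDA_COEF * exp(-.NMDA_SLOPE * V))
}

#' Tsodyks-Markram short-term plasticity parameters
#'
#' @param U baseline utilization of synaptic efficacy, in (0, 1).
#' @param tau_facil facilitation time constant, ms.
#' @param tau_rec recovery-from-depression time constant, ms.
#' @return A named list of class `"stpParams"`.
#' @export
stpParams <- function(U = 0.25, tau_facil = 500, tau_rec = 300) {
  stopifnot(U > 0, U < 1, tau_facil > 0, tau_rec > 0)
  structure(list(U = as.numeric(U), tau_facil = as.numeric(tau_facil),
                 tau_rec = as.numeric(tau_rec)), class = "stpParams")
}

#' Fresh short-term plasticity state
#'
#' State of one connection before any presynaptic spike has occurred.
#' @return list with `u`, `R`, `t_last` (all unset/NA).
#' @export
stpInit <- function() list(u = NA_real_, R = NA_real_, t_last = NA_real_)

#' Advance short-term plasticity state by one presynaptic spike
#'
#' First spike of a train initializes `u = U`, `R = 1 - U`; each later spike
#' at interval `dt = t_spike - t_last` applies the Tsodyks-Markram recursion
#' \deqn{u_{n+1} = u_n e^{-\Delta t/\tau_{facil}} +
#'       U (1 - u_n e^{-\Delta t/\tau_{facil}})}
#' \deqn{R_{n+1} = R_n (1 - u_{n+1}) e^{-\Delta t/\tau_{rec}} +
#'       1 - e^{-\Delta t/\tau_{rec}}}
#' (u updated first; R uses the updated u). The relative efficiency applied to
#' the spike is `a = u * R` with the post-update values.
#'
#' @param state an STP state as returned by [stpInit()] or a previous call.
#' @param t_spike presynaptic spike time, ms (must not precede `t_last`).
#' @param params an [stpParams()] object.
#' @return list with `state` (updated) and `a` (relative efficiency, in (0,1)).
#' @examples
#' st <- stpOnSpike(stpInit(), 0, stpParams())   # u=0.25, R=0.75, a=0.1875
#' @export
stpOnSpike <- function(state, t_spike, params) {
  if (!is.na(state$t_last) && t_spike < state$t_last) {
    stop(sprintf("presynaptic spikes out of order: %g ms before t_last = %g ms",
                 t_spike, state$t_last))
  }
  if (is.na(state$t_last)) {
    u <- params$U
    R <- 1 - params$U
  } else {
    dt <- t_spike - state$t_last
    ef <- exp(-dt / params$tau_facil)
    er <- exp(-dt / params$tau_rec)
    u <- state$u * ef + params$U * (1 - state$u * ef)
    R <- state$R * (1 - u) * er + 1 - er
  }
  list(state = list(u = u, R = R, t_last = t_spike), a = u * R)
}

#' Fixed point of the STP recursion under periodic spiking
#'
#' Closed-form steady state of the utilization/resource recursion for a
#' periodic presynaptic train with inter-spike interval `isi`.
#'
#' @param isi inter-spike interval, ms.
#' @param params an [stpParams()] object.
#' @return list with `u`, `R`, `a = u * R`.
#' @export
stpFixedPoint <- function(isi, params) {
  ef <- exp(-isi / params$tau_facil)
  er <- exp(-isi / params$tau_rec)
  u <- params$U / (1 - ef * (1 - params$U))
  R <- (1 - er) / (1 - (1 - u) * er)
  list(u = u, R = R, a = u * R)
}

#' Synaptic current from a set of delivered spike events
#'
#' Direct evaluation of the conductance-based current
#' \deqn{I_X = g_X^{max}\, s(V) \sum_{t_{sp}} a(t_{sp})
#'   \left(e^{-(t - t_{sp} - \tau_D)/\tau_{off}} -
#'         e^{-(t - t_{sp} - \tau_D)/\tau_{on}}\right) (V - E_{rev}^X).}
#' Events whose delay has not yet elapsed at time `t` contribute nothing.
#' Sign convention: the returned value is *subtracted* from the membrane
#' drive, so `V > E_rev` yields a hyperpolarizing effect (GABA-A) and
#' `V < E_rev` a depolarizing one (AMPA/NMDA).
#'
#' @param events data.frame (or list) with columns/fields `time` (presynaptic
#'   spike times, ms) and `a` (relative efficiencies); may be empty.
#' @param params a [synapseParams()] object.
#' @param V postsynaptic membrane potential, mV.
#' @param t evaluation time, ms.
#' @return current, pA.
#' @export
synapticCurrent <- function(events, params, V, t) {
  kern <- kernelSum(events, params, t)
  params$g_max * nmdaGate(V, params$receptor) * kern * (V - params$E_rev)
}

# Sum of double-exponential kernels of delivered events at one time point.
kernelSum <- function(events, params, t) {
  if (length(events$time) == 0L) return(0)
  el <- t - events$time - params$tau_D
  live <- el >= 0
  if (!any(live)) return(0)
  sum(events$a[live] *
        (exp(-el[live] / params$tau_off) - exp(-el[live] / params$tau_on)))
}

#' Conductance kernel sum over a time grid
#'
#' Evaluates the summed double-exponential kernel of a delivered event train
#' on a regular time grid, either by the direct per-event sum or by the
#' two-auxiliary-decay recursion the network engine uses (one decaying
#' accumulator per exponential; each delivery adds the event's efficiency to
#' both). The two methods are mathematically identical when events land on
#' grid points; their agreement is a package regression test.
#'
#' @param events data.frame with `time` (presynaptic spike times, ms) and `a`.
#' @param params a [synapseParams()] object.
#' @param times regular, increasing time grid (ms) starting at or before the
#'   first delivery.
#' @param method `"direct"` or `"recursive"`.
#' @return numeric vector of kernel sums (dimensionless), same length as
#'   `times`.
#' @export
conductanceSeries <- function(events, params, times,
                              method = c("direct", "recursive")) {
  method <- match.arg(method)
  if (method == "direct") {
    return(vapply(times, function(t) kernelSum(events, params, t), numeric(1)))
  }
  dt <- times[2L] - times[1L]
  stopifnot(all(abs(diff(times) - dt) < 1e-9))
  decOff <- exp(-dt / params$tau_off)
  decOn <- exp(-dt / params$tau_on)
  # delivery step index for each event (must land on the grid)
  del <- events$time + params$tau_D
  idx <- round((del - times[1L]) / dt) + 1L
  stopifnot(all(abs(del - (times[1L] + (idx - 1L) * dt)) < 1e-9))
  sOff <- 0
  sOn <- 0
  out <- numeric(length(times))
  for (k in seq_along(times)) {
    if (k > 1L) {
      sOff <- sOff * decOff
      sOn <- sOn * decOn
    }
    hit <- which(idx == k)
    if (length(hit)) {
      sOff <- sOff + sum(events$a[hit])
      sOn <- sOn + sum(events$a[hit])
    }
    out[k] <- sOff - sOn
  }
  out
}

#' Peak time of the double-exponential kernel
#'
#' Closed form for the time (after the presynaptic spike) at which the
#' difference-of-exponentials kernel peaks:
#' `t* = tau_D + tau_on * tau_off / (tau_off - tau_on) * log(tau_off/tau_on)`.
#'
#' @param params a [synapseParams()] object.
#' @return time of the kernel maximum, ms after the presynaptic spike.
#' @export
kernelPeakTime <- function(params) {
  params$tau_D + params$tau_on * params$tau_off /
    (params$tau_off - params$tau_on) * log(params$tau_off / params$tau_on)
}
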