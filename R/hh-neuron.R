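#' Hodgkin-Huxley neuron parameters
#'
#' Parameter set of the conductance-based point neuron used throughout the
#' model. Pyramidal cells and interneurons share all channel parameters and
#' differ only in membrane capacitance (0.5 vs 0.25 nF), which makes the
#' interneurons faster. Units: capacitance nF, conductances uS, potentials
#' mV; with currents in nA this gives membrane time in ms.
#'
#' @param type `"excitatory"` (pyramidal cell) or `"inhibitory"`
#'   (interneuron); selects the default capacitance.
#' @param C_m Membrane capacitance (nF).
#' @param g_K,g_Na,g_L Maximal potassium, sodium and leak conductances (uS).
#' @param E_K,E_Na,E_L Reversal potentials (mV).
#' @returns An object of class `hh_params` (a named list).
#' @examples
#' hh_params()
#' hh_params("inhibitory")
#' @export
hh_params <- function(type = c("excitatory", "inhibitory"),
                      C_m = NULL, g_K = 4.74, g_Na = 12.5, g_L = 0.025,
                      E_K = -80, E_Na = 40, E_L = -65) {
  type <- match.arg(type)
  if (is.null(C_m)) C_m <- if (type == "excitatory") 0.5 else 0.25
  if (!is.numeric(C_m) || C_m <= 0) abort("C_m must be > 0")
  for (g in list(g_K = g_K, g_Na = g_Na, g_L = g_L)) {
    if (!is.numeric(g) || length(g) != 1L || g < 0)
      abort("conductances must be single non-negative numbers")
  }
  if (!(E_K < E_L && E_L < E_Na))
    abort("reversal potentials must satisfy E_K < E_L < E_Na")
  structure(list(type = type, C_m = C_m, g_K = g_K, g_Na = g_Na, g_L = g_L,
                 E_K = E_K, E_Na = E_Na, E_L = E_L),
            class = "hh_params")
}

as_par_vec <- function(p) {
  c(p$C_m, p$g_K, p$g_Na, p$g_L, p$E_K, p$E_Na, p$E_L)
}

#' Voltage-dependent channel rate constants
#'
#' The six opening/closing rates of the potassium (n), sodium activation (m)
#' and sodium inactivation (h) gates, in 1/ms. The alpha_n and alpha_m
#' expressions have removable singularities at V = -20 and V = -16 mV and are
#' evaluated there by their analytic limits.
#'
#' @param V Membrane potential(s), mV.
#' @returns A tibble with columns `V`, `alpha_n`, `beta_n`, `alpha_m`,
#'   `beta_m`, `alpha_h`, `beta_h`.
#' @examples
#' hh_rate_constants(c(-65, -20, -16, 0))
#' @export
hh_rate_constants <- function(V) {
  if (!is.numeric(V) || length(V) < 1L || any(!is.finite(V)))
    abort("V must be finite numeric")
  rows <- lapply(V, hh_rate_constants_cpp)
  out <- do.call(rbind, rows)
  as_tibble(cbind(data.frame(V = V), as.data.frame(out)))
}

#' Resting equilibrium of the neuron
#'
#' Solves the steady state (dV/dt = dn/dt = dm/dt = dh/dt = 0) under a
#' constant injected current by root-finding on the voltage nullcline with
#' the gates at their voltage-clamped steady states.
#'
#' @param params An [hh_params()] object.
#' @param I Constant injected current, nA.
#' @param interval Voltage bracket (mV) searched for the equilibrium.
#' @returns Named numeric vector `c(V, n, m, h)`.
#' @export
hh_equilibrium <- function(params, I = 0, interval = c(-90, -40)) {
  stopifnot(inherits(params, "hh_params"))
  f <- function(V) {
    r <- hh_rate_constants_cpp(V)
    n <- r[1] / (r[1] + r[2]); m <- r[3] / (r[3] + r[4])
    h <- r[5] / (r[5] + r[6])
    -params$g_K * n^4 * (V - params$E_K) -
      params$g_Na * m^3 * h * (V - params$E_Na) -
      params$g_L * (V - params$E_L) + I
  }
  V <- uniroot(f, interval, tol = 1e-10)$root
  r <- hh_rate_constants_cpp(V)
  c(V = V, n = r[[1]] / (r[[1]] + r[[2]]), m = r[[3]] / (r[[3]] + r[[4]]),
    h = r[[5]] / (r[[5]] + r[[6]]))
}

#' Integrate a single neuron
#'
#' Fixed-step fourth-order Runge-Kutta integration of the single-neuron
#' equations under an injected current, which may be constant or a per-step
#' trace. Spikes are upward crossings of 0 mV separated by at least 2 ms.
#'
#' @param params An [hh_params()] object.
#' @param I Injected current (nA): a scalar, or a vector with one value per
#'   time step.
#' @param t_sim Simulated time, ms.
#' @param dt Integration step, ms (default 0.02).
#' @param init Initial state `c(V, n, m, h)`; default the resting
#'   equilibrium at I = 0.
#' @param record_v Keep the full voltage trace?
#' @returns A list with elements `spikes` (spike times, ms), `state` (final
#'   state) and, if requested, `V` (voltage trace) plus `time`.
#' @export
hh_simulate <- function(params, I, t_sim, dt = 0.02, init = NULL,
                        record_v = FALSE) {
  stopifnot(inherits(params, "hh_params"))
  if (!is.numeric(dt) || dt <= 0) abort("dt must be > 0")
  if (!is.numeric(t_sim) || t_sim <= 0) abort("t_sim must be > 0")
  n_steps <- round(t_sim / dt)
  if (length(I) != 1L && length(I) != n_steps)
    abort("I must be scalar or one value per step")
  if (any(!is.finite(I))) abort("I must be finite")
  if (is.null(init)) init <- hh_equilibrium(params, I = 0)
  out <- hh_simulate_cpp(as_par_vec(params), as.numeric(I), dt, n_steps,
                         as.numeric(init), record_v)
  if (record_v) out$time <- seq(0, by = dt, length.out = n_steps + 1L)
  out
}

#' Advance the neuron state by one integration step
#'
#' @param state Named numeric `c(V, n, m, h)`.
#' @inheritParams hh_simulate
#' @param I_syn Input current over the step, nA.
#' @returns The advanced state, gates bounded in `[0, 1]`.
#' @export
hh_step <- function(state, params, I_syn, dt = 0.02) {
  stopifnot(inherits(params, "hh_params"))
  if (!is.numeric(dt) || dt <= 0) abort("dt must be > 0")
  out <- hh_simulate_cpp(as_par_vec(params), I_syn, dt, 1L,
                         as.numeric(state), FALSE)
  setNames(out$state, c("V", "n", "m", "h"))
}

#' Mean firing rate under constant current
#'
#' Spike count after a discard window, divided by the counted window.
#'
#' @inheritParams hh_simulate
#' @param I Constant current, nA.
#' @param t_discard Initial transient excluded from the count, ms.
#' @returns Firing rate in Hz (0 if no spikes).
#' @examples
#' \donttest{firing_rate(hh_params(), I = 2)}
#' @export
firing_rate <- function(params, I, t_sim = 2000, t_discard = 200, dt = 0.02) {
  if (t_discard < 0 || t_sim <= t_discard)
    abort("need t_sim > t_discard >= 0")
  sim <- hh_simulate(params, I, t_sim, dt)
  sum(sim$spikes > t_discard) / ((t_sim - t_discard) / 1000)
}

#' f-I curve
#'
#' @inheritParams firing_rate
#' @param I Vector of currents to sweep, nA.
#' @returns A tibble with columns `I` (nA) and `rate` (Hz).
#' @export
fi_curve <- function(params, I, t_sim = 2000, t_discard = 200, dt = 0.02) {
  tibble(I = I,
         rate = vapply(I, function(x)
           firing_rate(params, x, t_sim, t_discard, dt), numeric(1)))
}

#' Rheobase by bisection
#'
#' Minimal constant current producing sustained repetitive firing, defined
#' as at least `min_spikes` spikes in a `t_sim` trial after discarding the
#' first `t_discard` ms.
#'
#' @inheritParams firing_rate
#' @param I_lo,I_hi Bracket (nA); the lower end must be silent, the upper
#'   end must fire.
#' @param resolution Bisection stops when the bracket is narrower than this
#'   (nA).
#' @param min_spikes Spike count defining sustained firing.
#' @returns Threshold current, nA (midpoint of the final bracket).
#' @examples
#' \donttest{rheobase(hh_params())}
#' @export
rheobase <- function(params, I_lo = 0.1, I_hi = 2.0, resolution = 0.01,
                     t_sim = 2000, t_discard = 200, min_spikes = 5,
                     dt = 0.02) {
  fires <- function(I) {
    sim <- hh_simulate(params, I, t_sim, dt)
    sum(sim$spikes > t_discard) >= min_spikes
  }
  if (fires(I_lo)) abort("invalid bracket: lower end already fires")
  if (!fires(I_hi)) abort("invalid bracket: upper end does not fire")
  while (I_hi - I_lo > resolution) {
    mid <- (I_lo + I_hi) / 2
    if (fires(mid)) I_hi <- mid else I_lo <- mid
  }
  (I_lo + I_hi) / 2
}
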