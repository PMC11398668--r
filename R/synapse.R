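#' Synaptic parameters
#'
#' Kinetic and conductance parameters of the four receptor channels.
#' Cross-area excitatory synapses are AMPA only (`g_AMPA_ext`); recurrent
#' excitatory synapses carry both an AMPA and an NMDA component; inhibitory
#' synapses are GABAergic. NMDA current is attenuated by the
#' voltage-dependent magnesium block (see [mg_block()]).
#'
#' `w_spike` (per-spike gating increment) and `alpha_nmda` (NMDA activation
#' rate) are calibration constants: they are fixed once so that a unitary
#' recurrent EPSC measured under voltage clamp at -65 mV has an AMPA peak of
#' 71 pA and an NMDA peak of 19 pA (NMDA/AMPA ratio 26.6%) at the reference
#' conductances g_AMPA = 0.11 uS, g_NMDA = 0.13 uS.
#'
#' @param g_AMPA_ext Cross-area AMPA conductance (uS).
#' @param g_AMPA,g_NMDA,g_GABA Recurrent conductances (uS).
#' @param V_E,V_I Excitatory and inhibitory reversal potentials (mV).
#' @param tau_AMPA,tau_NMDA_rise,tau_NMDA_decay,tau_GABA Gating time
#'   constants (ms).
#' @param Mg Extracellular magnesium concentration (mM).
#' @param alpha_nmda NMDA activation rate (1/ms); calibrated default.
#' @param w_spike Per-spike gating increment of the recurrent channels
#'   (dimensionless); calibrated default.
#' @param w_ext Per-spike gating increment of the cross-area external-AMPA
#'   channel. Not constrained by the unitary-EPSC data; calibrated once so
#'   that the cue reliably ignites the association area while delay-period
#'   feedback leaves the sensory area silent.
#' @param w_gaba Per-spike gating increment of the GABA channel. No unitary
#'   IPSC amplitude is available to pin it; calibrated once so the
#'   silent/transient/persistent regimes sit at the reference NMDA
#'   conductances (silent at 0.05, transient at 0.13, persistent at
#'   0.15 uS).
#' @returns An object of class `syn_params`.
#' @examples
#' syn_params()
#' syn_params(g_NMDA = 0.15)
#' @export
syn_params <- function(g_AMPA_ext = 0.22, g_AMPA = 0.11, g_NMDA = 0.13,
                       g_GABA = 0.47, V_E = 0, V_I = -70,
                       tau_AMPA = 2, tau_NMDA_rise = 2, tau_NMDA_decay = 100,
                       tau_GABA = 10, Mg = 1,
                       alpha_nmda = 2.0971, w_spike = 0.00993,
                       w_ext = 0.05, w_gaba = 0.05) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("g_AMPA_ext", "g_AMPA", "g_NMDA", "g_GABA", "tau_AMPA",
               "tau_NMDA_rise", "tau_NMDA_decay", "tau_GABA", "Mg",
               "alpha_nmda", "w_spike", "w_ext", "w_gaba")) {
    v <- get(nm)
    if (!num1(v) || v < 0) abort(paste0(nm, " must be a non-negative number"))
  }
  if (!(V_I < V_E)) abort("V_I must be below V_E")
  structure(list(g_AMPA_ext = g_AMPA_ext, g_AMPA = g_AMPA, g_NMDA = g_NMDA,
                 g_GABA = g_GABA, V_E = V_E, V_I = V_I, tau_AMPA = tau_AMPA,
                 tau_NMDA_rise = tau_NMDA_rise,
                 tau_NMDA_decay = tau_NMDA_decay, tau_GABA = tau_GABA,
                 Mg = Mg, alpha_nmda = alpha_nmda, w_spike = w_spike,
                 w_ext = w_ext, w_gaba = w_gaba),
            class = "syn_params")
}

#' Magnesium block of the NMDA channel
#'
#' Voltage-dependent attenuation factor
#' \eqn{B(V) = 1 / (1 + [Mg] e^{-0.062 V} / 3.57)}; strictly increasing in
#' V, in (0, 1] for Mg > 0, and identically 1 at Mg = 0.
#'
#' @param V Membrane potential(s), mV.
#' @param Mg Magnesium concentration, mM.
#' @returns Dimensionless factor(s) in (0, 1].
#' @examples
#' mg_block(0)    # 3.57 / 4.57
#' mg_block(-65)
#' @export
mg_block <- function(V, Mg = 1) {
  if (!is.numeric(Mg) || any(Mg < 0)) abort("Mg must be >= 0")
  1 / (1 + Mg * exp(-0.062 * V) / 3.57)
}

#' Empty synaptic gating state
#'
#' @param n_E,n_I Numbers of presynaptic pyramidal cells and interneurons.
#' @returns A list of gating vectors (`s_AMPA_ext`, `s_AMPA_rec`, `s_NMDA`,
#'   `x_NMDA` per pyramidal cell; `s_GABA` per interneuron).
#' @export
gating_state <- function(n_E, n_I) {
  list(s_AMPA_ext = numeric(n_E), s_AMPA_rec = numeric(n_E),
       s_NMDA = numeric(n_E), x_NMDA = numeric(n_E),
       s_GABA = numeric(n_I))
}

#' Advance synaptic gating by one step
#'
#' Exponential decay at the channel time constants, first-order NMDA
#' activation (`alpha_nmda * x * (1 - s)`, which keeps `s_NMDA` in
#' `[0, 1]`), then event increments: each presynaptic spike adds `w_spike`
#' to `x_NMDA` and `s_AMPA_rec` and `w_ext` to `s_AMPA_ext` (pyramidal
#' presynaptic cells) or `w_spike` to `s_GABA` (interneurons); each
#' background event adds `D_p` to `s_AMPA_ext`.
#'
#' @param state A gating state, see [gating_state()].
#' @param spikes_E Logical (or 0/1) vector: which pyramidal presynaptic
#'   cells spiked during the step.
#' @param spikes_I Same for interneurons.
#' @param bg_events Integer vector of background Poisson event counts per
#'   pyramidal presynaptic channel (added to `s_AMPA_ext`).
#' @param params A [syn_params()] object.
#' @param dt Step, ms.
#' @param D_p Background event increment.
#' @returns The advanced gating state.
#' @export
update_gating <- function(state, spikes_E = NULL, spikes_I = NULL,
                          bg_events = NULL, params = syn_params(),
                          dt = 0.02, D_p = 0.005) {
  if (dt <= 0) abort("dt must be > 0")
  w <- params$w_spike
  st <- state
  st$s_AMPA_ext <- st$s_AMPA_ext * exp(-dt / params$tau_AMPA)
  st$s_AMPA_rec <- st$s_AMPA_rec * exp(-dt / params$tau_AMPA)
  st$x_NMDA <- st$x_NMDA * exp(-dt / params$tau_NMDA_rise)
  st$s_GABA <- st$s_GABA * exp(-dt / params$tau_GABA)
  s <- st$s_NMDA
  s <- s + dt * (-s / params$tau_NMDA_decay +
                   params$alpha_nmda * st$x_NMDA * (1 - s))
  st$s_NMDA <- pmin(pmax(s, 0), 1)
  if (!is.null(spikes_E)) {
    sE <- as.numeric(spikes_E)
    st$x_NMDA <- st$x_NMDA + w * sE
    st$s_AMPA_rec <- st$s_AMPA_rec + w * sE
    st$s_AMPA_ext <- st$s_AMPA_ext + params$w_ext * sE
  }
  if (!is.null(spikes_I))
    st$s_GABA <- st$s_GABA + params$w_gaba * as.numeric(spikes_I)
  if (!is.null(bg_events))
    st$s_AMPA_ext <- st$s_AMPA_ext + D_p * as.numeric(bg_events)
  st
}

#' Total synaptic current onto one neuron
#'
#' Assembles the AMPA (external and recurrent), NMDA and GABA currents from
#' the presynaptic gating variables and the adjacency rows of the receiving
#' neuron. Sign convention: depolarizing currents are positive, so the AMPA
#' and NMDA terms are positive when `V_post < V_E` and the GABA term is
#' negative when `V_post > V_I`.
#'
#' @param V_post Postsynaptic membrane potential, mV.
#' @param gating Gating state of all presynaptic neurons
#'   (see [gating_state()]).
#' @param eps_rec_E Binary adjacency row over presynaptic pyramidal cells
#'   (recurrent).
#' @param eps_rec_I Binary adjacency row over presynaptic interneurons.
#' @param eps_ext Binary adjacency row over cross-area presynaptic pyramidal
#'   cells.
#' @param params A [syn_params()] object.
#' @returns Current in nA.
#' @export
synaptic_current <- function(V_post, gating, eps_rec_E, eps_rec_I,
                             eps_ext = NULL, params = syn_params()) {
  chk <- function(eps, len, nm) {
    if (length(eps) != len)
      abort(paste0(nm, " length does not match gating length"))
    if (!all(eps %in% c(0, 1))) abort(paste0(nm, " must be binary"))
  }
  chk(eps_rec_E, length(gating$s_AMPA_rec), "eps_rec_E")
  chk(eps_rec_I, length(gating$s_GABA), "eps_rec_I")
  p <- params
  I_ext <- 0
  if (!is.null(eps_ext)) {
    chk(eps_ext, length(gating$s_AMPA_ext), "eps_ext")
    I_ext <- p$g_AMPA_ext * (V_post - p$V_E) * sum(eps_ext * gating$s_AMPA_ext)
  }
  I_ampa <- p$g_AMPA * (V_post - p$V_E) * sum(eps_rec_E * gating$s_AMPA_rec)
  I_nmda <- p$g_NMDA * (V_post - p$V_E) * mg_block(V_post, p$Mg) *
    sum(eps_rec_E * gating$s_NMDA)
  I_gaba <- p$g_GABA * (V_post - p$V_I) * sum(eps_rec_I * gating$s_GABA)
  -(I_ext + I_ampa + I_nmda + I_gaba)
}

#' Unitary EPSC components under voltage clamp
#'
#' Delivers a single presynaptic spike to a postsynaptic neuron clamped at
#' `V_hold`, integrates the gating kinetics (AMPA analytically, NMDA with a
#' stiff ODE solver) and reports the peak magnitudes of the AMPA and NMDA
#' current components and their ratio.
#'
#' @param params A [syn_params()] object.
#' @param V_hold Holding potential, mV.
#' @param t_max Integration window, ms.
#' @returns One-row tibble: `peak_AMPA_pA`, `peak_NMDA_pA`, `ratio_pct`
#'   (NMDA/AMPA, %), `t_half_AMPA_ms`, `t_half_NMDA_ms` (times at which each
#'   component has decayed to half its peak).
#' @examples
#' unitary_epsc(syn_params())
#' @export
unitary_epsc <- function(params = syn_params(), V_hold = -65, t_max = 400) {
  p <- params
  w <- p$w_spike
  drive <- abs(V_hold - p$V_E)           # mV
  peak_ampa <- p$g_AMPA * drive * w * 1000   # uS * mV = nA -> pA
  t_half_ampa <- p$tau_AMPA * log(2)
  times <- seq(0, t_max, by = 0.05)
  sol <- deSolve::lsoda(
    y = c(x = w, s = 0), times = times,
    func = function(t, y, parms) {
      list(c(-y[1] / p$tau_NMDA_rise,
             -y[2] / p$tau_NMDA_decay +
               p$alpha_nmda * y[1] * (1 - y[2])))
    }, rtol = 1e-10, atol = 1e-12)
  s_nmda <- sol[, "s"]
  scale_nmda <- p$g_NMDA * drive * mg_block(V_hold, p$Mg) * 1000
  peak_nmda <- scale_nmda * max(s_nmda)
  ipk <- which.max(s_nmda)
  after <- s_nmda[ipk:length(s_nmda)]
  ih <- which(after <= max(s_nmda) / 2)[1]
  t_half_nmda <- if (is.na(ih)) NA_real_ else times[ipk + ih - 1L]
  tibble(peak_AMPA_pA = peak_ampa, peak_NMDA_pA = peak_nmda,
         ratio_pct = if (peak_ampa > 0) 100 * peak_nmda / peak_ampa
                     else if (peak_nmda == 0) 0 else NA_real_,
         t_half_AMPA_ms = t_half_ampa, t_half_NMDA_ms = t_half_nmda)
}
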