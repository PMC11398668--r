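#' Default run configuration
#'
#' Nested named list mirroring the model parameter objects, with every
#' value at its reference default. Serializes losslessly to YAML.
#'
#' @returns An object of class `wm_config`.
#' @export
wm_config <- function() {
  structure(list(
    neuron_E = list(C_m = 0.5, g_K = 4.74, g_Na = 12.5, g_L = 0.025,
                    E_K = -80, E_Na = 40, E_L = -65),
    neuron_I = list(C_m = 0.25, g_K = 4.74, g_Na = 12.5, g_L = 0.025,
                    E_K = -80, E_Na = 40, E_L = -65),
    synapse = list(g_AMPA_ext = 0.22, g_AMPA = 0.11, g_NMDA = 0.13,
                   g_GABA = 0.47, V_E = 0, V_I = -70, tau_AMPA = 2,
                   tau_NMDA_rise = 2, tau_NMDA_decay = 100, tau_GABA = 10,
                   Mg = 1,
                   # calibrated so a unitary EPSC at -65 mV clamp gives
                   # AMPA 71 pA / NMDA 19 pA at the reference conductances
                   alpha_nmda = 2.0971, w_spike = 0.00993,
                   # cross-area increment, set for reliable cue ignition
                   w_ext = 0.05, w_gaba = 0.05),
    connectivity = list(sensory = list(N_E = 80, N_I = 20, p_E_rec = 0.05,
                                       p_I_rec = 0.20),
                        association = list(N_E = 80, N_I = 20,
                                           p_E_rec = 0.20, p_I_rec = 0.20),
                        p_fb = 0.05),
    protocol = list(t_precue = 500, t_cue = 500, t_delay = 4000,
                    t_match = 500, I_cue = 2.0, t_reward_onset = 300,
                    t_settle = 200),
    noise = list(rate = 2300, D_p = 0.005),
    seeds = list(topology = 1, noise = 1),
    dt = 0.02,
    syn_scale = 1,
    output_dir = "."
  ), class = "wm_config")
}

merge_validate <- function(default, user, path = "") {
  if (is.null(user)) return(default)
  if (!is.list(default)) {
    if (!is.numeric(user) && !is.character(user))
      abort(paste0("invalid value for key '", path, "'"))
    return(user)
  }
  extra <- setdiff(names(user), names(default))
  if (length(extra))
    abort(paste0("unknown configuration key(s): ",
                 paste0(path, extra, collapse = ", ")))
  for (nm in names(user))
    default[[nm]] <- merge_validate(default[[nm]], user[[nm]],
                                    paste0(path, nm, "/"))
  default
}

check_config_values <- function(cfg) {
  for (nm in c("g_AMPA_ext", "g_AMPA", "g_NMDA", "g_GABA", "tau_AMPA",
               "tau_NMDA_rise", "tau_NMDA_decay", "tau_GABA", "Mg",
               "alpha_nmda", "w_spike", "w_ext", "w_gaba"))
    if (cfg$synapse[[nm]] < 0)
      abort(paste0("invalid value: synapse/", nm, " must be >= 0"))
  for (side in c("neuron_E", "neuron_I"))
    for (nm in c("C_m", "g_K", "g_Na", "g_L"))
      if (cfg[[side]][[nm]] < 0 || (nm == "C_m" && cfg[[side]][[nm]] == 0))
        abort(paste0("invalid value: ", side, "/", nm))
  for (aa in c("sensory", "association"))
    for (nm in c("p_E_rec", "p_I_rec")) {
      p <- cfg$connectivity[[aa]][[nm]]
      if (p < 0 || p > 1)
        abort(paste0("invalid value: connectivity/", aa, "/", nm,
                     " must lie in [0, 1]"))
    }
  if (cfg$dt <= 0) abort("invalid value: dt must be > 0")
  invisible(cfg)
}

#' Read / write a run configuration
#'
#' YAML on disk. Omitted fields take the packaged defaults; unknown keys
#' and out-of-range values are rejected with an error naming the key. An
#' empty (or missing-section) file therefore yields the full default
#' configuration.
#'
#' @param path File path.
#' @returns `load_config()` returns a validated `wm_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_validate(unclass(wm_config()), user)
  cfg <- structure(cfg, class = "wm_config")
  check_config_values(cfg)
  cfg
}

#' @rdname load_config
#' @param config A `wm_config` object.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build parameter objects from a configuration
#'
#' @param config A `wm_config`.
#' @returns List with `sensory`, `association`, `syn`, `protocol`,
#'   `noise`, `neuron_E`, `neuron_I`, `seeds`, `dt`, `syn_scale`, `p_fb`.
#' @export
config_objects <- function(config) {
  cfg <- config
  mk_area <- function(name) {
    a <- cfg$connectivity[[name]]
    area_spec(name, N_E = a$N_E, N_I = a$N_I, p_E_rec = a$p_E_rec,
              p_I_rec = a$p_I_rec)
  }
  mk_neuron <- function(nm, type) {
    p <- cfg[[nm]]
    hh_params(type, C_m = p$C_m, g_K = p$g_K, g_Na = p$g_Na, g_L = p$g_L,
              E_K = p$E_K, E_Na = p$E_Na, E_L = p$E_L)
  }
  list(sensory = mk_area("sensory"), association = mk_area("association"),
       syn = do.call(syn_params, cfg$synapse),
       protocol = do.call(protocol_spec, cfg$protocol),
       noise = do.call(noise_spec, cfg$noise),
       neuron_E = mk_neuron("neuron_E", "excitatory"),
       neuron_I = mk_neuron("neuron_I", "inhibitory"),
       seeds = cfg$seeds, dt = cfg$dt, syn_scale = cfg$syn_scale,
       p_fb = cfg$connectivity$p_fb)
}

#' Network-and-protocol fixtures
#'
#' `"standard"` is the reference model (80 pyramidal cells and 20
#' interneurons per area, full trial timing). `"mini"` is a reduced
#' network for fast tests and scaled-down ensemble experiments: 20/5
#' neurons per area with the recurrent and cross-area conductances scaled
#' by 4 (the population ratio), which preserves the expected synaptic
#' drive per neuron, and shortened phases (50/100/500/100 ms).
#'
#' @param kind `"mini"` or `"standard"`.
#' @param seed Topology seed used to build the network.
#' @param t_delay Optional delay override, ms.
#' @returns List with `network`, `sensory`, `association`, `syn`,
#'   `protocol`, `noise`, `syn_scale`, `seed`.
#' @examples
#' fx <- make_fixture("mini", seed = 1)
#' fx$network
#' @export
make_fixture <- function(kind = c("mini", "standard"), seed = 1,
                         t_delay = NULL) {
  kind <- match.arg(kind)
  if (kind == "mini") {
    sensory <- area_spec("sensory", N_E = 20, N_I = 5)
    association <- area_spec("association", N_E = 20, N_I = 5)
    protocol <- protocol_spec(t_precue = 50, t_cue = 100,
                              t_delay = t_delay %||% 500, t_match = 100,
                              t_settle = 100)
    syn_scale <- 4
  } else {
    sensory <- area_spec("sensory")
    association <- area_spec("association")
    protocol <- protocol_spec(t_delay = t_delay %||% 4000)
    syn_scale <- 1
  }
  network <- build_network(sensory, association, seed = seed)
  list(network = network, sensory = sensory, association = association,
       syn = syn_params(), protocol = protocol, noise = noise_spec(),
       syn_scale = syn_scale, seed = seed, kind = kind)
}

#' Write a reproducibility manifest
#'
#' Records the package version, R version, seeds and full configuration
#' next to an output file, so the run can be reproduced exactly.
#'
#' @param path Manifest path (YAML).
#' @param config A `wm_config`.
#' @param extra Optional named list appended verbatim.
#' @export
write_manifest <- function(path, config, extra = list()) {
  man <- c(list(package = "wmnet",
                version = as.character(utils::packageVersion("wmnet")),
                r_version = R.version.string,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                config = unclass(config)),
           extra)
  yaml::write_yaml(man, path)
  invisible(path)
}
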