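# Shared scaled-down study conditions for the ensemble experiments, plus
# cached ensembles so several test blocks can analyse the same runs.
#
# The "small" condition halves the linear population size of the reference
# network (40 pyramidal cells / 10 interneurons per area) and doubles the
# recurrent and cross-area conductances, preserving the expected recurrent
# drive per neuron; the delay is shortened to 1500 ms. dt = 0.05 ms: the
# taxonomy medians of the reference topology agree with dt = 0.02 well
# within seed-to-seed variability.

acc_cache <- new.env(parent = emptyenv())

small_conditions <- function(t_delay = 3000) {
  list(sensory = area_spec("sensory", N_E = 40, N_I = 10),
       association = area_spec("association", N_E = 40, N_I = 10),
       protocol = protocol_spec(t_precue = 200, t_cue = 500,
                                t_delay = t_delay, t_match = 200),
       syn_scale = 2, dt = 0.05)
}

small_trial <- function(topology_seed, noise_seed, syn = syn_params(),
                        cond = small_conditions()) {
  net <- build_network(cond$sensory, cond$association, seed = topology_seed)
  run_trial(net, syn = syn, protocol = cond$protocol, seed = noise_seed,
            syn_scale = cond$syn_scale, dt = cond$dt)
}

# 100 random topologies at fixed noise seed, reference synapses
topology_ensemble <- function() {
  if (!is.null(acc_cache$topo)) return(acc_cache$topo)
  cond <- small_conditions()
  acc_cache$topo <- wm_ensemble(
    100, vary = "topology", seed = 20240903,
    sensory = cond$sensory, association = cond$association,
    protocol = cond$protocol, syn_scale = cond$syn_scale, dt = cond$dt,
    with_features = TRUE)
  acc_cache$topo
}

# 100 noise realizations on one fixed topology
noise_ensemble <- function() {
  if (!is.null(acc_cache$noise)) return(acc_cache$noise)
  cond <- small_conditions()
  # the reference (transient-regime) topology, as in the published
  # noise-variability panel which shows a transient network
  acc_cache$noise <- wm_ensemble(
    100, vary = "noise", seed = 20240903,
    fixed_topology_seed = reference_topology_seed(),
    sensory = cond$sensory, association = cond$association,
    protocol = cond$protocol, syn_scale = cond$syn_scale, dt = cond$dt)
  acc_cache$noise
}


# Reference topology of the small condition: a network whose regime
# boundaries match the reference behaviour (silent at g_NMDA = 0.05 uS,
# transient at 0.13, persistent at 0.15); the transition threshold varies
# across topologies (the model's topology-induced bistability), so regime
# anchoring is defined on a reference network.
reference_topology_seed <- function() 3L

# Larger condition for the per-region predictions, whose claim depends on
# the location of the persistence transition along the connection
# probability axis: 60E/15I per area, conductance scale 4/3, 2500 ms delay.
anatomy_conditions <- function() {
  list(sensory = area_spec("sensory", N_E = 60, N_I = 15),
       association = area_spec("association", N_E = 60, N_I = 15),
       protocol = protocol_spec(t_precue = 200, t_cue = 500,
                                t_delay = 3000, t_match = 200),
       syn_scale = 4 / 3, dt = 0.05)
}
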