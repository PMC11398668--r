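#' Trial protocol specification
#'
#' Timing of the delayed match-to-sample trial. Protocol time 0 is the
#' start of the pre-cue interval; a settling interval of `t_settle` ms is
#' simulated before it (spikes there are discarded). The cue current is
#' applied to all sensory pyramidal cells during the cue window and again,
#' identically, during the match window; `t_reward_onset` ms after match
#' onset the association interneurons receive a current of the same
#' amplitude (reward/behavioural-response signal) until the end of the
#' trial.
#'
#' @param t_precue,t_cue,t_delay,t_match Phase durations, ms.
#' @param I_cue Cue amplitude, nA (supra-threshold; the model rheobase is
#'   0.7 nA).
#' @param t_reward_onset Reward latency after match onset, ms.
#' @param t_settle Settling time before protocol time 0, ms.
#' @returns An object of class `protocol_spec`.
#' @export
protocol_spec <- function(t_precue = 500, t_cue = 500, t_delay = 4000,
                          t_match = 500, I_cue = 2.0, t_reward_onset = 300,
                          t_settle = 200) {
  for (v in c(t_precue, t_cue, t_delay, t_match))
    if (!is.numeric(v) || v <= 0) abort("phase durations must be > 0")
  if (I_cue <= 0) abort("I_cue must be > 0")
  if (t_reward_onset < 0 || t_reward_onset > t_match + 300)
    abort("t_reward_onset out of range")
  if (t_settle < 0) abort("t_settle must be >= 0")
  structure(list(t_precue = t_precue, t_cue = t_cue, t_delay = t_delay,
                 t_match = t_match, I_cue = I_cue,
                 t_reward_onset = t_reward_onset, t_settle = t_settle),
            class = "protocol_spec")
}

#' Background-input specification
#'
#' Each neuron receives an independent Poisson train of background
#' excitatory events on its external-AMPA gating variable.
#'
#' @param rate Poisson rate per neuron, Hz.
#' @param D_p Gating increment per background event.
#' @returns An object of class `noise_spec`.
#' @export
noise_spec <- function(rate = 2300, D_p = 0.005) {
  if (rate < 0 || D_p < 0) abort("rate and D_p must be >= 0")
  structure(list(rate = rate, D_p = D_p), class = "noise_spec")
}

#' Run one delayed match-to-sample trial
#'
#' Integrates the full two-area network through pre-cue, cue, delay and
#' match phases and measures the duration of delay-period activity of the
#' association pyramidal population (time from cue removal to its last
#' spike within the delay, censored at the delay length).
#'
#' @param network A [build_network()] object.
#' @param syn A [syn_params()] object.
#' @param protocol A [protocol_spec()] object.
#' @param noise A [noise_spec()] object.
#' @param neuron_E,neuron_I [hh_params()] for the two cell classes.
#' @param seed Noise seed (integer); with the network's topology seed it
#'   makes the trial fully reproducible.
#' @param dt Integration step, ms.
#' @param syn_scale Factor applied to the recurrent and cross-area
#'   conductances (`g_AMPA`, `g_NMDA`, `g_GABA`, `g_AMPA_ext`). Used by
#'   reduced-size fixtures to preserve the expected recurrent drive per
#'   neuron when the population is smaller than the reference network; 1
#'   for the standard network.
#' @param duration_population Population whose last spike defines the
#'   working-memory duration (default association pyramidal cells).
#' @param censor_window Spike within this many ms of the delay end flags
#'   the trial as censored (activity survived the delay).
#' @param theta_s Silent/transient threshold passed to [classify_state()].
#' @returns An object of class `wm_trial`: list with `raster` (tibble
#'   `neuron`, `time`, `area`, `type`), `duration` (ms), `censored`,
#'   `state`, and the timing anchors `cue_offset`/`delay_end`.
#' @examples
#' \donttest{
#' net <- build_network(seed = 1)
#' tr <- run_trial(net, seed = 2)
#' tr$duration
#' }
#' @export
run_trial <- function(network, syn = syn_params(),
                      protocol = protocol_spec(), noise = noise_spec(),
                      neuron_E = hh_params("excitatory"),
                      neuron_I = hh_params("inhibitory"),
                      seed = NULL, dt = 0.02, syn_scale = 1,
                      duration_population = c("association_E", "sensory_E",
                                              "all"),
                      censor_window = 50, theta_s = 200) {
  stopifnot(inherits(network, "wm_network"),
            inherits(syn, "syn_params"),
            inherits(protocol, "protocol_spec"),
            inherits(noise, "noise_spec"))
  duration_population <- match.arg(duration_population)
  if (!is.null(seed)) set.seed(seed)
  lb <- network$labels
  type_i <- ifelse(lb$type == "E", 1L, 2L)
  area_i <- ifelse(lb$area == "sensory", 1L, 2L)
  neuron_par <- c(neuron_E$C_m, neuron_I$C_m, neuron_E$g_K, neuron_E$g_Na,
                  neuron_E$g_L, neuron_E$E_K, neuron_E$E_Na, neuron_E$E_L)
  syn_par <- c(syn$g_AMPA_ext * syn_scale, syn$g_AMPA * syn_scale,
               syn$g_NMDA * syn_scale, syn$g_GABA * syn_scale,
               syn$V_E, syn$V_I, syn$tau_AMPA, syn$tau_NMDA_rise,
               syn$tau_NMDA_decay, syn$tau_GABA, syn$Mg, syn$alpha_nmda,
               syn$w_spike, syn$w_ext, syn$w_gaba, syn$g_AMPA_ext)
  proto <- c(protocol$t_settle, protocol$t_precue, protocol$t_cue,
             protocol$t_delay, protocol$t_match, protocol$I_cue,
             protocol$t_reward_onset)
  raw <- run_trial_cpp(network$M_rec, network$M_ext, type_i, area_i,
                       neuron_par, syn_par, c(noise$rate, noise$D_p),
                       proto, dt)
  raster <- tibble(neuron = raw$neuron, time = raw$time)
  raster <- dplyr::left_join(raster,
                             dplyr::select(lb, neuron = "id", "area", "type"),
                             by = "neuron")
  cue_offset <- protocol$t_precue + protocol$t_cue
  delay_end <- cue_offset + protocol$t_delay
  pop <- switch(duration_population,
                association_E = lb$id[lb$area == "association" &
                                        lb$type == "E"],
                sensory_E = lb$id[lb$area == "sensory" & lb$type == "E"],
                all = lb$id)
  dur <- wm_duration(raster, population = pop, cue_offset = cue_offset,
                     delay_end = delay_end, censor_window = censor_window)
  structure(list(raster = raster, duration = dur,
                 censored = attr(dur, "censored"),
                 state = classify_state(dur, attr(dur, "censored"),
                                        theta_s = theta_s),
                 cue_offset = cue_offset, delay_end = delay_end,
                 t_end = raw$t_end, protocol = protocol, syn = syn,
                 noise = noise, seed = seed, dt = dt,
                 syn_scale = syn_scale, n_neurons = nrow(lb),
                 labels = lb),
            class = "wm_trial")
}

#' @export
print.wm_trial <- function(x, ...) {
  cat("<wm_trial> ", nrow(x$raster), " spikes / ", x$n_neurons,
      " neurons; WM duration ", round(as.numeric(x$duration), 1), " ms (",
      as.character(x$state),
      if (isTRUE(x$censored)) ", censored" else "", ")\n", sep = "")
  invisible(x)
}

#' Working-memory duration from a spike raster
#'
#' Time from cue removal until the last spike of the monitored population
#' within the delay period; 0 if the population is silent throughout the
#' delay. A spike within `censor_window` ms of the delay end flags the
#' value as censored (activity survived the full delay).
#'
#' @param raster Data frame with columns `neuron` and `time` (ms).
#' @param population Optional vector of neuron ids to restrict to.
#' @param cue_offset Time of cue removal, ms.
#' @param delay_end End of the delay period, ms.
#' @param censor_window Censoring window before `delay_end`, ms.
#' @returns Duration in ms with attribute `censored` (logical).
#' @examples
#' r <- data.frame(neuron = 1, time = 1500)
#' wm_duration(r, cue_offset = 1000, delay_end = 5000)
#' @export
wm_duration <- function(raster, population = NULL, cue_offset,
                        delay_end, censor_window = 50) {
  tt <- raster$time
  if (!is.null(population)) tt <- tt[raster$neuron %in% population]
  tt <- tt[tt > cue_offset & tt <= delay_end]
  if (length(tt) == 0L)
    return(structure(0, censored = FALSE))
  last <- max(tt)
  structure(last - cue_offset,
            censored = last > delay_end - censor_window)
}

#' Per-neuron activity durations
#'
#' [wm_duration()] applied separately to every neuron appearing in the
#' raster (neurons with no delay-period spikes get 0).
#'
#' @inheritParams wm_duration
#' @param neurons Neuron ids to report (default: all in the raster).
#' @returns Tibble with columns `neuron`, `duration`, `censored`.
#' @export
per_neuron_duration <- function(raster, cue_offset, delay_end,
                                censor_window = 50, neurons = NULL) {
  if (is.null(neurons)) neurons <- sort(unique(raster$neuron))
  res <- lapply(neurons, function(id)
    wm_duration(raster, population = id, cue_offset = cue_offset,
                delay_end = delay_end, censor_window = censor_window))
  tibble(neuron = neurons,
         duration = vapply(res, as.numeric, numeric(1)),
         censored = vapply(res, function(x) attr(x, "censored"), logical(1)))
}

#' Classify delay-period activity
#'
#' `silent` if the duration is below `theta_s`, `persistent` if censored
#' (activity reached the end of the delay), `transient` otherwise.
#'
#' @param duration Duration(s) in ms.
#' @param censored Logical censoring flag(s); taken from the `censored`
#'   attribute when missing.
#' @param theta_s Silent/transient threshold, ms.
#' @returns Factor with levels silent, transient, persistent.
#' @examples
#' classify_state(c(0, 1200, 4000), censored = c(FALSE, FALSE, TRUE))
#' @export
classify_state <- function(duration, censored = NULL, theta_s = 200) {
  if (is.null(censored)) censored <- isTRUE(attr(duration, "censored"))
  duration <- as.numeric(duration)
  censored <- rep_len(as.logical(censored), length(duration))
  out <- ifelse(censored, "persistent",
                ifelse(duration < theta_s, "silent", "transient"))
  factor(out, levels = c("silent", "transient", "persistent"))
}

#' Population firing-rate traces
#'
#' Binned spike counts per population divided by bin width and population
#' size, optionally smoothed with a centred moving average.
#'
#' @param raster Data frame with columns `neuron`, `time`, and (if `by` is
#'   used) the grouping columns.
#' @param t_end End of the trace, ms.
#' @param bin Bin width, ms.
#' @param smooth Moving-average window, ms (0 = none).
#' @param by Character vector of raster columns defining populations
#'   (default `c("area", "type")` when present).
#' @param pop_sizes Named vector of population sizes; inferred from a
#'   `wm_trial` or required when `raster` lacks the information.
#' @returns Tibble with columns `population`, `time` (bin centre, ms),
#'   `rate` (Hz).
#' @export
rate_trace <- function(raster, t_end, bin = 10, smooth = 0, by = NULL,
                       pop_sizes = NULL) {
  if (bin <= 0) abort("bin width must be > 0")
  if (inherits(raster, "wm_trial")) {
    trial <- raster
    raster <- trial$raster
    if (missing(t_end)) t_end <- trial$t_end
    if (is.null(pop_sizes)) {
      cnt <- dplyr::count(trial$labels, .data$area, .data$type)
      pop_sizes <- setNames(cnt$n, paste(cnt$area, cnt$type, sep = "_"))
    }
  }
  if (is.null(by)) by <- intersect(c("area", "type"), names(raster))
  breaks <- seq(0, t_end + bin, by = bin)
  centres <- breaks[-length(breaks)] + bin / 2
  pop_of <- if (length(by)) {
    do.call(paste, c(raster[by], sep = "_"))
  } else rep("all", nrow(raster))
  pops <- if (!is.null(pop_sizes)) names(pop_sizes) else sort(unique(pop_of))
  out <- lapply(pops, function(pp) {
    tt <- raster$time[pop_of == pp]
    counts <- if (length(tt))
      tabulate(findInterval(tt, breaks, left.open = TRUE),
               nbins = length(centres))
    else rep(0L, length(centres))
    n_pop <- if (!is.null(pop_sizes)) pop_sizes[[pp]] else
      length(unique(raster$neuron[pop_of == pp]))
    rate <- counts / n_pop / (bin / 1000)
    if (smooth > bin) {
      k <- max(1L, round(smooth / bin))
      if (k %% 2 == 0) k <- k + 1L
      rate <- as.numeric(stats::filter(rate, rep(1 / k, k), sides = 2))
      rate[is.na(rate)] <- 0
    }
    tibble(population = pp, time = centres, rate = rate)
  })
  dplyr::bind_rows(out)
}

#' Write a spike raster as TSV
#'
#' Two columns (`neuron`, `time` in ms) with a header comment naming the
#' populations.
#'
#' @param trial A `wm_trial` (or a raster data frame).
#' @param path Output path.
#' @export
write_raster <- function(trial, path) {
  raster <- if (inherits(trial, "wm_trial")) trial$raster else trial
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(trial, "wm_trial")) {
    cnt <- dplyr::count(trial$labels, .data$area, .data$type)
    writeLines(paste0("# populations: ",
                      paste(paste0(cnt$area, "_", cnt$type, "=", cnt$n),
                            collapse = " ")), con)
  }
  utils::write.table(raster[, c("neuron", "time")], con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
tidy.wm_trial <- function(x, ...) {
  as_tibble(x$raster)
}

#' @export
glance.wm_trial <- function(x, ...) {
  tibble(duration = as.numeric(x$duration), censored = isTRUE(x$censored),
         state = as.character(x$state), n_spikes = nrow(x$raster),
         n_neurons = x$n_neurons, cue_offset = x$cue_offset,
         delay_end = x$delay_end, seed = x$seed %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
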