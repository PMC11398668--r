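#' Ensembles of trials over random topologies and/or noise realizations
#'
#' Runs `n` delayed match-to-sample trials, varying the network topology,
#' the background-noise realization, or both, from a single master seed.
#' Optionally computes the seventeen structural variables of each
#' association-area recurrent matrix, for structure-function analyses.
#'
#' @param n Number of trials.
#' @param vary `"both"`, `"topology"` (noise seed held fixed) or `"noise"`
#'   (topology held fixed).
#' @param seed Master seed; per-trial topology and noise seeds are drawn
#'   from it.
#' @param sensory,association [area_spec()]s.
#' @param syn,protocol,noise,syn_scale,dt Passed to [run_trial()].
#' @param with_features Also compute [feature_vector()] per network?
#' @param fixed_topology_seed,fixed_noise_seed Optional explicit seed for
#'   the held-fixed source when `vary` is `"noise"` or `"topology"`
#'   (default: the first seed drawn from the master seed).
#' @returns Tibble with one row per trial: `id`, `topology_seed`,
#'   `noise_seed`, `duration`, `censored`, `state`, and (if requested) the
#'   17 feature columns.
#' @examples
#' \donttest{
#' fx <- make_fixture("mini", seed = 1)
#' wm_ensemble(3, seed = 1, sensory = fx$sensory,
#'             association = fx$association, protocol = fx$protocol,
#'             syn_scale = fx$syn_scale)
#' }
#' @export
wm_ensemble <- function(n, vary = c("both", "topology", "noise"), seed = 1,
                        sensory = area_spec("sensory"),
                        association = area_spec("association"),
                        syn = syn_params(), protocol = protocol_spec(),
                        noise = noise_spec(), syn_scale = 1, dt = 0.02,
                        with_features = FALSE, fixed_topology_seed = NULL,
                        fixed_noise_seed = NULL) {
  vary <- match.arg(vary)
  set.seed(seed)
  tseeds <- sample.int(2^30, n)
  nseeds <- sample.int(2^30, n)
  if (vary == "noise") tseeds[] <- fixed_topology_seed %||% tseeds[1]
  if (vary == "topology") nseeds[] <- fixed_noise_seed %||% nseeds[1]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    net <- build_network(sensory, association, seed = tseeds[i])
    tr <- run_trial(net, syn = syn, protocol = protocol, noise = noise,
                    seed = nseeds[i], dt = dt, syn_scale = syn_scale)
    row <- tibble(id = i, topology_seed = tseeds[i], noise_seed = nseeds[i],
                  duration = as.numeric(tr$duration),
                  censored = isTRUE(tr$censored),
                  state = as.character(tr$state))
    if (with_features) {
      lb <- net$labels
      fv <- feature_vector(net$M_association,
                           lb$type[lb$area == "association"])
      row <- dplyr::bind_cols(row, fv)
    }
    rows[[i]] <- row
  }
  dplyr::bind_rows(rows)
}

#' Structure-function correlation summary
#'
#' Spearman correlation of every structural variable with working-memory
#' duration across an ensemble.
#'
#' @param ensemble Output of `wm_ensemble(..., with_features = TRUE)`.
#' @returns Tibble `term`, `rho`, ordered by `abs(rho)` descending.
#' @export
structure_correlations <- function(ensemble) {
  feats <- intersect(feature_names(), names(ensemble))
  if (!length(feats)) abort("ensemble has no feature columns")
  rho <- vapply(feats, function(f)
    suppressWarnings(spearman_rho(ensemble[[f]], ensemble$duration)),
    numeric(1))
  out <- tibble(term = feats, rho = unname(rho))
  out[order(-abs(out$rho)), ]
}
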