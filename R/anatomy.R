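#' Spine-count and working-memory evidence table
#'
#' Basal-dendrite spine counts of layer-2/3 pyramidal neurons in 24 macaque
#' cortical areas, with the numbers of published positive and negative
#' reports of delay-period activity per area and the lobe assignment.
#' Shipped verbatim as packaged data (including the lobe assignments as
#' printed in the source table).
#'
#' @returns Tibble with columns `area`, `spine_count`, `n_positive`,
#'   `n_negative`, `lobe` (24 rows).
#' @examples
#' region_table()
#' @export
region_table <- function() {
  path <- system.file("extdata", "spine_table.csv", package = "wmnet",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_tibble(df)
}

#' Map spine counts to association-area connection probabilities
#'
#' Linear min-max normalization of the spine count onto the probability
#' range (default 15%-25%): the area with the fewest spines gets the lower
#' endpoint, the area with the most the upper endpoint.
#'
#' @param records Tibble with a `spine_count` column (see
#'   [region_table()]).
#' @param range Probability range `c(lo, hi)`.
#' @returns The input with an added `p_E_rec` column.
#' @examples
#' spine_to_probability(region_table())
#' @export
spine_to_probability <- function(records, range = c(0.15, 0.25)) {
  sc <- records$spine_count
  if (any(sc <= 0)) abort("spine counts must be positive")
  if (length(unique(sc)) < 2L)
    abort("need at least two distinct spine counts")
  p <- range[1] + diff(range) * (sc - min(sc)) / (max(sc) - min(sc))
  dplyr::mutate(as_tibble(records), p_E_rec = p)
}

#' Simulated working-memory durations per cortical region
#'
#' For each region, builds association areas whose pyramidal reception
#' probability is the region's spine-mapped value (the sensory area and
#' all other parameters stay at their defaults), runs `n_reps` trials with
#' fresh topology and noise seeds, and returns the duration samples.
#'
#' @param records Output of [spine_to_probability()] (or [region_table()],
#'   mapped internally).
#' @param n_reps Trials per region.
#' @param seed Master seed; per-trial seeds are drawn from it.
#' @param sensory,association Template [area_spec()]s; the association
#'   `p_E_rec` is overridden per region.
#' @param syn,protocol,noise,syn_scale,dt Passed to [run_trial()].
#' @returns Tibble with columns `area`, `p_E_rec`, `rep`, `duration`,
#'   `censored`, `state`.
#' @export
predict_regions <- function(records = region_table(), n_reps = 10,
                            seed = 1,
                            sensory = area_spec("sensory"),
                            association = area_spec("association"),
                            syn = syn_params(),
                            protocol = protocol_spec(),
                            noise = noise_spec(), syn_scale = 1,
                            dt = 0.02) {
  if (n_reps < 1) abort("n_reps must be >= 1")
  if (!"p_E_rec" %in% names(records))
    records <- spine_to_probability(records)
  set.seed(seed)
  tseeds <- matrix(sample.int(2^30, nrow(records) * n_reps),
                   nrow(records), n_reps)
  nseeds <- matrix(sample.int(2^30, nrow(records) * n_reps),
                   nrow(records), n_reps)
  out <- vector("list", nrow(records))
  for (r in seq_len(nrow(records))) {
    assoc <- area_spec("association", N_E = association$N_E,
                       N_I = association$N_I,
                       p_E_rec = records$p_E_rec[r],
                       p_I_rec = association$p_I_rec)
    rows <- vector("list", n_reps)
    for (j in seq_len(n_reps)) {
      net <- build_network(sensory, assoc, seed = tseeds[r, j])
      tr <- run_trial(net, syn = syn, protocol = protocol, noise = noise,
                      seed = nseeds[r, j], dt = dt, syn_scale = syn_scale)
      rows[[j]] <- tibble(area = records$area[r],
                          p_E_rec = records$p_E_rec[r], rep = j,
                          duration = as.numeric(tr$duration),
                          censored = isTRUE(tr$censored),
                          state = as.character(tr$state))
    }
    out[[r]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out)
}

#' Concordance of predictions with published evidence
#'
#' A region is predicted positive when its median simulated duration
#' reaches the persistence threshold; the empirical label is the sign of
#' (positive - negative) evidence counts, `unexplored` when both are zero.
#'
#' @param predictions Output of [predict_regions()].
#' @param records Evidence table (see [region_table()]).
#' @param threshold Persistence threshold in ms; default half of the
#'   largest observed delay cap (i.e. half the delay length for censored
#'   ensembles).
#' @returns Tibble with one row per region: `area`, `lobe`,
#'   `median_duration`, `predicted` (positive/negative), `evidence`
#'   (positive/negative/unexplored/mixed), `label`
#'   (agree/disagree/unexplored).
#' @export
concordance_table <- function(predictions, records = region_table(),
                              threshold = NULL) {
  med <- dplyr::summarise(
    dplyr::group_by(predictions, .data$area),
    median_duration = median(.data$duration), .groups = "drop")
  if (is.null(threshold)) threshold <- max(predictions$duration) / 2
  df <- dplyr::left_join(med,
                         dplyr::select(records, "area", "lobe",
                                       "n_positive", "n_negative"),
                         by = "area")
  df <- dplyr::mutate(
    df,
    predicted = ifelse(.data$median_duration >= threshold,
                       "positive", "negative"),
    evidence = dplyr::case_when(
      .data$n_positive == 0 & .data$n_negative == 0 ~ "unexplored",
      .data$n_positive > .data$n_negative ~ "positive",
      .data$n_negative > .data$n_positive ~ "negative",
      TRUE ~ "mixed"),
    label = dplyr::case_when(
      .data$evidence == "unexplored" ~ "unexplored",
      .data$evidence == "mixed" ~ "mixed",
      .data$predicted == .data$evidence ~ "agree",
      TRUE ~ "disagree"))
  dplyr::select(df, "area", "lobe", "median_duration", "predicted",
                "evidence", "label")
}
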