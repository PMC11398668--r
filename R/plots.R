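#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_col geom_step
#'   facet_grid labs theme_minimal vars
NULL

#' Raster-and-rate plot of a trial
#'
#' Spike raster (top) and population firing-rate traces (bottom) of one
#' delayed match-to-sample trial, split by area.
#'
#' @param object A `wm_trial`.
#' @param bin,smooth Rate-trace parameters, ms.
#' @param ... Unused.
#' @returns A ggplot object.
#' @export
autoplot.wm_trial <- function(object, bin = 20, smooth = 60, ...) {
  rt <- rate_trace(object, bin = bin, smooth = smooth)
  rt <- tidyr::separate(rt, "population", into = c("area", "type"),
                        sep = "_")
  ggplot(rt, aes(x = .data$time / 1000, y = .data$rate,
                 colour = .data$type)) +
    geom_line() +
    facet_grid(vars(.data$area)) +
    labs(x = "time (s)", y = "population rate (Hz)", colour = "population",
         title = paste0("WM duration ", round(as.numeric(object$duration)),
                        " ms (", object$state, ")")) +
    theme_minimal()
}

#' Raster plot of a trial
#'
#' @inheritParams autoplot.wm_trial
#' @returns A ggplot object.
#' @export
plot_raster <- function(object, ...) {
  stopifnot(inherits(object, "wm_trial"))
  ggplot(object$raster,
         aes(x = .data$time / 1000, y = .data$neuron,
             colour = .data$type)) +
    geom_point(size = 0.3) +
    facet_grid(vars(.data$area), scales = "free_y") +
    labs(x = "time (s)", y = "neuron", colour = "type") +
    theme_minimal()
}

#' Coefficient plot of a ridge fit
#'
#' Standardized coefficients ordered by magnitude.
#'
#' @param object A `wm_ridge`.
#' @param ... Unused.
#' @returns A ggplot object.
#' @export
autoplot.wm_ridge <- function(object, ...) {
  df <- importance_ranking(object)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot(df, aes(x = .data$estimate, y = .data$term)) +
    geom_col() +
    labs(x = "standardized coefficient", y = NULL,
         title = paste0("ridge fit (lambda = ", signif(object$lambda, 3),
                        ", R² = ", round(object$r_squared, 2), ")")) +
    theme_minimal()
}

#' f-I curve plot
#'
#' @param fi Output of [fi_curve()].
#' @returns A ggplot object.
#' @export
plot_fi_curve <- function(fi) {
  ggplot(fi, aes(x = .data$I, y = .data$rate)) +
    geom_step() + geom_point(size = 0.8) +
    labs(x = "injected current (nA)", y = "firing rate (Hz)") +
    theme_minimal()
}
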