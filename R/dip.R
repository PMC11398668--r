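#' Dip statistic of unimodality
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical cdf and the set of unimodal distribution functions (convex
#' below the mode, concave above, with an atom permitted at the mode).
#'
#' Computed here from the band characterization of the problem: for a
#' candidate mode position, a unimodal cdf within distance d of the
#' empirical cdf exists iff the convex (left) and concave (right) parts can
#' be threaded through the +/- d bands around the empirical cdf, which
#' reduces to chord conditions over ordered triples of support points plus
#' per-point jump conditions; the dip is the minimum over mode positions
#' (between points and at points) of the smallest feasible d.
#'
#' For n distinct observations the dip is at least 1/(2n), with equality
#' for perfectly "flat" (e.g. equispaced) samples.
#'
#' @param x Numeric sample (length >= 1).
#' @returns The dip statistic (a number in `[0, 0.25]`).
#' @examples
#' dip_stat(c(0, 1))           # 0.25, the maximal dip
#' dip_stat(seq(0, 1, 0.1))    # 1/(2n)
#' @export
dip_stat <- function(x) {
  x <- sort(as.numeric(x[is.finite(x)]))
  n <- length(x)
  if (n < 1L) abort("need at least one finite observation")
  u <- unique(x)
  m <- length(u)
  if (m == 1L) return(0)
  Fv <- cumsum(tabulate(match(x, u), nbins = m)) / n   # F at each point
  Fp <- c(0, Fv[-m])                                   # F just below
  jumps <- (Fv - Fp) / 2

  # LT[l]: largest left-side (convex) chord violation over triples i<j<l
  # RT[i]: largest right-side (concave) violation over triples i<j<l
  LT <- rep(-Inf, m)
  RT <- rep(-Inf, m)
  if (m >= 3) for (l in 3:m) {
    i <- 1:(l - 2)
    best <- -Inf
    for (j in 2:(l - 1)) {
      ii <- i[i < j]
      chord <- (Fp[ii] * (u[l] - u[j]) + Fp[l] * (u[j] - u[ii])) /
        (u[l] - u[ii])
      v <- (Fv[j] - chord) / 2
      best <- max(best, v)
    }
    LT[l] <- best
  }
  if (m >= 3) for (i in 1:(m - 2)) {
    best <- -Inf
    for (j in (i + 1):(m - 1)) {
      ll <- (j + 1):m
      chord <- (Fv[i] * (u[ll] - u[j]) + Fv[ll] * (u[j] - u[i])) /
        (u[ll] - u[i])
      v <- (chord - Fp[j]) / 2
      best <- max(best, v)
    }
    RT[i] <- best
  }
  cumLT <- cummax(LT)                     # max LT[3..a] at index a
  cumRT <- rev(cummax(rev(RT)))           # max RT[a..m-2] at index a
  cumJL <- cummax(jumps)                  # max jump among 1..a
  cumJR <- rev(cummax(rev(jumps)))        # max jump among a..m
  maxLT <- function(a) if (a >= 3) cumLT[min(a, m)] else 0
  maxRT <- function(a) if (a <= m - 2) cumRT[max(a, 1)] else 0
  floorsL <- function(a) if (a >= 1) cumJL[min(a, m)] else 0
  floorsR <- function(a) if (a <= m) cumJR[max(a, 1)] else 0

  best <- Inf
  # mode in the open interval after point k (k = 0..m): left part covers
  # points 1..k (chord outer ends may extend to k+1), right part covers
  # k+1..m (outer ends may extend down to k)
  for (k in 0:m) {
    dl <- max(floorsL(k), maxLT(k + 1))
    dr <- max(floorsR(k + 1), maxRT(k))
    best <- min(best, max(dl, dr))
  }
  # mode exactly at point t: the jump at t is absorbed by the mode atom
  for (t in 1:m) {
    dl <- max(floorsL(t - 1), maxLT(t))
    dr <- max(floorsR(t + 1), maxRT(t))
    best <- min(best, max(dl, dr))
  }
  max(best, 0)
}

#' Dip test of unimodality
#'
#' Monte-Carlo calibrated test: the observed [dip_stat()] is compared with
#' the dips of `B` uniform samples of the same size (the dip is invariant
#' to monotone location/scale, and the uniform is the conventional least
#' favourable unimodal null).
#'
#' @param x Numeric sample.
#' @param B Number of Monte-Carlo null samples.
#' @param seed Optional seed for the null simulation.
#' @returns A list of class `dip_test` with elements `statistic`,
#'   `p.value`, `n`, `B`.
#' @examples
#' set.seed(1)
#' bimodal <- c(rnorm(50), rnorm(50, 6))
#' dip_test(bimodal, B = 100, seed = 1)$p.value
#' @export
dip_test <- function(x, B = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) abort("need at least four observations")
  d0 <- dip_stat(x)
  null <- vapply(seq_len(B), function(b) dip_stat(runif(n)), numeric(1))
  p <- (1 + sum(null >= d0)) / (B + 1)
  structure(list(statistic = d0, p.value = p, n = n, B = B),
            class = "dip_test")
}

#' @export
print.dip_test <- function(x, ...) {
  cat("Dip test of unimodality: D = ", signif(x$statistic, 4),
      ", p = ", signif(x$p.value, 3), " (n = ", x$n, ", ", x$B,
      " Monte-Carlo null samples)\n", sep = "")
  invisible(x)
}
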