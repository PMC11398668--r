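#' @name graph_metrics
#' @title Structural metrics of the recurrent network
#'
#' @description
#' The adjacency convention throughout is `M[i, j] = 1` iff neuron j is
#' presynaptic to neuron i (row = receiver); node labels are `"E"`
#' (pyramidal) or `"I"` (interneuron). Metrics are computed on the entire
#' network, on the excitatory subnetwork (the subgraph induced by the
#' pyramidal cells), or - for counts - on the "inhibitory-involved"
#' complement defined by subtraction (entire minus excitatory).
NULL

check_adj <- function(M, zero_diag = FALSE) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) abort("M must be square")
  if (!all(M %in% c(0L, 1L))) abort("M must be binary")
  if (zero_diag && any(diag(M) != 0)) abort("M must have a zero diagonal")
  invisible(M)
}

check_labels <- function(M, labels) {
  if (length(labels) != nrow(M))
    abort("labels length does not match adjacency dimension")
  if (!all(labels %in% c("E", "I"))) abort("labels must be 'E' or 'I'")
  invisible(labels)
}

# igraph object with edges in signal direction (presynaptic -> receiver)
as_igraph <- function(M) {
  igraph::graph_from_adjacency_matrix(t(M), mode = "directed")
}

#' Average shortest path length
#'
#' Mean directed shortest-path length over ordered reachable pairs
#' (i != j); unreachable pairs are excluded from the mean and counted in
#' the `"n_unreachable"` attribute. `NA` (with a warning) when no pair is
#' reachable.
#'
#' @param M Binary adjacency matrix (row = receiver).
#' @returns Mean path length with attribute `n_unreachable`.
#' @examples
#' ring <- diag(4)[c(2, 3, 4, 1), ]  # directed 4-ring
#' avg_shortest_path(ring)           # 2
#' @export
avg_shortest_path <- function(M) {
  check_adj(M)
  D <- igraph::distances(as_igraph(M), mode = "out")
  off <- D[row(D) != col(D)]
  reach <- is.finite(off)
  if (!any(reach)) {
    warn("no reachable ordered pairs; average path length undefined")
    return(structure(NA_real_, n_unreachable = sum(!reach)))
  }
  structure(mean(off[reach]), n_unreachable = sum(!reach))
}

#' Average clustering coefficient
#'
#' Local clustering on the undirected projection (an undirected edge exists
#' if a connection exists in either direction):
#' `Cc_i = 2 E_i / (k_i (k_i - 1))` with `E_i` the number of edges among
#' the neighbours of i, set to 0 for nodes with fewer than two neighbours;
#' the network value is the mean over all nodes.
#'
#' @inheritParams avg_shortest_path
#' @returns Mean clustering coefficient in `[0, 1]`.
#' @export
avg_clustering <- function(M) {
  check_adj(M)
  U <- (M + t(M)) > 0
  diag(U) <- FALSE
  storage.mode(U) <- "integer"
  k <- rowSums(U)
  tri2 <- diag(U %*% U %*% U)      # 2 * E_i
  cc <- ifelse(k >= 2, tri2 / (k * (k - 1)), 0)
  mean(cc)
}

#' Block edge counts of the E/I partition
#'
#' Total numbers of edges in the four ordered source-class to target-class
#' blocks.
#'
#' @inheritParams avg_shortest_path
#' @param labels `"E"`/`"I"` node labels.
#' @returns Named numeric vector `d_EtoE`, `d_EtoI`, `d_ItoE`, `d_ItoI`.
#' @export
degree_blocks <- function(M, labels) {
  check_adj(M)
  check_labels(M, labels)
  E <- labels == "E"
  c(d_EtoE = sum(M[E, E, drop = FALSE]),
    d_EtoI = sum(M[!E, E, drop = FALSE]),
    d_ItoE = sum(M[E, !E, drop = FALSE]),
    d_ItoI = sum(M[!E, !E, drop = FALSE]))
}

#' Excitation-inhibition balance factor
#'
#' `(d_EtoE + d_ItoI) / (d_EtoI + d_ItoE)`: within-class edge counts over
#' between-class edge counts.
#'
#' @param blocks Named vector as returned by [degree_blocks()], or four
#'   numbers in that order.
#' @returns The balance factor; `NA` with a warning when the between-class
#'   count is zero.
#' @export
ei_balance_factor <- function(blocks) {
  blocks <- as.numeric(blocks)
  if (length(blocks) != 4L) abort("blocks must have four entries")
  den <- blocks[2] + blocks[3]
  if (den == 0) {
    warn("no between-class edges; E/I balance factor undefined")
    return(NA_real_)
  }
  (blocks[1] + blocks[4]) / den
}

#' Excitatory input fraction per node
#'
#' `P_i = k_i^E / (k_i^E + k_i^I)` with `k^E`/`k^I` the numbers of
#' excitatory/inhibitory afferents; `NA` for nodes with no input.
#'
#' @inheritParams degree_blocks
#' @returns Numeric vector of fractions in `[0, 1]` (or `NA`).
#' @export
excitatory_input_fraction <- function(M, labels) {
  check_adj(M)
  check_labels(M, labels)
  kE <- rowSums(M[, labels == "E", drop = FALSE])
  kI <- rowSums(M[, labels == "I", drop = FALSE])
  ifelse(kE + kI > 0, kE / (kE + kI), NA_real_)
}

#' Hub proportions and the rich-hub factor
#'
#' A node is a hub when its excitatory input fraction strictly exceeds the
#' threshold. `P_E_hub`/`P_I_hub` are the hub fractions among pyramidal
#' cells and interneurons; `F_richhub` is their ratio. Nodes with undefined
#' input fraction are excluded from numerator and denominator.
#'
#' @param P Vector of excitatory input fractions
#'   (see [excitatory_input_fraction()]).
#' @param labels `"E"`/`"I"` node labels.
#' @param threshold Hub threshold (strict inequality).
#' @param inhibitory_hubs `"excitatory_input"` scores interneuron hubs by
#'   the same excitatory-input fraction as pyramidal cells (the printed
#'   definition); `"inhibitory_input"` scores them by `1 - P` instead (the
#'   alternative reading in which an "inhibited hub" is a strongly
#'   inhibition-driven interneuron).
#' @returns Named vector `P_E_hub`, `P_I_hub`, `F_richhub` (`F_richhub` is
#'   `NA` with a warning when `P_I_hub` is zero).
#' @export
hub_measures <- function(P, labels, threshold = 0.80,
                         inhibitory_hubs = c("excitatory_input",
                                             "inhibitory_input")) {
  if (length(P) != length(labels)) abort("P and labels lengths differ")
  inhibitory_hubs <- match.arg(inhibitory_hubs)
  hub <- P > threshold
  if (inhibitory_hubs == "inhibitory_input")
    hub[labels == "I"] <- (1 - P[labels == "I"]) > threshold
  pe <- mean(hub[labels == "E"], na.rm = TRUE)
  pi_ <- mean(hub[labels == "I"], na.rm = TRUE)
  f <- if (is.na(pi_) || pi_ == 0) {
    warn("no inhibitory hubs; rich-hub factor undefined")
    NA_real_
  } else pe / pi_
  c(P_E_hub = pe, P_I_hub = pi_, F_richhub = f)
}

#' Directed 3-cycle count
#'
#' Number of directed cycles through three distinct nodes,
#' `trace(M^3) / 3`, on the requested node-induced view.
#'
#' @inheritParams degree_blocks
#' @param view `"entire"` or `"excitatory"` (subgraph induced by E nodes;
#'   requires `labels`).
#' @returns Integer count.
#' @examples
#' tri <- matrix(0, 3, 3); tri[2, 1] <- tri[3, 2] <- tri[1, 3] <- 1
#' count_3cycles(tri)  # 1
#' @export
count_3cycles <- function(M, view = c("entire", "excitatory"),
                          labels = NULL) {
  check_adj(M, zero_diag = TRUE)
  view <- match.arg(view)
  if (view == "excitatory") {
    check_labels(M, labels)
    M <- M[labels == "E", labels == "E", drop = FALSE]
  }
  storage.mode(M) <- "double"
  round(sum(diag(M %*% M %*% M)) / 3)
}

#' Directed 4-cycle count
#'
#' Number of directed cycles through four distinct nodes, computed from
#' `trace(M^4)` after removing degenerate closed 4-walks (back-and-forth
#' traversals of reciprocal pairs): with `r_i` the number of reciprocal
#' partners of node i, `C4 = (trace(M^4) - 2 sum r_i^2 + sum r_i) / 4`.
#'
#' @inheritParams count_3cycles
#' @returns Integer count.
#' @export
count_4cycles <- function(M, view = c("entire", "excitatory"),
                          labels = NULL) {
  check_adj(M, zero_diag = TRUE)
  view <- match.arg(view)
  if (view == "excitatory") {
    check_labels(M, labels)
    M <- M[labels == "E", labels == "E", drop = FALSE]
  }
  storage.mode(M) <- "double"
  M2 <- M %*% M
  r <- diag(M2)                      # reciprocal partners per node
  tr4 <- sum(diag(M2 %*% M2))
  round((tr4 - 2 * sum(r^2) + sum(r)) / 4)
}

# ---- triad motif census ----------------------------------------------------

# The 13 weakly connected 3-node digraph classes, numbered by edge count
# and, within the 3- and 4-edge groups, so that the cyclic classes are
# motifs 7 (the directed 3-cycle) and 10 (reciprocal pair closed through
# the third node). A[x, y] = 1 iff x -> y on nodes 1..3.
motif_representatives <- function() {
  e <- function(...) {
    A <- matrix(0L, 3, 3)
    for (p in list(...)) A[p[1], p[2]] <- 1L
    A
  }
  list(
    e(c(2, 1), c(2, 3)),                          # 1 divergence
    e(c(1, 2), c(3, 2)),                          # 2 convergence
    e(c(1, 2), c(2, 3)),                          # 3 chain
    e(c(1, 2), c(2, 1), c(2, 3)),                 # 4 reciprocal + out
    e(c(1, 2), c(2, 1), c(3, 2)),                 # 5 reciprocal + in
    e(c(1, 2), c(1, 3), c(2, 3)),                 # 6 feedforward loop
    e(c(1, 2), c(2, 3), c(3, 1)),                 # 7 3-cycle
    e(c(1, 2), c(2, 1), c(1, 3), c(2, 3)),        # 8 reciprocal drives third
    e(c(1, 2), c(2, 1), c(3, 1), c(3, 2)),        # 9 third drives reciprocal
    e(c(1, 2), c(2, 1), c(1, 3), c(3, 2)),        # 10 reciprocal + cycle
    e(c(1, 2), c(2, 1), c(2, 3), c(3, 2)),        # 11 two reciprocal pairs
    e(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3)),  # 12 complete minus one
    e(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))  # 13 complete
  )
}

triad_code <- function(A) {
  # bits for edges (1,2),(2,1),(1,3),(3,1),(2,3),(3,2)
  A[1, 2] + 2L * A[2, 1] + 4L * A[1, 3] + 8L * A[3, 1] +
    16L * A[2, 3] + 32L * A[3, 2]
}

triad_canonical <- function(A) {
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  min(vapply(perms, function(p) triad_code(A[p, p]), integer(1)))
}

motif_env <- new.env(parent = emptyenv())

# lookup table: 6-bit edge code -> motif class (0 = not weakly connected)
motif_class_table <- function() {
  if (!is.null(motif_env$table)) return(motif_env$table)
  canon <- vapply(motif_representatives(), triad_canonical, integer(1))
  tab <- integer(64)
  for (code in 0:63) {
    A <- matrix(0L, 3, 3)
    bits <- bitwAnd(code, c(1L, 2L, 4L, 8L, 16L, 32L)) > 0
    A[rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))] <-
      as.integer(bits)
    U <- (A + t(A)) > 0
    connected <- all(rowSums(U) + colSums(U) > 0) && sum(U) / 2 >= 2
    tab[code + 1L] <- if (connected) match(triad_canonical(A), canon) else 0L
  }
  stopifnot(!anyNA(tab))
  motif_env$table <- tab
  tab
}

census_one <- function(M) {
  n <- nrow(M)
  counts <- integer(13)
  if (n < 3) return(counts)
  trip <- utils::combn(n, 3)
  a <- trip[1, ]; b <- trip[2, ]; c_ <- trip[3, ]
  # A[x, y] = 1 iff x -> y; M is receiver-row, so x -> y is M[y, x]
  code <- M[cbind(b, a)] + 2L * M[cbind(a, b)] + 4L * M[cbind(c_, a)] +
    8L * M[cbind(a, c_)] + 16L * M[cbind(c_, b)] + 32L * M[cbind(b, c_)]
  cls <- motif_class_table()[code + 1L]
  cls <- cls[cls > 0L]
  counts[seq_len(13)] <- tabulate(cls, nbins = 13L)
  counts
}

#' Triad motif census
#'
#' Classifies every weakly connected unordered node triple into one of the
#' 13 connected 3-node digraph classes, for the entire network and for the
#' excitatory subnetwork; the inhibitory-involved census is the class-wise
#' difference. `F_motif` is the class-wise ratio
#' excitatory / inhibitory-involved.
#'
#' @inheritParams degree_blocks
#' @param labels `"E"`/`"I"` labels; when omitted only the entire view is
#'   returned.
#' @returns A tibble with columns `motif` (1-13), `entire`, and (with
#'   labels) `excitatory`, `inhibitory_involved`, `F_motif`.
#' @examples
#' M <- matrix(0L, 3, 3); M[2, 1] <- M[3, 2] <- M[1, 3] <- 1L
#' motif_census(M)  # one motif-7 (3-cycle) triad
#' @export
motif_census <- function(M, labels = NULL) {
  check_adj(M, zero_diag = TRUE)
  entire <- census_one(M)
  out <- tibble(motif = 1:13, entire = entire)
  if (!is.null(labels)) {
    check_labels(M, labels)
    E <- labels == "E"
    exc <- census_one(M[E, E, drop = FALSE])
    inh <- entire - exc
    out$excitatory <- exc
    out$inhibitory_involved <- inh
    out$F_motif <- ifelse(inh > 0, exc / inh, NA_real_)
  }
  out
}

#' The seventeen structural variables
#'
#' Assembles the full feature vector used in the structure-function
#' analyses, in a fixed documented order: the four E/I block edge counts
#' and their balance factor; the two hub proportions and the rich-hub
#' factor; the excitatory and inhibitory-involved 3-cycle counts and their
#' ratio; and the entire/excitatory/ratio versions of the clustering
#' coefficient and the average shortest path length. Undefined values
#' (zero denominators, unreachable graphs) propagate as `NA`.
#'
#' @inheritParams degree_blocks
#' @param hub_threshold Threshold for [hub_measures()].
#' @returns A one-row tibble with 17 columns: `d_EtoE`, `d_EtoI`, `d_ItoE`,
#'   `d_ItoI`, `F_EI`, `P_E_hub`, `P_I_hub`, `F_richhub`, `C3_E`, `C3_inh`,
#'   `F_cycle`, `Cc_all`, `Cc_E`, `R_Cc`, `L_all`, `L_E`, `R_L`.
#' @examples
#' net <- build_network(seed = 1)
#' lb <- with(net$labels, type[area == "association"])
#' feature_vector(net$M_association, lb)
#' @export
feature_vector <- function(M, labels, hub_threshold = 0.80) {
  check_adj(M, zero_diag = TRUE)
  check_labels(M, labels)
  E <- labels == "E"
  blocks <- degree_blocks(M, labels)
  F_EI <- suppressWarnings(ei_balance_factor(blocks))
  P <- excitatory_input_fraction(M, labels)
  hubs <- suppressWarnings(hub_measures(P, labels, hub_threshold))
  c3_all <- count_3cycles(M)
  c3_E <- count_3cycles(M, "excitatory", labels)
  c3_inh <- c3_all - c3_E
  F_cycle <- if (c3_inh > 0) c3_E / c3_inh else NA_real_
  ME <- M[E, E, drop = FALSE]
  Cc_all <- avg_clustering(M)
  Cc_E <- avg_clustering(ME)
  L_all <- suppressWarnings(as.numeric(avg_shortest_path(M)))
  L_E <- suppressWarnings(as.numeric(avg_shortest_path(ME)))
  tibble(d_EtoE = unname(blocks[1]), d_EtoI = unname(blocks[2]),
         d_ItoE = unname(blocks[3]), d_ItoI = unname(blocks[4]),
         F_EI = F_EI,
         P_E_hub = unname(hubs[1]), P_I_hub = unname(hubs[2]),
         F_richhub = unname(hubs[3]),
         C3_E = c3_E, C3_inh = c3_inh, F_cycle = F_cycle,
         Cc_all = Cc_all, Cc_E = Cc_E,
         R_Cc = if (!is.na(Cc_all) && Cc_all > 0) Cc_E / Cc_all else NA_real_,
         L_all = L_all, L_E = L_E,
         R_L = if (!is.na(L_all) && !is.na(L_E) && L_all > 0) L_E / L_all
               else NA_real_)
}

#' Names of the seventeen structural variables
#' @returns Character vector of length 17 in feature-vector order.
#' @export
feature_names <- function() {
  c("d_EtoE", "d_EtoI", "d_ItoE", "d_ItoI", "F_EI", "P_E_hub", "P_I_hub",
    "F_richhub", "C3_E", "C3_inh", "F_cycle", "Cc_all", "Cc_E", "R_Cc",
    "L_all", "L_E", "R_L")
}
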