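#' Cortical area specification
#'
#' Population sizes and reception probabilities of one area. Connectivity is
#' defined from the receiver's side: a pyramidal cell receives each possible
#' afferent independently with probability `p_E_rec` (5% in the sensory
#' area, 20% in the association area by default), an interneuron with
#' probability `p_I_rec` (20% within either area).
#'
#' @param name `"sensory"` or `"association"`; sets the default `p_E_rec`.
#' @param N_E,N_I Numbers of pyramidal cells and interneurons.
#' @param p_E_rec Reception probability of pyramidal cells.
#' @param p_I_rec Reception probability of interneurons (intra-area).
#' @returns An object of class `area_spec`.
#' @examples
#' area_spec("sensory")
#' area_spec("association", p_E_rec = 0.25)
#' @export
area_spec <- function(name = c("sensory", "association"), N_E = 80, N_I = 20,
                      p_E_rec = NULL, p_I_rec = 0.20) {
  name <- match.arg(name)
  if (is.null(p_E_rec)) p_E_rec <- if (name == "sensory") 0.05 else 0.20
  if (N_E < 1 || N_I < 1) abort("N_E and N_I must be positive")
  for (p in c(p_E_rec, p_I_rec))
    if (!is.numeric(p) || p < 0 || p > 1)
      abort("probabilities must lie in [0, 1]")
  structure(list(name = name, N_E = as.integer(N_E), N_I = as.integer(N_I),
                 p_E_rec = p_E_rec, p_I_rec = p_I_rec),
            class = "area_spec")
}

area_labels <- function(area) {
  rep(c("E", "I"), c(area$N_E, area$N_I))
}

#' Within-area recurrent adjacency matrix
#'
#' Entry `[i, j] = 1` means neuron j is presynaptic to neuron i (row =
#' receiver). Each potential edge j -> i (j != i) is present independently
#' with the receiver's reception probability; the diagonal is zero (no
#' autapses). The first `N_E` indices are pyramidal cells, the rest
#' interneurons (stored in the `"labels"` attribute).
#'
#' @param area An [area_spec()].
#' @param seed Optional integer seed for reproducibility.
#' @returns A binary integer matrix with a `"labels"` attribute.
#' @examples
#' M <- build_intra(area_spec("association"), seed = 1)
#' mean(rowSums(M)[1:80])  # close to 0.20 * 99
#' @export
build_intra <- function(area, seed = NULL) {
  stopifnot(inherits(area, "area_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- area$N_E + area$N_I
  p_row <- rep(c(area$p_E_rec, area$p_I_rec), c(area$N_E, area$N_I))
  M <- matrix(rbinom(n * n, 1L, rep(p_row, times = n)), n, n)
  diag(M) <- 0L
  storage.mode(M) <- "integer"
  attr(M, "labels") <- area_labels(area)
  M
}

#' Between-area adjacency matrix
#'
#' Feedforward (sensory to association) projections arise from sensory
#' pyramidal cells and target association pyramidal cells only, received
#' with the association pyramidal probability. Feedback (association to
#' sensory) projections arise from association pyramidal cells and target
#' both sensory populations, received with probability 5%. Interneurons
#' never project across areas.
#'
#' @param source,target [area_spec()] objects; the pairing must match the
#'   direction (feedforward: sensory -> association; feedback the reverse).
#' @param direction `"feedforward"` or `"feedback"`.
#' @param p_fb Reception probability of both sensory populations for
#'   feedback projections.
#' @param seed Optional integer seed.
#' @returns Binary integer matrix, rows = target-area neurons (receivers),
#'   columns = source-area neurons.
#' @export
build_inter <- function(source, target,
                        direction = c("feedforward", "feedback"),
                        p_fb = 0.05, seed = NULL) {
  stopifnot(inherits(source, "area_spec"), inherits(target, "area_spec"))
  direction <- match.arg(direction)
  ok <- (direction == "feedforward" && source$name == "sensory" &&
           target$name == "association") ||
    (direction == "feedback" && source$name == "association" &&
       target$name == "sensory")
  if (!ok)
    abort("direction inconsistent with area names (feedforward: sensory -> association)")
  if (!is.null(seed)) set.seed(seed)
  n_src <- source$N_E + source$N_I
  n_tgt <- target$N_E + target$N_I
  M <- matrix(0L, n_tgt, n_src)
  if (direction == "feedforward") {
    # source E -> target E at the target's pyramidal reception probability
    M[seq_len(target$N_E), seq_len(source$N_E)] <-
      rbinom(target$N_E * source$N_E, 1L, target$p_E_rec)
  } else {
    # source E -> target E and I, both at p_fb
    M[, seq_len(source$N_E)] <- rbinom(n_tgt * source$N_E, 1L, p_fb)
  }
  storage.mode(M) <- "integer"
  attr(M, "dimnames_roles") <- c("receiver", "source")
  M
}

#' Build the full two-area network
#'
#' Draws the two within-area recurrent matrices and the two between-area
#' matrices from a single topology seed and assembles them into the
#' whole-network block form used by the simulator. Global neuron indexing:
#' sensory E, sensory I, association E, association I.
#'
#' @param sensory,association [area_spec()] objects.
#' @param seed Topology seed (integer).
#' @param p_fb Feedback reception probability.
#' @returns An object of class `wm_network`: list with the per-area
#'   recurrent matrices, the feedforward/feedback matrices, the combined
#'   `M_rec` and `M_ext` (N x N, N = total neurons), and a `labels` tibble
#'   (`id`, `area`, `type`).
#' @examples
#' net <- build_network(seed = 1)
#' net$labels
#' @export
build_network <- function(sensory = area_spec("sensory"),
                          association = area_spec("association"),
                          seed = NULL, p_fb = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  M_s <- build_intra(sensory)
  M_a <- build_intra(association)
  ff <- build_inter(sensory, association, "feedforward")
  fb <- build_inter(association, sensory, "feedback", p_fb = p_fb)
  n_s <- sensory$N_E + sensory$N_I
  n_a <- association$N_E + association$N_I
  N <- n_s + n_a
  M_rec <- matrix(0L, N, N)
  M_rec[seq_len(n_s), seq_len(n_s)] <- M_s
  M_rec[n_s + seq_len(n_a), n_s + seq_len(n_a)] <- M_a
  M_ext <- matrix(0L, N, N)
  M_ext[n_s + seq_len(n_a), seq_len(n_s)] <- ff   # sensory -> association
  M_ext[seq_len(n_s), n_s + seq_len(n_a)] <- fb   # association -> sensory
  labels <- tibble(
    id = seq_len(N),
    area = rep(c("sensory", "association"), c(n_s, n_a)),
    type = c(area_labels(sensory), area_labels(association)))
  structure(list(sensory = sensory, association = association,
                 M_sensory = M_s, M_association = M_a,
                 ff = ff, fb = fb, M_rec = M_rec, M_ext = M_ext,
                 labels = labels, seed = seed),
            class = "wm_network")
}

#' @export
print.wm_network <- function(x, ...) {
  cat("<wm_network> ", nrow(x$M_rec), " neurons (sensory ",
      x$sensory$N_E, "E/", x$sensory$N_I, "I, association ",
      x$association$N_E, "E/", x$association$N_I, "I), ",
      sum(x$M_rec), " recurrent + ", sum(x$M_ext),
      " cross-area edges\n", sep = "")
  invisible(x)
}

#' Write / read a labelled adjacency matrix
#'
#' Dense whitespace-delimited text format: a first line `# labels: E E ...`
#' followed by the 0/1 matrix rows.
#'
#' @param M Binary matrix with a `"labels"` attribute (or `labels` given).
#' @param path File path.
#' @param labels Optional character vector of node labels (`"E"`/`"I"`).
#' @returns `read_adjacency()` returns the matrix with its `"labels"`
#'   attribute restored; `write_adjacency()` returns `path` invisibly.
#' @export
write_adjacency <- function(M, path, labels = attr(M, "labels")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(labels))
    writeLines(paste("# labels:", paste(labels, collapse = " ")), con)
  utils::write.table(M, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  first <- readLines(path, n = 1L)
  labels <- NULL
  skip <- 0L
  if (startsWith(first, "# labels:")) {
    labels <- strsplit(trimws(sub("# labels:", "", first)), "\\s+")[[1]]
    skip <- 1L
  }
  M <- as.matrix(utils::read.table(path, skip = skip))
  dimnames(M) <- NULL
  storage.mode(M) <- "integer"
  if (!all(M %in% c(0L, 1L))) abort("adjacency file must be binary")
  attr(M, "labels") <- labels
  M
}

#' Write / read an edge list
#'
#' Three-column TSV (`pre`, `post`, `tag`) plus a `# nodes:` header line
#' carrying the node count and labels, so empty rows/columns round-trip.
#'
#' @inheritParams write_adjacency
#' @param tag Character scalar stored in the third column.
#' @export
write_edge_list <- function(M, path, labels = attr(M, "labels"),
                            tag = "rec") {
  idx <- which(M == 1L, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# nodes: ", nrow(M),
                    if (!is.null(labels))
                      paste0(" labels: ", paste(labels, collapse = " "))), con)
  writeLines("pre\tpost\ttag", con)
  if (nrow(idx))
    utils::write.table(
      data.frame(pre = idx[, 2], post = idx[, 1], tag = tag),
      con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# nodes:")) abort("missing '# nodes:' header")
  body <- sub("# nodes:\\s*", "", first)
  n <- as.integer(strsplit(trimws(body), "\\s+")[[1]][1])
  labels <- NULL
  if (grepl("labels:", body))
    labels <- strsplit(trimws(sub(".*labels:", "", body)), "\\s+")[[1]]
  df <- utils::read.table(path, skip = 2L, sep = "\t",
                          col.names = c("pre", "post", "tag"))
  M <- matrix(0L, n, n)
  if (nrow(df)) M[cbind(df$post, df$pre)] <- 1L
  attr(M, "labels") <- labels
  M
}
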