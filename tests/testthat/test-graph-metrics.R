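ring4 <- local({
  M <- matrix(0L, 4, 4)
  for (i in 1:4) M[i %% 4 + 1, i] <- 1L  # i -> i+1, receiver-row
  M
})
complete_digraph <- function(n) {
  M <- matrix(1L, n, n); diag(M) <- 0L; M
}

test_that("average shortest path length: closed forms and BFS oracle", {
  expect_equal(as.numeric(avg_shortest_path(ring4)), 2)
  expect_equal(as.numeric(avg_shortest_path(complete_digraph(5))), 1)
  set.seed(1)
  for (rep in 1:20) {
    M <- random_digraph(12, runif(1, 0.1, 0.5))
    got <- avg_shortest_path(M)
    ora <- oracle_spl_bfs(M)
    if (is.na(ora$mean)) {
      expect_warning(avg_shortest_path(M))
    } else {
      expect_equal(as.numeric(got), ora$mean)
      expect_equal(attr(got, "n_unreachable"), ora$n_unreachable)
    }
  }
  expect_warning(avg_shortest_path(matrix(0L, 3, 3)), "unreachable|undefined")
})

test_that("clustering coefficient: closed forms and triangle oracle", {
  expect_equal(avg_clustering(complete_digraph(6)), 1)
  star <- matrix(0L, 5, 5); star[1, 2:5] <- 1L   # hub receives from leaves
  expect_equal(avg_clustering(star), 0)
  set.seed(2)
  for (rep in 1:20) {
    M <- random_digraph(12, runif(1, 0.1, 0.6))
    expect_equal(avg_clustering(M), oracle_clustering(M))
  }
})

test_that("block edge counts partition the network", {
  labels <- rep(c("E", "I"), c(80, 20))
  b <- degree_blocks(complete_digraph(100), labels)
  expect_equal(unname(b["d_EtoE"]), 80 * 79)
  expect_equal(unname(b["d_EtoI"]), 20 * 80)
  expect_equal(unname(b["d_ItoE"]), 80 * 20)
  expect_equal(unname(b["d_ItoI"]), 20 * 19)
  expect_equal(sum(degree_blocks(matrix(0L, 5, 5), rep(c("E","I"), c(3,2)))), 0)
  set.seed(3)
  M <- random_digraph(30)
  lb <- sample(c("E", "I"), 30, replace = TRUE)
  expect_equal(sum(degree_blocks(M, lb)), sum(M))
  expect_error(degree_blocks(M, lb[-1]), "length")
})

test_that("E/I balance factor from block counts", {
  expect_equal(ei_balance_factor(c(10, 5, 5, 10)), 2)
  expect_equal(ei_balance_factor(c(0, 3, 4, 0)), 0)
  # complete digraph with 80/20 split: 6700 / 3160
  b <- degree_blocks(complete_digraph(100), rep(c("E", "I"), c(80, 20)))
  expect_equal(ei_balance_factor(b), (6320 + 380) / (1600 + 1600))
  expect_warning(f <- ei_balance_factor(c(1, 0, 0, 1)), "undefined")
  expect_true(is.na(f))
})

test_that("excitatory input fraction and hub measures", {
  M <- matrix(0L, 5, 5)
  M[1, 2:5] <- 1L
  lb <- c("E", "E", "E", "I", "I")
  P <- excitatory_input_fraction(M, lb)
  expect_equal(P[1], 2 / 4)          # k_E = 2, k_I = 2
  expect_true(all(is.na(P[2:5])))    # no inputs
  h <- hub_measures(c(1, 1, 1, 1, 1), lb)
  expect_equal(unname(h), c(1, 1, 1))
  # threshold is strict: exactly 0.8 is not a hub
  h2 <- hub_measures(c(0.8, 0.81, 1, 0.8, 0.9), lb)
  expect_equal(unname(h2["P_E_hub"]), 2 / 3)
  expect_equal(unname(h2["P_I_hub"]), 1 / 2)
  expect_warning(h3 <- hub_measures(c(1, 1, 1, 0.1, 0.2), lb), "undefined")
  expect_true(is.na(h3["F_richhub"]))
  # alternative interneuron-hub reading: scored by inhibitory input
  # (strict threshold: 1 - 0.2 = 0.8 exactly is not a hub)
  h4 <- hub_measures(c(1, 1, 1, 0.1, 0.2), lb,
                     inhibitory_hubs = "inhibitory_input")
  expect_equal(unname(h4["P_I_hub"]), 1 / 2)
  # random instance against exhaustive per-node check
  set.seed(4)
  M <- random_digraph(15, 0.4)
  lb <- sample(c("E", "I"), 15, replace = TRUE, prob = c(0.7, 0.3))
  P <- excitatory_input_fraction(M, lb)
  for (i in 1:15) {
    kE <- sum(M[i, lb == "E"]); kI <- sum(M[i, lb == "I"])
    if (kE + kI == 0) expect_true(is.na(P[i]))
    else expect_equal(P[i], kE / (kE + kI))
  }
})

test_that("3-cycle and 4-cycle counts equal enumeration oracles", {
  tri <- matrix(0L, 3, 3); tri[2, 1] <- tri[3, 2] <- tri[1, 3] <- 1L
  expect_equal(count_3cycles(tri), 1)
  expect_equal(count_3cycles(complete_digraph(3)), 2)
  set.seed(5)
  for (rep in 1:20) {
    M <- random_digraph(10, runif(1, 0.1, 0.6))
    expect_equal(count_3cycles(M), oracle_3cycles(M))
    expect_equal(count_4cycles(M), oracle_4cycles(M))
  }
  # directed 4-ring has one 4-cycle and no reciprocal degeneracies
  expect_equal(count_4cycles(ring4), 1)
  # a pure reciprocal pair has no 4-cycle despite closed 4-walks
  pair <- matrix(0L, 2, 2); pair[1, 2] <- pair[2, 1] <- 1L
  expect_equal(count_4cycles(pair), 0)
})

test_that("excitatory view of cycles depends only on the E-subgraph", {
  set.seed(6)
  M <- random_digraph(12, 0.4)
  lb <- rep(c("E", "I"), c(8, 4))
  base <- count_3cycles(M, "excitatory", lb)
  M2 <- M
  M2[9:12, ] <- random_digraph(12, 0.5)[9:12, ]  # rewire I rows only
  expect_equal(count_3cycles(M2, "excitatory", lb), base)
})

test_that("motif census: 13 classes, exact counts, additivity", {
  # the complete triad is the single 6-edge class
  mc <- motif_census(complete_digraph(3))
  expect_equal(mc$entire, c(rep(0, 12), 1))
  # all 64 possible triads map to exactly 13 connected classes
  tab <- wmnet:::motif_class_table()
  expect_setequal(sort(unique(tab[tab > 0])), 1:13)
  # a directed 3-cycle is motif 7; the feedforward triangle is motif 6
  cyc <- matrix(0L, 3, 3); cyc[2, 1] <- cyc[3, 2] <- cyc[1, 3] <- 1L
  expect_equal(motif_census(cyc)$entire[7], 1)
  ffl <- matrix(0L, 3, 3); ffl[2, 1] <- ffl[3, 1] <- ffl[3, 2] <- 1L
  expect_equal(motif_census(ffl)$entire[6], 1)
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(7:9, 1)
    M <- random_digraph(n, runif(1, 0.15, 0.5))
    lb <- sample(c("E", "I"), n, replace = TRUE, prob = c(0.75, 0.25))
    mc <- motif_census(M, lb)
    # class-wise additivity: entire = excitatory + inhibitory-involved
    expect_equal(mc$entire, mc$excitatory + mc$inhibitory_involved)
    # total count = number of weakly connected triples (oracle)
    sig <- oracle_motif_signatures(M)
    expect_equal(sum(mc$entire), sum(sig))
    # count multiset matches the independent isomorphism oracle
    expect_equal(sort(mc$entire[mc$entire > 0], decreasing = TRUE),
                 unname(sort(as.integer(sig), decreasing = TRUE)))
    # motif 13 = number of fully reciprocally connected triads
    R <- (M == 1L) & (t(M) == 1L)
    full <- 0
    for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n)
      if (R[a, b] && R[a, cc] && R[b, cc]) full <- full + 1
    expect_equal(mc$entire[13], full)
  }
})

test_that("motif census agrees with the igraph triad census", {
  skip_if_not_installed("igraph")
  set.seed(8)
  for (rep in 1:10) {
    M <- random_digraph(10, 0.3)
    g <- igraph::graph_from_adjacency_matrix(t(M), mode = "directed")
    tc <- igraph::triad_census(g)
    # igraph order: 003 012 102 021D 021U 021C 111D 111U 030T 030C 201
    #               120D 120U 120C 210 300; the last 13 are connected
    mc <- motif_census(M)$entire
    expect_equal(sum(mc), sum(tc[4:16]))
    expect_equal(mc[6], tc[9])   # feedforward loop = 030T
    expect_equal(mc[7], tc[10])  # 3-cycle = 030C
    expect_equal(mc[11], tc[11]) # two reciprocal pairs = 201
    expect_equal(mc[12], tc[15]) # 210
    expect_equal(mc[13], tc[16]) # 300
    expect_equal(sum(mc[1:3]), sum(tc[4:6]))    # 2-edge classes
    expect_equal(sum(mc[4:5]), sum(tc[7:8]))    # reciprocal + single edge
    expect_equal(sum(mc[8:10]), sum(tc[12:14])) # 120 family
  }
})

test_that("feature vector assembles all 17 variables deterministically", {
  net <- build_network(seed = 1)
  lb <- net$labels$type[net$labels$area == "association"]
  fv <- feature_vector(net$M_association, lb)
  expect_equal(names(fv), feature_names())
  expect_equal(ncol(fv), 17)
  fv2 <- feature_vector(build_network(seed = 1)$M_association, lb)
  expect_identical(fv, fv2)
  # complete digraph: closed forms
  lbc <- rep(c("E", "I"), c(6, 3))
  fvc <- feature_vector(complete_digraph(9), lbc)
  expect_equal(fvc$Cc_all, 1)
  expect_equal(fvc$L_all, 1)
  expect_equal(fvc$C3_E, 2 * choose(6, 3))
  # empty graph: counts zero, ratios flagged undefined
  fve <- suppressWarnings(feature_vector(matrix(0L, 9, 9), lbc))
  expect_equal(fve$d_EtoE + fve$d_EtoI + fve$d_ItoE + fve$d_ItoI, 0)
  expect_true(is.na(fve$F_EI) && is.na(fve$F_cycle) && is.na(fve$L_all))
})

test_that("3-cycle and 4-cycle counts are tightly correlated across topologies", {
  set.seed(9)
  c3 <- c4 <- numeric(200)
  for (i in 1:200) {
    M <- build_intra(area_spec("association", N_E = 40, N_I = 10))
    c3[i] <- count_3cycles(M)
    c4[i] <- count_4cycles(M)
  }
  expect_gt(cor(c3, c4), 0.9)
})
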