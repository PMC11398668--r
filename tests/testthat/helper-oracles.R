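# Brute-force oracles used to pin down the fast implementations.

# mean directed shortest path by breadth-first search from every node
oracle_spl_bfs <- function(M) {
  n <- nrow(M)
  # edge j -> i iff M[i, j] == 1; successors of v are which(M[, v] == 1)
  total <- 0; npairs <- 0; unreach <- 0
  for (v in seq_len(n)) {
    dist <- rep(Inf, n); dist[v] <- 0
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      succ <- which(M[, u] == 1L)
      for (s in succ) if (!is.finite(dist[s])) {
        dist[s] <- dist[u] + 1
        queue <- c(queue, s)
      }
    }
    d <- dist[-v]
    total <- total + sum(d[is.finite(d)])
    npairs <- npairs + sum(is.finite(d))
    unreach <- unreach + sum(!is.finite(d))
  }
  list(mean = if (npairs) total / npairs else NA_real_,
       n_unreachable = unreach)
}

# per-node clustering by explicit neighbour-pair enumeration
oracle_clustering <- function(M) {
  n <- nrow(M)
  U <- (M + t(M)) > 0; diag(U) <- FALSE
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(U[v, ])
    k <- length(nb)
    if (k < 2) { cc[v] <- 0; next }
    e <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a < b && U[nb[a], nb[b]]) e <- e + 1
    }
    cc[v] <- 2 * e / (k * (k - 1))
  }
  mean(cc)
}

# directed 3-cycles by enumeration over ordered triples
oracle_3cycles <- function(M) {
  n <- nrow(M)
  cnt <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i != j && j != k && i != k &&
        M[j, i] == 1 && M[k, j] == 1 && M[i, k] == 1)  # i->j->k->i
      cnt <- cnt + 1
  }
  cnt / 3
}

# directed 4-cycles by enumeration over ordered quadruples
oracle_4cycles <- function(M) {
  n <- nrow(M)
  cnt <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
    for (l in seq_len(n)) {
      if (length(unique(c(i, j, k, l))) == 4 &&
          M[j, i] == 1 && M[k, j] == 1 && M[l, k] == 1 && M[i, l] == 1)
        cnt <- cnt + 1
    }
  cnt / 4
}

# triad classification by isomorphism signature: the sorted 6-bit codes of
# a triad under all vertex permutations identify its class without naming
# it.  Returns the signature string, or NA for non-connected triads.
oracle_triad_signature <- function(A) {
  U <- (A + t(A)) > 0
  deg <- rowSums(U) + colSums(U)
  if (any(deg == 0) || sum(U) / 2 < 2) return(NA_character_)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  codes <- vapply(perms, function(p) {
    B <- A[p, p]
    B[1, 2] + 2 * B[2, 1] + 4 * B[1, 3] + 8 * B[3, 1] + 16 * B[2, 3] +
      32 * B[3, 2]
  }, numeric(1))
  paste(sort(unique(codes)), collapse = "-")
}

# census of signatures over all unordered triples (M receiver-row)
oracle_motif_signatures <- function(M) {
  n <- nrow(M)
  sig <- character(0)
  for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n) {
    idx <- c(a, b, cc)
    A <- t(M[idx, idx])   # A[x, y] = 1 iff x -> y
    s <- oracle_triad_signature(A)
    if (!is.na(s)) sig <- c(sig, s)
  }
  sort(table(sig), decreasing = TRUE)
}

# random binary digraph with zero diagonal (receiver-row convention)
random_digraph <- function(n, p = 0.3) {
  M <- matrix(rbinom(n * n, 1L, p), n, n)
  diag(M) <- 0L
  storage.mode(M) <- "integer"
  M
}

# smallest band half-width d for which a convex function fits under the
# upper bounds and over the lower bounds at the given abscissae; geometric
# route via the lower convex hull of the upper-bound points
hull_min_d <- function(u, upper, lower) {
  m <- length(u)
  if (m == 0) return(0)
  if (m == 1) return(max((lower - upper) / 2, 0))
  # lower convex hull of the upper-bound points (monotone chain)
  lh <- integer(0)
  for (i in seq_len(m)) {
    while (length(lh) >= 2) {
      a <- lh[length(lh) - 1]; b <- lh[length(lh)]
      # drop b if it lies above segment a-i
      if ((upper[b] - upper[a]) * (u[i] - u[a]) >=
            (upper[i] - upper[a]) * (u[b] - u[a])) lh <- lh[-length(lh)]
      else break
    }
    lh <- c(lh, i)
  }
  hv <- stats::approx(u[lh], upper[lh], xout = u, rule = 2)$y
  max(c((lower - hv) / 2, 0))
}

# dip statistic by mode-slot enumeration with the hull oracle per side
oracle_dip <- function(x) {
  x <- sort(x)
  u <- unique(x)
  m <- length(u)
  Fv <- cumsum(tabulate(match(x, u), nbins = m)) / length(x)
  Fp <- c(0, Fv[-m])
  d_left <- function(idx_mid, idx_out) {
    # convex side: lower bounds F at middles, upper bounds Fp at all
    keep <- sort(unique(c(idx_mid, idx_out)))
    if (!length(keep)) return(0)
    lo <- ifelse(keep %in% idx_mid, Fv[keep], -Inf)
    hull_min_d(u[keep], Fp[keep], lo)
  }
  d_right <- function(idx_mid, idx_out) {
    # concave side: reflect x -> -x swaps roles; survival S = 1 - F
    keep <- sort(unique(c(idx_mid, idx_out)))
    if (!length(keep)) return(0)
    ur <- rev(-u[keep])
    upper_r <- rev(1 - Fv[keep])
    lower_r <- rev(ifelse(keep %in% idx_mid, 1 - Fp[keep], -Inf))
    hull_min_d(ur, upper_r, lower_r)
  }
  best <- Inf
  for (k in 0:m) {   # mode between u[k] and u[k+1]
    dl <- d_left(seq_len(k), seq_len(min(k + 1, m)))
    dr <- d_right(if (k + 1 <= m) (k + 1):m else integer(0),
                  if (k >= 1) k:m else 1:m)
    best <- min(best, max(dl, dr))
  }
  for (t in 1:m) {   # mode at u[t]
    dl <- d_left(seq_len(t - 1), seq_len(t))
    dr <- d_right(if (t + 1 <= m) (t + 1):m else integer(0), t:m)
    best <- min(best, max(dl, dr))
  }
  best
}

# naive Spearman: average ranks then Pearson product-moment formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# ridge cost minimized numerically (independent of the closed form)
oracle_ridge <- function(X, y, lambda) {
  X <- as.matrix(X)
  std <- list(c = colMeans(X), s = apply(X, 2, sd))
  Xs <- sweep(sweep(X, 2, std$c), 2, std$s, "/")
  n <- nrow(Xs); p <- ncol(Xs)
  cost <- function(b) {
    mean((y - b[1] - Xs %*% b[-1])^2) + lambda * sum(b[-1]^2)
  }
  fit <- optim(c(mean(y), rep(0, p)), cost, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  list(beta0 = fit$par[1], beta = fit$par[-1])
}
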