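# shared fixtures and independent oracles used across the test files

# random deterministic memory-m strategy (uses the ambient RNG)
rand_strategy <- function(m) {
  memory_strategy(rbinom(4^m, 1, 0.5), m = m)
}

# independent stationary-distribution oracle: damped power iteration
power_stationary <- function(M, iters = 200000, tol = 1e-14) {
  v <- rep(1 / nrow(M), nrow(M))
  for (i in seq_len(iters)) {
    v2 <- 0.5 * (as.vector(v %*% M) + v)
    if (max(abs(v2 - v)) < tol) return(v2 / sum(v2))
    v <- v2
  }
  v / sum(v)
}

# brute-force minimum in-arborescence (every non-root node has exactly one
# outgoing edge; all paths lead to root); for small K only
brute_arborescence <- function(cost, root) {
  K <- nrow(cost)
  if (K == 1) return(0)
  nodes <- setdiff(seq_len(K), root)
  best <- Inf
  choices <- lapply(nodes, function(u) setdiff(seq_len(K), u))
  grid <- do.call(expand.grid, choices)
  for (r in seq_len(nrow(grid))) {
    nxt <- integer(K)
    nxt[nodes] <- as.integer(unlist(grid[r, ]))
    w <- 0
    ok <- TRUE
    for (u in nodes) {
      w <- w + cost[u, nxt[u]]
      # follow path; must reach root without cycling
      v <- u
      for (step in seq_len(K)) {
        v <- nxt[v]
        if (v == root) break
      }
      if (v != root) { ok <- FALSE; break }
    }
    if (ok && w < best) best <- w
  }
  best
}

# membership in the convex hull of the feasible payoff diamond
in_payoff_diamond <- function(piA, piB, payoffs, tol = 1e-9) {
  verts <- rbind(c(payoffs$R, payoffs$R), c(payoffs$T, payoffs$S),
                 c(payoffs$P, payoffs$P), c(payoffs$S, payoffs$T))
  n <- nrow(verts)
  sgn <- 0
  for (i in seq_len(n)) {
    a <- verts[i, ]
    b <- verts[i %% n + 1, ]
    cr <- (b[1] - a[1]) * (piB - a[2]) - (b[2] - a[2]) * (piA - a[1])
    if (abs(cr) < tol) next
    if (sgn == 0) sgn <- sign(cr)
    else if (sign(cr) != sgn) return(FALSE)
  }
  TRUE
}

# four-state joint-state index shorthand used in several tests
st <- function(alice, bob) joint_state_index(alice, bob)
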