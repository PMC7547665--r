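# Joint play dynamics of a strategy pair under implementation error:
# the Markov chain over joint states, stationary long-run payoffs, and the
# exact e -> 0+ limit via the Freidlin-Wentzell construction.

## ---- payoff matrices ------------------------------------------------------

#' Payoff matrix of the two-player game
#'
#' The prisoner's dilemma requires `T > R > P > S` and `2R > T + S`; the
#' constructor also accepts any payoffs with `R > P`, `2R > T + S` and
#' `T > S` (mutual cooperation socially optimal, exploiting better than being
#' exploited), which covers the snowdrift and stag-hunt orderings.
#'
#' @param R,T,S,P elementary payoffs (reward, temptation, sucker, punishment).
#' @return a `payoff_matrix` object.
#' @examples
#' payoff_matrix()            # (3, 4, 0, 1)
#' donation_payoffs(b = 3)    # R = 2, T = 3, S = -1, P = 0
#' @export
payoff_matrix <- function(R = 3, T = 4, S = 0, P = 1) {
  if (!(R > P && 2 * R > T + S && T > S))
    stop("need R > P, 2R > T + S and T > S")
  structure(list(R = R, T = T, S = S, P = P),
            class = "payoff_matrix")
}

#' @param b benefit of the donation game (unit cost); sets `R = b - 1`,
#'   `T = b`, `S = -1`, `P = 0`.
#' @rdname payoff_matrix
#' @export
donation_payoffs <- function(b) {
  if (b <= 1) stop("donation benefit b must exceed the unit cost 1")
  out <- payoff_matrix(R = b - 1, T = b, S = -1, P = 0)
  out$b <- b
  out
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat(sprintf("<payoffs R=%g T=%g S=%g P=%g%s>\n", x$R, x$T, x$S, x$P,
              if (!is.null(x$b)) sprintf(" (donation b=%g)", x$b) else ""))
  invisible(x)
}

# per-player payoffs of realized pair (a, b): focal player's payoff
.pair_payoff <- function(a, b, payoffs) {
  ifelse(a == 0 & b == 0, payoffs$R,
  ifelse(a == 0 & b == 1, payoffs$S,
  ifelse(a == 1 & b == 0, payoffs$T, payoffs$P)))
}

## ---- chain construction ---------------------------------------------------

# error-adjusted cooperation probability
.realized_coop <- function(q, e) q * (1 - e) + (1 - q) * e

#' Joint Markov chain of a strategy pair under implementation error
#'
#' Builds the row-stochastic transition matrix of the joint play process:
#' each round, both players draw their intended action from their strategy,
#' each realized action is flipped independently with probability `e`, and
#' the joint state shifts accordingly.  Memory strategies of different
#' lengths are embedded into the larger memory; if either strategy is a
#' Moore automaton, the chain runs over reachable automaton product states
#' augmented with the last realized pair.
#'
#' @param sA,sB strategies ([memory_strategy()], [memory_one()], or
#'   [moore_automaton()]).
#' @param e implementation error rate per player-action, in \[0, 1/2).
#' @param payoffs a [payoff_matrix()], stored for payoff computations.
#' @return a `joint_chain` object with elements `matrix` (transition
#'   probabilities), `last_pair` (realized pair per state, used for payoff
#'   attribution), `e`, `payoffs`.
#' @examples
#' ch <- build_chain(make_named("TFT"), make_named("TFT"), e = 1e-3)
#' rowSums(ch$matrix)
#' @export
build_chain <- function(sA, sB, e, payoffs = payoff_matrix()) {
  if (e < 0 || e >= 0.5) stop("error rate e must lie in [0, 1/2)")
  if (inherits(sA, "moore_automaton") || inherits(sB, "moore_automaton")) {
    return(.build_chain_automaton(sA, sB, e, payoffs))
  }
  stopifnot(inherits(sA, "memory_strategy"), inherits(sB, "memory_strategy"))
  m <- max(sA$m, sB$m)
  sA <- embed_strategy(sA, m)
  sB <- embed_strategy(sB, m)
  n <- 4^m
  idx <- 0:(n - 1)
  qA <- .realized_coop(sA$probs, e)
  qB <- .realized_coop(sB$probs[swap_state(idx, m) + 1], e)
  M <- matrix(0, n, n)
  for (a in 0:1) for (b in 0:1) {
    pr <- (if (a == 0) qA else 1 - qA) * (if (b == 0) qB else 1 - qB)
    tgt <- shift_state(idx, a, b, m)
    ij <- cbind(idx + 1, tgt + 1)
    M[ij] <- M[ij] + pr
  }
  structure(list(kind = "memory", m = m, matrix = M,
                 last_pair = cbind(a = idx %/% 2^m %% 2, b = idx %% 2),
                 deterministic = sA$deterministic && sB$deterministic,
                 e = e, payoffs = payoffs),
            class = "joint_chain")
}

.as_automaton <- function(s) {
  if (inherits(s, "moore_automaton")) return(s)
  stopifnot(inherits(s, "memory_strategy"))
  if (!s$deterministic)
    stop("automaton pairing requires deterministic strategies")
  to_automaton(s, minimize = TRUE)
}

# product states (uA, uB, last realized pair), reachable closure from the
# first round at both automata's initial states
.automaton_product <- function(aA, aB) {
  pair_chr <- c("cc", "cd", "dc", "dd")
  key <- function(u, v, p) paste(u, v, p)
  states <- list()
  index <- new.env(parent = emptyenv())
  queue <- list()
  push <- function(u, v, p) {
    k <- key(u, v, p)
    if (is.null(index[[k]])) {
      states[[length(states) + 1]] <<- c(u, v, p)
      index[[k]] <<- length(states)
      queue[[length(queue) + 1]] <<- c(u, v, p)
    }
    index[[k]]
  }
  for (p in 1:4) {
    ab <- c((p - 1) %/% 2, (p - 1) %% 2)
    push(aA$transition[aA$initial, pair_chr[p]],
         aB$transition[aB$initial, pair_chr[2 * ab[2] + ab[1] + 1]], p)
  }
  i <- 1
  while (i <= length(queue)) {
    st <- queue[[i]]; i <- i + 1
    for (p in 1:4) {
      ab <- c((p - 1) %/% 2, (p - 1) %% 2)
      push(aA$transition[st[1], pair_chr[p]],
           aB$transition[st[2], pair_chr[2 * ab[2] + ab[1] + 1]], p)
    }
  }
  do.call(rbind, states)  # columns uA, uB, pair
}

.build_chain_automaton <- function(sA, sB, e, payoffs) {
  aA <- .as_automaton(sA)
  aB <- .as_automaton(sB)
  pair_chr <- c("cc", "cd", "dc", "dd")
  states <- .automaton_product(aA, aB)
  n <- nrow(states)
  skey <- paste(states[, 1], states[, 2], states[, 3])
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    uA <- states[i, 1]; uB <- states[i, 2]
    qA <- .realized_coop(as.numeric(aA$output[uA] == "c"), e)
    qB <- .realized_coop(as.numeric(aB$output[uB] == "c"), e)
    for (a in 0:1) for (b in 0:1) {
      pr <- (if (a == 0) qA else 1 - qA) * (if (b == 0) qB else 1 - qB)
      p <- 2 * a + b + 1
      vA <- aA$transition[uA, pair_chr[p]]
      vB <- aB$transition[uB, pair_chr[2 * b + a + 1]]
      j <- match(paste(vA, vB, p), skey)
      M[i, j] <- M[i, j] + pr
    }
  }
  structure(list(kind = "automaton", matrix = M,
                 last_pair = cbind(a = (states[, 3] - 1) %/% 2,
                                   b = (states[, 3] - 1) %% 2),
                 states = states,
                 deterministic = TRUE, e = e, payoffs = payoffs),
            class = "joint_chain")
}

#' @export
print.joint_chain <- function(x, ...) {
  cat(sprintf("<joint chain: %d states, e = %g (%s representation)>\n",
              nrow(x$matrix), x$e, x$kind))
  invisible(x)
}

## ---- stationary payoffs ---------------------------------------------------

# stationary vector of a row-stochastic matrix; dense solve with a damped
# power-iteration fallback for (numerically) reducible chains
.stationary <- function(M) {
  n <- nrow(M)
  A <- t(M) - diag(n)
  A[1, ] <- 1
  rhs <- c(1, rep(0, n - 1))
  pi <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (!is.null(pi) && all(pi > -1e-9)) {
    pi <- pmax(pi, 0)
    return(pi / sum(pi))
  }
  v <- rep(1 / n, n)
  for (it in seq_len(50000)) {
    v2 <- 0.5 * (as.vector(v %*% M) + v)  # lazy chain: aperiodic, same pi
    if (max(abs(v2 - v)) < 1e-14) { v <- v2; break }
    v <- v2
  }
  v / sum(v)
}

#' Long-run average payoffs of a joint chain
#'
#' Solves `pi M = pi`, `sum(pi) = 1` and attributes to each state the payoff
#' of its most recent realized action pair.  Requires an ergodic chain
#' (`e > 0`, or at least one strategy with interior cooperation
#' probabilities); for a deterministic pair at `e = 0` use
#' [zero_error_limit()] instead.
#'
#' @param chain a [build_chain()] result.
#' @param payoffs optional [payoff_matrix()] overriding the chain's.
#' @return list with `pi_A`, `pi_B` and the `stationary` distribution.
#' @export
stationary_payoffs <- function(chain, payoffs = NULL) {
  stopifnot(inherits(chain, "joint_chain"))
  if (is.null(payoffs)) payoffs <- chain$payoffs
  if (chain$e == 0 && isTRUE(chain$deterministic))
    stop("deterministic pair at e = 0 is reducible: ",
         "use zero_error_limit() or a positive error rate")
  pi <- .stationary(chain$matrix)
  a <- chain$last_pair[, 1]
  b <- chain$last_pair[, 2]
  list(pi_A = sum(pi * .pair_payoff(a, b, payoffs)),
       pi_B = sum(pi * .pair_payoff(b, a, payoffs)),
       stationary = pi)
}

## ---- zero-error limit (Freidlin-Wentzell) ---------------------------------

# generic limit analysis: n states, deterministic map nxt (1-based),
# succ/cost: n x 4 realized branches (successor 1-based, flip cost)
.limit_core_r <- function(n, nxt, succ, cost) {
  colr <- integer(n)   # 0 unvisited, 1 on path, 2 done
  class_of <- rep(NA_integer_, n)
  cycles <- list()
  for (s0 in seq_len(n)) {
    if (colr[s0]) next
    path <- integer(0)
    u <- s0
    while (colr[u] == 0) { colr[u] <- 1L; path <- c(path, u); u <- nxt[u] }
    if (colr[u] == 1L) {
      pos <- match(u, path)
      cid <- length(cycles) + 1L
      cyc <- path[pos:length(path)]
      cycles[[cid]] <- cyc
      class_of[cyc] <- cid
    }
    colr[path] <- 2L
  }
  K <- length(cycles)
  V <- matrix(Inf, K, K)
  for (cc in seq_len(K)) {
    dist <- rep(Inf, n)
    done <- rep(FALSE, n)
    dist[cycles[[cc]]] <- 0
    repeat {
      u <- which.min(replace(dist, done, Inf))
      if (!length(u) || !is.finite(dist[u]) || done[u]) break
      done[u] <- TRUE
      cu <- class_of[u]
      if (!is.na(cu) && cu != cc) {
        V[cc, cu] <- min(V[cc, cu], dist[u])
        next  # never pass through another recurrent class
      }
      for (k in 1:4) {
        t <- succ[u, k]
        w <- dist[u] + cost[u, k]
        if (w < dist[t]) dist[t] <- w
      }
    }
  }
  W <- vapply(seq_len(K), function(r) cpp_min_arborescence(V, r - 1L), numeric(1))
  support <- which(W <= min(W) + 1e-9)
  list(class_of = class_of, cycles = cycles, cost = V, W = W, support = support)
}

#' Exact zero-error limit of deterministic pair play
#'
#' For two deterministic strategies the error-free play is a deterministic
#' map on joint states whose recurrent classes are cycles.  As the error
#' rate tends to zero the stationary distribution concentrates on the
#' class(es) minimizing the Freidlin--Wentzell weight `W`: the minimal total
#' number of action flips of a spanning in-arborescence of the class graph,
#' where the cost between classes is the least number of flipped actions
#' along any path not passing through other recurrent classes.
#'
#' @param sA,sB deterministic strategies ([memory_strategy()] or
#'   [moore_automaton()]).
#' @return a `limit_analysis` object: `classes` (list of recurrent classes,
#'   each a vector of 0-based joint-state indices for memory pairs, or rows
#'   of the product-state table for automata), `class_pairs` (realized
#'   `(a, b)` pairs along each cycle), `cost`, `W`, `support` (indices of
#'   weight-minimizing classes), `class_of`, `kind`, `m`.
#' @examples
#' la <- zero_error_limit(make_named("WSLS"), make_named("WSLS"))
#' la$support            # the full-cooperation class
#' @export
zero_error_limit <- function(sA, sB) {
  autom <- inherits(sA, "moore_automaton") || inherits(sB, "moore_automaton")
  if (!autom) {
    stopifnot(inherits(sA, "memory_strategy"), inherits(sB, "memory_strategy"))
    if (!sA$deterministic || !sB$deterministic)
      stop("zero_error_limit() needs deterministic strategies; ",
           "use stationary_payoffs() at small e for probabilistic pairs")
    m <- max(sA$m, sB$m)
    actA <- strategy_actions(embed_strategy(sA, m))
    actB <- strategy_actions(embed_strategy(sB, m))
    n <- 4^m
    idx <- 0:(n - 1)
    aA <- actA[idx + 1]
    aB <- actB[swap_state(idx, m) + 1]
    succ <- matrix(0L, n, 4)
    cost <- matrix(0, n, 4)
    k <- 0
    for (a in 0:1) for (b in 0:1) {
      k <- k + 1
      succ[, k] <- shift_state(idx, a, b, m) + 1L
      cost[, k] <- (a != aA) + (b != aB)
    }
    nxt <- succ[cbind(seq_len(n), 2 * aA + aB + 1)]
    res <- .limit_core_r(n, nxt, succ, cost)
    pairs <- lapply(res$cycles, function(cy) cbind(a = aA[cy], b = aB[cy]))
    res$cycles <- lapply(res$cycles, function(cy) cy - 1L)  # 0-based states
    out <- c(res, list(class_pairs = pairs, kind = "memory", m = m))
  } else {
    aAau <- .as_automaton(sA)
    aBau <- .as_automaton(sB)
    states <- .automaton_product(aAau, aBau)
    n <- nrow(states)
    skey <- paste(states[, 1], states[, 2], states[, 3])
    pair_chr <- c("cc", "cd", "dc", "dd")
    aA <- as.integer(aAau$output[states[, 1]] == "d")
    aB <- as.integer(aBau$output[states[, 2]] == "d")
    succ <- matrix(0L, n, 4)
    cost <- matrix(0, n, 4)
    k <- 0
    for (a in 0:1) for (b in 0:1) {
      k <- k + 1
      for (i in seq_len(n)) {
        vA <- aAau$transition[states[i, 1], pair_chr[2 * a + b + 1]]
        vB <- aBau$transition[states[i, 2], pair_chr[2 * b + a + 1]]
        succ[i, k] <- match(paste(vA, vB, 2 * a + b + 1), skey)
      }
      cost[, k] <- (a != aA) + (b != aB)
    }
    nxt <- succ[cbind(seq_len(n), 2 * aA + aB + 1)]
    res <- .limit_core_r(n, nxt, succ, cost)
    pairs <- lapply(res$cycles, function(cy) cbind(a = aA[cy], b = aB[cy]))
    out <- c(res, list(class_pairs = pairs, kind = "automaton",
                       states = states))
  }
  class(out) <- "limit_analysis"
  out
}

#' @export
print.limit_analysis <- function(x, ...) {
  K <- length(x$cycles)
  cat(sprintf("<zero-error limit: %d recurrent class%s, support = {%s}>\n",
              K, if (K == 1) "" else "es",
              paste(x$support, collapse = ", ")))
  cat("  W:", paste(format(x$W), collapse = " "), "\n")
  invisible(x)
}

#' Cycle-average payoffs of the recurrent classes of a limit analysis
#'
#' @param la a [zero_error_limit()] result.
#' @param payoffs a [payoff_matrix()].
#' @return data frame with one row per class: `pi_A`, `pi_B`, `in_support`.
#' @export
limit_payoffs <- function(la, payoffs = payoff_matrix()) {
  stopifnot(inherits(la, "limit_analysis"))
  res <- t(vapply(la$class_pairs, function(pp) {
    c(mean(.pair_payoff(pp[, 1], pp[, 2], payoffs)),
      mean(.pair_payoff(pp[, 2], pp[, 1], payoffs)))
  }, numeric(2)))
  data.frame(class = seq_along(la$class_pairs), pi_A = res[, 1],
             pi_B = res[, 2],
             in_support = seq_along(la$class_pairs) %in% la$support)
}

## ---- payoff cloud ---------------------------------------------------------

#' Payoffs of a focal strategy against random memory-three co-players
#'
#' Draws `n` co-players uniformly from the 64-dimensional unit hypercube of
#' probabilistic memory-three strategies and computes the pair's long-run
#' payoffs.  A defensible focal strategy is guaranteed `pi_A >= pi_B` in the
#' zero-error limit against every co-player.
#'
#' @param alice focal strategy (any memory strategy; embedded to memory 3).
#' @param n number of sampled co-players.
#' @param payoffs a [payoff_matrix()].
#' @param e error rate (default 0; the random interior co-player makes the
#'   chain ergodic almost surely).
#' @param seed optional integer seed for reproducibility.
#' @return data frame with columns `sample_id`, `pi_A`, `pi_B`.
#' @examples
#' cloud <- sample_payoff_cloud(capri(), n = 20, seed = 1)
#' all(cloud$pi_A >= cloud$pi_B - 1e-9)
#' @export
sample_payoff_cloud <- function(alice, n, payoffs = payoff_matrix(), e = 0,
                                seed = NULL) {
  stopifnot(n >= 0)
  alice <- embed_strategy(alice, 3)
  draw <- function() matrix(runif(64 * n), nrow = n)
  probs <- if (is.null(seed)) draw() else .with_seed(seed, draw())
  out <- data.frame(sample_id = seq_len(n), pi_A = numeric(n), pi_B = numeric(n))
  for (i in seq_len(n)) {
    bob <- probabilistic_memory_strategy(probs[i, ], m = 3)
    ch <- build_chain(alice, bob, e = e, payoffs = payoffs)
    ch$deterministic <- FALSE  # interior co-player: ergodic a.s.
    sp <- stationary_payoffs(ch)
    out$pi_A[i] <- sp$pi_A
    out$pi_B[i] <- sp$pi_B
  }
  attr(out, "seed") <- seed
  attr(out, "e") <- e
  out
}

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}
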