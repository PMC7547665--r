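# The three axioms for repeated-game strategies: efficiency, defensibility,
# distinguishability; plus recovery-path extraction and explicit exploit
# witnesses for non-defensible strategies.

## ---- defensibility --------------------------------------------------------

# adversarial state graph of a deterministic memory strategy: nodes are the
# joint states, Alice's action is fixed by her table, Bob chooses either
# action; edge weight = sign(payoff_A - payoff_B) of the realized pair.
.defense_edges <- function(s) {
  if (inherits(s, "moore_automaton")) {
    n <- length(s$output)
    a <- as.integer(s$output == "d")
    from <- rep(seq_len(n), each = 2)
    b <- rep(0:1, n)
    af <- a[from]
    to <- s$transition[cbind(from, 2 * af + b + 1)]  # columns are cc,cd,dc,dd
    return(data.frame(from = from, to = to, a = af, b = b,
                      w = (af == 1 & b == 0) - (af == 0 & b == 1)))
  }
  stopifnot(inherits(s, "memory_strategy"), s$deterministic)
  acts <- strategy_actions(s)
  m <- s$m
  n <- 4^m
  from <- rep(1:n, each = 2)
  b <- rep(0:1, n)
  af <- acts[from]
  to <- shift_state(from - 1L, af, b, m) + 1L
  data.frame(from = from, to = to, a = af, b = b,
             w = (af == 1 & b == 0) - (af == 0 & b == 1))
}

#' Defensibility: never outperformed at zero error
#'
#' A strategy is defensible if, playing error-free against *any* co-player
#' (of arbitrary memory) from *any* initial state, its long-run payoff is
#' never below the co-player's.  This holds iff the adversarial state graph
#' over the strategy's own information states -- Alice's action fixed by her
#' table, an edge for each of Bob's two actions, weighted by
#' `sign(payoff_A - payoff_B)` -- contains no negative-weight cycle: any
#' co-player's play traces a walk on this graph, and a long-run payoff
#' advantage requires a negative cycle.  The sign weights make the verdict
#' independent of the payoff values, given `T > S`.
#'
#' @param s a deterministic [memory_strategy()] or [moore_automaton()].
#' @return `TRUE`/`FALSE`.
#' @examples
#' is_defensible(make_named("TFT"))   # TRUE
#' is_defensible(make_named("WSLS"))  # FALSE
#' @export
is_defensible <- function(s) {
  if (inherits(s, "memory_strategy") && s$deterministic) {
    return(cpp_defensible(strategy_actions(s), s$m))
  }
  ed <- .defense_edges(s)  # automaton path
  n <- max(ed$from, ed$to)
  D <- matrix(Inf, n, n)
  ij <- cbind(ed$from, ed$to)
  D[ij] <- pmin(D[ij], ed$w)
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  all(diag(D) >= 0)
}

#' Extract a negative cycle witnessing non-defensibility
#'
#' Runs Bellman--Ford with predecessor tracking on the adversarial state
#' graph and walks back a negative-weight cycle, if one exists.
#'
#' @param s a deterministic [memory_strategy()] or [moore_automaton()].
#' @return `NULL` if defensible; otherwise a list with `states` (1-based
#'   node sequence around the cycle), `alice`/`bob` (action characters along
#'   its edges), and `weight` (total cycle weight, negative).
#' @export
find_negative_cycle <- function(s) {
  ed <- .defense_edges(s)
  n <- max(ed$from, ed$to)
  dist <- rep(0, n)  # virtual source connected to every node with weight 0
  pre <- rep(NA_integer_, n)
  pre_edge <- rep(NA_integer_, n)
  relaxed <- NA_integer_
  for (it in seq_len(n + 1)) {
    relaxed <- NA_integer_
    for (k in seq_len(nrow(ed))) {
      u <- ed$from[k]; v <- ed$to[k]
      if (dist[u] + ed$w[k] < dist[v] - 1e-12) {
        dist[v] <- dist[u] + ed$w[k]
        pre[v] <- u
        pre_edge[v] <- k
        relaxed <- v
      }
    }
    if (is.na(relaxed)) break
  }
  if (is.na(relaxed)) return(NULL)
  # walk back n steps to land on the cycle, then collect it
  v <- relaxed
  for (i in seq_len(n)) v <- pre[v]
  cyc_nodes <- integer(0)
  cyc_edges <- integer(0)
  u <- v
  repeat {
    cyc_nodes <- c(pre[u], cyc_nodes)
    cyc_edges <- c(pre_edge[u], cyc_edges)
    u <- pre[u]
    if (u == v) break
  }
  list(states = cyc_nodes,
       alice = c("c", "d")[ed$a[cyc_edges] + 1],
       bob = c("c", "d")[ed$b[cyc_edges] + 1],
       weight = sum(ed$w[cyc_edges]))
}

#' Realize an exploit cycle by a scripted co-player
#'
#' Confirms a [find_negative_cycle()] witness by actually playing it out:
#' Bob repeats the cycle's action script while Alice follows her table from
#' the cycle's starting state.  Returns the realized per-round payoff
#' advantage of Bob over Alice, which is positive for a genuine witness.
#'
#' @param s the deterministic [memory_strategy()] under test.
#' @param cycle a witness from [find_negative_cycle()].
#' @param payoffs a [payoff_matrix()].
#' @param reps number of cycle periods to play.
#' @return average `payoff_B - payoff_A` per round over the played rounds.
#' @export
verify_exploit <- function(s, cycle, payoffs = payoff_matrix(), reps = 5) {
  stopifnot(inherits(s, "memory_strategy"), s$deterministic)
  acts <- strategy_actions(s)
  m <- s$m
  st <- cycle$states[1] - 1L
  L <- length(cycle$bob)
  diff <- 0
  rounds <- L * reps
  for (t in seq_len(rounds)) {
    a <- acts[st + 1]
    b <- as.integer(cycle$bob[(t - 1) %% L + 1] == "d")
    stopifnot(a == (cycle$alice[(t - 1) %% L + 1] == "d"))  # script consistent
    diff <- diff + .pair_payoff(b, a, payoffs) - .pair_payoff(a, b, payoffs)
    st <- shift_state(st, a, b, m)
  }
  diff / rounds
}

## ---- efficiency -----------------------------------------------------------

#' Efficiency: self-play reaches mutual cooperation as e -> 0+
#'
#' A strategy is efficient if, when both players use it, the probability of
#' mutual cooperation tends to one as the implementation error rate tends to
#' zero.  For deterministic strategies this is decided exactly by
#' [zero_error_limit()]: the weight-minimizing recurrent class(es) of
#' self-play must consist solely of mutual-cooperation rounds (for a memory
#' strategy, the single full-cooperation fixed point).  Probabilistic
#' strategies are assessed numerically: the stationary mass on the
#' full-cooperation state at `e = 1e-6` must exceed 0.99.
#'
#' @param s a [memory_strategy()] (deterministic or probabilistic) or
#'   [moore_automaton()].
#' @return `TRUE`/`FALSE`.
#' @examples
#' is_efficient(make_named("WSLS"))  # TRUE
#' is_efficient(make_named("AllD"))  # FALSE
#' @export
is_efficient <- function(s) {
  if (inherits(s, "memory_strategy") && !s$deterministic) {
    ch <- build_chain(s, s, e = 1e-6)
    pi <- .stationary(ch$matrix)
    return(pi[1] >= 0.99)  # state 0 = full-cooperation history
  }
  la <- zero_error_limit(s, s)
  all(vapply(la$support, function(k) all(la$class_pairs[[k]] == 0), logical(1)))
}

## ---- distinguishability ---------------------------------------------------

#' Distinguishability: strictly beats unconditional cooperation
#'
#' A strategy is distinguishable if its limit payoff strictly exceeds the
#' co-player's when the co-player is AllC, preventing neutral drift towards
#' unconditional cooperators.  Decided by the zero-error limit of the pair
#' (strategy, AllC): against AllC the error-free cycles contain no `(c, d)`
#' rounds, so the strategy is ahead iff the limit cycles contain at least
#' one of its defections.  When several weight-minimizing classes disagree,
#' the verdict defers to numerical stationary payoffs at
#' `e = 1e-5` and `1e-6`, requiring a payoff gap above `10 e (T - S)`.
#'
#' @param s a deterministic [memory_strategy()] or [moore_automaton()].
#' @return `TRUE`/`FALSE`.
#' @examples
#' is_distinguishable(make_named("TFT"))   # FALSE: drifts with AllC
#' is_distinguishable(make_named("AllD"))  # TRUE
#' @export
is_distinguishable <- function(s) {
  allc <- memory_strategy("cccc", m = 1, name = "AllC")
  la <- zero_error_limit(s, allc)
  gains <- vapply(la$support, function(k) any(la$class_pairs[[k]][, 1] == 1),
                  logical(1))
  if (all(gains)) return(TRUE)
  if (!any(gains)) return(FALSE)
  # tied classes with opposite verdicts: numerical fallback
  for (e in c(1e-5, 1e-6)) {
    ch <- build_chain(s, allc, e = e)
    ch$deterministic <- FALSE  # error makes it ergodic
    sp <- stationary_payoffs(ch)
    gap <- (sp$pi_A - sp$pi_B) / (ch$payoffs$T - ch$payoffs$S)
    if (gap <= 10 * e) return(FALSE)
  }
  TRUE
}

## ---- aggregate classification ---------------------------------------------

#' Classify a strategy against the three axioms
#'
#' Evaluates efficiency, defensibility and distinguishability and derives
#' the combined verdicts: a *friendly rival* is efficient and defensible
#' (hence simultaneously a partner and a rival); a *successful* strategy
#' additionally satisfies distinguishability.
#'
#' @param s a deterministic [memory_strategy()] or [moore_automaton()].
#' @return a `classification_result`: list with `efficient`, `defensible`,
#'   `distinguishable`, `friendly_rival`, `successful`, and `recovery_steps`
#'   (steps to recover mutual cooperation after a single co-player error;
#'   `NA` if it never recovers or mutual cooperation is not a fixed point).
#' @examples
#' classify_strategy(capri())
#' @export
classify_strategy <- function(s) {
  eff <- is_efficient(s)
  def <- is_defensible(s)
  dis <- is_distinguishable(s)
  steps <- NA_integer_
  if (inherits(s, "memory_strategy") && s$deterministic &&
      strategy_actions(s)[1] == 0L) {
    rp <- recovery_path(s)
    if (rp$recovered) steps <- rp$steps_after_error
  }
  structure(list(efficient = eff, defensible = def, distinguishable = dis,
                 friendly_rival = eff && def,
                 successful = eff && def && dis,
                 recovery_steps = steps,
                 strategy = s),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  nm <- x$strategy$name
  cat(sprintf("<classification%s>\n", if (!is.null(nm)) paste0(" of ", nm) else ""))
  cat(sprintf("  efficient:        %s\n", x$efficient))
  cat(sprintf("  defensible:       %s\n", x$defensible))
  cat(sprintf("  distinguishable:  %s\n", x$distinguishable))
  cat(sprintf("  friendly rival:   %s   successful: %s\n",
              x$friendly_rival, x$successful))
  if (!is.na(x$recovery_steps))
    cat(sprintf("  recovery steps:   %d\n", x$recovery_steps))
  invisible(x)
}

## ---- recovery paths --------------------------------------------------------

#' Recovery path after a single erroneous defection
#'
#' Starting from mutual cooperation, the co-player (Bob) defects once by
#' error; both players then follow the strategy without further errors.
#' The path records both action sequences from the error round onward.  The
#' error round counts as time step 0; `steps_after_error` is the index of
#' the first round of the uninterrupted run of mutual cooperation that
#' persists once the joint state has returned to the full-cooperation
#' history (so the shortest possible path, punish once then cooperate,
#' takes 2 steps).
#'
#' @param s a deterministic [memory_strategy()] with `s(c^m, c^m) = c`.
#' @param max_rounds give up after this many rounds.
#' @return a `recovery_path`: list with `alice`, `bob` (action characters
#'   starting at the error round), `recovered`, `steps_after_error`.
#' @examples
#' recovery_path(capri())      # c,d,c / d,c,c -- two steps
#' @export
recovery_path <- function(s, max_rounds = 64) {
  stopifnot(inherits(s, "memory_strategy"), s$deterministic)
  acts <- strategy_actions(s)
  m <- s$m
  if (acts[1] != 0L) stop("mutual cooperation is not a fixed point of this strategy")
  st <- shift_state(0L, 0L, 1L, m)  # Bob's erroneous defection
  alice <- "c"
  bob <- "d"
  recovered <- FALSE
  for (t in seq_len(max_rounds)) {
    a <- acts[st + 1]
    b <- acts[swap_state(st, m) + 1]
    alice <- c(alice, c("c", "d")[a + 1])
    bob <- c(bob, c("c", "d")[b + 1])
    st <- shift_state(st, a, b, m)
    if (st == 0L) { recovered <- TRUE; break }
  }
  steps <- NA_integer_
  if (recovered) {
    pairs_cc <- alice == "c" & bob == "c"
    last_bad <- max(which(!pairs_cc))  # index 1 = error round (time step 0)
    steps <- last_bad  # first round of the restored all-(c,c) run
    keep <- seq_len(min(length(alice), last_bad + 1))
    alice <- alice[keep]
    bob <- bob[keep]
  }
  structure(list(alice = alice, bob = bob, recovered = recovered,
                 steps_after_error = steps),
            class = "recovery_path")
}

#' @export
print.recovery_path <- function(x, ...) {
  cat("<recovery path after co-player's error>\n")
  cat("  Alice:", paste(x$alice, collapse = " "), "\n")
  cat("  Bob:  ", paste(x$bob, collapse = " "), "\n")
  if (x$recovered)
    cat("  recovered in", x$steps_after_error, "time steps\n")
  else cat("  did not recover\n")
  invisible(x)
}

# compact pattern string for tallies, e.g. "cdc/dcc"
.recovery_pattern <- function(rp) {
  paste0(paste(rp$alice, collapse = ""), "/", paste(rp$bob, collapse = ""))
}

## ---- empirical defensibility for probabilistic strategies -----------------

#' Empirical payoff-dominance check for probabilistic strategies
#'
#' The exact negative-cycle criterion applies to deterministic strategies.
#' For probabilistic ones (e.g. extortionate ZD) this helper verifies the
#' rival property empirically: the focal strategy's stationary payoff is at
#' least the co-player's, against every strategy in a battery of opponents,
#' at a small error rate.
#'
#' The rival property is a statement about error-free play; at a positive
#' error rate the payoff relation is perturbed by O(e) terms, so the default
#' evaluation uses a very small `e` with a matching tolerance.
#'
#' @param s focal strategy.
#' @param opponents list of opponent strategies; defaults to all 16
#'   deterministic memory-one tables plus `n_random` random probabilistic
#'   memory-two strategies.
#' @param e evaluation error rate.
#' @param n_random number of random opponents in the default battery.
#' @param seed seed for the random battery.
#' @param tol tolerance on the payoff difference.
#' @return `TRUE` if never outperformed beyond `tol`; the worst observed
#'   `pi_B - pi_A` is attached as attribute `"max_gap"`.
#' @export
check_defensible_empirical <- function(s, opponents = NULL, e = 1e-8,
                                       n_random = 30, seed = 1, tol = 1e-6) {
  if (is.null(opponents)) {
    opponents <- c(
      lapply(0:15, function(id) decode_strategy(id, 1)),
      .with_seed(seed, replicate(n_random,
        probabilistic_memory_strategy(runif(16), m = 2), simplify = FALSE)))
  }
  worst <- -Inf
  for (opp in opponents) {
    ch <- build_chain(s, opp, e = e)
    ch$deterministic <- FALSE
    sp <- stationary_payoffs(ch)
    worst <- max(worst, sp$pi_B - sp$pi_A)
  }
  structure(worst <= tol, max_gap = worst)
}
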