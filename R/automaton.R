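# Moore-automaton representation of strategies: conversion from memory-m
# tables, Hopcroft-style minimization, and co-simulation utilities.

#' Moore automaton strategy
#'
#' A finite-state machine whose current state determines the action to play
#' (`output`) and whose transitions are driven by the realized action pair of
#' the round, `(own, co-player)`, one of `cc`, `cd`, `dc`, `dd`.
#'
#' @param output character vector of `"c"`/`"d"`, one per state.
#' @param transition integer matrix, `n_states x 4`, columns named
#'   `cc, cd, dc, dd`, entries 1-based state indices.
#' @param initial 1-based initial state.
#' @param name optional display name.
#' @return an object of class `moore_automaton`.
#' @export
moore_automaton <- function(output, transition, initial = 1, name = NULL) {
  output <- as.character(output)
  n <- length(output)
  transition <- as.matrix(transition)
  if (!all(output %in% c("c", "d"))) stop("outputs must be 'c' or 'd'")
  if (nrow(transition) != n || ncol(transition) != 4)
    stop("transition must be n_states x 4")
  if (is.null(colnames(transition))) colnames(transition) <- c("cc", "cd", "dc", "dd")
  transition <- transition[, c("cc", "cd", "dc", "dd"), drop = FALSE]
  storage.mode(transition) <- "integer"
  if (any(transition < 1L | transition > n)) stop("transition targets out of range")
  if (initial < 1 || initial > n) stop("initial state out of range")
  structure(list(output = output, transition = transition,
                 initial = as.integer(initial), name = name),
            class = c("moore_automaton", "pd_strategy"))
}

#' @export
print.moore_automaton <- function(x, ...) {
  nm <- if (!is.null(x$name)) paste0(" '", x$name, "'") else ""
  cat(sprintf("<Moore automaton%s: %d states, initial %d>\n",
              nm, length(x$output), x$initial))
  cat("  outputs:", paste(x$output, collapse = ""), "\n")
  invisible(x)
}

#' Convert a deterministic memory strategy to a Moore automaton
#'
#' Each joint history becomes a state whose output is the table's action and
#' whose transitions follow the history shift; the initial state is the
#' full-cooperation history.  The automaton plays identically to the table
#' for every realized action-pair sequence.
#'
#' @param s a deterministic [memory_strategy()].
#' @param minimize collapse play-equivalent states (default `TRUE`).
#' @return a [moore_automaton()].
#' @examples
#' length(to_automaton(make_named("TFT"))$output)  # 2
#' @export
to_automaton <- function(s, minimize = TRUE) {
  stopifnot(inherits(s, "memory_strategy"), s$deterministic)
  acts <- strategy_actions(s)
  m <- s$m
  n <- 4^m
  idx <- 0:(n - 1)
  tr <- cbind(cc = shift_state(idx, 0, 0, m),
              cd = shift_state(idx, 0, 1, m),
              dc = shift_state(idx, 1, 0, m),
              dd = shift_state(idx, 1, 1, m)) + 1L
  a <- moore_automaton(output = c("c", "d")[acts + 1], transition = tr,
                       initial = 1L, name = s$name)
  if (minimize) minimize_automaton(a) else a
}

#' Minimize a Moore automaton
#'
#' Drops states unreachable from the initial state, then merges
#' play-equivalent states by partition refinement (initial partition by
#' output, refined by transition-block signatures).  The result is the
#' unique minimal automaton producing the same play; the operation is
#' idempotent.
#'
#' @param a a [moore_automaton()].
#' @return a minimized [moore_automaton()].
#' @export
minimize_automaton <- function(a) {
  stopifnot(inherits(a, "moore_automaton"))
  n <- length(a$output)
  # reachable states
  seen <- rep(FALSE, n)
  queue <- a$initial
  seen[a$initial] <- TRUE
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (t in a$transition[u, ]) if (!seen[t]) { seen[t] <- TRUE; queue <- c(queue, t) }
  }
  keep <- which(seen)
  remap <- integer(n); remap[keep] <- seq_along(keep)
  out <- a$output[keep]
  tr <- matrix(remap[a$transition[keep, , drop = FALSE]], ncol = 4,
               dimnames = list(NULL, c("cc", "cd", "dc", "dd")))
  init <- remap[a$initial]
  # partition refinement
  block <- match(out, c("c", "d"))
  repeat {
    sig <- paste(block, block[tr[, 1]], block[tr[, 2]], block[tr[, 3]], block[tr[, 4]])
    newblock <- match(sig, unique(sig))
    if (identical(newblock, block)) break
    block <- newblock
  }
  reps <- match(seq_len(max(block)), block)  # representative state per block
  moore_automaton(output = out[reps],
                  transition = matrix(block[tr[reps, , drop = FALSE]], ncol = 4,
                                      dimnames = list(NULL, c("cc", "cd", "dc", "dd"))),
                  initial = block[init], name = a$name)
}

#' Outputs of a strategy along a realized action-pair sequence
#'
#' Returns the action the strategy would prescribe before each round, given
#' the sequence of realized pairs `(own, co-player)` so far.  Memory
#' strategies start from the full-cooperation history; automata from their
#' initial state.  Used to check play-equivalence of representations.
#'
#' @param s a deterministic [memory_strategy()] or [moore_automaton()].
#' @param pairs character vector of realized pairs from `cc, cd, dc, dd`.
#' @return character vector of length `length(pairs) + 1` of `"c"`/`"d"`.
#' @export
strategy_outputs <- function(s, pairs) {
  stopifnot(all(pairs %in% c("cc", "cd", "dc", "dd")))
  if (inherits(s, "moore_automaton")) {
    u <- s$initial
    out <- character(length(pairs) + 1)
    for (i in seq_along(pairs)) {
      out[i] <- s$output[u]
      u <- s$transition[u, pairs[i]]
    }
    out[length(pairs) + 1] <- s$output[u]
    return(out)
  }
  stopifnot(inherits(s, "memory_strategy"), s$deterministic)
  acts <- strategy_actions(s)
  m <- s$m
  st <- 0L  # full cooperation
  out <- character(length(pairs) + 1)
  for (i in seq_along(pairs)) {
    out[i] <- c("c", "d")[acts[st + 1] + 1]
    ab <- strsplit(pairs[i], "")[[1]]
    st <- shift_state(st, ab[1], ab[2], m)
  }
  out[length(pairs) + 1] <- c("c", "d")[acts[st + 1] + 1]
  out
}
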