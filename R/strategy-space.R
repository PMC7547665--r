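# Strategy representations: joint states, deterministic memory-m tables,
# probabilistic memory strategies, memory-one tuples, reactive pairs,
# zero-determinant tuples, and the named strategies of the literature.

## ---- joint states ---------------------------------------------------------

#' Index of a joint memory state
#'
#' A joint state records both players' last `m` actions.  It is packed into a
#' single integer `(hA << m) | hB` with `c = 0`, `d = 1` and the oldest action
#' in the most significant bit of each m-bit history, so the full-cooperation
#' state is always index 0 and full defection is the largest index.
#'
#' @param alice,bob character vectors like `c("c","c","d")` or strings like
#'   `"ccd"` giving the last `m` actions, oldest first.
#' @return 0-based state index.
#' @examples
#' joint_state_index("ccc", "ccd")  # 1
#' joint_state_index("d", "c")      # 2 (m = 1)
#' @export
joint_state_index <- function(alice, bob) {
  a <- .parse_actions(alice)
  b <- .parse_actions(bob)
  stopifnot(length(a) == length(b))
  m <- length(a)
  ha <- sum(a * 2^((m - 1):0))
  hb <- sum(b * 2^((m - 1):0))
  ha * 2^m + hb
}

#' Human-readable label of a joint state index
#'
#' @param s 0-based state index (vectorised).
#' @param m memory length.
#' @return character like `"(ccd,ccc)"`.
#' @examples
#' state_label(0, 3)  # "(ccc,ccc)"
#' @export
state_label <- function(s, m) {
  vapply(s, function(si) {
    ha <- si %/% 2^m
    hb <- si %% 2^m
    paste0("(", .hist_string(ha, m), ",", .hist_string(hb, m), ")")
  }, character(1))
}

#' Shift a joint state by one round
#'
#' Drops the oldest action of each history and appends the realized pair
#' `(a, b)`.
#'
#' @param s 0-based state index.
#' @param a,b realized actions of Alice and Bob: `"c"`/`"d"` or 0/1.
#' @param m memory length.
#' @return 0-based successor index.
#' @export
shift_state <- function(s, a, b, m) {
  a <- .action_bit(a)
  b <- .action_bit(b)
  mask <- 2^m - 1
  ha <- s %/% 2^m
  hb <- s %% 2^m
  ha <- bitwAnd(bitwOr(ha * 2L, a), mask)
  hb <- bitwAnd(bitwOr(hb * 2L, b), mask)
  ha * 2^m + hb
}

#' Swap the two players' viewpoints of a joint state
#'
#' @inheritParams shift_state
#' @return index of the state with Alice's and Bob's histories exchanged.
#' @export
swap_state <- function(s, m) {
  (s %% 2^m) * 2^m + s %/% 2^m
}

.action_bit <- function(a) {
  if (is.character(a)) a <- match(a, c("c", "d")) - 1L
  a <- as.integer(a)
  if (anyNA(a) || any(a < 0L | a > 1L)) stop("actions must be 'c'/'d' or 0/1")
  a
}

.parse_actions <- function(x) {
  if (length(x) == 1L && is.character(x) && nchar(x) > 1L)
    x <- strsplit(x, "")[[1]]
  .action_bit(x)
}

.hist_string <- function(h, m) {
  bits <- (h %/% 2^((m - 1):0)) %% 2
  paste(c("c", "d")[bits + 1], collapse = "")
}

## ---- memory strategies ----------------------------------------------------

#' Deterministic or probabilistic memory-m strategy
#'
#' `memory_strategy()` builds a strategy that chooses its action as a
#' function of the joint state of the previous `m` rounds.  Deterministic
#' strategies are given as an action table (`"c"`/`"d"` per state, in state
#' index order); probabilistic strategies as per-state cooperation
#' probabilities.
#'
#' @param actions a string of `4^m` characters from `{c, d}`, or a vector of
#'   such characters, or 0/1 integers (1 = defect), in state-index order.
#' @param m memory length (inferred from `length(actions)` if omitted).
#' @param name optional display name.
#' @return an object of class `memory_strategy`.
#' @examples
#' tft <- memory_strategy("cdcd", name = "TFT")
#' encode_strategy(tft)  # 10
#' @export
memory_strategy <- function(actions, m = NULL, name = NULL) {
  bits <- .parse_actions(actions)
  if (is.null(m)) {
    m <- round(log2(length(bits)) / 2)
  }
  if (length(bits) != 4^m) stop("need 4^m = ", 4^m, " actions, got ", length(bits))
  structure(list(m = as.integer(m), probs = 1 - bits, deterministic = TRUE,
                 p0 = 1, name = name),
            class = c("memory_strategy", "pd_strategy"))
}

#' @param probs numeric vector of `4^m` cooperation probabilities in
#'   \[0, 1\], in state-index order.
#' @rdname memory_strategy
#' @export
probabilistic_memory_strategy <- function(probs, m = NULL, name = NULL) {
  probs <- as.numeric(probs)
  if (is.null(m)) m <- round(log2(length(probs)) / 2)
  if (length(probs) != 4^m) stop("need 4^m = ", 4^m, " probabilities")
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  det <- all(probs %in% c(0, 1))
  structure(list(m = as.integer(m), probs = probs, deterministic = det,
                 p0 = 1, name = name),
            class = c("memory_strategy", "pd_strategy"))
}

#' @export
print.memory_strategy <- function(x, ...) {
  kind <- if (x$deterministic) "deterministic" else "probabilistic"
  nm <- if (!is.null(x$name)) paste0(" '", x$name, "'") else ""
  cat(sprintf("<memory-%d %s strategy%s>\n", x$m, kind, nm))
  if (x$deterministic) {
    cat("  actions:", paste(c("c", "d")[2 - x$probs], collapse = ""), "\n")
    cat("  id:     ", format(encode_strategy(x)), "\n")
  } else {
    cat("  coop probs:", paste(signif(utils::head(x$probs, 8), 3), collapse = " "),
        if (length(x$probs) > 8) "..." else "", "\n")
  }
  invisible(x)
}

# integer 0/1 action vector (1 = defect) of a deterministic strategy
strategy_actions <- function(s) {
  stopifnot(inherits(s, "memory_strategy"), s$deterministic)
  as.integer(1 - s$probs)
}

#' Encode / decode deterministic strategies as integer ids
#'
#' Bit `i` of the id (least significant bit = state 0) is 1 iff the strategy
#' defects at state `i`.  For `m <= 2` the id fits exactly in a double and is
#' returned as a number; for `m = 3` (64 bits) it is returned as a 16-digit
#' hexadecimal string.  `decode_strategy()` accepts either form.
#'
#' @param s a deterministic [memory_strategy()].
#' @return `encode_strategy()`: numeric id (`m <= 2`) or hex string (`m = 3`).
#' @examples
#' encode_strategy(memory_strategy("dddd"))  # AllD, id 15
#' decode_strategy(10, m = 1)                # TFT
#' @export
encode_strategy <- function(s) {
  bits <- strategy_actions(s)
  if (s$m <= 2) return(sum(bits * 2^(seq_along(bits) - 1)))
  .bits_to_hex(bits)
}

#' @param id numeric id or hexadecimal string (with or without `"0x"`).
#' @param m memory length.
#' @param name optional display name.
#' @rdname encode_strategy
#' @export
decode_strategy <- function(id, m, name = NULL) {
  n <- 4^m
  if (is.character(id)) {
    bits <- .hex_to_bits(id, n)
  } else {
    if (id < 0 || id >= 2^n) stop("id out of range for m = ", m)
    bits <- (floor(id / 2^(0:(n - 1)))) %% 2
  }
  memory_strategy(as.integer(bits), m = m, name = name)
}

.bits_to_hex <- function(bits) {
  n <- length(bits)
  stopifnot(n %% 4 == 0)
  digs <- vapply(seq_len(n / 4), function(j) {
    v <- sum(bits[(4 * j - 3):(4 * j)] * c(1, 2, 4, 8))
    format.hexmode(as.integer(v))
  }, character(1))
  paste0("0x", paste(rev(digs), collapse = ""))
}

.hex_to_bits <- function(hex, n) {
  hex <- sub("^0[xX]", "", hex)
  digs <- rev(strsplit(tolower(hex), "")[[1]])
  vals <- strtoi(digs, base = 16L)
  if (anyNA(vals)) stop("invalid hex id")
  bits <- integer(length(vals) * 4)
  for (j in seq_along(vals))
    bits[(4 * j - 3):(4 * j)] <- (vals[j] %/% c(1L, 2L, 4L, 8L)) %% 2L
  if (length(bits) < n) bits <- c(bits, integer(n - length(bits)))
  if (length(bits) > n && any(bits[(n + 1):length(bits)] != 0))
    stop("hex id out of range for this m")
  bits[seq_len(n)]
}

#' Embed a memory strategy into a longer memory
#'
#' A memory-m' strategy conditions only on the last m' actions; embedding it
#' at memory `m >= m'` repeats its prescriptions over the extended histories.
#' Used internally to pair strategies of different memory lengths.
#'
#' @param s a [memory_strategy()].
#' @param m target memory length.
#' @export
embed_strategy <- function(s, m) {
  stopifnot(inherits(s, "memory_strategy"), m >= s$m)
  if (m == s$m) return(s)
  m0 <- s$m
  idx <- 0:(4^m - 1)
  ha <- (idx %/% 2^m) %% 2^m0
  hb <- idx %% 2^m0
  out <- probabilistic_memory_strategy(s$probs[ha * 2^m0 + hb + 1], m = m,
                                       name = s$name)
  out$deterministic <- s$deterministic
  out$p0 <- s$p0
  out
}

## ---- text format ----------------------------------------------------------

#' Read and write the one-line strategy text format
#'
#' The format is `m=<int> <4^m characters of c/d>`; a hexadecimal id is also
#' accepted in place of the action string.  `format_strategy()` and
#' `parse_strategy()` round-trip bit-exactly.
#'
#' @param text a line like `"m=2 cdcdcdcdcdcdcdcd"` or `"m=1 0xa"`.
#' @examples
#' parse_strategy("m=1 cdcd")
#' format_strategy(make_named("capri"))
#' @export
parse_strategy <- function(text) {
  text <- trimws(text)
  mm <- regmatches(text, regexec("^m=([0-9]+)\\s+(\\S+)$", text))[[1]]
  if (length(mm) != 3) stop("cannot parse strategy line: ", text)
  m <- as.integer(mm[2])
  body <- mm[3]
  if (grepl("^0[xX]", body) || grepl("^[0-9a-fA-F]+$", body) && !grepl("^[cd]+$", body)) {
    decode_strategy(body, m = m)
  } else {
    memory_strategy(body, m = m)
  }
}

#' @param s a deterministic [memory_strategy()].
#' @rdname parse_strategy
#' @export
format_strategy <- function(s) {
  stopifnot(inherits(s, "memory_strategy"), s$deterministic)
  paste0("m=", s$m, " ", paste(c("c", "d")[strategy_actions(s) + 1], collapse = ""))
}

## ---- memory-one, reactive and ZD tuples -----------------------------------

#' Memory-one strategy from the payoff-conditioned five-tuple
#'
#' The classic representation `(p0, pR, pS, pT, pP)`: `p0` is the
#' first-round cooperation probability and `p_beta` the probability to
#' cooperate after receiving payoff `beta` in the previous round.  Payoffs
#' map to realized action pairs from the focal player's view as
#' R = (c,c), S = (c,d), T = (d,c), P = (d,d).  `p0` is stored but plays no
#' role in long-run payoff computations, which are stationary averages.
#'
#' @param p0,pR,pS,pT,pP probabilities in \[0, 1\].
#' @param name optional display name.
#' @return a `memory_one` object (also a [memory_strategy()] with m = 1).
#' @examples
#' memory_one(1, 1, 0, 1, 0, name = "TFT")
#' @export
memory_one <- function(p0, pR, pS, pT, pP, name = NULL) {
  p <- c(p0, pR, pS, pT, pP)
  if (any(p < -1e-12 | p > 1 + 1e-12)) stop("probabilities must lie in [0, 1]")
  p <- pmin(pmax(p, 0), 1)
  # state order: (c,c)=0 -> R, (c,d)=1 -> S, (d,c)=2 -> T, (d,d)=3 -> P
  out <- probabilistic_memory_strategy(c(p[2], p[3], p[4], p[5]), m = 1, name = name)
  out$p0 <- p[1]
  out$tuple <- stats::setNames(p, c("p0", "pR", "pS", "pT", "pP"))
  class(out) <- c("memory_one", class(out))
  out
}

#' Reactive strategy
#'
#' Cooperates with probability `pc` after the co-player's cooperation and
#' `pd` after the co-player's defection, ignoring its own last move.
#'
#' @param pc,pd probabilities in \[0, 1\].
#' @param name optional display name (default `"R(pc,pd)"`).
#' @export
reactive_strategy <- function(pc, pd, name = NULL) {
  if (is.null(name)) name <- sprintf("R(%g,%g)", pc, pd)
  out <- memory_one(pc, pc, pd, pc, pd, name = name)
  out$pc <- pc
  out$pd <- pd
  class(out) <- c("reactive_strategy", class(out))
  out
}

#' Zero-determinant strategies
#'
#' Generous and extortionate zero-determinant (ZD) memory-one strategies with
#' baseline parameter `eta` in \[0, 1\] and scale `phi > 0`:
#' generous: `(1, 1, 1 - phi*((1-eta)(S-R) + T-S), phi*((1-eta)(R-T) + T-S),
#' phi*(1-eta)*(R-P))`; extortionate: `(0, 1 - phi*(1-eta)*(R-P),
#' 1 - phi*((1-eta)(S-P) + T-S), phi*((1-eta)(P-T) + T-S), 0)`.
#' The constructor rejects parameter choices whose probabilities leave
#' \[0, 1\].
#'
#' @param phi positive scale parameter.
#' @param eta baseline parameter in \[0, 1\].
#' @param flavor `"generous"` or `"extortionate"`.
#' @param payoffs a [payoff_matrix()].
#' @export
zd_strategy <- function(phi, eta, flavor = c("generous", "extortionate"),
                        payoffs = payoff_matrix()) {
  flavor <- match.arg(flavor)
  if (phi <= 0) stop("phi must be positive")
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  R <- payoffs$R; T <- payoffs$T; S <- payoffs$S; P <- payoffs$P
  p <- if (flavor == "generous") {
    c(1, 1,
      1 - phi * ((1 - eta) * (S - R) + T - S),
      phi * ((1 - eta) * (R - T) + T - S),
      phi * (1 - eta) * (R - P))
  } else {
    c(0,
      1 - phi * (1 - eta) * (R - P),
      1 - phi * ((1 - eta) * (S - P) + T - S),
      phi * ((1 - eta) * (P - T) + T - S),
      0)
  }
  if (any(p < -1e-12 | p > 1 + 1e-12))
    stop(flavor, " ZD probabilities leave [0,1] for phi=", phi, ", eta=", eta)
  out <- memory_one(p[1], p[2], p[3], p[4], p[5],
                    name = paste0(flavor, "-ZD"))
  out$phi <- phi
  out$eta <- eta
  out$flavor <- flavor
  class(out) <- c("zd_strategy", class(out))
  out
}

## ---- named strategies -----------------------------------------------------

# CAPRI action table (memory three), rows = Alice's history ccc..ddd,
# columns = Bob's history ccc..ddd, row-major = state-index order.
# Five rules: Cooperate at mutual cooperation; Accept punishment; Punish a
# defection once; Recover from mutual defection; In all other cases defect.
.capri_actions <- paste0(
  "cdddcddd",  # ccc
  "cdcddddd",  # ccd
  "dcddcddd",  # cdc
  "dddddddd",  # cdd
  "cdcdcdcd",  # dcc
  "dddddddd",  # dcd
  "ddddcdcc",  # ddc
  "ddddddcd")  # ddd

#' Construct a named strategy
#'
#' Instantiates the well-known strategies of the repeated prisoner's dilemma
#' by name (case-insensitive): `AllC`, `AllD`, `TFT`, `GTFT` (generous TFT,
#' parameter `q`), `TF2T` (tit-for-two-tats, memory two), `WSLS`
#' (win-stay-lose-shift), `generous-ZD` / `extortionate-ZD` (parameters
#' `phi`, `eta`, `payoffs`), `Trigger` (grim trigger, a two-state automaton),
#' `CAPRI` (the memory-three friendly rival), and `TFT-ATFT` (the memory-two
#' friendly rival, recovered by exhaustive search; see [tft_atft()]).
#'
#' @param name strategy name.
#' @param q GTFT generosity (probability to cooperate after being exploited
#'   or after mutual defection).
#' @param phi,eta,payoffs ZD parameters, see [zd_strategy()].
#' @return a strategy object (memory-one tuple, memory-m table, or automaton).
#' @examples
#' make_named("TFT")$tuple
#' make_named("CAPRI")
#' @export
make_named <- function(name, q = 0.3, phi = 0.1, eta = 0.5,
                       payoffs = payoff_matrix()) {
  key <- tolower(gsub("[ _]", "-", name))
  switch(key,
    "allc" = memory_one(1, 1, 1, 1, 1, name = "AllC"),
    "alld" = memory_one(0, 0, 0, 0, 0, name = "AllD"),
    "tft" = memory_one(1, 1, 0, 1, 0, name = "TFT"),
    "gtft" = memory_one(1, 1, q, 1, q, name = sprintf("GTFT(%g)", q)),
    "wsls" = memory_one(1, 1, 0, 0, 1, name = "WSLS"),
    "tf2t" = .make_tf2t(),
    "generous-zd" = zd_strategy(phi, eta, "generous", payoffs),
    "extortionate-zd" = zd_strategy(phi, eta, "extortionate", payoffs),
    "trigger" = ,
    "grim" = grim_trigger(),
    "capri" = capri(),
    "tft-atft" = ,
    "tftatft" = tft_atft(),
    stop("unknown strategy name: ", name)
  )
}

.make_tf2t <- function() {
  # defect iff the co-player defected in both of the previous two rounds
  idx <- 0:15
  acts <- ifelse(idx %% 4 == 3, 1L, 0L)
  memory_strategy(acts, m = 2, name = "TF2T")
}

#' The CAPRI strategy
#'
#' The memory-three friendly rival defined by five rules: Cooperate at mutual
#' cooperation; Accept punishment after one's own erroneous defection; Punish
#' the co-player's defection by defecting once; Recover cooperation when
#' either player cooperated at mutual defection; In all other cases, defect.
#' It is efficient, defensible and distinguishable, and recovers from a
#' single error in two time steps (the shortest possible).
#'
#' @return a deterministic memory-3 [memory_strategy()].
#' @examples
#' cls <- classify_strategy(capri())
#' cls$successful
#' @export
capri <- function() memory_strategy(.capri_actions, m = 3, name = "CAPRI")

#' Memory-two adaptation of CAPRI (not defensible)
#'
#' A memory-two strategy following CAPRI's five rules, which forces the
#' prescriptions `(cd,dc) -> c` and `(dc,cd) -> c` to recover from error.
#' Those prescriptions open a negative cycle in the adversarial state graph:
#' the co-player can alternate defections so that every one of Alice's
#' punishments is refunded, gaining `(T - S)` once per period.  Used to
#' demonstrate why the genuine CAPRI needs memory three.
#'
#' @return a deterministic memory-2 [memory_strategy()].
#' @seealso [find_negative_cycle()], [verify_exploit()]
#' @export
capri_two <- function() {
  coop <- c("(cc,cc)",             # cooperate
            "(cd,cc)", "(dc,cd)",  # accept punishment
            "(cd,dc)", "(dc,cc)",  # after punishing once
            "(cc,dc)",             # co-player accepted punishment
            "(dd,dc)", "(dc,dc)")  # recover from mutual defection
  acts <- rep(1L, 16)
  labs <- state_label(0:15, 2)
  acts[labs %in% coop] <- 0L
  memory_strategy(acts, m = 2, name = "CAPRI-2")
}

#' Grim trigger as a two-state automaton
#'
#' Cooperates until any defection (by either player) has been observed, then
#' defects forever.  Grim trigger conditions on the unbounded past, so it is
#' not memory-m for any finite m and is represented as a Moore automaton.
#'
#' @return a [moore_automaton()].
#' @export
grim_trigger <- function() {
  tr <- matrix(c(1, 2, 2, 2,
                 2, 2, 2, 2), nrow = 2, byrow = TRUE,
               dimnames = list(NULL, c("cc", "cd", "dc", "dd")))
  moore_automaton(output = c("c", "d"), transition = tr, initial = 1,
                  name = "Trigger")
}

#' The TFT-ATFT strategy, recovered by exhaustive search
#'
#' Among the 65,536 deterministic memory-two strategies exactly four satisfy
#' efficiency, defensibility and distinguishability.  They differ only at
#' rarely visited states; the canonical member returned here is the one that
#' agrees with TFT (copy the co-player's last move) at all four states whose
#' own history is `cc`, with the smallest id as tie-break.  It behaves as TFT
#' except after its own erroneous defection, when it switches to
#' anti-tit-for-tat moves; its recovery path takes three time steps.
#'
#' The memory-two scan runs on first use (a few seconds) and is cached for
#' the session.
#'
#' @return a deterministic memory-2 [memory_strategy()].
#' @export
tft_atft <- function() {
  if (!is.null(.fr_cache$tft_atft)) return(.fr_cache$tft_atft)
  rep2 <- enumerate_strategies(2)
  ids <- rep2$successful_ids
  stopifnot(length(ids) >= 1)
  agrees_tft <- vapply(ids, function(id) {
    acts <- strategy_actions(decode_strategy(id, 2))
    # states with own history cc are indices 0..3; TFT copies Bob's last move
    all(acts[1:4] == c(0L, 1L, 0L, 1L))
  }, logical(1))
  pick <- if (any(agrees_tft)) min(ids[agrees_tft]) else min(ids)
  out <- decode_strategy(pick, 2, name = "TFT-ATFT")
  .fr_cache$tft_atft <- out
  out
}
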