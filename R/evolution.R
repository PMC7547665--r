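# Low-mutation Moran/imitation dynamics over a mutant set of reactive
# strategies plus optional special strategies (CAPRI, TFT-ATFT): closed-form
# fixation probabilities, long-run resident abundances, and the
# evolutionary-robustness certificate of friendly rivals.

## ---- configuration --------------------------------------------------------

#' Configuration of the low-mutation evolutionary simulation
#'
#' The population is monomorphic between mutation events (low-mutation
#' regime): a single mutant either fixes, with the closed-form Moran
#' fixation probability, or vanishes.  Defaults follow the donation-game
#' setting `b = 3`, `N = 50`, `e = 1e-3`, selection strength
#' `sigma = 10 / N` (so `N sigma = 10`), with mutants drawn from the 11 x 11
#' reactive-strategy grid and, with probability `mu`, from the `special`
#' set.
#'
#' @param N population size (>= 2).
#' @param b donation-game benefit (unit cost); payoffs `R = b - 1`, `T = b`,
#'   `S = -1`, `P = 0`.
#' @param e implementation error rate used for all long-run payoffs.
#' @param sigma selection strength (default `10 / N`).
#' @param mu probability that a mutant is drawn from the special set
#'   (uniformly within it) instead of the reactive grid.
#' @param special named list of special strategies (e.g.
#'   `list(CAPRI = capri())`).
#' @param grid list of reactive mutants (default [reactive_grid()]).
#' @param steps number of mutant introductions per run.
#' @param runs number of independent runs to average.
#' @param seed integer seed.
#' @return an `evolution_config` list.
#' @export
evolution_config <- function(N = 50, b = 3, e = 1e-3, sigma = 10 / N,
                             mu = 0, special = list(), grid = reactive_grid(),
                             steps = 1e5, runs = 3, seed = 1) {
  if (N < 2) stop("population size N must be at least 2")
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  if (mu > 0 && length(special) == 0) stop("mu > 0 needs a non-empty special set")
  if (length(special) && is.null(names(special)))
    names(special) <- vapply(special, function(s)
      if (!is.null(s$name)) s$name else "special", character(1))
  structure(list(N = N, b = b, e = e, sigma = sigma, mu = mu,
                 special = special, grid = grid, steps = steps, runs = runs,
                 seed = seed, payoffs = donation_payoffs(b)),
            class = "evolution_config")
}

#' The discretized reactive-strategy mutant set
#'
#' Reactive strategies `(pc, pd)` on the grid
#' `{0, 1/10, ..., 9/10, 1}^2` (121 strategies by default).
#'
#' @param levels grid levels for each probability.
#' @return named list of [reactive_strategy()] objects.
#' @export
reactive_grid <- function(levels = seq(0, 1, by = 0.1)) {
  out <- list()
  for (pc in levels) for (pd in levels) {
    s <- reactive_strategy(pc, pd)
    out[[s$name]] <- s
  }
  out
}

#' Partner / rival / other classification of a reactive strategy
#'
#' Rival reactive strategies never cooperate after a defection
#' (`pd = 0`); partners always reciprocate cooperation (`pc = 1`) and are
#' forgiving but not too forgiving
#' (`pd < p_d* = min{1 - (T-R)/(R-S), (R-P)/(T-P)}`).  A strategy with
#' `pc = 1` and `pd = 0` counts as a rival (tie-break).
#'
#' @param s a [reactive_strategy()].
#' @param payoffs a [payoff_matrix()].
#' @return `"rival"`, `"partner"` or `"other"`.
#' @examples
#' classify_reactive(reactive_strategy(1, 0.5), donation_payoffs(3))  # partner
#' @export
classify_reactive <- function(s, payoffs) {
  stopifnot(inherits(s, "reactive_strategy"))
  if (s$pd == 0) return("rival")
  pdstar <- reactive_pd_star(payoffs)
  if (s$pc == 1 && s$pd < pdstar) return("partner")
  "other"
}

#' @rdname classify_reactive
#' @export
reactive_pd_star <- function(payoffs) {
  with(payoffs, min(1 - (T - R) / (R - S), (R - P) / (T - P)))
}

## ---- fixation probabilities -----------------------------------------------

#' Pairwise imitation probability
#'
#' Fermi update: the probability that a player with payoff `sx` adopts the
#' strategy of a co-player with payoff `sy` is
#' `1 / (1 + exp(sigma (sx - sy)))`.
#'
#' @param sx,sy average payoffs.
#' @param sigma selection strength.
#' @export
imitation_probability <- function(sx, sy, sigma) {
  1 / (1 + exp(sigma * (sx - sy)))
}

#' Moran fixation probability from the four pair payoffs
#'
#' Closed form for a single mutant X in a resident population of Y under
#' the imitation process:
#' `rho = 1 / sum_{i=0}^{N-1} prod_{j=1}^{i} exp(sigma ((N-j-1) s_yy +
#' j s_yx - (N-j) s_xy - (j-1) s_xx))`, evaluated in log space (cumulative
#' sums of exponents with a log-sum-exp) so that large `sigma N` cannot
#' overflow.  Equal payoffs give exactly `1/N`.
#'
#' @param s_xx,s_xy,s_yx,s_yy long-run payoffs: mutant vs mutant, mutant vs
#'   resident, resident vs mutant, resident vs resident.
#' @param N population size.
#' @param sigma selection strength.
#' @return fixation probability in \[0, 1\].
#' @examples
#' fixation_from_payoffs(2, 2, 2, 2, N = 50, sigma = 0.2)  # 1/50
#' @export
fixation_from_payoffs <- function(s_xx, s_xy, s_yx, s_yy, N, sigma) {
  if (N < 2) stop("N must be at least 2")
  j <- seq_len(N - 1)
  terms <- sigma * ((N - j - 1) * s_yy + j * s_yx - (N - j) * s_xy -
                      (j - 1) * s_xx)
  expo <- c(0, cumsum(terms))  # E_i for i = 0 .. N-1
  mx <- max(expo)
  exp(-(mx + log(sum(exp(expo - mx)))))
}

#' Fixation probability of a mutant strategy against a resident
#'
#' Computes the four pair payoffs as stationary chain averages at the
#' configured error rate and donation payoffs, then applies
#' [fixation_from_payoffs()].
#'
#' @param x mutant strategy.
#' @param y resident strategy.
#' @param cfg an [evolution_config()].
#' @return list with `rho` and the four `payoffs`.
#' @export
fixation_probability <- function(x, y, cfg = evolution_config()) {
  pxx <- .pair_payoffs(x, x, cfg)
  pxy <- .pair_payoffs(x, y, cfg)
  pyy <- .pair_payoffs(y, y, cfg)
  rho <- fixation_from_payoffs(pxx[1], pxy[1], pxy[2], pyy[1],
                               N = cfg$N, sigma = cfg$sigma)
  list(rho = rho,
       payoffs = c(s_xx = pxx[1], s_xy = pxy[1], s_yx = pxy[2], s_yy = pyy[1]))
}

# (pi_A, pi_B) of strategy a against strategy b at the configured e
.pair_payoffs <- function(a, b, cfg) {
  ch <- build_chain(a, b, e = cfg$e, payoffs = cfg$payoffs)
  if (cfg$e > 0) ch$deterministic <- FALSE
  sp <- stationary_payoffs(ch)
  c(sp$pi_A, sp$pi_B)
}

## ---- payoff table over the mutant set -------------------------------------

#' Pairwise long-run payoff table of a strategy set
#'
#' `S[i, j]` is the stationary payoff of strategy `i` against strategy `j`
#' at error rate `e`.  Each unordered pair needs one chain solve.
#'
#' @param strategies named list of strategies.
#' @param payoffs a [payoff_matrix()].
#' @param e error rate.
#' @return numeric matrix with strategy names on both dimensions.
#' @export
payoff_table <- function(strategies, payoffs, e) {
  n <- length(strategies)
  S <- matrix(NA_real_, n, n,
              dimnames = list(names(strategies), names(strategies)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ch <- build_chain(strategies[[i]], strategies[[j]], e = e,
                        payoffs = payoffs)
      if (e > 0) ch$deterministic <- FALSE
      sp <- stationary_payoffs(ch)
      S[i, j] <- sp$pi_A
      S[j, i] <- sp$pi_B
    }
  }
  S
}

## ---- the Moran simulation -------------------------------------------------

#' Low-mutation Moran simulation over the mutant set
#'
#' The resident strategy performs a random walk on the strategy set: at each
#' step a mutant is drawn (from the special set with probability `mu`,
#' uniformly within it; otherwise uniformly from the reactive grid) and
#' replaces the resident with its fixation probability.  Abundance is the
#' fraction of steps each strategy spends as resident, averaged over
#' `cfg$runs` independent runs.
#'
#' @param cfg an [evolution_config()].
#' @param payoff_cache optional precomputed [payoff_table()] over
#'   `c(cfg$grid, cfg$special)` (computed if missing; reusable across
#'   configurations sharing `b` and `e`).
#' @param verbose print timing messages.
#' @return an `abundance_report`: `per_strategy` (named abundance vector,
#'   sums to 1), `per_class` (partner / rival / other / special fractions),
#'   `config`, and the `payoff_cache` used.
#' @export
run_moran <- function(cfg = evolution_config(), payoff_cache = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(cfg, "evolution_config"))
  strategies <- c(cfg$grid, cfg$special)
  n <- length(strategies)
  if (n == 0) stop("empty mutant set")
  n_grid <- length(cfg$grid)
  if (is.null(payoff_cache)) {
    if (verbose) message("computing ", n, "x", n, " payoff table ...")
    payoff_cache <- payoff_table(strategies, cfg$payoffs, cfg$e)
  }
  stopifnot(nrow(payoff_cache) == n)
  classes <- c(vapply(cfg$grid, classify_reactive, character(1),
                      payoffs = cfg$payoffs),
               rep("special", length(cfg$special)))

  # fixation probability of mutant i against resident j, precomputed once
  rho_mat <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    rho_mat[i, j] <- fixation_from_payoffs(
      payoff_cache[i, i], payoff_cache[i, j],
      payoff_cache[j, i], payoff_cache[j, j],
      N = cfg$N, sigma = cfg$sigma)

  occupancy <- matrix(0, nrow = cfg$runs, ncol = n)
  for (r in seq_len(cfg$runs)) {
    occupancy[r, ] <- .with_seed(cfg$seed + r - 1, {
      counts <- numeric(n)
      resident <- sample.int(n_grid, 1)
      u_special <- runif(cfg$steps)
      u_fix <- runif(cfg$steps)
      for (t in seq_len(cfg$steps)) {
        mutant <- if (u_special[t] < cfg$mu)
          n_grid + sample.int(n - n_grid, 1)
        else sample.int(n_grid, 1)
        if (u_fix[t] < rho_mat[mutant, resident]) resident <- mutant
        counts[resident] <- counts[resident] + 1
      }
      counts / cfg$steps
    })
  }
  per_strategy <- colMeans(occupancy)
  names(per_strategy) <- names(strategies)
  per_class <- vapply(c("partner", "rival", "other", "special"),
                      function(k) sum(per_strategy[classes == k]), numeric(1))
  structure(list(per_strategy = per_strategy, per_class = per_class,
                 classes = classes, config = cfg,
                 payoff_cache = payoff_cache),
            class = "abundance_report")
}

#' @export
print.abundance_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<abundance: b=%g N=%d e=%g sigma=%g mu=%g, %g steps x %d runs>\n",
              cfg$b, cfg$N, cfg$e, cfg$sigma, cfg$mu, cfg$steps, cfg$runs))
  cat("  per class:",
      paste(sprintf("%s=%.3f", names(x$per_class), x$per_class),
            collapse = "  "), "\n")
  top <- sort(x$per_strategy, decreasing = TRUE)[1:min(5, length(x$per_strategy))]
  cat("  top strategies:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = "  "), "\n")
  invisible(x)
}

#' Abundance report as JSON
#'
#' @param report an [run_moran()] result.
#' @return JSON string echoing the configuration and the abundances.
#' @export
abundance_json <- function(report) {
  stopifnot(inherits(report, "abundance_report"))
  cfg <- report$config
  jsonlite::toJSON(list(
    config = list(N = cfg$N, b = cfg$b, e = cfg$e, sigma = cfg$sigma,
                  mu = cfg$mu, steps = cfg$steps, runs = cfg$runs,
                  seed = cfg$seed,
                  special = names(cfg$special)),
    per_class = as.list(report$per_class),
    per_strategy = as.list(report$per_strategy)), auto_unbox = TRUE,
    digits = NA)
}

## ---- evolutionary robustness ----------------------------------------------

#' Evolutionary-robustness certificate of a friendly rival
#'
#' A strategy Y that is simultaneously a partner (`s_yy >= s_xy`,
#' `s_yy >= s_xx`) and a rival (`s_yx >= s_xy`) has mutant fixation
#' probability `rho <= 1/N` for every mutant X, population size N and
#' selection strength (by Jensen's inequality applied to the closed-form
#' `rho`).  This helper checks the three payoff inequalities and the
#' fixation bound for every supplied mutant and N.
#'
#' The partner and rival payoff inequalities are exact statements about the
#' zero-error limit: at any finite error rate a defector-type mutant earns
#' O(e) more than the friendly rival (whose recovery rule donates a round of
#' cooperation at rate O(e)), so at `N = 2` its fixation probability exceeds
#' `1/N` by O(sigma e).  The certificate therefore evaluates payoffs at a
#' very small error rate (`e = 1e-8` by default, a numerical stand-in for
#' the limit) and allows tolerance `tol` on each inequality and on the
#' `1/N` bound.
#'
#' @param y resident strategy (expected to be a friendly rival; a warning is
#'   issued otherwise for deterministic memory strategies).
#' @param mutants list of mutant strategies (default [reactive_grid()]).
#' @param N_grid population sizes to test.
#' @param payoffs a [payoff_matrix()].
#' @param e evaluation error rate (default effectively the e -> 0+ limit).
#' @param sigma_rule function of N giving sigma (default `10 / N`).
#' @param tol tolerance on the payoff inequalities and the fixation bound.
#' @return list with `ok` (no violations), `violations` (data frame of
#'   offending payoffs / fixation probabilities), and the full `table`.
#' @examples
#' \donttest{
#' cert <- robustness_certificate(capri(), mutants = list(make_named("AllD")))
#' cert$ok
#' }
#' @export
robustness_certificate <- function(y, mutants = reactive_grid(),
                                   N_grid = c(2, 10, 50),
                                   payoffs = donation_payoffs(3), e = 1e-8,
                                   sigma_rule = function(N) 10 / N,
                                   tol = 1e-6) {
  if (inherits(y, "memory_strategy") && y$deterministic) {
    cl <- cpp_classify(strategy_actions(y), y$m, need_distinguishable = FALSE)
    if (!(cl$efficient && cl$defensible))
      warning("resident is not a friendly rival; the 1/N bound need not hold")
  }
  cfg0 <- list(e = e, payoffs = payoffs)
  syy <- .pair_payoffs(y, y, cfg0)[1]
  rows <- list()
  for (k in seq_along(mutants)) {
    x <- mutants[[k]]
    sxx <- .pair_payoffs(x, x, cfg0)[1]
    sxy_syx <- .pair_payoffs(x, y, cfg0)
    sxy <- sxy_syx[1]; syx <- sxy_syx[2]
    ineq <- c(partner1 = syy >= sxy - tol, partner2 = syy >= sxx - tol,
              rival = syx >= sxy - tol)
    for (N in N_grid) {
      rho <- fixation_from_payoffs(sxx, sxy, syx, syy, N, sigma_rule(N))
      rows[[length(rows) + 1]] <- data.frame(
        mutant = if (!is.null(x$name)) x$name else paste0("mutant", k),
        N = N, rho = rho, bound = 1 / N,
        s_xx = sxx, s_xy = sxy, s_yx = syx, s_yy = syy,
        ok = all(ineq) && rho <= 1 / N + tol)
    }
  }
  tab <- do.call(rbind, rows)
  list(ok = all(tab$ok), violations = tab[!tab$ok, , drop = FALSE],
       table = tab)
}
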