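# Exhaustive classification of the memory-one and memory-two strategy
# spaces, random sampling of the memory-three space, and recovery-pattern
# tallies over successful strategies.

#' Exhaustively classify a memory-m strategy space (m <= 2)
#'
#' Scans every deterministic strategy id in `[0, 2^(4^m))`, deciding
#' defensibility (negative-cycle check) and efficiency (zero-error limit of
#' self-play) for each, and distinguishability for the strategies passing
#' both.  The whole memory-two space (65,536 strategies) takes a few
#' seconds; memory three is out of reach of a desk machine (about 1.8e19
#' strategies) and is refused -- use [sample_m3()].
#'
#' Results are memoised for the session; `cache_file` additionally persists
#' the per-strategy table as CSV (`id, m, efficient, defensible,
#' distinguishable, recovery_steps`) and is reused when present.
#'
#' @param m memory length, 1 or 2.
#' @param cache_file optional CSV path for the per-strategy table.
#' @param verbose print progress messages.
#' @return an `enumeration_report`: `m`, `total`, `n_efficient`,
#'   `n_defensible`, `n_intersection` (friendly rivals), `n_successful`,
#'   `friendly_rival_ids`, `successful_ids`, `pattern_tally` (recovery
#'   patterns of the successful strategies), and the full `table`.
#' @examples
#' \donttest{
#' rep1 <- enumerate_strategies(1)
#' rep1$n_intersection  # 0: no friendly rival with memory one
#' }
#' @export
enumerate_strategies <- function(m, cache_file = NULL, verbose = FALSE) {
  if (!m %in% c(1, 2))
    stop("exhaustive enumeration is only feasible for m in {1, 2}; ",
         "for m = 3 use sample_m3()")
  key <- paste0("scan_m", m)
  if (!is.null(.fr_cache[[key]])) return(.fr_cache[[key]])

  tab <- NULL
  if (!is.null(cache_file) && file.exists(cache_file)) {
    tab <- utils::read.csv(cache_file)
    if (verbose) message("loaded cached scan from ", cache_file)
  }
  if (is.null(tab)) {
    if (verbose) message("scanning ", 2^(4^m), " memory-", m, " strategies ...")
    sc <- cpp_scan(m)
    tab <- data.frame(id = seq_along(sc$efficient) - 1, m = m,
                      efficient = sc$efficient, defensible = sc$defensible,
                      distinguishable = sc$distinguishable,
                      recovery_steps = NA_integer_)
    fr <- which(tab$efficient & tab$defensible)
    for (i in fr) {
      rp <- recovery_path(decode_strategy(tab$id[i], m))
      if (rp$recovered) tab$recovery_steps[i] <- rp$steps_after_error
    }
    if (!is.null(cache_file)) utils::write.csv(tab, cache_file, row.names = FALSE)
  }

  fr_ids <- tab$id[tab$efficient & tab$defensible]
  succ_ids <- tab$id[tab$efficient & tab$defensible &
                       !is.na(tab$distinguishable) & tab$distinguishable]
  tally <- if (length(succ_ids)) {
    tally_recovery_patterns(succ_ids, m)
  } else integer(0)
  out <- structure(list(
    m = m, total = nrow(tab),
    n_efficient = sum(tab$efficient),
    n_defensible = sum(tab$defensible),
    n_intersection = length(fr_ids),
    n_successful = length(succ_ids),
    friendly_rival_ids = fr_ids,
    successful_ids = succ_ids,
    pattern_tally = tally,
    table = tab), class = "enumeration_report")
  .fr_cache[[key]] <- out
  out
}

#' @export
print.enumeration_report <- function(x, ...) {
  cat(sprintf("<memory-%d enumeration: %d strategies>\n", x$m, x$total))
  cat(sprintf("  efficient:        %d\n", x$n_efficient))
  cat(sprintf("  defensible:       %d\n", x$n_defensible))
  cat(sprintf("  friendly rivals:  %d\n", x$n_intersection))
  cat(sprintf("  successful:       %d\n", x$n_successful))
  if (length(x$successful_ids))
    cat("  successful ids:  ", paste(x$successful_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Headline counts of an enumeration as JSON
#'
#' @param report an [enumerate_strategies()] report.
#' @return a JSON string with the four headline counts.
#' @export
enumeration_summary_json <- function(report) {
  stopifnot(inherits(report, "enumeration_report"))
  jsonlite::toJSON(list(m = report$m, total = report$total,
                        n_efficient = report$n_efficient,
                        n_defensible = report$n_defensible,
                        n_intersection = report$n_intersection,
                        n_successful = report$n_successful),
                   auto_unbox = TRUE)
}

#' Classify a random sample of the memory-three space
#'
#' The memory-three space holds 2^64 strategies; friendly rivals are a
#' vanishing fraction of it (about 3.8e-7), so random sampling is a
#' desk-scale probe, not a search.  Draws `n` ids uniformly and classifies
#' each; reproducible under `seed`.
#'
#' @param n number of sampled strategies.
#' @param seed integer seed.
#' @param filter optional character vector from
#'   `c("efficient", "defensible", "distinguishable", "successful")`; only
#'   rows satisfying all named criteria are returned.
#' @param include optional list of extra strategies to classify alongside
#'   the sample (e.g. `list(capri())`).
#' @return data frame with columns `id` (hex), `efficient`, `defensible`,
#'   `distinguishable`, `successful`.
#' @examples
#' sample_m3(5, seed = 42)
#' @export
sample_m3 <- function(n, seed = 1, filter = NULL, include = NULL) {
  stopifnot(n >= 0)
  bits <- .with_seed(seed, matrix(rbinom(64 * n, 1, 0.5), nrow = max(n, 0)))
  strategies <- lapply(seq_len(n), function(i) memory_strategy(bits[i, ], m = 3))
  strategies <- c(strategies, lapply(include, embed_strategy, m = 3))
  rows <- lapply(strategies, function(s) {
    acts <- strategy_actions(s)
    cl <- cpp_classify(acts, 3L, need_distinguishable = TRUE)
    data.frame(id = encode_strategy(s),
               efficient = cl$efficient, defensible = cl$defensible,
               distinguishable = cl$distinguishable,
               successful = cl$efficient && cl$defensible &&
                 isTRUE(cl$distinguishable))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), efficient = logical(0),
               defensible = logical(0), distinguishable = logical(0),
               successful = logical(0))
  if (!is.null(filter)) {
    bad <- setdiff(filter, c("efficient", "defensible", "distinguishable",
                             "successful"))
    if (length(bad)) stop("unknown filter criteria: ", paste(bad, collapse = ", "))
    keep <- rep(TRUE, nrow(out))
    for (f in filter) keep <- keep & !is.na(out[[f]]) & out[[f]]
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Tally recovery patterns over successful strategies
#'
#' Groups strategies by the action sequences of their recovery path after a
#' single co-player error (Alice's and Bob's actions from the error round to
#' the first restored mutual cooperation).
#'
#' @param ids strategy ids (numeric or hex) or a list of strategies.
#' @param m memory length (ignored when `ids` is a list of strategies).
#' @return named integer vector, names like `"cdc/dcc"`, sorted by count.
#' @examples
#' tally_recovery_patterns(list(capri()))
#' @export
tally_recovery_patterns <- function(ids, m = NULL) {
  if (length(ids) == 0) return(integer(0))
  strategies <- if (is.list(ids) && inherits(ids[[1]], "pd_strategy")) ids
  else lapply(ids, decode_strategy, m = m)
  pats <- vapply(strategies, function(s) {
    rp <- recovery_path(s)
    if (!rp$recovered)
      stop("non-recovering strategy in tally: successful strategies must ",
           "recover mutual cooperation")
    .recovery_pattern(rp)
  }, character(1))
  sort(table(pats), decreasing = TRUE)
}
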