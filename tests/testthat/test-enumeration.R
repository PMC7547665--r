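test_that("memory-one space: 16 strategies, no friendly rival", {
  rep1 <- enumerate_strategies(1)
  expect_equal(rep1$total, 16)
  expect_equal(rep1$n_intersection, 0)
  expect_equal(rep1$n_successful, 0)
  # cross-check the counts against per-strategy classification
  eff <- vapply(0:15, function(id) is_efficient(decode_strategy(id, 1)), logical(1))
  def <- vapply(0:15, function(id) is_defensible(decode_strategy(id, 1)), logical(1))
  expect_equal(rep1$n_efficient, sum(eff))
  expect_equal(rep1$n_defensible, sum(def))
  expect_false(any(eff & def))
})

test_that("enumeration refuses the memory-three space", {
  expect_error(enumerate_strategies(3), "sample_m3")
})

test_that("friendly rivals contain the successful strategies and self-cooperate", {
  rep2 <- enumerate_strategies(2)
  expect_true(all(rep2$successful_ids %in% rep2$friendly_rival_ids))
  for (id in rep2$friendly_rival_ids) {
    s <- decode_strategy(id, 2)
    lp <- limit_payoffs(zero_error_limit(s, s))
    expect_equal(lp$pi_A[lp$in_support], 3)  # self-play limit payoff R
  }
})

test_that("the four successful memory-two strategies share TFT-ATFT's recovery pattern", {
  rep2 <- enumerate_strategies(2)
  expect_length(rep2$pattern_tally, 1)
  expect_equal(names(rep2$pattern_tally), "cddc/ddcc")
  expect_equal(unname(rep2$pattern_tally[1]), 4L)
  ta <- tft_atft()
  expect_true(ta$m == 2)
  rp <- recovery_path(ta)
  expect_equal(rp$steps_after_error, 3L)
  # behaves as TFT whenever its own recent history is clean
  expect_equal(strategy_actions(ta)[1:4], c(0L, 1L, 0L, 1L))
  cl <- classify_strategy(ta)
  expect_true(cl$successful)
})

test_that("memory-three sampling is reproducible and flags CAPRI as successful", {
  s1 <- sample_m3(50, seed = 123)
  s2 <- sample_m3(50, seed = 123)
  expect_identical(s1, s2)
  expect_false(identical(s1, sample_m3(50, seed = 124)))
  # friendly rivals are a ~4e-7 fraction: a random draw finds essentially none
  expect_lte(sum(s1$efficient & s1$defensible), 1)

  inc <- sample_m3(0, seed = 1, include = list(capri()))
  expect_equal(nrow(inc), 1)
  expect_true(inc$successful)

  filt <- sample_m3(50, seed = 123, filter = "defensible")
  expect_true(all(filt$defensible))
  expect_error(sample_m3(5, filter = "shiny"), "unknown filter")
})

test_that("recovery-pattern tallies group by action sequences and reject non-recovery", {
  expect_equal(length(tally_recovery_patterns(integer(0))), 0)
  tl <- tally_recovery_patterns(list(capri()))
  expect_equal(names(tl), "cdc/dcc")
  grim3 <- memory_strategy(c(0L, rep(1L, 63)), 3)
  expect_error(tally_recovery_patterns(list(grim3)), "recover")
})

test_that("cmd wrappers emit valid JSON and CSV", {
  js <- cmd_classify(name = "CAPRI", quiet = TRUE)
  parsed <- jsonlite::fromJSON(js)
  expect_true(parsed$successful)
  expect_equal(parsed$recovery_steps, 2)
  expect_equal(parsed$recovery_path$alice, "cdc")

  tmp <- tempfile(fileext = ".csv")
  js2 <- cmd_enumerate(1, out = tmp, quiet = TRUE)
  expect_equal(jsonlite::fromJSON(js2)$n_intersection, 0)
  tab <- read.csv(tmp)
  expect_equal(nrow(tab), 16)
  unlink(tmp)

  res <- cmd_sample_payoffs(name = "CAPRI", n = 10, seed = 3, quiet = TRUE)
  expect_equal(res$summary$frac_not_outperformed, 1)
})

test_that("on-disk scan caches round-trip through CSV", {
  tmp <- tempfile(fileext = ".csv")
  r1 <- enumerate_strategies(1)
  write.csv(r1$table, tmp, row.names = FALSE)
  tab <- read.csv(tmp)
  expect_identical(tab$efficient, r1$table$efficient)
  expect_identical(tab$defensible, r1$table$defensible)
  expect_identical(as.integer(tab$recovery_steps), r1$table$recovery_steps)
  unlink(tmp)
})
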