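test_that("classic strategies land on the documented sides of each criterion", {
  expect_true(is_defensible(make_named("AllD")))
  expect_true(is_defensible(make_named("TFT")))
  expect_true(is_defensible(grim_trigger()))
  expect_false(is_defensible(make_named("WSLS")))

  expect_true(is_efficient(memory_strategy(strrep("c", 4))))   # AllC
  expect_true(is_efficient(make_named("WSLS")))
  expect_true(is_efficient(make_named("TF2T")))
  expect_true(is_efficient(make_named("GTFT", q = 0.3)))       # probabilistic path
  expect_false(is_efficient(make_named("AllD")))
  expect_false(is_efficient(grim_trigger()))

  expect_true(is_distinguishable(make_named("AllD")))
  expect_false(is_distinguishable(make_named("TFT")))
  expect_false(is_distinguishable(memory_strategy(strrep("c", 4))))
})

test_that("aggregate classification composes the flags correctly", {
  tft <- classify_strategy(make_named("TFT"))
  expect_equal(unlist(tft[c("efficient", "defensible", "distinguishable",
                            "friendly_rival", "successful")]),
               c(efficient = FALSE, defensible = TRUE, distinguishable = FALSE,
                 friendly_rival = FALSE, successful = FALSE))
  allc <- classify_strategy(memory_strategy(strrep("c", 4)))
  expect_true(allc$efficient && !allc$defensible && !allc$successful)
  cap <- classify_strategy(capri())
  expect_true(cap$successful)
  expect_equal(cap$recovery_steps, 2L)
})

test_that("a strategy defecting at full cooperation cannot be efficient", {
  set.seed(29)
  for (i in 1:20) {
    acts <- rbinom(16, 1, 0.5)
    acts[1] <- 1L  # defect at (cc,cc)
    expect_false(is_efficient(memory_strategy(acts, 2)))
  }
})

test_that("recovery paths: CAPRI two steps, TFT-ATFT three, grim-like never", {
  rp <- recovery_path(capri())
  expect_true(rp$recovered)
  expect_equal(rp$steps_after_error, 2L)
  expect_equal(paste(rp$alice, collapse = ""), "cdc")
  expect_equal(paste(rp$bob, collapse = ""), "dcc")

  # grim as a memory-3 table: defect unless everything was cooperative
  grim3 <- memory_strategy(c(0L, rep(1L, 63)), 3)
  expect_false(recovery_path(grim3)$recovered)

  expect_error(recovery_path(make_named("AllD")), "fixed point")
})

test_that("non-defensible verdicts come with a realizable exploit cycle", {
  set.seed(31)
  tested <- 0
  while (tested < 15) {
    s <- rand_strategy(2)
    if (is_defensible(s)) next
    tested <- tested + 1
    nc <- find_negative_cycle(s)
    expect_false(is.null(nc))
    expect_lt(nc$weight, 0)
    expect_gt(verify_exploit(s, nc), 0)  # Bob's realized advantage per round
  }
})

test_that("defensible strategies are never outperformed in co-simulation", {
  set.seed(37)
  checked <- 0
  while (checked < 10) {
    s <- rand_strategy(2)
    if (!is_defensible(s)) next
    checked <- checked + 1
    actA <- 1 - embed_strategy(s, 3)$probs
    for (j in 1:25) {
      opp <- rbinom(64, 1, 0.5)
      gain <- friendlyrival:::cpp_max_opponent_gain(actA, opp, 3L)
      expect_lte(gain, 1e-9)
    }
  }
})

test_that("the memory-two CAPRI adaptation is exploitable through its recovery states", {
  c2 <- capri_two()
  acts <- 1 - c2$probs
  expect_equal(acts[st("cd", "dc") + 1], 0)  # the forced recovery prescriptions
  expect_equal(acts[st("dc", "cd") + 1], 0)
  expect_false(is_defensible(c2))
  expect_true(is_defensible(capri()))  # memory three resolves it

  # the exploit sequence: Bob alternates d,c,d against Alice's c,d,c pattern,
  # cycling (cc,cd) -> (cd,dc) -> (dc,cd) -> (cc,dc) -> (cc,cd)
  exploit_cycle <- list(states = st("cc", "cd") + 1L,
              alice = c("d", "c", "c", "c"),
              bob = c("c", "d", "c", "d"))
  gain <- verify_exploit(c2, exploit_cycle)
  expect_equal(gain, (4 - 0) / 4)  # one net (T - S) per four rounds

  # and an automatically found witness agrees in sign
  nc <- find_negative_cycle(c2)
  expect_gt(verify_exploit(c2, nc), 0)
})

test_that("R-level criteria agree with the compiled bulk classifier", {
  set.seed(41)
  for (i in 1:40) {
    m <- sample(2:3, 1)
    s <- rand_strategy(m)
    cc <- friendlyrival:::cpp_classify(strategy_actions(s), s$m, TRUE)
    expect_identical(is_efficient(s), cc$efficient)
    expect_identical(is_defensible(s), cc$defensible)
    expect_identical(is_distinguishable(s), as.logical(cc$distinguishable))
  }
})

test_that("extortionate ZD is empirically never outperformed near the error-free limit", {
  ez <- make_named("extortionate-ZD", phi = 0.1, eta = 0.5)
  res <- check_defensible_empirical(ez)
  expect_true(res)
  # AllC by contrast is beaten outright
  res2 <- check_defensible_empirical(make_named("AllC"),
                                     opponents = list(make_named("AllD")))
  expect_false(res2)
})
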