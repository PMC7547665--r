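test_that("joint state indexing, shifting and swapping behave as an m-round window", {
  expect_equal(joint_state_index("ccc", "ccc"), 0)
  expect_equal(joint_state_index("ddd", "ddd"), 63)
  expect_equal(joint_state_index("ccc", "ccd"), 1)
  expect_equal(state_label(joint_state_index("cdc", "dcc"), 3), "(cdc,dcc)")
  set.seed(1)
  for (m in 1:3) {
    s <- sample(0:(4^m - 1), 5, replace = TRUE)
    expect_equal(swap_state(swap_state(s, m), m), s)
    # shift drops the oldest action and appends the new pair
    s2 <- shift_state(s, 1, 0, m)
    expect_equal(s2 %% 2, rep(0, 5))                       # Bob's newest = c
    expect_equal((s2 %/% 2^m) %% 2, rep(1, 5))             # Alice's newest = d
  }
})

test_that("encode/decode is a bijection over the whole m=1 space and samples of m=2/3", {
  for (id in 0:15) expect_equal(encode_strategy(decode_strategy(id, 1)), id)
  set.seed(42)
  for (id in sample(0:65535, 50)) {
    expect_equal(encode_strategy(decode_strategy(id, 2)), id)
  }
  for (i in 1:20) {
    s <- rand_strategy(3)
    hex <- encode_strategy(s)
    expect_match(hex, "^0x[0-9a-f]{16}$")
    expect_identical(strategy_actions(decode_strategy(hex, 3)),
                     strategy_actions(s))
  }
  expect_equal(encode_strategy(memory_strategy("dddd")), 15)  # AllD
  expect_equal(encode_strategy(memory_strategy(strrep("c", 16))), 0)  # AllC m=2
})

test_that("strategy text format round-trips, including hex ids", {
  s <- make_named("capri")
  expect_identical(strategy_actions(parse_strategy(format_strategy(s))),
                   strategy_actions(s))
  expect_equal(encode_strategy(parse_strategy("m=1 cdcd")), 10)
  expect_equal(encode_strategy(parse_strategy("m=2 0x929a")), 37530)
  expect_error(parse_strategy("nonsense"), "cannot parse")
})

test_that("memory-one tuples map to action-pair conditioning via R,S,T,P", {
  tft <- make_named("TFT")
  expect_equal(unname(tft$tuple), c(1, 1, 0, 1, 0))
  expect_equal(tft$probs, memory_strategy("cdcd")$probs)
  wsls <- make_named("WSLS")
  expect_equal(unname(wsls$tuple), c(1, 1, 0, 0, 1))
  expect_equal(wsls$probs, memory_strategy("cddc")$probs)
  alld <- make_named("AllD")
  expect_equal(alld$probs, memory_strategy("dddd")$probs)
  allc <- make_named("AllC")
  expect_equal(allc$probs, rep(1, 4))
})

test_that("every named strategy instantiates and CAPRI matches its five rules", {
  for (nm in c("AllC", "AllD", "TFT", "GTFT", "TF2T", "WSLS", "generous-ZD",
               "extortionate-ZD", "Trigger", "CAPRI"))
    expect_s3_class(make_named(nm), "pd_strategy")
  expect_error(make_named("nope"), "unknown strategy")

  cap <- capri()
  acts <- 1 - cap$probs
  lab <- function(a, b) acts[st(a, b) + 1]
  # common prescriptions of all successful memory-three strategies
  expect_equal(lab("ccc", "ccc"), 0)  # c
  expect_equal(lab("ccc", "ddd"), 1)  # d
  expect_equal(lab("cdd", "ddd"), 1)  # d
  expect_equal(lab("ddd", "ddd"), 1)  # d
  # accept punishment
  for (s0 in list(c("ccd", "ccc"), c("cdc", "ccd"), c("dcc", "cdc"), c("ccc", "dcc")))
    expect_equal(lab(s0[1], s0[2]), 0)
  # punish once, then come back
  expect_equal(lab("ccc", "ccd"), 1)
  for (s0 in list(c("ccd", "cdc"), c("cdc", "dcc"), c("dcc", "ccc")))
    expect_equal(lab(s0[1], s0[2]), 0)
  # recover from mutual defection
  for (s0 in list(c("ddd", "ddc"), c("ddc", "dcc"), c("ddc", "ddd"),
                  c("dcc", "ddc"), c("ddc", "ddc"), c("dcc", "dcc")))
    expect_equal(lab(s0[1], s0[2]), 0)
  # otherwise defect: the table holds exactly 14 cooperative entries
  expect_equal(sum(acts == 0), 14)
})

test_that("TF2T defects exactly after two consecutive co-player defections", {
  tf2t <- make_named("TF2T")
  acts <- 1 - tf2t$probs
  idx <- 0:15
  expect_equal(acts, as.numeric(idx %% 4 == 3))
})

test_that("ZD constructors respect Table-style probability bounds", {
  gz <- zd_strategy(0.1, 0.5, "generous")
  expect_true(all(gz$tuple >= 0 & gz$tuple <= 1))
  expect_equal(unname(gz$tuple[1]), 1)  # generous ZD cooperates first
  ez <- zd_strategy(0.1, 0.5, "extortionate")
  expect_equal(unname(ez$tuple[c(1, 5)]), c(0, 0))  # p0 = pP = 0 exactly
  expect_error(zd_strategy(5, 0.5, "generous"), "leave")
  expect_error(zd_strategy(-1, 0.5, "generous"), "positive")
})

test_that("embedding preserves play against any co-player", {
  set.seed(3)
  s1 <- rand_strategy(1)
  s3 <- embed_strategy(s1, 3)
  pairs <- sample(c("cc", "cd", "dc", "dd"), 30, replace = TRUE)
  expect_identical(strategy_outputs(s1, pairs), strategy_outputs(s3, pairs))
})
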