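test_that("constant strategies minimize to a single state", {
  expect_length(to_automaton(memory_strategy(strrep("c", 64), m = 3))$output, 1)
  expect_length(to_automaton(memory_strategy("dddd", m = 1))$output, 1)
})

test_that("TFT minimizes to the two-state copy machine", {
  a <- to_automaton(make_named("TFT"))
  expect_length(a$output, 2)
  cstate <- which(a$output == "c")
  dstate <- which(a$output == "d")
  # next action copies the co-player's last move regardless of own move
  expect_equal(unname(a$transition[cstate, c("cc", "dc")]), rep(cstate, 2))
  expect_equal(unname(a$transition[cstate, c("cd", "dd")]), rep(dstate, 2))
})

test_that("minimization is idempotent and preserves play", {
  set.seed(7)
  for (i in 1:10) {
    s <- rand_strategy(2)
    raw <- to_automaton(s, minimize = FALSE)
    mini <- minimize_automaton(raw)
    mini2 <- minimize_automaton(mini)
    expect_equal(length(mini2$output), length(mini$output))
    pairs <- sample(c("cc", "cd", "dc", "dd"), 200, replace = TRUE)
    expect_identical(strategy_outputs(s, pairs), strategy_outputs(mini, pairs))
    expect_identical(strategy_outputs(mini, pairs), strategy_outputs(mini2, pairs))
  }
})

test_that("CAPRI's automaton can defect for ever against a cooperator", {
  a <- to_automaton(capri())
  # a defecting state with a self-loop on the realized pair (d, c)
  selfloop <- any(a$output == "d" & a$transition[, "dc"] == seq_along(a$output))
  expect_true(selfloop)
})

test_that("grim trigger automaton is irreversible", {
  g <- grim_trigger()
  expect_identical(strategy_outputs(g, c("cc", "cc", "cd", "cc", "cc")),
                   c("c", "c", "c", "d", "d", "d"))
})
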