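test_that("payoff matrix validates the social-dilemma conditions", {
  expect_s3_class(payoff_matrix(), "payoff_matrix")
  don <- donation_payoffs(3)
  expect_equal(with(don, c(R, T, S, P)), c(2, 3, -1, 0))
  expect_error(payoff_matrix(R = 1, T = 4, S = 0, P = 2))   # R < P
  expect_error(donation_payoffs(0.5), "exceed")
  # snowdrift ordering T > R > S > P is accepted
  expect_s3_class(payoff_matrix(R = 3, T = 4, S = 1, P = 0), "payoff_matrix")
})

test_that("chain rows are stochastic and full noise gives uniform branches", {
  ch <- build_chain(capri(), capri(), e = 1e-3)
  expect_equal(nrow(ch$matrix), 64)
  expect_equal(rowSums(ch$matrix), rep(1, 64), tolerance = 1e-12)
  ch2 <- build_chain(make_named("TFT"), make_named("WSLS"), e = 0.4999999)
  expect_true(all(abs(ch2$matrix[ch2$matrix > 0] - 0.25) < 1e-5))
})

test_that("constant play recovers the elementary payoffs", {
  ch <- build_chain(make_named("AllD"), make_named("AllC"), e = 1e-6)
  sp <- stationary_payoffs(ch)
  expect_equal(sp$pi_A, 4, tolerance = 1e-4)  # T
  expect_equal(sp$pi_B, 0, tolerance = 1e-4)  # S
})

test_that("noisy TFT self-play averages all four payoffs; WSLS self-play earns R", {
  ch <- build_chain(make_named("TFT"), make_named("TFT"), e = 1e-6)
  sp <- stationary_payoffs(ch)
  expect_equal(sp$pi_A, (3 + 4 + 0 + 1) / 4, tolerance = 1e-3)
  la <- zero_error_limit(make_named("WSLS"), make_named("WSLS"))
  lp <- limit_payoffs(la)
  expect_equal(lp$pi_A[lp$in_support], 3)  # R
})

test_that("role swap exchanges the two payoffs exactly; self-play is symmetric", {
  set.seed(11)
  for (i in 1:5) {
    a <- probabilistic_memory_strategy(runif(16), 2)
    b <- probabilistic_memory_strategy(runif(4), 1)
    s1 <- stationary_payoffs(build_chain(a, b, e = 0.01))
    s2 <- stationary_payoffs(build_chain(b, a, e = 0.01))
    expect_equal(s1$pi_A, s2$pi_B, tolerance = 1e-12)
    expect_equal(s1$pi_B, s2$pi_A, tolerance = 1e-12)
    ss <- stationary_payoffs(build_chain(a, a, e = 0.01))
    expect_equal(ss$pi_A, ss$pi_B, tolerance = 1e-12)
  }
})

test_that("stationary solve matches an independent power-iteration oracle", {
  set.seed(13)
  for (i in 1:20) {
    a <- probabilistic_memory_strategy(runif(4^sample(1:2, 1)))
    b <- probabilistic_memory_strategy(runif(4^sample(1:2, 1)))
    ch <- build_chain(a, b, e = 0.02)
    sp <- stationary_payoffs(ch)
    expect_equal(sp$stationary, power_stationary(ch$matrix), tolerance = 1e-10)
  }
})

test_that("all computed payoff pairs stay inside the feasible diamond", {
  set.seed(17)
  pm <- payoff_matrix()
  for (i in 1:20) {
    a <- probabilistic_memory_strategy(runif(16), 2)
    b <- probabilistic_memory_strategy(runif(16), 2)
    sp <- stationary_payoffs(build_chain(a, b, e = 0.05, payoffs = pm))
    expect_true(in_payoff_diamond(sp$pi_A, sp$pi_B, pm))
  }
})

test_that("deterministic pairs at e = 0 are routed to the limit analysis", {
  ch <- build_chain(make_named("TFT"), make_named("TFT"), e = 0)
  expect_error(stationary_payoffs(ch), "zero_error_limit")
})

test_that("zero-error limit: absorbing cooperation, grim collapse to defection", {
  la <- zero_error_limit(memory_strategy("cccc"), memory_strategy("cccc"))
  expect_length(la$cycles, 1)
  expect_equal(la$cycles[[1]], 0L)
  expect_equal(la$support, 1L)

  lg <- zero_error_limit(grim_trigger(), grim_trigger())
  lp <- limit_payoffs(lg)
  # the only supported class is mutual defection (payoff P); reaching it
  # costs one flip, leaving it is impossible
  expect_equal(lp$pi_A[lp$in_support], 1)
  expect_true(is.infinite(lg$W[which(!lp$in_support)]))

  lc <- zero_error_limit(capri(), capri())
  expect_length(lc$support, 1)
  expect_equal(lc$cycles[[lc$support]], 0L)  # (ccc,ccc) alone
})

test_that("limit support agrees with small-e stationary mass, increasingly so", {
  set.seed(19)
  ids <- sample(0:65535, 60)
  for (id in ids) {
    s <- decode_strategy(id, 2)
    la <- zero_error_limit(s, s)
    sup_states <- unlist(la$cycles[la$support]) + 1
    masses <- vapply(c(1e-4, 1e-5, 1e-6), function(e) {
      ch <- build_chain(s, s, e = e)
      ch$deterministic <- FALSE
      sum(stationary_payoffs(ch)$stationary[sup_states])
    }, numeric(1))
    expect_gt(masses[3], 0.99)
    expect_true(all(diff(masses) > -1e-6))  # mass grows as e shrinks
  }
})

test_that("minimum arborescence matches brute-force enumeration on small graphs", {
  set.seed(23)
  for (rep in 1:40) {
    K <- sample(2:5, 1)
    cost <- matrix(sample(c(1:6, Inf), K * K, replace = TRUE), K, K)
    diag(cost) <- Inf
    for (root in 1:K) {
      got <- friendlyrival:::cpp_min_arborescence(cost, root - 1L)
      expect_equal(got, brute_arborescence(cost, root))
    }
  }
})

test_that("payoff clouds are reproducible and AllC is exploited on average", {
  c1 <- sample_payoff_cloud(capri(), n = 30, seed = 99)
  c2 <- sample_payoff_cloud(capri(), n = 30, seed = 99)
  expect_identical(c1, c2)
  ca <- sample_payoff_cloud(make_named("AllC"), n = 200, seed = 1)
  expect_gte(mean(ca$pi_B), mean(ca$pi_A))
  c0 <- sample_payoff_cloud(capri(), n = 0, seed = 1)
  expect_equal(nrow(c0), 0)
})
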