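test_that("imitation probability is the symmetric Fermi rule", {
  expect_equal(imitation_probability(5, 1, 0), 0.5)
  expect_equal(imitation_probability(2, 2, 3), 0.5)
  set.seed(43)
  sx <- rnorm(20); sy <- rnorm(20); sg <- runif(20, 0, 5)
  expect_equal(imitation_probability(sx, sy, sg) +
                 imitation_probability(sy, sx, sg), rep(1, 20))
  # monotone decreasing in s_x - s_y
  expect_true(all(diff(imitation_probability(seq(0, 2, 0.1), 1, 2)) < 0))
})

test_that("neutral mutants fix with probability exactly 1/N", {
  for (N in c(2, 10, 50, 100))
    for (sg in c(0, 0.1, 2))
      expect_equal(fixation_from_payoffs(1.3, 1.3, 1.3, 1.3, N, sg), 1 / N)
})

test_that("log-space fixation equals the direct product form", {
  direct <- function(sxx, sxy, syx, syy, N, sigma) {
    tot <- 0
    for (i in 0:(N - 1)) {
      pr <- 1
      for (j in seq_len(i))
        pr <- pr * exp(sigma * ((N - j - 1) * syy + j * syx -
                                  (N - j) * sxy - (j - 1) * sxx))
      tot <- tot + pr
    }
    1 / tot
  }
  set.seed(47)
  for (k in 1:100) {
    p <- runif(4, -1, 4)
    N <- sample(2:40, 1)
    sg <- runif(1, 0, 1)
    expect_equal(fixation_from_payoffs(p[1], p[2], p[3], p[4], N, sg),
                 direct(p[1], p[2], p[3], p[4], N, sg), tolerance = 1e-10)
  }
  # N = 2 closed form: 1 / (1 + exp(sigma (s_yx - s_xy)))
  expect_equal(fixation_from_payoffs(1, 2, 3, 4, 2, 0.7),
               1 / (1 + exp(0.7 * (3 - 2))))
  # extreme selection does not overflow
  expect_true(is.finite(fixation_from_payoffs(0, 0, 10, -10, 100, 50)))
})

test_that("reactive strategies split into partners, rivals and others at b = 3", {
  don <- donation_payoffs(3)
  expect_equal(reactive_pd_star(don), 2 / 3)
  expect_equal(classify_reactive(reactive_strategy(1, 0), don), "rival")
  expect_equal(classify_reactive(reactive_strategy(0.4, 0), don), "rival")
  expect_equal(classify_reactive(reactive_strategy(1, 0.5), don), "partner")
  expect_equal(classify_reactive(reactive_strategy(1, 0.7), don), "other")
  expect_equal(classify_reactive(reactive_strategy(0.5, 0.5), don), "other")
  grid <- reactive_grid()
  expect_length(grid, 121)
})

test_that("payoff tables are consistent with direct chain solves", {
  don <- donation_payoffs(3)
  strategies <- list(AllD = make_named("AllD"), TFT = make_named("TFT"),
                     CAPRI = capri())
  S <- payoff_table(strategies, don, e = 1e-3)
  sp <- stationary_payoffs(build_chain(strategies$TFT, strategies$CAPRI,
                                       e = 1e-3, payoffs = don))
  expect_equal(S["TFT", "CAPRI"], sp$pi_A, tolerance = 1e-12)
  expect_equal(S["CAPRI", "TFT"], sp$pi_B, tolerance = 1e-12)
})

test_that("two neutral strategies split residency evenly", {
  s <- reactive_strategy(0.5, 0.5)
  cfg <- evolution_config(grid = list(A = s, B = s), steps = 2e4, runs = 2,
                          seed = 7)
  rep <- run_moran(cfg)
  expect_equal(sum(rep$per_strategy), 1, tolerance = 1e-9)
  expect_equal(unname(rep$per_strategy["A"]), 0.5, tolerance = 0.05)
})

test_that("moran runs are reproducible under the seed", {
  cfg <- evolution_config(grid = reactive_grid(c(0, 0.5, 1)), steps = 2000,
                          runs = 2, seed = 5)
  r1 <- run_moran(cfg)
  r2 <- run_moran(cfg, payoff_cache = r1$payoff_cache)
  expect_identical(r1$per_strategy, r2$per_strategy)
})

test_that("WSLS fails the robustness certificate against AllD", {
  expect_warning(
    cert <- robustness_certificate(make_named("WSLS"),
                                   mutants = list(make_named("AllD")),
                                   N_grid = 50),
    "not a friendly rival")
  expect_false(cert$ok)
  expect_true(any(cert$violations$s_yx < cert$violations$s_xy))
})

test_that("a resident facing itself sits exactly on the neutral boundary", {
  cert <- robustness_certificate(capri(), mutants = list(capri()),
                                 N_grid = c(2, 10))
  expect_true(cert$ok)
  expect_equal(cert$table$rho, 1 / cert$table$N)
})

test_that("CAPRI abundance does not fall as selection strengthens", {
  # small-grid surrogate of the full sweep, three sigma values
  grid <- reactive_grid(c(0, 0.5, 1))
  ab <- vapply(c(0.1, 0.2, 0.4), function(sg) {
    cfg <- evolution_config(sigma = sg, mu = 0.01,
                            special = list(CAPRI = capri()), grid = grid,
                            steps = 2e4, runs = 2, seed = 31)
    run_moran(cfg)$per_strategy[["CAPRI"]]
  }, numeric(1))
  expect_true(all(diff(ab) > -0.05))  # monotone trend up to noise
})
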