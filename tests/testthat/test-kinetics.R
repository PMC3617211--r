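nf_rates <- rate_set(1, 0.1, 1, 0.1, 0.1)
nr_rates <- rate_set(1, 0.1, 1, 0.001, 0.1)

test_that("rate sets validate their invariants", {
  expect_s3_class(nf_rates, "rate_set")
  expect_error(rate_set(0, 0, 0, 0, 0), "at least one rate")
  expect_error(rate_set(-1, 0.1, 1, 0.1, 0.1), "non-negative")
  expect_error(rate_set(Inf, 0.1, 1, 0.1, 0.1), "finite")
  expect_equal(as_rate_set(c(k1 = 1, k_m1 = 0.1, k2 = 1, k_m2 = 0.1, k3 = 0.1)),
    nf_rates)
})

test_that("the generator places each rate on its edge and conserves mass", {
  q <- pathway_generator(rate_set(0, 0, 0, 0, 1))
  off <- q
  diag(off) <- 0
  expect_equal(off["P", "S"], 1)
  expect_equal(sum(off != 0), 1)

  q <- pathway_generator(nf_rates)
  expect_equal(unname(q["I", "S"]), 1) # k1
  expect_equal(unname(q["S", "I"]), 0.1) # k_m1
  expect_equal(unname(q["P", "I"]), 1) # k2
  expect_equal(unname(q["I", "P"]), 0.1) # k_m2
  expect_equal(unname(q["P", "S"]), 0.1) # k3
  expect_equal(unname(q["S", "P"]), 0) # no P -> S edge
  expect_equal(unname(colSums(q)), c(0, 0, 0))
})

test_that("time courses are exact and conserve probability", {
  # t = 0 returns the initial state unchanged
  tc0 <- simulate_pathway(nf_rates, times = 0)
  expect_equal(unlist(tc0[1, c("S", "I", "P")]), c(S = 1, I = 0, P = 0))

  # single-exponential closed form: only k3 active, p(t) = 1 - exp(-k3 t)
  t_half <- log(2) / 0.1
  tc <- simulate_pathway(rate_set(0, 0, 0, 0, 0.1), times = c(1, t_half, 50))
  expect_equal(tc$P, 1 - exp(-0.1 * tc$time), tolerance = 1e-10)
  expect_equal(tc$P[2], 0.5, tolerance = 1e-9)

  # conservation along a generic trajectory
  tc <- simulate_pathway(nr_rates, times = c(0.1, 1, 10, 100))
  expect_true(all(abs(tc$S + tc$I + tc$P - 1) < 1e-9))
  expect_true(all(tc$S >= 0 & tc$I >= 0 & tc$P >= 0))

  expect_error(simulate_pathway(nf_rates, times = c(2, 1)), "increasing")
  expect_error(simulate_pathway(nf_rates, times = numeric(0)), "times")
  expect_error(
    simulate_pathway(nf_rates, times = 1, initial = c(S = 0.7, I = 0.7, P = -0.4)),
    "probabilities"
  )
})

test_that("limiting distributions match the tree-theorem values", {
  # NF reference: tree weights (0.01, 0.11, 1.11)
  expect_equal(limiting_state(nf_rates),
    c(S = 0.01, I = 0.11, P = 1.11) / 1.23,
    tolerance = 1e-10
  )
  # NR reference: tree weights (0.0001, 0.0011, 1.11)
  expect_equal(limiting_state(nr_rates),
    c(S = 1e-4, I = 1.1e-3, P = 1.11) / 1.1112,
    tolerance = 1e-10
  )
})

test_that("reducible chains settle into the closed classes reachable from S", {
  # S absorbing (k1 = k3 = 0): nothing leaves the start state
  expect_equal(limiting_state(rate_set(0, 0.1, 1, 0.1, 0)),
    c(S = 1, I = 0, P = 0))
  # I is the unique absorbing state (k_m1 = k2 = 0)
  expect_equal(limiting_state(rate_set(1, 0, 0, 0.1, 0.1)),
    c(S = 0, I = 1, P = 0))
  # closed class {I, P} with S transient (k_m1 = 0)
  lim <- limiting_state(rate_set(1, 0, 1, 0.001, 0.1))
  expect_equal(lim, c(S = 0, I = 0.001 / 1.001, P = 1 / 1.001),
    tolerance = 1e-10)
  # with the bpSL genotype even mass starting in P drains through the
  # reversible steps into the absorbing damage state
  lim_p <- limiting_state(rate_set(0, 0.1, 1, 0.1, 0),
    initial = c(S = 0, I = 0, P = 1))
  expect_equal(lim_p, c(S = 1, I = 0, P = 0))
})

test_that("long-time integration agrees with the analytic limit", {
  r <- rate_set(1, 0.1, 1, 0.001, 0.1)
  tc <- simulate_pathway(r, times = 1e4)
  expect_equal(unlist(tc[1, c("S", "I", "P")]), limiting_state(r),
    tolerance = 1e-6
  )
})

test_that("time to repair matches the closed form and detects dead ends", {
  expect_equal(time_to_repair(rate_set(0, 0, 0, 0, 0.1), threshold = 0.5),
    log(2) / 0.1,
    tolerance = 1e-5
  )
  # bpSL: P is never populated
  expect_identical(time_to_repair(rate_set(0, 0.1, 1, 0.1, 0)), Inf)
  # repair through the compensatory route is slower than the main route
  f1_ko <- apply_perturbations(nr_rates, perturbation("F1", "KNOCKOUT"))
  expect_gt(time_to_repair(f1_ko), time_to_repair(nr_rates))
  expect_error(time_to_repair(nr_rates, threshold = 0), "threshold")
  expect_error(time_to_repair(nr_rates, threshold = 1), "threshold")
})

test_that("compensatory route probability follows first-step analysis", {
  # only route is direct
  expect_equal(compensatory_route_prob(rate_set(0, 0.1, 1, 0.1, 0.1)), 1)
  # only route is the main path
  expect_equal(compensatory_route_prob(rate_set(1, 0.1, 1, 0.1, 0)), 0)
  # generic case: q = a / (1 - b c)
  a <- 0.1 / 1.1
  b <- 1 / 1.1
  cc <- 0.1 / 1.1
  expect_equal(compensatory_route_prob(nf_rates), a / (1 - b * cc),
    tolerance = 1e-12
  )
  expect_equal(round(compensatory_route_prob(nf_rates), 4), 0.0991)
  # P unreachable
  expect_error(compensatory_route_prob(rate_set(0, 0.1, 1, 0.1, 0)), "unreachable")
  expect_error(compensatory_route_prob(rate_set(1, 0.1, 0, 0.1, 0)), "unreachable")
})

test_that("rate configs round-trip through the flat key:value format", {
  path <- withr::local_tempfile(fileext = ".cfg")
  write_rate_config(nr_rates, path)
  expect_equal(read_rate_config(path), nr_rates)
  writeLines(c("k1: 1", "k_m1: 0.1", "k2: 1", "k_m2: 0.1", "k3: 0.1", "bogus: 2"),
    path)
  expect_error(read_rate_config(path), "unknown")
  writeLines(c("k1: 1"), path)
  expect_error(read_rate_config(path), "missing")
})
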