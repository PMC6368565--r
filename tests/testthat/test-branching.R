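test_that("birth-death transition law matches closed-form moments", {
  b <- 0.15; d <- 0.13; t <- 40; n0 <- 500
  set.seed(201)
  x <- bd_transition(rep(n0, 4000), b, d, t)
  # mean n0 * e^{rt}
  expect_equal(mean(x), n0 * exp((b - d) * t), tolerance = 0.02)
  # single-lineage extinction probability
  set.seed(202)
  y <- bd_transition(rep(1, 4000), b, d, t)
  e <- exp((b - d) * t)
  alpha <- d * (e - 1) / (b * e - d)
  expect_equal(mean(y == 0), alpha, tolerance = 0.05)
})

test_that("mu = 0 runs match the deterministic closed forms", {
  set.seed(203)
  # d' = 0.25: remnant 1e10 * e^{-15} ~ 3 cells -> pCR
  runs <- replicate(40, simulate_run(branching_params(mu = 0,
                                                      d_prime = 0.25)),
                    simplify = FALSE)
  res <- vapply(runs, `[[`, numeric(1), "residual")
  expect_equal(mean(res), 1e10 * exp(-15), tolerance = 0.5)
  expect_true(all(vapply(runs, classify_outcome, character(1)) == "pCR"))
  # d' = 0.16: remnant ~2.2e9 -> sensitive residual
  set.seed(204)
  run <- simulate_run(branching_params(mu = 0, d_prime = 0.16))
  expect_equal(run$residual, 1e10 * exp(-1.5), tolerance = 1e-3)
  expect_equal(classify_outcome(run), "sensitive_residual")
  expect_equal(run$n_clones_detect, 0)
})

test_that("outcome classification applies thresholds in order", {
  run <- structure(list(residual = 9000, sensitive = 9000, clones = numeric(0),
                        aggregate = 0), class = "branching_run")
  expect_equal(classify_outcome(run), "pCR")
  run2 <- structure(list(residual = 1e9, sensitive = 1e8,
                         clones = c(8.5e8, 0.5e8), aggregate = 0),
                    class = "branching_run")
  expect_equal(classify_outcome(run2), "clonal_replacement")
  run3 <- structure(list(residual = 1e9, sensitive = 5e8,
                         clones = c(3e8, 2e8), aggregate = 0),
                    class = "branching_run")
  expect_equal(classify_outcome(run3), "polyclonal_resistance")
  run4 <- structure(list(residual = 1e9, sensitive = 8.5e8,
                         clones = c(1.5e8), aggregate = 0),
                    class = "branching_run")
  expect_equal(classify_outcome(run4), "sensitive_residual")
})

test_that("clone counts at detection scale linearly in mu", {
  set.seed(205)
  k7 <- mean(replicate(300,
    simulate_run(branching_params(mu = 1e-7))$n_clones_detect))
  k8 <- mean(replicate(300,
    simulate_run(branching_params(mu = 1e-8))$n_clones_detect))
  expect_equal(k7 / k8, 10, tolerance = 0.2)
})

test_that("clone sizes decrease with later birth in expectation", {
  set.seed(206)
  firsts <- seconds <- c()
  for (i in 1:300) {
    r <- simulate_run(branching_params(mu = 1e-8, d_prime = 0.2))
    if (length(r$clone_sizes_detect) >= 2) {
      firsts <- c(firsts, r$clone_sizes_detect[1])
      seconds <- c(seconds, r$clone_sizes_detect[2])
    }
  }
  expect_gt(length(firsts), 30)
  expect_gt(mean(firsts), mean(seconds))
})

test_that("outcome frequencies are monotone in mu", {
  set.seed(207)
  of <- outcome_frequencies(d_prime_grid = 0.25,
                            mu_grid = c(1e-10, 1e-7, 1e-5), n_sims = 150)
  expect_true(all(diff(of$p_pcr) <= 2 * of$se[1] + 1e-12))
  resist <- of$p_clonal + of$p_polyclonal
  expect_true(all(diff(resist) >= -2 * of$se[1]))
  # mu = 1e-10 at d' = 0.25: closed-form remnant ~3 cells, pCR dominates
  expect_gt(of$p_pcr[1], 0.95)
})

test_that("hybrid engine agrees with Gillespie on small instances", {
  # small detection size so the exact per-event simulation is feasible
  set.seed(208)
  n <- 600
  p <- branching_params(mu = 2e-3, d_prime = 0.2, detect_size = 1e3,
                        treat_days = 30, stoch_threshold = 200)
  eng <- vapply(seq_len(n), function(i) {
    r <- simulate_run(p)
    c(r$residual, r$sensitive,
      if (length(r$clones)) max(r$clones) else 0)
  }, numeric(3))
  gil <- vapply(seq_len(n), function(i) {
    g <- clonalshift:::cpp_gillespie_run(0.15, 0.13, 0.2, 2e-3, 1e3, 30)
    c(g$residual, g$sensitive, g$max_clone)
  }, numeric(3))
  cls <- function(m) {
    resid <- m[1, ]; sens <- m[2, ]; mx <- m[3, ]
    ifelse(resid < 30, "pCR",
           ifelse(sens / resid >= 0.8, "sensitive_residual",
                  ifelse(mx / resid >= 0.8, "clonal_replacement",
                         "polyclonal_resistance")))
  }
  fe <- table(factor(cls(eng), levels = c("pCR", "sensitive_residual",
                                          "clonal_replacement",
                                          "polyclonal_resistance"))) / n
  fg <- table(factor(cls(gil), levels = names(fe))) / n
  se <- sqrt(pmax(fg * (1 - fg), 0.25 / n) / n)
  expect_true(all(abs(fe - fg) <= 3 * se + 1e-9))
})

test_that("mu inference identities hold", {
  set.seed(209)
  # no filter, no shrink restriction: interval equals the prior 5-95%
  res <- infer_mu_interval(d_prime_grid = 0.2, shrink_range = c(0, Inf),
                           outcome_filter = "none", n_grid = 20,
                           n_per_point = 2)
  grid <- 10^seq(-10, -2, length.out = 20)
  expect_equal(unname(res$pooled),
               unname(quantile(rep(grid, each = 2), c(0.05, 0.95))))
  expect_equal(res$n_qualifying, 40)
})
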