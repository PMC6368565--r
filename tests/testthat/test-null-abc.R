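# Minimal synthetic "panel" tables with a planted octant layout, cheap
# stand-ins for full virtual-tumor cohorts in the null-distribution tests.
fake_panel <- function(thfr_target, n_regions = 8, n_mut = 40) {
  n_rep <- round(thfr_target * 20)
  ccf <- rbind(
    matrix(0.9, 20 - n_rep, n_regions),            # clonal everywhere
    matrix(c(rep(0.02, n_rep), rep(0.9, n_rep * (n_regions - 1))),
           n_rep, n_regions),                      # rare in region 1 only
    matrix(0.2, n_mut - 20, n_regions))            # subclonal noise
  colnames(ccf) <- paste0("S", seq_len(n_regions))
  tab <- ccf_table(ccf)
  attr(tab, "octant") <- rep(1:8, length.out = n_regions)
  tab
}

test_that("tHFR null collects per-tumor values under a scheme", {
  set.seed(301)
  tabs <- c(lapply(rep(0, 6), fake_panel), lapply(rep(0.3, 4), fake_panel))
  null <- build_thfr_null(tabs, scheme = "random", n_post = 2)
  expect_equal(null$n_tumors, 10)
  expect_true(all(null$values >= 0 & null$values <= 1))
  expect_equal(null$values, sort(null$values))
  # zero-heterogeneity tumors contribute 0
  null0 <- build_thfr_null(lapply(1:5, function(i)
                             fake_panel(0, n_regions = 16)),
                           scheme = "opposite_octant_pre_post", n_post = 2)
  expect_equal(null0$values, rep(0, 5))
})

test_that("the quadrant-aware scheme splits post samples across quadrants", {
  set.seed(302)
  tabs <- lapply(1:6, function(i) fake_panel(0.2, n_regions = 16))
  null <- build_thfr_null(tabs, scheme = "opposite_quadrants_post",
                          n_post = 2, n_post_pool = 4)
  expect_equal(null$n_tumors, 6)
})

test_that("percentile convention: strictly-less-than, ties below", {
  null <- structure(list(values = c(0, 0, 0.1, 0.2, 0.5), scheme = "random",
                         n_post = 2, n_tumors = 5), class = "thfr_null")
  expect_equal(test_clonal_replacement(0, null)$percentile, 0)
  expect_equal(test_clonal_replacement(0.1, null)$percentile, 0.4)
  expect_equal(test_clonal_replacement(0.6, null)$percentile, 1)
  expect_true(test_clonal_replacement(0.6, null)$verdict)
  expect_false(test_clonal_replacement(0.1, null)$verdict)
  # monotone in the observed value
  obs <- seq(0, 1, by = 0.1)
  pcts <- vapply(obs, function(o)
    test_clonal_replacement(o, null)$percentile, numeric(1))
  expect_true(all(diff(pcts) >= 0))
})

test_that("rejection ABC reduces to the prior at acceptance 1", {
  set.seed(303)
  sim <- data.frame(s = rep(c(0, 0.1, 0.4), each = 20),
                    deme_size = rep(c(1000, 5000), 30),
                    fst = rnorm(60, 0.1, 0.02),
                    mean_hfr_panel = runif(60, 0, 0.3),
                    f_subclonal = runif(60),
                    ksd = runif(60, 0, 0.5))
  obs <- c(fst = 0.1, mean_hfr_panel = 0.1, f_subclonal = 0.5, ksd = 0.2)
  res <- abc_infer(obs, sim, acceptance_fraction = 1)
  expect_equal(unname(res$posterior_s), rep(1 / 3, 3))
  expect_equal(sum(res$posterior_s), 1)
  expect_equal(sum(res$posterior_deme), 1)
})

test_that("ABC recovers parameters when statistics separate them", {
  set.seed(304)
  # statistics increase with s: distance-based acceptance must find the mode
  mk <- function(s, n) data.frame(
    s = s, deme_size = 1000,
    fst = rnorm(n, 0.05 + s, 0.03),
    mean_hfr_panel = rnorm(n, s / 2, 0.03),
    f_subclonal = runif(n), ksd = rnorm(n, s, 0.05))
  sim <- rbind(mk(0, 50), mk(0.2, 50), mk(0.5, 50))
  obs_from <- mk(0.2, 1)
  res <- abc_infer(unlist(obs_from[c("fst", "mean_hfr_panel",
                                     "f_subclonal", "ksd")]),
                   sim, acceptance_fraction = 0.05)
  expect_equal(posterior_mode(res$posterior_s), 0.2)
  # missing observed statistic dropped with warning
  obs2 <- c(fst = 0.25, mean_hfr_panel = NA, f_subclonal = 0.5, ksd = 0.2)
  expect_warning(res2 <- abc_infer(obs2, sim), "missing")
  expect_false("mean_hfr_panel" %in% res2$stats_used)
})

test_that("ABC posterior concentrates as the tolerance tightens", {
  set.seed(305)
  mk <- function(s, n) data.frame(
    s = s, deme_size = 1000,
    fst = rnorm(n, 0.05 + s, 0.05),
    mean_hfr_panel = rnorm(n, s / 2, 0.05),
    f_subclonal = runif(n), ksd = rnorm(n, s, 0.08))
  sim <- rbind(mk(0, 80), mk(0.2, 80), mk(0.5, 80))
  obs <- c(fst = 0.55, mean_hfr_panel = 0.25, f_subclonal = 0.5, ksd = 0.5)
  ent <- function(p) -sum(p * log(p + 1e-12))
  e_wide <- ent(abc_infer(obs, sim, 1)$posterior_s)
  e_tight <- ent(abc_infer(obs, sim, 0.05)$posterior_s)
  expect_lt(e_tight, e_wide)
})
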