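# Small-scale tumors keep these tests fast; growth dynamics are identical
# at larger target sizes.
small_params <- function(...) spatial_params(target_cells = 2e5,
                                             deme_size = 1000, ...)

test_that("cell counts are conserved across demes", {
  set.seed(101)
  tum <- grow_tumor(small_params())
  expect_gte(tum$summary$n_cells, 2e5)
  expect_equal(sum(tum$demes$n_cells), tum$summary$n_cells)
  # deme occupancy bounded by 2 x deme size (transient fission overshoot)
  expect_lte(max(tum$demes$n_cells), 2.5 * 1000)
})

test_that("truncal mutations are clonal in every sample", {
  set.seed(102)
  tum <- grow_tumor(small_params())
  smp <- take_samples(tum, "all_octants", 6)
  for (s in smp$samples) {
    truncal <- s$fraction[s$mut_id < 50]
    expect_equal(length(truncal), 50)
    expect_true(all(truncal == 1))
  }
  # and clonal after sequencing emulation at full depth
  tab <- emulate_sequencing(smp, mean_depth = 1000)
  truncal_rows <- paste0("m", 0:49)
  expect_true(all(tab$ccf[truncal_rows, ] > 0.5))
})

test_that("sampling schemes honor octant constraints", {
  set.seed(103)
  tum <- grow_tumor(small_params())
  loc <- take_samples(tum, "local", 3)
  expect_equal(length(unique(vapply(loc$samples, `[[`, numeric(1),
                                    "octant"))), 1L)
  dis <- take_samples(tum, "distant", 4)
  expect_equal(length(unique(vapply(dis$samples, `[[`, numeric(1),
                                    "octant"))), 4L)
  alln <- take_samples(tum, "all_octants", 20)
  occupied <- sort(unique(tum$demes$octant))
  expect_true(all(occupied %in%
                    vapply(alln$samples, `[[`, numeric(1), "octant")))
  opp <- take_samples(tum, "opposite_octant_pre_post", 3)
  octs <- vapply(opp$samples, `[[`, numeric(1), "octant")
  expect_equal(octs[2], octs[3])
  expect_equal(octs[1], 9 - octs[2])
  # focal demes are sampled without replacement
  expect_equal(anyDuplicated(vapply(alln$samples, `[[`, numeric(1),
                                    "focal")), 0L)
})

test_that("sequencing emulation applies the calling filters", {
  frac <- cbind(c(1, 0.5, 0.4, 0.02, 0), c(1, 0.5, 0.4, 0.02, 0))
  fake <- list(samples = list(
    list(mut_id = 0:4, fraction = frac[, 1], n_cells = 1000),
    list(mut_id = 0:4, fraction = frac[, 2], n_cells = 1000)),
    scheme = "all_octants")
  set.seed(104)
  tab <- emulate_sequencing(fake, mean_depth = 100, min_fraction = 0)
  # true fraction 0 gives no alt reads anywhere -> filtered out
  expect_false("m4" %in% rownames(tab$ccf))
  # high-fraction mutations survive the filter and CCF tracks 2 x VAF
  expect_true(all(c("m0", "m1") %in% rownames(tab$ccf)))
  expect_true(all(abs(tab$ccf["m0", ] - 1) < 0.35))
  # depth below 20 in any sample removes the mutation
  set.seed(105)
  tab2 <- emulate_sequencing(fake, mean_depth = 100, min_fraction = 0,
                             thresholds = thresholds(min_depth = 120))
  expect_lt(nrow(tab2$ccf), nrow(tab$ccf))
})

test_that("infinite-depth limit recovers true fractions", {
  frac <- c(1, 0.6, 0.2)
  fake <- list(samples = list(list(mut_id = 0:2, fraction = frac,
                                   n_cells = 1000)))
  set.seed(106)
  tab <- emulate_sequencing(fake, mean_depth = 20000, min_fraction = 0)
  expect_equal(as.vector(tab$ccf[, 1]), frac, tolerance = 0.02)
})

test_that("neutral small tumors show near-zero distant HFR", {
  set.seed(107)
  hfr <- replicate(8, {
    tum <- grow_tumor(small_params())
    dis <- emulate_sequencing(take_samples(tum, "distant", 2))
    suppressWarnings(pairwise_hfr(dis, "S1", "S2")$hfr)
  })
  expect_lt(mean(hfr), 0.05)
})

test_that("driver bookkeeping does not perturb neutral dynamics", {
  # s = 0 with drivers vs driver_prob = 0: HFR distributions indistinguishable
  set.seed(108)
  h1 <- replicate(12, {
    tum <- grow_tumor(small_params(s = 0))
    dis <- emulate_sequencing(take_samples(tum, "distant", 2))
    suppressWarnings(pairwise_hfr(dis, "S1", "S2")$hfr)
  })
  h2 <- replicate(12, {
    tum <- grow_tumor(small_params(s = 0, driver_prob = 0))
    dis <- emulate_sequencing(take_samples(tum, "distant", 2))
    suppressWarnings(pairwise_hfr(dis, "S1", "S2")$hfr)
  })
  expect_gt(suppressWarnings(ks.test(h1, h2)$p.value), 0.01)
})

test_that("tighter spatial constraint (smaller demes) does not lower HFR", {
  set.seed(115)
  mean_hfr <- function(deme) mean(replicate(10, {
    tum <- grow_tumor(spatial_params(s = 0.5, deme_size = deme,
                                     target_cells = 2e6))
    dis <- emulate_sequencing(take_samples(tum, "distant", 2))
    suppressWarnings(pairwise_hfr(dis, "S1", "S2")$hfr)
  }))
  expect_gte(mean_hfr(1000), mean_hfr(10000) - 0.005)
})

test_that("cohort simulation returns the summary-statistic table", {
  set.seed(109)
  co <- simulate_cohort(s_grid = 0, deme_grid = 1000, n_tumors = 2,
                        params_base = small_params(),
                        n_region_samples = 8, k_reclass = c(1, 2),
                        keep_tables = TRUE)
  expect_equal(nrow(co), 2)
  expect_true(all(c("hfr_local", "hfr_distant", "fst", "mean_hfr_panel",
                    "f_subclonal", "ksd", "reclass_k1", "reclass_k2") %in%
                    names(co)))
  tabs <- attr(co, "tables")
  expect_equal(length(tabs), 2)
  expect_equal(length(attr(tabs[[1]], "octant")), 8)
  # reclassification is non-decreasing in k by construction
  expect_true(all(co$reclass_k2 >= co$reclass_k1 - 1e-9))
})

test_that("growth is reproducible under a fixed seed", {
  p <- small_params()
  set.seed(110); t1 <- grow_tumor(p)$summary
  set.seed(110); t2 <- grow_tumor(p)$summary
  expect_equal(t1, t2)
})
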