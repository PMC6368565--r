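test_that("ccf_from_vaf matches the purity/copy-number algebra", {
  expect_equal(ccf_from_vaf(0.5, 1.0, 2, 1, 2), 1.0)
  # algebraic oracle: 0.25 * (0.5*2 + 0.5*2) / (0.5*1) = 1
  expect_equal(ccf_from_vaf(0.25, 0.5, 2, 1, 2), 1.0)
  expect_equal(ccf_from_vaf(0, 0.3, 3, 2, 2), 0)
  expect_equal(ccf_from_vaf(0.9, 0.9, 2, 1, 2), 1.5)  # clipped
  expect_error(ccf_from_vaf(0.2, 0, 2, 1, 2), "uninformative")
  expect_error(ccf_from_vaf(0.2, 0.5, 2, 3, 2), "multiplicity")
})

test_that("pairwise Fst reproduces hand-computed Hudson values", {
  # single fixed-difference SNV: corrections vanish, Fst = 1
  tab <- mutation_table(matrix(c(1, 0), 1, 2,
                               dimnames = list("m1", c("A", "B"))),
                        matrix(100L, 1, 2),
                        matrix(c(100L, 0L), 1, 2))
  expect_equal(pairwise_fst(tab, "A", "B"), 1.0)

  # f_a = f_b = 0.5 at depth 101: (0 - 0.0025 - 0.0025) / 0.5 = -0.01
  tab2 <- mutation_table(matrix(c(0.4, 0.4), 1, 2,
                                dimnames = list("m1", c("A", "B"))),
                         matrix(101L, 1, 2), matrix(50L, 1, 2))
  tab2$alt_reads[] <- 50.5  # exact f = 0.5 (fractional reads for the oracle)
  expect_equal(pairwise_fst(tab2, "A", "B"), -0.01, tolerance = 1e-12)

  # duplicated region: expectation <= 0 (no differentiation)
  set.seed(42)
  ccf <- matrix(rep(runif(30, 0.05, 0.45), 2), 30, 2,
                dimnames = list(NULL, c("A", "B")))
  vals <- replicate(30, {
    dep <- matrix(rpois(60, 100), 30, 2)
    alt <- matrix(rbinom(60, as.vector(dep), as.vector(ccf) / 2), 30, 2)
    t3 <- mutation_table(ccf, dep, alt)
    pairwise_fst(t3, "A", "B")
  })
  expect_lt(mean(vals), 0.01)
})

test_that("case Fst averages estimable pairs", {
  set.seed(7)
  ccf <- matrix(runif(30, 0, 0.4), 10, 3,
                dimnames = list(NULL, c("A", "B", "C")))
  tab <- ccf_table(ccf)
  pf <- c(pairwise_fst(tab, "A", "B"), pairwise_fst(tab, "A", "C"),
          pairwise_fst(tab, "B", "C"))
  expect_equal(case_fst(tab), mean(pf))
})

test_that("HFR matches the counting definition and its conventions", {
  # identical regions, all clonal: r1 = r2 = 0, c = n, hfr = 0
  tab <- ccf_table(matrix(0.9, 10, 2, dimnames = list(NULL, c("A", "B"))))
  h <- pairwise_hfr(tab, "A", "B")
  expect_equal(c(h$r1, h$r2, h$c, h$hfr), c(0, 0, 10, 0))

  # hand enumeration: (0.9/0.9, 0.8/0.05, 0.02/0.7, 0.6/0.3)
  ccf <- rbind(c(0.9, 0.9), c(0.8, 0.05), c(0.02, 0.7), c(0.6, 0.3))
  colnames(ccf) <- c("A", "B")
  h2 <- pairwise_hfr(ccf_table(ccf), "A", "B")
  expect_equal(c(h2$r1, h2$r2, h2$c, h2$hfr), c(1, 1, 1, 0.5))

  # zero-denominator convention: region B has no clonal mutations
  ccf3 <- rbind(c(0.8, 0.02), c(0.9, 0.05))
  colnames(ccf3) <- c("A", "B")
  h3 <- pairwise_hfr(ccf_table(ccf3), "A", "B")
  expect_equal(h3$hfr, 0.5)

  # no clonal mutations anywhere: hfr 0 with a warning
  ccf4 <- matrix(0.2, 3, 2, dimnames = list(NULL, c("A", "B")))
  expect_warning(h4 <- pairwise_hfr(ccf_table(ccf4), "A", "B"),
                 "no clonal")
  expect_equal(h4$hfr, 0)
})

test_that("tHFR matches direct counts and subset averaging", {
  # all clonal everywhere
  tab <- ccf_table(matrix(0.9, 8, 3, dimnames = list(NULL, c("P", "A", "B"))),
                   timepoints = c("pre", "post", "post"))
  expect_equal(thfr(tab)$thfr, 0)

  # constructed 10-mutation table: tC = 7, tR = 3
  ccf <- cbind(c(rep(0.9, 7), rep(0.02, 3)),
               rep(0.8, 10), rep(0.9, 10))
  colnames(ccf) <- c("P", "A", "B")
  tab2 <- ccf_table(ccf, timepoints = c("pre", "post", "post"))
  res <- thfr(tab2)
  expect_equal(c(res$t_c, res$t_r, res$thfr), c(7, 3, 0.30))

  # subset averaging over single post regions
  oracle <- mean(c(naive_thfr(ccf, "P", "A")$thfr,
                   naive_thfr(ccf, "P", "B")$thfr))
  expect_equal(thfr(tab2, n_post = 1)$thfr, oracle)

  # not estimable
  ccf5 <- matrix(0.2, 4, 2, dimnames = list(NULL, c("P", "A")))
  expect_true(is.na(thfr(ccf_table(ccf5, timepoints = c("pre", "post")))$thfr))
})

test_that("reclassification fraction matches enumeration", {
  # clonal set {m1..m4}; m2 rare in A, m3 rare in B; k = 2 over {A, B} -> 0.5
  ccf <- rbind(c(0.9, 0.9, 0.9), c(0.8, 0.05, 0.6),
               c(0.7, 0.6, 0.02), c(0.9, 0.8, 0.9))
  colnames(ccf) <- c("F", "A", "B")
  tab <- ccf_table(ccf)
  expect_equal(reclassification_fraction(tab, "F", 2), 0.5)
  # k = 1: average over {A} and {B}: (1/4 + 1/4) / 2 = 0.25
  expect_equal(reclassification_fraction(tab, "F", 1), 0.25)
  # identical regions -> 0
  tab2 <- ccf_table(matrix(0.9, 5, 3, dimnames = list(NULL, c("F", "A", "B"))))
  expect_equal(reclassification_fraction(tab2, "F", 1), 0)
  # no clonal mutations -> sentinel
  tab3 <- ccf_table(matrix(0.2, 5, 3, dimnames = list(NULL, c("F", "A", "B"))))
  expect_true(is.na(reclassification_fraction(tab3, "F", 1)))
})

test_that("timing classification follows the rules and precedence", {
  ccf <- rbind(truncal = c(0.9, 0.9, 0.9),
               post_only = c(0.0, 0.8, 0.8),
               subclonal_pre = c(0.3, 0.7, 0.7),
               subclonal_absent_post = c(0.5, 0.02, 0.9),
               post_only_and_absent = c(0.05, 0.9, 0.02))
  colnames(ccf) <- c("P", "A", "B")
  tab <- ccf_table(ccf, timepoints = c("pre", "post", "post"))
  lab <- classify_timing(tab)
  expect_equal(lab$label[1:4],
               c("truncal", "post_only", "subclonal", "subclonal"))
  # precedence: absent pre AND absent in one post -> post_only wins
  expect_equal(lab$label[5], "post_only")
})

test_that("read-filtered mutations never change the statistics", {
  set.seed(11)
  ccf <- matrix(runif(40, 0, 1), 10, 4,
                dimnames = list(paste0("m", 1:10), c("P", "A", "B", "C")))
  tab <- ccf_table(ccf, timepoints = c("pre", "post", "post", "post"))
  # append a mutation failing depth and one failing alt support
  bad_ccf <- rbind(ccf, lowdep = c(0.9, 0.9, 0.9, 0.9),
                   lowalt = c(0.9, 0.9, 0.9, 0.9))
  tab2 <- ccf_table(bad_ccf, timepoints = c("pre", "post", "post", "post"))
  tab2$depth["lowdep", "A"] <- 5L
  tab2$alt_reads["lowdep", "A"] <- 2L
  tab2$alt_reads["lowalt", ] <- 2L
  expect_equal(pairwise_hfr(tab2, "A", "B")$hfr,
               pairwise_hfr(tab, "A", "B")$hfr)
  expect_equal(thfr(tab2)$thfr, thfr(tab)$thfr)
  expect_equal(pairwise_fst(tab2, "A", "B"), pairwise_fst(tab, "A", "B"))
  expect_equal(classify_timing(tab2)$mut_id, classify_timing(tab)$mut_id)
})

test_that("brute-force recounts match on random small tables", {
  set.seed(23)
  for (rep in 1:20) {
    n_mut <- sample(5:20, 1)
    n_reg <- sample(3:5, 1)
    ccf <- matrix(sample(c(0, 0.02, 0.05, 0.3, 0.6, 0.9, 1),
                         n_mut * n_reg, replace = TRUE), n_mut, n_reg)
    colnames(ccf) <- c("P", paste0("R", seq_len(n_reg - 1)))
    tab <- ccf_table(ccf, timepoints = c("pre", rep("post", n_reg - 1)))
    a <- colnames(ccf)[2]; b <- colnames(ccf)[n_reg]
    h <- pairwise_hfr(tab, a, b)
    ho <- naive_hfr(ccf, a, b)
    expect_equal(c(h$r1, h$r2, h$c, h$hfr),
                 c(ho$r1, ho$r2, ho$c, ho$hfr))
    # swap symmetry
    expect_equal(pairwise_hfr(tab, b, a)$hfr, h$hfr)
    tres <- thfr(tab)
    tor <- naive_thfr(ccf, "P", colnames(ccf)[-1])
    expect_equal(tres$thfr, tor$thfr)
    # Fst against the naive loop (all subclonal so the inclusion rule is
    # moot; the naive recount runs on the read-filtered table)
    ccf_sub <- ccf * 0.4
    tab_sub <- ccf_table(ccf_sub,
                         timepoints = c("pre", rep("post", n_reg - 1)))
    tf <- apply_read_filters(tab_sub)
    expect_equal(pairwise_fst(tab_sub, a, b),
                 naive_fst(vaf_matrix(tf), tf$depth, a, b))
  }
})

test_that("statistics stay inside [0, 1] on random tables", {
  set.seed(31)
  for (rep in 1:10) {
    ccf <- matrix(runif(24, 0, 1.2), 8, 3,
                  dimnames = list(NULL, c("P", "A", "B")))
    tab <- ccf_table(ccf, timepoints = c("pre", "post", "post"))
    h <- suppressWarnings(pairwise_hfr(tab, "A", "B")$hfr)
    expect_gte(h, 0); expect_lte(h, 1)
    tv <- thfr(tab)$thfr
    if (!is.na(tv)) { expect_gte(tv, 0); expect_lte(tv, 1) }
    rv <- reclassification_fraction(tab, "A", 1)
    if (!is.na(rv)) { expect_gte(rv, 0); expect_lte(rv, 1) }
  }
})
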