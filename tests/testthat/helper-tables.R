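# Build a mutation_table directly from a CCF matrix: reads are made
# consistent with the CCFs (vaf = ccf/2 on a diploid pure sample) at a flat
# depth, so read filters pass unless stated otherwise.
ccf_table <- function(ccf, depth = 100, timepoints = NULL) {
  ccf <- as.matrix(ccf)
  dep <- matrix(depth, nrow(ccf), ncol(ccf), dimnames = dimnames(ccf))
  alt <- round(dep * pmin(ccf / 2, 1))
  mutation_table(ccf, dep, alt, timepoints = timepoints)
}

# Naive recount oracles: straight loops over the definitions, kept
# independent of the package's vectorized implementations.
naive_hfr <- function(ccf, a, b, hi = 0.5, lo = 0.1) {
  r1 <- r2 <- cc <- 0
  for (i in seq_len(nrow(ccf))) {
    ca <- ccf[i, a]; cb <- ccf[i, b]
    if (ca > hi && cb < lo) r1 <- r1 + 1
    if (cb > hi && ca < lo) r2 <- r2 + 1
    if (ca > hi && cb > hi) cc <- cc + 1
  }
  t1 <- if (r1 + cc > 0) r1 / (r1 + cc) else 0
  t2 <- if (r2 + cc > 0) r2 / (r2 + cc) else 0
  list(r1 = r1, r2 = r2, c = cc, hfr = (t1 + t2) / 2)
}

naive_thfr <- function(ccf, pre, posts, hi = 0.5, lo = 0.1) {
  tc <- tr <- 0
  for (i in seq_len(nrow(ccf))) {
    post_clonal <- TRUE
    for (p in posts) if (ccf[i, p] <= hi) post_clonal <- FALSE
    if (!post_clonal) next
    if (ccf[i, pre] > hi) tc <- tc + 1
    if (ccf[i, pre] < lo) tr <- tr + 1
  }
  list(t_c = tc, t_r = tr,
       thfr = if (tc + tr == 0) NA_real_ else tr / (tr + tc))
}

naive_fst <- function(vaf, dep, a, b) {
  num <- den <- 0
  for (i in seq_len(nrow(vaf))) {
    fa <- vaf[i, a]; fb <- vaf[i, b]
    da <- dep[i, a]; db <- dep[i, b]
    num <- num + (fa - fb)^2 - fa * (1 - fa) / (da - 1) -
      fb * (1 - fb) / (db - 1)
    den <- den + fa * (1 - fb) + fb * (1 - fa)
  }
  if (den == 0) NA_real_ else num / den
}
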