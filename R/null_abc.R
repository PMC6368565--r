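#' Empirical tHFR null distribution from virtual tumors
#'
#' For each virtual tumor's emulated sample panel, designates a
#' pre-treatment sample and post-treatment samples according to a named
#' sampling scheme and computes tHFR (averaged over all post-sample subsets
#' of size `n_post`). The collection across tumors is the null distribution
#' of clonal change attributable to spatial heterogeneity alone ("geographic
#' killing"), against which an observed tHFR is tested.
#'
#' Schemes: `opposite_octant_pre_post` picks the pre sample from one octant
#' and post samples from the opposite octant; `opposite_quadrants_post`
#' additionally splits the post samples between two opposite quadrants
#' (the quadrant-aware scheme); `random` ignores geometry.
#'
#' @param tables list of emulated panel [mutation_table()]s, each with an
#'   `octant` attribute giving the octant of each sample (as produced by
#'   [simulate_cohort()] with `keep_tables = TRUE`).
#' @param scheme sampling scheme name.
#' @param n_post number of post-treatment samples used (1-3).
#' @param n_post_pool how many post candidates to draw before subset
#'   averaging (defaults to `n_post`; set higher to average over subsets).
#' @param thresholds a [thresholds()] object.
#' @return a list of class `thfr_null`: sorted `values`, `scheme`, `n_post`,
#'   `n_tumors`.
#' @export
build_thfr_null <- function(tables,
                            scheme = c("opposite_octant_pre_post",
                                       "opposite_quadrants_post", "random"),
                            n_post = 2, n_post_pool = NULL,
                            thresholds = clonalshift::thresholds()) {
  scheme <- match.arg(scheme)
  if (is.null(n_post_pool)) n_post_pool <- n_post
  vals <- vapply(tables, function(tab) {
    oct <- attr(tab, "octant")
    if (is.null(oct)) stop("tables need an 'octant' attribute")
    rg <- region_names(tab)
    sel <- switch(scheme,
      random = {
        idx <- sample(seq_along(rg), 1 + n_post_pool)
        list(pre = rg[idx[1]], post = rg[idx[-1]])
      },
      opposite_octant_pre_post = {
        quad <- (oct - 1) %% 4 + 1
        ok <- Filter(function(o) sum(oct == o) >= 1 &&
                       sum(oct == (9 - o)) >= n_post_pool, unique(oct))
        if (length(ok) == 0) return(NA_real_)
        o <- if (length(ok) == 1) ok else sample(ok, 1)
        pre_i <- which(oct == o)
        pre_i <- if (length(pre_i) == 1) pre_i else sample(pre_i, 1)
        post_i <- which(oct == (9 - o))
        post_i <- if (length(post_i) == n_post_pool) post_i else
          sample(post_i, n_post_pool)
        list(pre = rg[pre_i], post = rg[post_i])
      },
      opposite_quadrants_post = {
        quad <- (oct - 1) %% 4 + 1
        half <- ceiling(n_post_pool / 2)
        ok <- Filter(function(q) sum(quad == q) >= half &&
                       sum(quad == (5 - q)) >= n_post_pool - half + 1,
                     unique(quad))
        if (length(ok) == 0) return(NA_real_)
        q <- if (length(ok) == 1) ok else sample(ok, 1)
        pre_i <- sample(seq_along(rg), 1)
        a <- setdiff(which(quad == q), pre_i)
        b <- setdiff(which(quad == (5 - q)), pre_i)
        if (length(a) < half || length(b) < n_post_pool - half)
          return(NA_real_)
        post_i <- c(if (length(a) == 1) a else sample(a, half),
                    if (length(b) == 1) b else sample(b, n_post_pool - half))
        list(pre = rg[pre_i], post = rg[post_i])
      })
    if (!is.list(sel)) return(NA_real_)
    v <- thfr(tab, pre_region = sel$pre, post_regions = sel$post,
              n_post = n_post, thresholds = thresholds)$thfr
    if (is.na(v)) 0 else v
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("no tumor satisfied the sampling scheme")
  structure(list(values = sort(vals), scheme = scheme, n_post = n_post,
                 n_tumors = length(vals)), class = "thfr_null")
}

#' Test an observed tHFR against the virtual-tumor null
#'
#' The percentile is the strictly-less-than fraction of null values below
#' the observed tHFR (ties count below). The verdict flags clonal
#' replacement when the percentile exceeds `cutoff` — i.e. when spatial
#' heterogeneity of untreated virtual tumors rarely produces as much
#' apparent clonal change.
#'
#' @param observed_thfr observed tHFR value.
#' @param null a [build_thfr_null()] result.
#' @param cutoff verdict percentile cutoff (default 0.90).
#' @return list with `percentile`, `verdict` (logical: consistent with
#'   clonal replacement) and `n_null`.
#' @export
test_clonal_replacement <- function(observed_thfr, null, cutoff = 0.90) {
  stopifnot(length(null$values) > 0)
  pct <- mean(null$values < observed_thfr)
  list(percentile = pct, verdict = pct > cutoff, n_null = null$n_tumors)
}

#' Rejection ABC over the selection / deme-size grid
#'
#' Standardizes each summary statistic (by the simulated table's mean and
#' standard deviation), computes Euclidean distances between the observed
#' statistic vector and every simulated tumor, accepts the closest
#' `acceptance_fraction`, and reports acceptance counts per parameter value
#' as posterior mass. Observed statistics that are missing (`NA`) are
#' dropped from the distance with a warning.
#'
#' The default statistic set — case Fst, mean pairwise HFR, fraction of
#' mutations subclonal in at least one region, and mean pairwise KS distance
#' between region CCF distributions — is a pragmatic reconstruction of the
#' heterogeneity-metric panel used with such simulators, not a reproduction
#' of any external implementation.
#'
#' @param observed_stats named numeric vector of observed summary
#'   statistics.
#' @param simulated_table data.frame from [simulate_cohort()] with columns
#'   `s`, `deme_size` and the statistics.
#' @param acceptance_fraction fraction of simulations accepted.
#' @param stats which statistic columns to use.
#' @return a list of class `abc_result`: `posterior_s`, `posterior_deme`
#'   (named probability vectors), `accepted` (data.frame of accepted draws),
#'   `acceptance_fraction`, `stats_used`.
#' @export
abc_infer <- function(observed_stats, simulated_table,
                      acceptance_fraction = 0.05,
                      stats = c("fst", "mean_hfr_panel", "f_subclonal",
                                "ksd")) {
  stats <- intersect(stats, names(simulated_table))
  obs <- observed_stats[stats]
  drop <- is.na(obs)
  if (any(drop)) {
    warning("dropping missing observed statistic(s): ",
            paste(stats[drop], collapse = ", "))
    stats <- stats[!drop]
    obs <- obs[!drop]
  }
  if (length(stats) == 0) stop("no usable summary statistics")
  sim <- as.matrix(simulated_table[stats])
  ok <- stats::complete.cases(sim)
  sim <- sim[ok, , drop = FALSE]
  tab <- simulated_table[ok, ]
  mu <- colMeans(sim)
  sd <- apply(sim, 2, stats::sd)
  sd[sd == 0] <- 1
  z <- sweep(sweep(sim, 2, mu), 2, sd, "/")
  zo <- (unlist(obs) - mu) / sd
  dist <- sqrt(rowSums(sweep(z, 2, zo)^2))
  n_acc <- max(1, ceiling(acceptance_fraction * nrow(sim)))
  acc <- tab[order(dist)[seq_len(n_acc)], ]
  post <- function(x) {
    p <- table(x) / length(x)
    stats::setNames(as.numeric(p), names(p))
  }
  structure(list(posterior_s = post(acc$s),
                 posterior_deme = post(acc$deme_size),
                 accepted = acc,
                 acceptance_fraction = acceptance_fraction,
                 stats_used = stats), class = "abc_result")
}

#' Posterior mode of an ABC axis
#'
#' @param posterior named probability vector from [abc_infer()].
#' @return the parameter value (numeric) with the largest mass; ties go to
#'   the smaller value.
#' @export
posterior_mode <- function(posterior) {
  as.numeric(names(posterior)[which.max(posterior)])
}
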