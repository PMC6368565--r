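#' Analysis thresholds
#'
#' Cutoffs shared by the heterogeneity statistics and the mutation timing
#' classifier. Defaults follow the study conventions: a mutation is treated
#' as clonal ("high-frequency") in a region at CCF > 0.5, as absent-or-rare
#' at CCF < 0.1; SNVs enter the Fst calculation when subclonal (CCF < 0.5)
#' in at least one of the compared regions; truncal mutations have mean CCF
#' > 0.6 across regions and > 0.25 in each; pre-treatment subclonal means
#' CCF < 0.4; read filters require depth >= 20 in every sample and >= 4
#' variant reads in at least one sample.
#'
#' @param clonal_ccf CCF above which a mutation counts as clonal in a region.
#' @param rare_ccf CCF below which a mutation counts as absent or rare.
#' @param subclonal_ccf inclusion cutoff for Fst (subclonal in >= 1 region).
#' @param truncal_mean_ccf minimum mean CCF for the truncal class.
#' @param truncal_min_ccf minimum per-region CCF for the truncal class.
#' @param subclonal_pre_ccf pre-treatment CCF below which a mutation is
#'   subclonal.
#' @param min_depth minimum depth required in every sample.
#' @param min_alt minimum variant reads required in at least one sample.
#' @return a list of class `thresholds`.
#' @export
thresholds <- function(clonal_ccf = 0.5, rare_ccf = 0.1, subclonal_ccf = 0.5,
                       truncal_mean_ccf = 0.6, truncal_min_ccf = 0.25,
                       subclonal_pre_ccf = 0.4, min_depth = 20, min_alt = 4) {
  stopifnot(rare_ccf < clonal_ccf, clonal_ccf >= 0, rare_ccf >= 0,
            subclonal_ccf >= 0, min_depth >= 0, min_alt >= 0)
  structure(list(clonal_ccf = clonal_ccf, rare_ccf = rare_ccf,
                 subclonal_ccf = subclonal_ccf,
                 truncal_mean_ccf = truncal_mean_ccf,
                 truncal_min_ccf = truncal_min_ccf,
                 subclonal_pre_ccf = subclonal_pre_ccf,
                 min_depth = min_depth, min_alt = min_alt),
            class = "thresholds")
}

#' Apply mutation-calling read filters
#'
#' Drops mutations covered by fewer than `min_depth` reads in any sample, or
#' whose variant allele is not supported by at least `min_alt` reads in at
#' least one sample — the same calling criteria applied to patient tumors
#' and to emulated sequencing of virtual tumors.
#'
#' @param table a [mutation_table()].
#' @param thresholds a [thresholds()] object.
#' @return the filtered [mutation_table()].
#' @export
apply_read_filters <- function(table, thresholds = clonalshift::thresholds()) {
  keep <- apply(table$depth >= thresholds$min_depth, 1, all) &
    apply(table$alt_reads >= thresholds$min_alt, 1, any)
  table[keep, ]
}

#' CCF from VAF, purity and local copy number
#'
#' Adjusts an observed variant allele fraction for tumor purity and local
#' copy number to estimate the cancer cell fraction:
#' `ccf = vaf * (purity * total_cn + (1 - purity) * normal_cn) /
#' (purity * multiplicity)`, clipped to `[0, 1.5]`. Multiplicity (number of
#' mutated copies per carrying cell) defaults to 1 when unknown.
#'
#' @param vaf variant allele fraction in `[0, 1]` (vectorized).
#' @param purity tumor purity in `(0, 1]`.
#' @param total_cn absolute tumor copy number at the locus (>= 1).
#' @param multiplicity mutated copies per carrying tumor cell (>= 1,
#'   `<= total_cn`).
#' @param normal_cn copy number in contaminating normal cells (2 for
#'   autosomes).
#' @return CCF estimate(s) in `[0, 1.5]`.
#' @export
ccf_from_vaf <- function(vaf, purity, total_cn = 2, multiplicity = 1,
                         normal_cn = 2) {
  if (any(purity <= 0)) stop("uninformative sample: purity must be > 0")
  if (any(multiplicity > total_cn)) stop("multiplicity exceeds total copy number")
  if (any(vaf < 0 | vaf > 1)) stop("vaf must lie in [0, 1]")
  ccf <- vaf * (purity * total_cn + (1 - purity) * normal_cn) /
    (purity * multiplicity)
  pmin(pmax(ccf, 0), 1.5)
}

#' Hudson's Fst between two tumor regions
#'
#' Depth-corrected ratio-of-sums Hudson estimator of differentiation between
#' regions `a` and `b`, computed over subclonal SNVs (CCF below
#' `subclonal_ccf` in at least one of the two regions). Per SNV the
#' numerator term is `(f_a - f_b)^2 - f_a(1-f_a)/(d_a-1) - f_b(1-f_b)/(d_b-1)`
#' and the denominator term `f_a(1-f_b) + f_b(1-f_a)`, where `f` is the VAF
#' and `d` the depth; the statistic is the ratio of the summed terms. The
#' sampling correction can push the estimate slightly negative; it is
#' reported unclipped. SNVs with depth <= 1 in either region are excluded
#' with a warning (the correction is undefined there).
#'
#' @param table a [mutation_table()] (read filters are applied first).
#' @param region_a,region_b region names.
#' @param thresholds a [thresholds()] object.
#' @param loh_mask optional logical vector (TRUE = exclude), e.g. SNVs with
#'   discordant loss of heterozygosity between the regions; LOH calling
#'   itself is upstream of this package.
#' @return Fst estimate, or `NA` when no polymorphic SNVs remain
#'   ("not estimable").
#' @export
pairwise_fst <- function(table, region_a, region_b,
                         thresholds = clonalshift::thresholds(),
                         loh_mask = NULL) {
  check_region(table, region_a); check_region(table, region_b)
  tab <- apply_read_filters(table, thresholds)
  if (!is.null(loh_mask)) {
    loh <- loh_mask[match(tab$mutations$mut_id, table$mutations$mut_id)]
    tab <- tab[!loh, ]
  }
  ccf <- tab$ccf[, c(region_a, region_b), drop = FALSE]
  sub <- ccf[, 1] < thresholds$subclonal_ccf | ccf[, 2] < thresholds$subclonal_ccf
  v <- vaf_matrix(tab)
  fa <- v[sub, region_a]; fb <- v[sub, region_b]
  da <- tab$depth[sub, region_a]; db <- tab$depth[sub, region_b]
  lowd <- da <= 1 | db <= 1
  if (any(lowd)) {
    warning(sprintf("excluding %d SNV(s) with depth <= 1 from Fst", sum(lowd)))
    fa <- fa[!lowd]; fb <- fb[!lowd]; da <- da[!lowd]; db <- db[!lowd]
  }
  num <- sum((fa - fb)^2 - fa * (1 - fa) / (da - 1) - fb * (1 - fb) / (db - 1))
  den <- sum(fa * (1 - fb) + fb * (1 - fa))
  if (length(fa) == 0 || den == 0) return(NA_real_)
  num / den
}

#' Case-level Fst
#'
#' Unweighted mean of [pairwise_fst()] over all region pairs; pairs that are
#' not estimable are skipped.
#'
#' @inheritParams pairwise_fst
#' @return mean Fst, or `NA` when no pair is estimable.
#' @export
case_fst <- function(table, thresholds = clonalshift::thresholds(),
                     loh_mask = NULL) {
  rg <- region_names(table)
  if (length(rg) < 2) stop("case Fst needs at least two regions")
  prs <- utils::combn(rg, 2)
  vals <- apply(prs, 2, function(p)
    pairwise_fst(table, p[1], p[2], thresholds, loh_mask))
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' High-frequency regional statistic (HFR) between two regions
#'
#' Counts mutations clonal (CCF > `clonal_ccf`) in one region and absent or
#' rare (CCF < `rare_ccf`) in the other (`r1`, `r2`), and mutations clonal
#' in both (`c`). The statistic averages the two directional fractions:
#' `hfr = (r1/(r1 + c) + r2/(r2 + c)) / 2`, a directional term with zero
#' denominator contributing 0. Mutations clonal in one region but at
#' intermediate CCF in the other contribute to neither count, so HFR uses
#' only drastic, reliable CCF differences.
#'
#' @inheritParams pairwise_fst
#' @return a list of class `hfr_breakdown`: counts `r1`, `r2`, `c` and the
#'   statistic `hfr` in `[0, 1]`. Symmetric under swapping the regions.
#' @export
pairwise_hfr <- function(table, region_a, region_b,
                         thresholds = clonalshift::thresholds()) {
  check_region(table, region_a); check_region(table, region_b)
  tab <- apply_read_filters(table, thresholds)
  a <- tab$ccf[, region_a]; b <- tab$ccf[, region_b]
  hi <- thresholds$clonal_ccf; lo <- thresholds$rare_ccf
  r1 <- sum(a > hi & b < lo)
  r2 <- sum(b > hi & a < lo)
  cc <- sum(a > hi & b > hi)
  if (r1 + r2 + cc == 0)
    warning("no clonal mutations in either region; HFR set to 0")
  term <- function(r) if (r + cc == 0) 0 else r / (r + cc)
  structure(list(r1 = r1, r2 = r2, c = cc,
                 hfr = (term(r1) + term(r2)) / 2),
            class = "hfr_breakdown")
}

#' Mean pairwise HFR across all regions of a case
#'
#' @inheritParams pairwise_fst
#' @param regions optional subset of regions (default: all).
#' @return mean of `hfr` over all unordered region pairs.
#' @export
mean_pairwise_hfr <- function(table, thresholds = clonalshift::thresholds(),
                              regions = NULL) {
  rg <- if (is.null(regions)) region_names(table) else regions
  if (length(rg) < 2) stop("need at least two regions")
  prs <- utils::combn(rg, 2)
  mean(apply(prs, 2, function(p)
    pairwise_hfr(table, p[1], p[2], thresholds)$hfr))
}

#' Temporal HFR (tHFR): clonal change across treatment
#'
#' The proportion of mutations clonal (CCF > `clonal_ccf`) in every
#' post-treatment region that were absent or rare (CCF < `rare_ccf`) in the
#' single pre-treatment region: `thfr = t_r / (t_r + t_c)`, where `t_c`
#' counts mutations clonal in all samples including the pre sample and
#' `t_r` counts mutations clonal in every post sample but rare pre.
#'
#' When `n_post` is given, tHFR is averaged over all subsets of the post
#' regions of that size, which makes values comparable across cases with
#' different numbers of post-treatment samples.
#'
#' @param table a [mutation_table()] with exactly one `pre` region (or
#'   supply `pre_region`).
#' @param pre_region,post_regions region names; default taken from the
#'   table's timepoint tags.
#' @param n_post optional subset size for subset-averaged tHFR.
#' @param thresholds a [thresholds()] object.
#' @return a list of class `thfr_breakdown` with `t_c`, `t_r` and `thfr`
#'   (`NA` when `t_c + t_r = 0`, not estimable); for subset-averaged calls
#'   `thfr` is the average and `subsets` records the per-subset values.
#' @export
thfr <- function(table, pre_region = NULL, post_regions = NULL, n_post = NULL,
                 thresholds = clonalshift::thresholds()) {
  if (is.null(pre_region)) {
    pr <- pre_regions(table)
    if (length(pr) != 1) stop("exactly one pre-treatment region required")
    pre_region <- pr
  }
  if (is.null(post_regions))
    post_regions <- setdiff(region_names(table), pre_region)
  if (length(post_regions) < 1) stop("at least one post-treatment region required")
  check_region(table, pre_region)
  for (r in post_regions) check_region(table, r)
  tab <- apply_read_filters(table, thresholds)
  one <- function(posts) {
    hi <- thresholds$clonal_ccf; lo <- thresholds$rare_ccf
    post_cl <- apply(tab$ccf[, posts, drop = FALSE] > hi, 1, all)
    pre_ccf <- tab$ccf[, pre_region]
    t_c <- sum(post_cl & pre_ccf > hi)
    t_r <- sum(post_cl & pre_ccf < lo)
    list(t_c = t_c, t_r = t_r,
         thfr = if (t_c + t_r == 0) NA_real_ else t_r / (t_r + t_c))
  }
  if (is.null(n_post) || n_post >= length(post_regions)) {
    res <- one(post_regions)
    return(structure(res, class = "thfr_breakdown"))
  }
  subsets <- utils::combn(post_regions, n_post, simplify = FALSE)
  vals <- vapply(subsets, function(s) one(s)$thfr, numeric(1))
  structure(list(t_c = NA_integer_, t_r = NA_integer_,
                 thfr = mean(vals, na.rm = TRUE), subsets = vals),
            class = "thfr_breakdown")
}

#' Fraction of apparently clonal mutations reclassified by extra regions
#'
#' Among mutations clonal (CCF > `clonal_ccf`) in a first region, the
#' fraction found definitively subclonal (CCF < `rare_ccf`) in at least one
#' of `k_additional` further regions — the information gained from
#' multi-region sampling. With more candidate regions than `k_additional`,
#' the fraction is averaged over full enumeration of region subsets, or over
#' `n_draws` random draws when enumeration is larger than `max_enumerate`.
#'
#' @param table a [mutation_table()].
#' @param first_region name of the index region.
#' @param k_additional number of additional regions consulted.
#' @param thresholds a [thresholds()] object.
#' @param n_draws random draws used when not enumerating.
#' @param max_enumerate largest subset count enumerated exactly.
#' @return reclassified fraction in `[0, 1]`, or `NA` when the first region
#'   has no clonal mutations.
#' @export
reclassification_fraction <- function(table, first_region, k_additional = 1,
                                      thresholds = clonalshift::thresholds(),
                                      n_draws = 100, max_enumerate = 200) {
  check_region(table, first_region)
  others <- setdiff(region_names(table), first_region)
  if (length(others) < k_additional)
    stop("not enough additional regions available")
  tab <- apply_read_filters(table, thresholds)
  clonal <- tab$ccf[, first_region] > thresholds$clonal_ccf
  if (!any(clonal)) return(NA_real_)
  rare <- tab$ccf[clonal, others, drop = FALSE] < thresholds$rare_ccf
  frac_for <- function(set)
    mean(apply(rare[, set, drop = FALSE], 1, any))
  n_subsets <- choose(length(others), k_additional)
  if (n_subsets <= max_enumerate) {
    sets <- utils::combn(others, k_additional, simplify = FALSE)
  } else {
    sets <- replicate(n_draws, sample(others, k_additional), simplify = FALSE)
  }
  mean(vapply(sets, frac_for, numeric(1)))
}

#' Classify mutation timing across treatment
#'
#' Assigns each mutation passing the read filters one of three labels:
#' `truncal` (mean CCF > `truncal_mean_ccf` across all regions and
#' > `truncal_min_ccf` in each region), `post_only` (absent — CCF below
#' `rare_ccf` — in the pre-treatment sample), or `subclonal` (present
#' pre-treatment with CCF < `subclonal_pre_ccf`, or absent in at least one
#' post-treatment sample). Precedence is truncal, then post_only, then
#' subclonal; mutations matching no rule are labeled `unclassified`.
#'
#' @param table a [mutation_table()] with one pre and >= 1 post region.
#' @param thresholds a [thresholds()] object.
#' @return data.frame with columns `mut_id` and `label`.
#' @export
classify_timing <- function(table, thresholds = clonalshift::thresholds()) {
  pr <- pre_regions(table); po <- post_regions(table)
  if (length(pr) != 1 || length(po) < 1)
    stop("classification needs one pre and at least one post region")
  tab <- apply_read_filters(table, thresholds)
  ccf <- tab$ccf
  lo <- thresholds$rare_ccf
  truncal <- rowMeans(ccf) > thresholds$truncal_mean_ccf &
    apply(ccf > thresholds$truncal_min_ccf, 1, all)
  post_only <- ccf[, pr] < lo
  subclonal <- (ccf[, pr] >= lo & ccf[, pr] < thresholds$subclonal_pre_ccf) |
    apply(ccf[, po, drop = FALSE] < lo, 1, any)
  label <- rep("unclassified", nrow(ccf))
  label[subclonal] <- "subclonal"
  label[post_only] <- "post_only"
  label[truncal] <- "truncal"
  data.frame(mut_id = tab$mutations$mut_id, label = label,
             stringsAsFactors = FALSE)
}
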