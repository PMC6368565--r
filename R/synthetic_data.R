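#' Planted clone architecture for synthetic multi-region cases
#'
#' Describes a cohort-like tumor — one pre-treatment region plus several
#' post-treatment regions — with a planted clone structure: truncal
#' mutations clonal everywhere, regional subclones confined to declared
#' region sets, and optionally a replacing resistant clone that is clonal in
#' every post region yet rare pre-treatment (the clonal-replacement
#' signature). Reads are later drawn with binomial noise at the declared
#' depth and purity.
#'
#' @param scenario `"clonal_replacement"`, `"geographic_heterogeneity"` or
#'   `"homogeneous"`; presets the clone structure, overridable via the other
#'   arguments.
#' @param regions region names; the first is the pre-treatment region.
#' @param n_truncal number of truncal mutations (CCF 1 everywhere).
#' @param subclones list of `list(regions =, ccf =, n =)` entries: a clone of
#'   `n` mutations at CCF `ccf` in the named regions and 0 elsewhere.
#' @param replacing_clone `list(post_ccf =, pre_ccf =, n =)` or `NULL`; a
#'   clone at `post_ccf` (>= 0.8 by convention) in every post region and
#'   `pre_ccf` (<= 0.05) pre-treatment.
#' @param purity per-region tumor purity (recycled).
#' @param depth per-region mean sequencing depth (recycled).
#' @return a list of class `planted_architecture`.
#' @export
planted_architecture <- function(scenario = c("clonal_replacement",
                                              "geographic_heterogeneity",
                                              "homogeneous"),
                                 regions = c("PRE", "POST1", "POST2"),
                                 n_truncal = 60,
                                 subclones = NULL,
                                 replacing_clone = NULL,
                                 purity = 0.7, depth = 100) {
  scenario <- match.arg(scenario)
  posts <- regions[-1]
  if (is.null(subclones))
    subclones <- switch(scenario,
      homogeneous = list(),
      geographic_heterogeneity = lapply(seq_along(posts), function(i)
        list(regions = posts[i], ccf = 0.8, n = 15)),
      clonal_replacement = list(
        list(regions = posts[1], ccf = 0.3, n = 10)))
  if (is.null(replacing_clone) && scenario == "clonal_replacement")
    replacing_clone <- list(post_ccf = 0.95, pre_ccf = 0.02, n = 25)
  for (sc in subclones) {
    stopifnot(all(sc$regions %in% regions), sc$ccf >= 0, sc$ccf <= 1)
  }
  if (!is.null(replacing_clone))
    stopifnot(replacing_clone$post_ccf <= 1, replacing_clone$pre_ccf >= 0)
  structure(list(scenario = scenario, regions = regions,
                 n_truncal = n_truncal, subclones = subclones,
                 replacing_clone = replacing_clone,
                 purity = rep_len(purity, length(regions)),
                 depth = rep_len(depth, length(regions))),
            class = "planted_architecture")
}

#' Generate a synthetic multi-region case
#'
#' Lays out the true CCF matrix from the planted architecture, then draws
#' reads per mutation and region: depth ~ Poisson(region depth), variant
#' reads ~ Binomial(depth, ccf x purity / 2) (heterozygous diploid sites
#' with normal-cell contamination), and recovers observed CCFs with
#' [ccf_from_vaf()]. Truth labels (clone membership and the timing class
#' each mutation should receive) ride along in `$truth` so tests never
#' re-derive them from the noisy table.
#'
#' Seed the RNG before calling for reproducibility.
#'
#' @param arch a [planted_architecture()] object.
#' @return a list of class `synthetic_case`: `table` (a [mutation_table()]
#'   of observed values), `true_ccf` (noise-free matrix) and `truth`
#'   (data.frame: `mut_id`, `clone`, `expected_timing`).
#' @export
generate_case <- function(arch = planted_architecture()) {
  regions <- arch$regions
  nr <- length(regions)
  blocks <- list(list(clone = "truncal", n = arch$n_truncal,
                      ccf = rep(1, nr)))
  if (!is.null(arch$replacing_clone)) {
    rc <- arch$replacing_clone
    blocks[[length(blocks) + 1]] <-
      list(clone = "replacing", n = rc$n,
           ccf = c(rc$pre_ccf, rep(rc$post_ccf, nr - 1)))
  }
  for (i in seq_along(arch$subclones)) {
    sc <- arch$subclones[[i]]
    ccf <- ifelse(regions %in% sc$regions, sc$ccf, 0)
    blocks[[length(blocks) + 1]] <-
      list(clone = paste0("subclone", i), n = sc$n, ccf = ccf)
  }
  true_ccf <- do.call(rbind, lapply(blocks, function(bl)
    matrix(bl$ccf, bl$n, nr, byrow = TRUE)))
  clone <- unlist(lapply(blocks, function(bl) rep(bl$clone, bl$n)))
  colnames(true_ccf) <- regions
  rownames(true_ccf) <- paste0("m", seq_len(nrow(true_ccf)))

  m <- nrow(true_ccf)
  depth <- matrix(stats::rpois(m * nr, rep(arch$depth, each = m)), m, nr,
                  dimnames = dimnames(true_ccf))
  p_alt <- sweep(true_ccf, 2, arch$purity, "*") / 2
  alt <- matrix(stats::rbinom(m * nr, as.vector(depth), as.vector(p_alt)),
                m, nr, dimnames = dimnames(true_ccf))
  vaf <- ifelse(depth > 0, alt / depth, 0)
  obs_ccf <- matrix(0, m, nr, dimnames = dimnames(true_ccf))
  for (j in seq_len(nr))
    obs_ccf[, j] <- ccf_from_vaf(vaf[, j], arch$purity[j])

  timepoints <- c("pre", rep("post", nr - 1))
  tab <- mutation_table(obs_ccf, depth, alt, timepoints = timepoints)

  th <- thresholds()
  expected <- vapply(seq_len(m), function(i) {
    cc <- true_ccf[i, ]
    if (mean(cc) > th$truncal_mean_ccf && all(cc > th$truncal_min_ccf))
      "truncal"
    else if (cc[1] < th$rare_ccf) "post_only"
    else if (cc[1] < th$subclonal_pre_ccf || any(cc[-1] < th$rare_ccf))
      "subclonal"
    else "unclassified"
  }, character(1))
  structure(list(table = tab, true_ccf = true_ccf,
                 truth = data.frame(mut_id = rownames(true_ccf),
                                    clone = clone,
                                    expected_timing = expected,
                                    stringsAsFactors = FALSE)),
            class = "synthetic_case")
}

#' Write a synthetic case to disk
#'
#' The observed table goes to the shared TSV dialect via
#' [write_mutation_table()]; truth labels go to a sidecar TSV so tests never
#' parse them out of the data table.
#'
#' @param case a [generate_case()] result.
#' @param path output TSV path for the mutation table.
#' @param truth_path sidecar TSV path (default: `path` with `.truth.tsv`).
#' @param manifest_path optional region manifest path.
#' @return `path`, invisibly.
#' @export
write_synthetic_case <- function(case, path,
                                 truth_path = sub("\\.tsv$", ".truth.tsv",
                                                  path),
                                 manifest_path = NULL) {
  write_mutation_table(case$table, path, manifest_path)
  data.table::fwrite(case$truth, truth_path, sep = "\t")
  invisible(path)
}
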