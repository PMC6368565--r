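#' Parameters of the spatial deme model
#'
#' Defaults follow the virtual-tumor study conditions: per-cell birth rate
#' 0.55 and death rate 0.45 per generation, 0.6 new exome mutations per cell
#' division (Poisson), a 1-in-1e5 chance that a new mutation is a driver,
#' drivers multiplying the birth rate by `(1 + s)` each, and 50
#' pre-transformation truncal SNVs carried by every tumor cell. `s` is drawn
#' from the study grid {0, 0.05, 0.1, 0.2, 0.4, 0.5} and `deme_size` from
#' {1000, 5000, 10000, 50000}. `target_cells` is scalable: the full-scale
#' condition is 1e9 cells, desk-scale runs use 1e6-1e7.
#'
#' @param s selection coefficient per driver mutation (>= 0).
#' @param deme_size cells per deme (carrying capacity before fission).
#' @param birth,death per-generation birth and death rates (`birth > death`).
#' @param mut_rate expected new exome mutations per cell division.
#' @param driver_prob probability that a new mutation is a driver.
#' @param n_truncal truncal SNVs present in the founding cell.
#' @param target_cells final tumor size in cells.
#' @param sample_cells cells per regional sample; defaults to
#'   `target_cells / 1000`, the scaled analogue of ~1e6-cell samples from a
#'   1e9-cell tumor.
#' @param max_restarts how many founding-lineage extinctions to tolerate.
#' @return a list of class `spatial_params`.
#' @export
spatial_params <- function(s = 0, deme_size = 5000, birth = 0.55,
                           death = 0.45, mut_rate = 0.6,
                           driver_prob = 1e-5, n_truncal = 50,
                           target_cells = 1e6, sample_cells = NULL,
                           max_restarts = 1000) {
  stopifnot(birth > death, s >= 0, deme_size >= 2,
            target_cells >= deme_size, mut_rate > 0)
  if (is.null(sample_cells)) sample_cells <- max(target_cells / 1000, 500)
  structure(list(s = s, deme_size = as.integer(deme_size), birth = birth,
                 death = death, mut_rate = mut_rate,
                 driver_prob = driver_prob, n_truncal = as.integer(n_truncal),
                 target_cells = target_cells, sample_cells = sample_cells,
                 max_restarts = as.integer(max_restarts)),
            class = "spatial_params")
}

#' Grow a virtual tumor
#'
#' Runs the deme-based spatial agent model: demes on a 3D lattice fill to
#' `deme_size` cells through a per-generation birth-death update (drivers
#' multiply the birth rate by `1 + s` each), then fission into an adjacent
#' empty lattice site; demes boxed in at capacity become quiescent, so
#' growth is peripherally dominated. Mutations arise Poisson(`mut_rate`) per
#' division under an infinite-sites model. Growth is conditioned on survival
#' of the founding lineage (extinct runs are restarted and counted).
#'
#' Seed the R RNG (`set.seed`) before calling for reproducibility.
#'
#' @param params a [spatial_params()] object.
#' @return an object of class `virtual_tumor` wrapping the simulation state,
#'   with `$params`, `$summary` (cells, demes, genotypes, mutations,
#'   restarts) and `$demes` (per-deme lattice coordinates, occupancy, octant
#'   and quadrant index relative to the founding deme).
#' @export
grow_tumor <- function(params = spatial_params()) {
  ptr <- cpp_grow_tumor(params$deme_size, params$birth, params$death,
                        params$mut_rate, params$driver_prob, params$s,
                        params$n_truncal, params$target_cells,
                        params$max_restarts)
  demes <- cpp_deme_info(ptr)
  demes$octant <- octant_index(demes$x, demes$y, demes$z)
  demes$quadrant <- quadrant_index(demes$x, demes$y)
  structure(list(ptr = ptr, params = params,
                 summary = cpp_tumor_summary(ptr), demes = demes),
            class = "virtual_tumor")
}

#' @export
print.virtual_tumor <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "virtual_tumor: %.3g cells in %d demes (deme size %d, s = %g)\n",
    s$n_cells, as.integer(s$n_demes), s$deme_size, x$params$s))
  cat(sprintf("  %.3g mutation events, %d founding-lineage restarts\n",
              s$n_mutations, s$restarts))
  invisible(x)
}

octant_index <- function(x, y, z)
  1L + (x >= 0) + 2L * (y >= 0) + 4L * (z >= 0)

quadrant_index <- function(x, y) 1L + (x >= 0) + 2L * (y >= 0)

opposite_octant <- function(o) 9L - o
opposite_quadrant <- function(q) 5L - q

#' Take regional samples from a virtual tumor
#'
#' Each sample is a contiguous neighborhood (focal deme plus nearest
#' occupied demes) of about `sample_cells` cells, honoring a named sampling
#' scheme on the tumor's octant/quadrant index:
#'
#' * `local` - all focal demes from one octant,
#' * `distant` - focal demes from pairwise distinct octants,
#' * `all_octants` - `n_samples` spread across the occupied octants,
#' * `opposite_octant_pre_post` - sample 1 ("pre") from one octant, the
#'   remainder ("post") from the opposite octant,
#' * `opposite_quadrants_post` - sample 1 ("pre") from a random octant, the
#'   remaining samples split evenly between two opposite quadrants.
#'
#' Focal demes are drawn without replacement. Seed the RNG for
#' reproducibility.
#'
#' @param tumor a [grow_tumor()] result.
#' @param scheme sampling scheme name.
#' @param n_samples number of regional samples.
#' @return a list of class `regional_samples`: per sample the focal deme,
#'   octant, and true per-mutation cell fractions (`mut_id`, `fraction`).
#' @export
take_samples <- function(tumor, scheme = c("all_octants", "local", "distant",
                                           "opposite_octant_pre_post",
                                           "opposite_quadrants_post"),
                         n_samples = 2) {
  scheme <- match.arg(scheme)
  d <- tumor$demes
  pick_from <- function(pool, n) {
    if (length(pool) < n) stop("sampling scheme unsatisfiable on this tumor")
    if (length(pool) == 1) pool else sample(pool, n)
  }
  focal <- switch(scheme,
    local = {
      tab <- table(d$octant)
      oct <- as.integer(names(tab)[tab >= n_samples])
      if (length(oct) == 0) stop("no octant holds enough demes")
      o <- if (length(oct) == 1) oct else sample(oct, 1)
      pick_from(d$deme[d$octant == o], n_samples)
    },
    distant = {
      oct <- unique(d$octant)
      if (length(oct) < n_samples)
        stop("fewer occupied octants than requested distant samples")
      os <- sample(oct, n_samples)
      vapply(os, function(o) pick_from(d$deme[d$octant == o], 1), numeric(1))
    },
    all_octants = {
      oct <- unique(d$octant)
      os <- rep(oct, length.out = max(n_samples, length(oct)))[seq_len(n_samples)]
      unlist(lapply(split(seq_along(os), os), function(ii) {
        o <- os[ii[1]]
        pick_from(d$deme[d$octant == o], length(ii))
      }), use.names = FALSE)
    },
    opposite_octant_pre_post = {
      count_in <- function(o) sum(d$octant == o)
      ok <- Filter(function(o) count_in(o) >= 1 &&
                     count_in(opposite_octant(o)) >= n_samples - 1, 1:8)
      if (length(ok) == 0) stop("no opposite-octant pair holds enough demes")
      o <- if (length(ok) == 1) ok else sample(ok, 1)
      c(pick_from(d$deme[d$octant == o], 1),
        pick_from(d$deme[d$octant == opposite_octant(o)], n_samples - 1))
    },
    opposite_quadrants_post = {
      n_post <- n_samples - 1
      half <- ceiling(n_post / 2)
      count_in <- function(q) sum(d$quadrant == q)
      ok <- Filter(function(q) count_in(q) >= half &&
                     count_in(opposite_quadrant(q)) >= n_post - half + 1, 1:4)
      if (length(ok) == 0) stop("no opposite-quadrant pair holds enough demes")
      q <- if (length(ok) == 1) ok else sample(ok, 1)
      pre <- pick_from(d$deme, 1)
      c(pre,
        pick_from(setdiff(d$deme[d$quadrant == q], pre), half),
        pick_from(setdiff(d$deme[d$quadrant == opposite_quadrant(q)], pre),
                  n_post - half))
    })
  samples <- lapply(focal, function(f) {
    s <- cpp_take_sample(tumor$ptr, f, tumor$params$sample_cells)
    s$focal <- f
    s$octant <- d$octant[d$deme == f]
    s
  })
  structure(list(samples = samples, scheme = scheme,
                 sample_cells = tumor$params$sample_cells),
            class = "regional_samples")
}

#' Emulate multi-region sequencing of tumor samples
#'
#' Converts true per-mutation cell fractions into read counts: depth ~
#' Poisson(`mean_depth`), variant reads ~ Binomial(depth, fraction / 2) for
#' heterozygous diploid sites (the simulated genome is diploid and CNA-free,
#' so CCF = 2 x VAF, clipped to `[0, 1.5]`). The mutation-calling filters
#' are then applied across the sample set: drop mutations covered by fewer
#' than `min_depth` reads in any sample or with fewer than `min_alt` variant
#' reads in every sample.
#'
#' @param samples a [take_samples()] result (or list with `$samples`).
#' @param mean_depth mean sequencing depth.
#' @param timepoints optional per-sample timepoint tags (default: first
#'   sample `pre` and the rest `post` for pre/post schemes, otherwise all
#'   `post`).
#' @param thresholds a [thresholds()] object supplying the read filters.
#' @param min_fraction mutations below this true fraction in every sample
#'   are dropped before read emulation (far below the calling limit; keeps
#'   tables small).
#' @return a [mutation_table()] of emulated CCFs, depths and variant reads.
#' @export
emulate_sequencing <- function(samples, mean_depth = 100, timepoints = NULL,
                               thresholds = clonalshift::thresholds(),
                               min_fraction = 0.005) {
  sl <- samples$samples
  n <- length(sl)
  # union of mutations at reportable frequency in at least one sample;
  # fractions of retained mutations are then gathered from every sample
  ids <- sort(unique(unlist(lapply(sl, function(s)
    s$mut_id[s$fraction >= min_fraction]))))
  frac <- matrix(0, length(ids), n,
                 dimnames = list(paste0("m", ids),
                                 paste0("S", seq_len(n))))
  for (j in seq_len(n)) {
    hit <- match(sl[[j]]$mut_id, ids)
    ok <- !is.na(hit)
    frac[hit[ok], j] <- sl[[j]]$fraction[ok]
  }
  m <- nrow(frac)
  depth <- matrix(stats::rpois(m * n, mean_depth), m, n,
                  dimnames = dimnames(frac))
  alt <- matrix(stats::rbinom(m * n, as.vector(depth),
                              pmin(as.vector(frac) / 2, 1)), m, n,
                dimnames = dimnames(frac))
  ccf <- pmin(2 * alt / pmax(depth, 1), 1.5)
  ccf[depth == 0] <- 0
  if (is.null(timepoints)) {
    timepoints <- if (!is.null(samples$scheme) &&
                      samples$scheme %in% c("opposite_octant_pre_post",
                                            "opposite_quadrants_post"))
      c("pre", rep("post", n - 1)) else rep("post", n)
  }
  tab <- mutation_table(ccf, depth, alt, timepoints = timepoints)
  apply_read_filters(tab, thresholds)
}

#' Simulate a cohort of virtual tumors with summary statistics
#'
#' For each parameter combination in the grid, grows `n_tumors` virtual
#' tumors, takes 20 regional samples across all octants (plus a local and a
#' distant pair), emulates sequencing, and records the summary statistics
#' used downstream: mean pairwise HFR under local and distant sampling,
#' case Fst over the sample panel, reclassification fractions for selected
#' numbers of additional regions, the fraction of mutations subclonal in at
#' least one region, and the mean pairwise Kolmogorov-Smirnov distance
#' between region CCF distributions.
#'
#' @param s_grid,deme_grid parameter grids; tumors are simulated for every
#'   combination.
#' @param n_tumors tumors per grid point.
#' @param params_base baseline [spatial_params()] supplying all other
#'   parameters (including `target_cells`).
#' @param n_region_samples regional samples per tumor for the panel.
#' @param k_reclass values of "additional regions" for reclassification.
#' @param mean_depth sequencing depth.
#' @param thresholds a [thresholds()] object.
#' @param keep_tables return the emulated panel tables (needed to build
#'   tHFR nulls) in attribute `tables`.
#' @param progress print one line per tumor.
#' @return data.frame, one row per tumor: parameters, `hfr_local`,
#'   `hfr_distant`, `fst`, `mean_hfr_panel`, `f_subclonal`, `ksd`, and
#'   `reclass_k<k>` columns. When `keep_tables = TRUE` the emulated panel
#'   [mutation_table()]s (with octant annotations) are attached as
#'   `attr(, "tables")`.
#' @export
simulate_cohort <- function(s_grid = c(0.05, 0.1, 0.2, 0.4, 0.5),
                            deme_grid = c(1000, 5000, 10000),
                            n_tumors = 10,
                            params_base = spatial_params(),
                            n_region_samples = 20,
                            k_reclass = c(1, 2, 19),
                            mean_depth = 100,
                            thresholds = clonalshift::thresholds(),
                            keep_tables = FALSE,
                            progress = FALSE) {
  grid <- expand.grid(s = s_grid, deme_size = deme_grid)
  rows <- list()
  tables <- list()
  ti <- 0
  for (gi in seq_len(nrow(grid))) {
    for (rep in seq_len(n_tumors)) {
      ti <- ti + 1
      p <- params_base
      p$s <- grid$s[gi]
      p$deme_size <- as.integer(grid$deme_size[gi])
      tum <- grow_tumor(p)
      panel <- take_samples(tum, "all_octants", n_region_samples)
      tab <- emulate_sequencing(panel, mean_depth, thresholds = thresholds)
      octs <- vapply(panel$samples, `[[`, numeric(1), "octant")
      attr(tab, "octant") <- octs
      loc <- emulate_sequencing(take_samples(tum, "local", 2), mean_depth,
                                thresholds = thresholds)
      dis <- emulate_sequencing(take_samples(tum, "distant", 2), mean_depth,
                                thresholds = thresholds)
      rg <- region_names(tab)
      reclass <- vapply(k_reclass, function(k) {
        v <- reclassification_fraction(tab, rg[1], k, thresholds,
                                       n_draws = 30)
        if (is.na(v)) 0 else v
      }, numeric(1))
      row <- data.frame(
        tumor = ti, s = p$s, deme_size = p$deme_size,
        n_cells = tum$summary$n_cells,
        hfr_local = pairwise_hfr(loc, "S1", "S2", thresholds)$hfr,
        hfr_distant = pairwise_hfr(dis, "S1", "S2", thresholds)$hfr,
        fst = case_fst(tab, thresholds),
        mean_hfr_panel = mean_pairwise_hfr(tab, thresholds),
        f_subclonal = fraction_subclonal(tab, thresholds),
        ksd = mean_pairwise_ksd(tab))
      for (i in seq_along(k_reclass))
        row[[paste0("reclass_k", k_reclass[i])]] <- reclass[i]
      rows[[ti]] <- row
      if (keep_tables) tables[[ti]] <- tab
      if (progress)
        message(sprintf("tumor %d: s=%g deme=%d hfr_d=%.3f", ti, p$s,
                        p$deme_size, row$hfr_distant))
    }
  }
  out <- do.call(rbind, rows)
  if (keep_tables) attr(out, "tables") <- tables
  out
}

#' Fraction of mutations subclonal in at least one region
#'
#' A pragmatic reconstruction of the "fraction heterogeneous/subclonal"
#' summary statistic: among mutations present (CCF > `rare_ccf`) somewhere,
#' the fraction with CCF below `subclonal_ccf` in at least one region.
#'
#' @param table a [mutation_table()].
#' @param thresholds a [thresholds()] object.
#' @return fraction in `[0, 1]`.
#' @export
fraction_subclonal <- function(table, thresholds = clonalshift::thresholds()) {
  present <- apply(table$ccf > thresholds$rare_ccf, 1, any)
  if (!any(present)) return(0)
  sub <- apply(table$ccf[present, , drop = FALSE] <
                 thresholds$subclonal_ccf, 1, any)
  mean(sub)
}

#' Mean pairwise Kolmogorov-Smirnov distance between region CCF profiles
#'
#' A reconstruction of the "KSD" summary statistic: the two-sample KS
#' statistic between the CCF distributions of each region pair, averaged
#' over pairs.
#'
#' @param table a [mutation_table()].
#' @return mean KS distance in `[0, 1]`.
#' @export
mean_pairwise_ksd <- function(table) {
  rg <- region_names(table)
  if (length(rg) < 2) stop("need at least two regions")
  prs <- utils::combn(rg, 2)
  mean(apply(prs, 2, function(p)
    suppressWarnings(stats::ks.test(table$ccf[, p[1]],
                                    table$ccf[, p[2]])$statistic)))
}
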