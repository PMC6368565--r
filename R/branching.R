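#' Parameters of the multi-type branching treatment model
#'
#' Continuous-time birth-death model of tumor growth to detection followed
#' by a fixed course of therapy. All cells divide at rate `b` per day and
#' die at rate `d` (net growth 2%/day at the defaults). Resistance-conferring
#' aberrations arise at effective rate `mu` per cell division; each event
#' founds a distinct resistant clone (infinite-allele labeling). Growth
#' stops at `detect_size` cells; during the `treat_days` of therapy no new
#' aberrations arise, sensitive cells die at the elevated rate `d_prime`
#' (`d_prime > b`, so the sensitive compartment declines) and resistant
#' cells keep their pre-treatment rates.
#'
#' @param b division rate per day.
#' @param d baseline death rate per day.
#' @param d_prime sensitive-cell death rate under treatment (one of 0.16,
#'   0.2, 0.25 in the study conditions).
#' @param mu effective resistance aberration rate per cell division,
#'   `[0, 1]`; the study explores 1e-10 to 1e-2.
#' @param detect_size tumor size triggering treatment (cells).
#' @param treat_days treatment duration in days.
#' @param stoch_threshold population size below which dynamics are simulated
#'   stochastically (exact birth-death transition law) and above which
#'   deterministically.
#' @param max_clones number of earliest-founded resistant clones tracked
#'   individually; later (hence smaller) clones are aggregated by their
#'   exact expectation.
#' @return a list of class `branching_params`.
#' @export
branching_params <- function(b = 0.15, d = 0.13, d_prime = 0.2, mu = 1e-6,
                             detect_size = 1e10, treat_days = 150,
                             stoch_threshold = 1e3, max_clones = 200) {
  stopifnot(b > d, d_prime > b, mu >= 0, mu <= 1, detect_size > 0,
            treat_days > 0)
  structure(list(b = b, d = d, d_prime = d_prime, mu = mu,
                 detect_size = detect_size, treat_days = treat_days,
                 stoch_threshold = stoch_threshold, max_clones = max_clones),
            class = "branching_params")
}

# Exact transition law of a linear birth-death process: population after
# time t starting from n cells, rates (b, d). Survivor lineages are
# binomial, each surviving lineage geometric; their sum is negative
# binomial. Valid for b != d.
#' Sample the exact birth-death transition
#'
#' Draws the population size after time `t` of a linear birth-death process
#' with per-capita birth rate `b` and death rate `d`, starting from `n`
#' cells (vectorized over `n`).
#'
#' @param n starting population size(s).
#' @param b,d per-capita birth and death rates per day.
#' @param t elapsed time in days.
#' @return integer-valued numeric vector of population sizes.
#' @export
bd_transition <- function(n, b, d, t) {
  if (t == 0) return(n)
  r <- b - d
  e <- exp(r * t)
  alpha <- d * (e - 1) / (b * e - d)   # P(single lineage extinct)
  beta <- b * alpha / d                # geometric parameter of survivors
  out <- numeric(length(n))
  big <- n > 2^30
  if (any(big)) {
    # deterministic regime: relative fluctuations are O(1/sqrt(n))
    out[big] <- round(n[big] * e)
  }
  if (any(!big)) {
    nn <- n[!big]
    k <- stats::rbinom(length(nn), nn, 1 - alpha)
    extra <- numeric(length(nn))
    pos <- k > 0
    if (any(pos))
      extra[pos] <- stats::rnbinom(sum(pos), k[pos], 1 - beta)
    out[!big] <- k + extra
  }
  out
}

# P(a single cell's lineage is alive after time t)
bd_alive_prob <- function(b, d, t) {
  r <- b - d
  e <- exp(r * t)
  1 - d * (e - 1) / (b * e - d)
}

# size of a single-cell lineage after time t conditioned on being alive:
# geometric on {1, 2, ...}
bd_size_given_alive <- function(m, b, d, t) {
  r <- b - d
  e <- exp(r * t)
  alpha <- d * (e - 1) / (b * e - d)
  beta <- b * alpha / d
  1 + stats::rnbinom(m, 1, 1 - beta)
}

#' Simulate one growth-and-treatment run
#'
#' Hybrid simulation of the branching model: the sensitive bulk is simulated
#' by exact birth-death transitions while below `stoch_threshold` cells
#' (conditioning on non-extinction of the founding lineage; extinct attempts
#' are resampled and counted) and deterministically above it. Resistant
#' clones alive at detection are generated by thinning the founding Poisson
#' process (intensity `mu * b * N(t)`) with the exact probability that a
#' clone founded at time `t` survives to detection, and their detection
#' sizes drawn from the exact conditioned birth-death law. The earliest
#' `max_clones` clones are tracked individually; the remaining (later,
#' smaller) clones enter as an aggregated compartment equal to their exact
#' expectation. Treatment updates every compartment by the exact transition
#' law (deterministically above 2^30 cells).
#'
#' @param params a [branching_params()] object.
#' @return a list of class `branching_run`: `pre_sensitive`,
#'   `clone_sizes_detect` (individually tracked clones, birth-ordered),
#'   `aggregate_detect`, post-treatment `sensitive`, `clones`
#'   (post-treatment sizes), `aggregate`, `residual`, `n_clones_detect`,
#'   and `extinct_attempts`.
#' @export
simulate_run <- function(params = branching_params()) {
  b <- params$b; d <- params$d; r <- b - d
  N <- params$detect_size
  thr <- params$stoch_threshold

  # stochastic early phase, conditioned on reaching the threshold; the
  # trajectory is recorded so clone founding during this phase is included
  extinct <- 0
  dt_step <- 5
  repeat {
    n <- 1
    t0 <- 0
    path_t <- numeric(0)
    path_n <- numeric(0)
    while (n > 0 && n < thr) {
      path_t <- c(path_t, t0)
      path_n <- c(path_n, n)
      n <- bd_transition(n, b, d, dt_step)
      t0 <- t0 + dt_step
    }
    if (n > 0) break
    extinct <- extinct + 1
  }
  t_thr <- t0
  T_total <- t_thr + log(N / n) / r

  # resistant clones alive at detection, founded while N(t) = N e^{-r tau}
  # (tau = time before detection); founding intensity mu * b * N(t), thinned
  # by the alive-at-detection probability. The sub-threshold era uses the
  # recorded stochastic trajectory instead of the deterministic bulk.
  taus_early <- numeric(0)
  if (length(path_t) && params$mu > 0) {
    tau_mid <- T_total - (path_t + dt_step / 2)
    lam_k <- params$mu * b * path_n * dt_step * bd_alive_prob(b, d, tau_mid)
    K_early <- stats::rpois(1, sum(lam_k))
    if (K_early > 0) {
      step <- sample.int(length(lam_k), K_early, replace = TRUE,
                         prob = lam_k)
      taus_early <- T_total - (path_t[step] + stats::runif(K_early) * dt_step)
      taus_early <- sort(taus_early, decreasing = TRUE)
    }
  }
  tau_max <- log(N / n) / r
  ngrid <- 400
  tau <- seq(0, tau_max, length.out = ngrid)
  lam <- params$mu * b * N * exp(-r * tau) * bd_alive_prob(b, d, tau)
  cum <- c(0, cumsum((lam[-1] + lam[-ngrid]) / 2 * diff(tau)))
  Lambda <- cum[ngrid]
  K_main <- stats::rpois(1, Lambda)
  M <- min(K_main, params$max_clones)
  # The founding process is a Poisson process in the cumulative-intensity
  # coordinate, where arrivals are uniform on [0, Lambda]. Small cumulative
  # coordinates correspond to clones founded last (the intensity is written
  # backward in time), so the earliest-born — hence largest — clones are the
  # M LARGEST order statistics, obtained by sequential beta gaps.
  taus_main <- numeric(0)
  if (K_main > 0) {
    # sequential beta gaps: the i-th largest of the remaining uniforms
    ord <- Lambda * cumprod(stats::rbeta(M, K_main - seq_len(M) + 1, 1))
    taus_main <- stats::approx(cum, tau, xout = ord, rule = 2)$y
  }
  taus <- c(taus_early, taus_main)  # early-phase clones were born earlier
  clone_sizes <- if (length(taus))
    bd_size_given_alive(length(taus), b, d, taus) else numeric(0)
  # aggregate of untracked clones: those with the K_main - M smallest
  # cumulative coordinates, i.e. founded after the last tracked clone. Their
  # exact expected total at detection is the intensity-weighted conditioned
  # mean e^{r tau} / alive_prob, integrated over the region.
  aggregate <- 0
  if (K_main > M) {
    tau_cut <- taus_main[length(taus_main)] # latest tracked founding
    mean_alive <- exp(r * tau) / bd_alive_prob(b, d, tau)
    num <- c(0, cumsum((lam[-1] * mean_alive[-1] +
                          lam[-ngrid] * mean_alive[-ngrid]) / 2 * diff(tau)))
    Lambda_cut <- stats::approx(tau, cum, xout = tau_cut, rule = 2)$y
    Enum_cut <- stats::approx(tau, num, xout = tau_cut, rule = 2)$y
    # (K_main - M) untracked clones uniformly distributed below Lambda_cut
    aggregate <- (K_main - M) * Enum_cut / max(Lambda_cut,
                                               .Machine$double.eps)
  }
  K <- K_main + length(taus_early)

  total_res <- sum(clone_sizes) + aggregate
  pre_sensitive <- max(N - total_res, 0)

  # treatment
  sens_post <- treat_compartment(pre_sensitive, b, params$d_prime,
                                 params$treat_days, thr)
  clones_post <- if (length(clone_sizes))
    bd_transition(clone_sizes, b, d, params$treat_days) else numeric(0)
  aggregate_post <- aggregate * exp(r * params$treat_days)

  structure(list(
    pre_sensitive = pre_sensitive,
    clone_sizes_detect = clone_sizes,
    aggregate_detect = aggregate,
    sensitive = sens_post,
    clones = clones_post,
    aggregate = aggregate_post,
    residual = sens_post + sum(clones_post) + aggregate_post,
    n_clones_detect = K,
    extinct_attempts = extinct), class = "branching_run")
}

# declining compartment under treatment: deterministic while large, exact
# stochastic transition once the expected trajectory drops below threshold
treat_compartment <- function(n0, b, d_prime, days, thr) {
  if (n0 <= 0) return(0)
  r <- b - d_prime  # negative
  n_end_det <- n0 * exp(r * days)
  if (n0 <= thr) return(bd_transition(round(n0), b, d_prime, days))
  # deterministic compartments stay continuous: relative fluctuations (and
  # rounding) are negligible above the stochastic threshold
  if (n_end_det >= thr) return(n_end_det)
  t_cross <- log(thr / n0) / r
  bd_transition(round(thr), b, d_prime, days - t_cross)
}

#' Classify a treatment outcome
#'
#' Four mutually exclusive outcomes, in order: `pCR` when the residual tumor
#' has fewer than `pcr_cells` cells; otherwise `sensitive_residual` when
#' sensitive cells make up at least `dominance` of the residual;
#' `clonal_replacement` when a single resistant clone does; else
#' `polyclonal_resistance`.
#'
#' @param run a [simulate_run()] result.
#' @param pcr_cells residual size below which the outcome is pCR.
#' @param dominance fraction defining compartment dominance.
#' @return one of `"pCR"`, `"sensitive_residual"`, `"clonal_replacement"`,
#'   `"polyclonal_resistance"`.
#' @export
classify_outcome <- function(run, pcr_cells = 1e4, dominance = 0.8) {
  if (run$residual < pcr_cells) return("pCR")
  if (run$sensitive / run$residual >= dominance) return("sensitive_residual")
  mx <- if (length(run$clones)) max(run$clones) else 0
  if (mx / run$residual >= dominance) return("clonal_replacement")
  "polyclonal_resistance"
}

#' Outcome proportions across a parameter grid
#'
#' Monte-Carlo outcome frequencies of the branching treatment model for
#' every combination of sensitive death rate and resistance aberration
#' rate, with binomial standard errors.
#'
#' @param d_prime_grid sensitive death rates under treatment.
#' @param mu_grid effective resistance aberration rates.
#' @param n_sims runs per grid point.
#' @param params_base baseline [branching_params()].
#' @param shrink_range optionally record the fraction of runs whose residual
#'   falls inside this range of the pre-treatment size (used by
#'   [infer_mu_interval()]).
#' @return data.frame: one row per (d_prime, mu) with outcome proportions
#'   `p_pcr`, `p_sensitive`, `p_clonal`, `p_polyclonal`, their common
#'   binomial standard error scale `se` (computed at p = 0.5), and
#'   `p_clonal_shrink` when `shrink_range` is given.
#' @export
outcome_frequencies <- function(d_prime_grid = c(0.16, 0.2, 0.25),
                                mu_grid = 10^seq(-10, -2, by = 1),
                                n_sims = 1000,
                                params_base = branching_params(),
                                shrink_range = NULL) {
  rows <- list()
  for (dp in d_prime_grid) for (mu in mu_grid) {
    p <- params_base; p$d_prime <- dp; p$mu <- mu
    oc <- character(n_sims)
    qual <- logical(n_sims)
    for (i in seq_len(n_sims)) {
      run <- simulate_run(p)
      oc[i] <- classify_outcome(run)
      if (!is.null(shrink_range)) {
        shr <- run$residual / p$detect_size
        qual[i] <- oc[i] == "clonal_replacement" &&
          shr >= shrink_range[1] && shr <= shrink_range[2]
      }
    }
    row <- data.frame(
      d_prime = dp, mu = mu, n_sims = n_sims,
      p_pcr = mean(oc == "pCR"),
      p_sensitive = mean(oc == "sensitive_residual"),
      p_clonal = mean(oc == "clonal_replacement"),
      p_polyclonal = mean(oc == "polyclonal_resistance"),
      se = sqrt(0.25 / n_sims))
    if (!is.null(shrink_range)) row$p_clonal_shrink <- mean(qual)
    rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, rows)
}

#' Infer the effective resistance aberration rate interval
#'
#' Draws `mu` from a log-uniform prior grid, simulates the branching model,
#' keeps the runs matching the observed pattern (outcome filter plus
#' shrinkage of the tumor to within `shrink_range` of its pre-treatment
#' size), and reports the 5th-95th percentile of the qualifying `mu` values.
#' Results are reported per sensitive death rate and pooled.
#'
#' @param d_prime_grid sensitive death rates to scan (pooled in the headline
#'   interval).
#' @param shrink_range residual/pre-treatment size window, default 10-50%.
#' @param outcome_filter outcome required of qualifying runs.
#' @param mu_range prior range for `mu` (log-uniform).
#' @param n_grid number of log-spaced prior grid points.
#' @param n_per_point simulated runs per grid point and death rate.
#' @param params_base baseline [branching_params()].
#' @param probs interval probabilities.
#' @return a list with `pooled` (named interval vector, `NA` when no run
#'   qualifies), `per_d_prime` (data.frame), `n_qualifying`, and the
#'   qualifying `mu` draws in `mu_values`.
#' @export
infer_mu_interval <- function(d_prime_grid = c(0.16, 0.2, 0.25),
                              shrink_range = c(0.10, 0.50),
                              outcome_filter = "clonal_replacement",
                              mu_range = c(1e-10, 1e-2), n_grid = 60,
                              n_per_point = 50,
                              params_base = branching_params(),
                              probs = c(0.05, 0.95)) {
  mu_grid <- 10^seq(log10(mu_range[1]), log10(mu_range[2]),
                    length.out = n_grid)
  qual_mu <- list()
  for (dp in d_prime_grid) {
    vals <- numeric(0)
    for (mu in mu_grid) {
      p <- params_base; p$d_prime <- dp; p$mu <- mu
      for (i in seq_len(n_per_point)) {
        run <- simulate_run(p)
        ok <- if (identical(outcome_filter, "none")) TRUE else
          classify_outcome(run) == outcome_filter
        shr <- run$residual / p$detect_size
        if (ok && shr >= shrink_range[1] && shr <= shrink_range[2])
          vals <- c(vals, mu)
      }
    }
    qual_mu[[as.character(dp)]] <- vals
  }
  pooled_vals <- unlist(qual_mu, use.names = FALSE)
  per <- data.frame(
    d_prime = d_prime_grid,
    n_qualifying = vapply(qual_mu, length, integer(1)),
    mu_low = vapply(qual_mu, function(v)
      if (length(v)) stats::quantile(v, probs[1]) else NA_real_, numeric(1)),
    mu_high = vapply(qual_mu, function(v)
      if (length(v)) stats::quantile(v, probs[2]) else NA_real_, numeric(1)))
  pooled <- if (length(pooled_vals))
    stats::quantile(pooled_vals, probs) else c(NA_real_, NA_real_)
  names(pooled) <- paste0("q", probs * 100)
  list(pooled = pooled, per_d_prime = per,
       n_qualifying = length(pooled_vals), mu_values = pooled_vals)
}
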