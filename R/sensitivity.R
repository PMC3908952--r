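#' The seven standard caller configurations
#'
#' The configuration set compared in the sensitivity experiment:
#' \itemize{
#'   \item `default`: full Wright-Fisher prior, theta = 0.001, p = 0.5;
#'   \item `flat`, `cond2`: alternative initial AFS, same theta and p;
#'   \item `theta0.01`, `theta0.1`: full prior with elevated mutation rate;
#'   \item `p0.75`, `p1.0`: full prior with relaxed calling threshold.
#' }
#' All use the correlated error model with the package's calibrated decay
#' (`eta = 0.89`).
#'
#' @param model An [error_model()] shared by every configuration.
#' @return Named list of [caller_config()]s.
#' @export
standard_configs <- function(model = error_model()) {
  cfg <- function(prior, p, id)
    caller_config(prior, threshold = p, model = model, id = id)
  list(
    default    = cfg(afs_prior("full", 2, 0.001), 0.5, "default"),
    flat       = cfg(afs_prior("flat", 2, 0.001), 0.5, "flat"),
    cond2      = cfg(afs_prior("cond2", 2, 0.001), 0.5, "cond2"),
    theta0.01  = cfg(afs_prior("full", 2, 0.01), 0.5, "theta0.01"),
    theta0.1   = cfg(afs_prior("full", 2, 0.1), 0.5, "theta0.1"),
    p0.75      = cfg(afs_prior("full", 2, 0.001), 0.75, "p0.75"),
    p1.0       = cfg(afs_prior("full", 2, 0.001), 1.0, "p1.0")
  )
}

#' Minimum detectable mutant fraction at one depth
#'
#' Scans alternate-read counts 1..floor(depth/2) in ascending order over
#' the simulated pileups and returns the first count at which the caller
#' declares the site variant, together with the QUAL at that count.
#'
#' @param depth Total read depth.
#' @param config A [caller_config()] (M = 2).
#' @param spec A [simulation_spec()].
#' @return One-row data.frame: `config_id, depth, min_alt_count,
#'   min_alt_pct, qual_at_min` (count and derived columns `NA` when no
#'   count up to 50% is called).
#' @export
min_detectable <- function(depth, config = caller_config(),
                           spec = simulation_spec()) {
  stopifnot(depth >= 1)
  for (na in seq_len(depth %/% 2L)) {
    site <- simulate_site_pileup(depth, na, spec)
    gl <- genotype_log_likelihoods(site, spec$alt_allele, config$model)
    res <- call_single(gl, config)
    if (res$called)
      return(data.frame(config_id = config$id, depth = depth,
                        min_alt_count = na,
                        min_alt_pct = 100 * na / depth,
                        qual_at_min = res$qual,
                        stringsAsFactors = FALSE))
  }
  data.frame(config_id = config$id, depth = depth,
             min_alt_count = NA_integer_, min_alt_pct = NA_real_,
             qual_at_min = NA_real_, stringsAsFactors = FALSE)
}

#' Sensitivity sweep over depths and caller configurations
#'
#' Runs [min_detectable()] for every (configuration, depth) pair and
#' summarizes each configuration by the mean/min/max of its minimum
#' detectable mutant-allele percentage and of the QUAL at the minimum,
#' over the depths where a detection at <= 50% exists.
#'
#' @param configs Named list of [caller_config()]s; default
#'   [standard_configs()].
#' @param depths Integer depths; default every integer 4..100.
#' @param spec A [simulation_spec()].
#' @return List with `points` (one row per config x depth) and `summary`
#'   (one row per config: `config_id, n_depths, mean_pct, min_pct,
#'   max_pct, mean_qual, min_qual, max_qual`).
#' @export
sweep_sensitivity <- function(configs = standard_configs(),
                              depths = 4:100, spec = simulation_spec()) {
  stopifnot(length(configs) >= 1)
  points <- do.call(rbind, lapply(configs, function(cfg)
    do.call(rbind, lapply(depths, min_detectable, config = cfg,
                          spec = spec))))
  rownames(points) <- NULL
  summary <- do.call(rbind, lapply(split(points, points$config_id), function(g) {
    g <- g[!is.na(g$min_alt_pct), , drop = FALSE]
    data.frame(config_id = g$config_id[1], n_depths = nrow(g),
               mean_pct = mean(g$min_alt_pct), min_pct = min(g$min_alt_pct),
               max_pct = max(g$min_alt_pct), mean_qual = mean(g$qual_at_min),
               min_qual = min(g$qual_at_min), max_qual = max(g$qual_at_min),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(points = points, summary = summary)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired per-depth values, the comparison
#' used between caller configurations.  Zero differences are dropped
#' (Wilcoxon convention) and ties are mid-ranked; the exact null
#' distribution is used for n <= 25 tie-free differences, otherwise the
#' normal approximation with continuity correction.
#'
#' @param x,y Equal-length numeric vectors of paired values.
#' @return Two-sided p-value (1 when all differences are zero).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) return(1)
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  res <- suppressWarnings(stats::wilcox.test(d, alternative = "two.sided",
                                             mu = 0, exact = exact,
                                             correct = TRUE))
  min(1, res$p.value)
}

#' Joint-calling experiment on simulated samples
#'
#' Builds one simulated pileup per sample from `(depth, n_alt)` pairs,
#' computes per-sample genotype likelihoods, and calls the site jointly
#' with [call_multi()] under a prior with M = 2 x samples.
#'
#' @param sample_specs List of `c(depth, n_alt)` pairs, one per sample.
#' @param prior_model AFS model for the joint prior; default "full".
#' @param theta Scaled mutation rate of the joint prior.
#' @param threshold Calling threshold.
#' @param model An [error_model()].
#' @param spec A [simulation_spec()].
#' @return List: `called` (logical), `qual`, `p_ref`, per-sample
#'   `genotypes` and `gq`, and the underlying `result` ([call_multi()]
#'   output).
#' @export
multi_sample_experiment <- function(sample_specs, prior_model = "full",
                                    theta = 0.001, threshold = 0.5,
                                    model = error_model(),
                                    spec = simulation_spec()) {
  n <- length(sample_specs)
  stopifnot(n >= 2)
  gls <- lapply(seq_len(n), function(i) {
    ds <- sample_specs[[i]]
    site <- simulate_site_pileup(ds[1], ds[2], spec,
                                 sample_id = paste0("sim", i))
    genotype_log_likelihoods(site, spec$alt_allele, model)
  })
  cfg <- caller_config(afs_prior(prior_model, 2L * n, theta),
                       threshold = threshold, model = model,
                       id = paste0("multi_", prior_model))
  res <- call_multi(gls, cfg)
  list(called = res$called, qual = res$qual, p_ref = res$p_ref,
       genotypes = res$sample_genotypes, gq = res$sample_gq, result = res)
}
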