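#' Allele frequency spectrum priors
#'
#' Constructs the prior probability vector `phi = (phi_0, ..., phi_M)`
#' over the number k of alternate alleles among M sampled chromosomes,
#' the `F` in the calling posterior `P(ref | D, F)`.
#'
#' Three spectra are available:
#' \describe{
#'   \item{`full`}{the neutral Wright-Fisher spectrum,
#'     `phi_k = theta / k` for k = 1..M and
#'     `phi_0 = 1 - theta * H_M` with `H_M` the M-th harmonic number.
#'     This is the default spectrum of a standard exome pipeline and
#'     places almost all mass on the non-variant state.}
#'   \item{`cond2`}{the spectrum induced by the allele-frequency density
#'     `2 (1 - f)` (the Wright-Fisher spectrum conditioned on observing
#'     the allele in a two-chromosome sample):
#'     `phi_k = 2 (M + 1 - k) / ((M + 1)(M + 2))`.
#'     At M = 2 this is (1/2, 1/3, 1/6).}
#'   \item{`flat`}{the uniform spectrum `phi_k = 1 / (M + 1)`, the
#'     least-informative initial AFS; it maximizes sensitivity to
#'     low-level mosaic variants because it does not penalize the
#'     variant states a priori.}
#' }
#'
#' @param model One of `"full"`, `"cond2"`, `"flat"`.
#' @param M Number of chromosomes (2 x number of diploid samples), even.
#' @param theta Scaled mutation rate (used by the `full` model only);
#'   default 0.001.
#' @return Object of class `afs_prior` with fields `model`, `M`, `theta`
#'   and `phi` (length M + 1, summing to 1).
#' @examples
#' afs_prior("full", 2)$phi    # 0.9985 0.0010 0.0005
#' afs_prior("flat", 2)$phi    # 1/3 1/3 1/3
#' afs_prior("cond2", 2)$phi   # 1/2 1/3 1/6
#' @export
afs_prior <- function(model = c("full", "cond2", "flat"), M = 2,
                      theta = 0.001) {
  model <- match.arg(model)
  M <- as.integer(M)
  if (M < 2L || M %% 2L != 0L) stop("M must be an even integer >= 2")
  if (theta <= 0) stop("theta must be positive")
  k <- 0:M
  phi <- switch(model,
    full = {
      h <- sum(1 / (1:M))
      if (theta * h >= 1)
        stop("theta too large for the full model: phi_0 would be negative ",
             "(need theta < 1/H_M = ", format(1 / h), ")")
      c(1 - theta * h, theta / (1:M))
    },
    cond2 = 2 * (M + 1 - k) / ((M + 1) * (M + 2)),
    flat = rep(1 / (M + 1), M + 1L)
  )
  new_afs_prior(model, M, theta, phi)
}

new_afs_prior <- function(model, M, theta, phi, iterations = 0L,
                          converged = TRUE) {
  stopifnot(length(phi) == M + 1L, all(phi >= 0),
            abs(sum(phi) - 1) < 1e-12)
  structure(list(model = model, M = M, theta = theta, phi = phi,
                 iterations = iterations, converged = converged),
            class = "afs_prior")
}

#' @export
print.afs_prior <- function(x, ...) {
  cat(sprintf("afs_prior '%s'  M=%d theta=%g\n", x$model, x$M, x$theta))
  cat("  phi:", paste(signif(x$phi, 4), collapse = " "), "\n")
  if (x$iterations > 0L)
    cat(sprintf("  EM-refined: %d iteration(s)%s\n", x$iterations,
                if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Refine an AFS prior by expectation-maximization
#'
#' Iterates `phi_k <- mean over sites of P(k | D_s, phi)` until the
#' largest per-component change drops below `tol` or `max_iter` is
#' reached.  Each iteration is a full EM step for the mixture-over-k
#' model, so the observed-data log-likelihood
#' `sum_s log sum_k phi_k P(D_s | k)` is non-decreasing.  Starting the
#' iteration from a flat spectrum versus the full spectrum can reach
#' different fixed points; the initial AFS therefore matters for the
#' final calls.
#'
#' @param initial An [afs_prior()]; its `M` fixes the number of samples
#'   per site (M/2).
#' @param gl_by_site List of sites; each site is either a single
#'   [genotype_likelihoods()] (single-sample, M = 2) or a list of
#'   per-sample `genotype_likelihoods` (joint, M = 2 x samples).
#' @param tol Convergence tolerance on `max |delta phi|`; default 1e-6.
#' @param max_iter Iteration cap; default 100.  Non-convergence returns
#'   the last iterate with `converged = FALSE` and a warning.
#' @return A refined `afs_prior` (model tag preserved) with fields
#'   `iterations` and `converged`.
#' @export
em_refine <- function(initial, gl_by_site, tol = 1e-6, max_iter = 100) {
  if (!length(gl_by_site)) stop("em_refine needs at least one site")
  # per-site log10 P(D_s | k), rows = sites
  lik <- t(vapply(gl_by_site, function(site) {
    if (inherits(site, "genotype_likelihoods")) site <- list(site)
    joint_log10_lik_by_count(site)
  }, numeric(initial$M + 1L)))
  phi <- initial$phi
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    lw <- sweep(lik, 2, log10(phi + .Machine$double.xmin), "+")
    post <- t(apply(lw, 1, function(w) {
      w <- w - max(w); p <- 10^w; p / sum(p)
    }))
    phi_new <- colMeans(post)
    delta <- max(abs(phi_new - phi))
    phi <- phi_new / sum(phi_new)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge within ", max_iter, " iterations ",
            "(last max |delta phi| above ", format(tol), ")")
  new_afs_prior(initial$model, initial$M, initial$theta, phi,
                iterations = it, converged = converged)
}

#' Observed-data log-likelihood of an AFS
#'
#' `sum_s log10 sum_k phi_k P(D_s | k)`, the quantity each
#' [em_refine()] iteration is guaranteed not to decrease.
#'
#' @inheritParams em_refine
#' @param prior An [afs_prior()].
#' @return Scalar log10 likelihood.
#' @export
afs_log_likelihood <- function(prior, gl_by_site) {
  sum(vapply(gl_by_site, function(site) {
    if (inherits(site, "genotype_likelihoods")) site <- list(site)
    lk <- joint_log10_lik_by_count(site)
    log10_sum_exp(log10(prior$phi + .Machine$double.xmin) + lk)
  }, numeric(1)))
}
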