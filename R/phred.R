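#' Phred scale conversions
#'
#' Utilities for converting between Phred-scaled qualities, error
#' probabilities and percent accuracies.  A Phred score q corresponds to an
#' error probability of 10^(-q/10), so Phred 10 is 90% accuracy and
#' Phred 30 is 99.9%.
#'
#' @param q Numeric vector of Phred-scaled values, all >= 0.
#' @return `phred_to_accuracy` returns the percent accuracy
#'   `100 * (1 - 10^(-q/10))`; `phred_to_prob` the error probability
#'   `10^(-q/10)`; `prob_to_phred` the Phred value `-10*log10(p)`.
#' @examples
#' phred_to_accuracy(10)    # 90
#' phred_to_accuracy(12.3)  # 94.1...
#' @export
phred_to_accuracy <- function(q) {
  if (any(q < 0)) stop("Phred values must be non-negative")
  100 * (1 - 10^(-q / 10))
}

#' @rdname phred_to_accuracy
#' @export
phred_to_prob <- function(q) {
  if (any(q < 0)) stop("Phred values must be non-negative")
  10^(-q / 10)
}

#' @rdname phred_to_accuracy
#' @param p Probability vector in (0, 1].
#' @export
prob_to_phred <- function(p) {
  -10 * log10(p)
}

## round half away from zero (Phred/PL convention, unlike base round())
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

## log10(sum(10^x)) without overflow
log10_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log10(sum(10^(x - m)))
}
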