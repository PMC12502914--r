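#' Internal weights from a problem's own stage-one coefficients
#'
#' An initial positive coefficient is evidence for a positive final effect
#' and against a negative one (and vice versa), so each feature j gets a
#' weight for the positive direction (slot j: `max(0, beta_j)`) and for
#' the negative direction (slot p+j: `|min(0, beta_j)|`). At most one of
#' the two is nonzero.
#'
#' @param beta Length-p vector of stage-one coefficients for one problem.
#' @return Non-negative vector of length 2p.
#' @examples
#' internal_weights(c(1.2, -0.4, 0))
#' @export
internal_weights <- function(beta) {
  stopifnot(all(is.finite(beta)))
  c(pmax(0, beta), abs(pmin(0, beta)))
}

#' External weights from the other problems' stage-one coefficients
#'
#' Pools evidence across the other problems: slot j sums the positive
#' parts and slot p+j the absolute negative parts of the initial
#' coefficients of feature j over all other problems, so both directions
#' can receive nonzero weight when the problems disagree on the sign.
#' With a single problem (zero columns) the empty sums give all zeros.
#'
#' @param beta_other Matrix with p rows and one column per other problem
#'   (q - 1 columns, possibly zero).
#' @return Non-negative vector of length 2p.
#' @examples
#' external_weights(cbind(c(0.4, 0.1), c(-0.2, 0.3)))
#' @export
external_weights <- function(beta_other) {
  beta_other <- as.matrix(beta_other)
  stopifnot(all(is.finite(beta_other)))
  if (ncol(beta_other) == 0L) return(numeric(2L * nrow(beta_other)))
  pos <- array(pmax(0, beta_other), dim = dim(beta_other))
  neg <- array(pmin(0, beta_other), dim = dim(beta_other))
  c(rowSums(pos), abs(rowSums(neg)))
}

#' Penalty factors from internal and external weights
#'
#' The prior weight of coordinate j is
#' `internal[j]^delta_int + external[j]^delta_ext`, with the convention
#' `0^0 = 1` applied per term, so an exponent of zero switches that
#' information source off entirely (every term contributes 1). The raw
#' penalty factor is the reciprocal prior; a zero prior maps to `Inf`,
#' which excludes the coordinate direction from the stage-two fit. Finite
#' factors are rescaled to average exactly one, so the stage-two penalty
#' scale stays comparable across exponent settings.
#'
#' @param internal,external Non-negative weight vectors of length 2p, as
#'   returned by [internal_weights()] and [external_weights()].
#' @param delta_int,delta_ext Non-negative scaling exponents.
#' @return Penalty-factor vector of length 2p with entries in (0, Inf];
#'   finite entries average one.
#' @examples
#' w <- internal_weights(c(0.5, -1))
#' penalty_factors(w, numeric(4), delta_int = 1, delta_ext = 0)
#' @export
penalty_factors <- function(internal, external, delta_int, delta_ext) {
  stopifnot(length(internal) == length(external),
            all(internal >= 0), all(external >= 0),
            delta_int >= 0, delta_ext >= 0)
  prior <- internal^delta_int + external^delta_ext # R evaluates 0^0 as 1
  raw <- ifelse(prior > 0, 1 / prior, Inf)
  normalise_pf(raw)
}
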