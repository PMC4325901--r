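#' Action entropy
#'
#' Shannon entropy (in bits) of the two-action selection distribution,
#' \eqn{H = -[p \log_2 p + (1-p)\log_2(1-p)]} with \eqn{0\log_2 0 \equiv 0}.
#' The training goal is to drive it from 1 (indifference) to 0 (the trained
#' action dominant).
#'
#' @param p_T probability of the trained action, in `[0, 1]`; vectorized.
#' @return Entropy in `[0, 1]` bits.
#' @examples
#' action_entropy(c(0, 0.5, 0.8, 1))
#' @export
action_entropy <- function(p_T) {
  if (any(!is.na(p_T) & (p_T < 0 | p_T > 1)))
    stop("'p_T' must lie in [0, 1]")
  .entropy_bits(p_T)
}

## internal, no domain check (engine hot path)
.entropy_bits <- function(p) {
  h <- -(p * log2(p) + (1 - p) * log2(1 - p))
  h[p <= 0 | p >= 1] <- 0
  h
}

#' Instructional efficiency
#'
#' Ratio of the realized gain in trained-action probability between two
#' consecutive iterations to the maximum possible gain,
#' \eqn{IE = (p_{i+1} - p_i) / (1 - p_i)}. It equals 1 when the next
#' iteration reaches certainty and is negative when the probability drops.
#' As \eqn{p_i \to 1} the divisor vanishes and the measure has a
#' singularity; values whose divisor falls below `eps` are returned as `NA`
#' (the explicit undefined marker).
#'
#' @param p_now,p_next trained-action probabilities at iterations `i` and
#'   `i + 1`, in `[0, 1]`; vectorized.
#' @param eps singularity guard for the divisor `1 - p_now`.
#' @return Numeric vector, `NA` where undefined.
#' @examples
#' instructional_efficiency(0.5, 0.75)  # 0.5
#' instructional_efficiency(1, 1)       # NA (singular)
#' @export
instructional_efficiency <- function(p_now, p_next, eps = 1e-12) {
  if (any(!is.na(p_now) & (p_now < 0 | p_now > 1)) ||
      any(!is.na(p_next) & (p_next < 0 | p_next > 1)))
    stop("probabilities must lie in [0, 1]")
  .efficiency(p_now, p_next, eps)
}

.efficiency <- function(p_now, p_next, eps = 1e-12) {
  ie <- (p_next - p_now) / (1 - p_now)
  ie[1 - p_now < eps] <- NA_real_
  ie
}
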