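#' Closed-form solution of the irreversible two-step chain A -> B -> C
#'
#' Analytic occupancies of the sequential first-order chain
#' \eqn{A \to B \to C} with rate constants `k1`, `k2` and initial condition
#' \eqn{A(0)=1}. Serves as the independent oracle for the numerical
#' integrator on any condition whose active subnetwork reduces to a linear
#' chain (e.g. agonist-bound receptor -> coupled -> subunit-separated).
#'
#' The repeated-root case \eqn{k_1 = k_2 = k}, where the textbook formula
#' degenerates, is handled continuously via the limit
#' \eqn{B(t) = k t e^{-k t}}.
#'
#' @param k1,k2 Rate constants in 1/s; both must be positive and finite.
#' @param t Time points in seconds (vector, all >= 0).
#' @return A matrix with one row per time point and columns
#'   `fracA`, `fracB`, `fracC` summing to 1.
#' @examples
#' closed_form_chain(1 / 0.22, 1 / 1.92, c(0, 1, 5))
#' @export
closed_form_chain <- function(k1, k2, t) {
  if (!all(is.finite(c(k1, k2))) || k1 <= 0 || k2 <= 0)
    stop("closed_form_chain: k1 and k2 must be positive and finite")
  if (!all(is.finite(t)) || any(t < 0))
    stop("closed_form_chain: t must be finite and non-negative")
  a <- exp(-k1 * t)
  if (abs(k1 - k2) <= 1e-9 * max(k1, k2)) {
    b <- k1 * t * exp(-k1 * t)
  } else {
    b <- k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
  }
  cbind(fracA = a, fracB = b, fracC = pmax(0, 1 - a - b))
}
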