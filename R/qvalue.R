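#' Storey q-values
#'
#' Estimates the null proportion `pi0` at a single fixed `lambda` (no spline
#' smoothing): `pi0 = (#\{p > lambda\} + 1) / ((1 - lambda) * m)`, capped at
#' one — the +1 safeguard keeps `pi0` in (0, 1] and applies the degenerate
#' clamp when no p-value exceeds `lambda`. Q-values are the usual step-up
#' minimum: `q_(i) = min_(j >= i) pi0 * m * p_(j) / j` over the sorted
#' p-values. Forcing `pi0 = 1` reproduces Benjamini-Hochberg exactly.
#'
#' @param p p-values in `[0, 1]`.
#' @param lambda tuning parameter in `[0, 1)` for the `pi0` estimate.
#' @param pi0 optional override for the null proportion (e.g. `1` for BH).
#' @return a `cd_qvalues` list: `p_values`, `q_values`, `pi0`, `lambda`.
#' @export
storey_qvalues <- function(p, lambda = 0.5, pi0 = NULL) {
  if (!length(p)) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- (sum(p > lambda) + 1) / ((1 - lambda) * m)
    pi0 <- min(1, pi0)
  } else {
    if (pi0 <= 0 || pi0 > 1) stop("pi0 must be in (0, 1]")
  }
  o <- order(p)
  ranks <- seq_len(m)
  q_sorted <- rev(cummin(rev(pi0 * m * p[o] / ranks)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  structure(list(p_values = p, q_values = q, pi0 = pi0, lambda = lambda),
            class = "cd_qvalues")
}

#' @export
print.cd_qvalues <- function(x, ...) {
  cat("Storey q-values:", length(x$p_values), "tests, pi0 =",
      signif(x$pi0, 4), "(lambda =", x$lambda, ")\n")
  invisible(x)
}
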