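#' General reversible (REV/GTR) nucleotide substitution model
#'
#' Builds a continuous-time reversible rate matrix \eqn{Q} from symmetric
#' exchangeabilities \eqn{s_{ij}} and equilibrium base frequencies \eqn{\pi},
#' with \eqn{Q_{ij} = s_{ij}\pi_j} for \eqn{i \ne j}, rows summing to zero,
#' normalized so the expected substitution rate at stationarity is one
#' (\eqn{-\sum_i \pi_i Q_{ii} = 1}). All rate variation is then carried by
#' branch lengths and scale factors, which keeps the model identifiable.
#'
#' @param exchangeabilities numeric vector of length 6 giving
#'   \eqn{s_{AC}, s_{AG}, s_{AT}, s_{CG}, s_{CT}, s_{GT}} (non-negative,
#'   relative; overall scale is removed by the normalization).
#' @param pi equilibrium frequencies for A, C, G, T; must be positive and is
#'   renormalized to sum to one.
#' @return an object of class `cd_model` with elements `s`, `pi`, `Q`, and a
#'   cached symmetric eigendecomposition used by [transition_matrix()].
#' @examples
#' m <- rev_model(c(1, 4, 1, 1, 4, 1), c(0.3, 0.2, 0.2, 0.3))
#' transition_matrix(m, t = 0.1)
#' @export
rev_model <- function(exchangeabilities = rep(1, 6),
                      pi = rep(0.25, 4)) {
  s <- as.numeric(exchangeabilities)
  pi <- as.numeric(pi)
  stopifnot(length(s) == 6, length(pi) == 4)
  if (any(!is.finite(s)) || any(s < 0)) stop("exchangeabilities must be finite and >= 0")
  if (any(!is.finite(pi)) || any(pi <= 0)) stop("pi must be finite and > 0")
  pi <- pi / sum(pi)
  S <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  S[upper.tri(S)] <- s
  S <- S + t(S)
  Q <- S * rep(pi, each = 4) # Q_ij = s_ij * pi_j (i != j)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  if (rate <= 0) stop("degenerate model: zero total rate")
  Q <- Q / rate
  # symmetric similarity transform: B = D^{1/2} Q D^{-1/2} has real spectrum
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2 # symmetrize away rounding
  eig <- eigen(B, symmetric = TRUE)
  A <- eig$vectors / sq                      # D^{-1/2} U
  Bm <- t(eig$vectors) * rep(sq, each = 4)   # U' D^{1/2}
  # M[, k] = vec(outer(A[, k], Bm[k, ])) so that the flattened transition
  # matrices for all edges come from one product M %*% exp(values %o% t)
  M <- vapply(1:4, function(k) as.vector(A[, k] %o% Bm[k, ]), numeric(16))
  structure(list(
    s = s / rate, pi = pi, Q = Q,
    eig = list(values = eig$values, A = A, B = Bm, M = M)
  ), class = "cd_model")
}

#' @export
print.cd_model <- function(x, ...) {
  cat("REV substitution model (unit expected rate)\n")
  cat("  pi:", paste(sprintf("%s=%.4f", DNA_BASES, x$pi), collapse = " "), "\n")
  cat("  s :", paste(sprintf("%.4f", x$s), collapse = " "), "\n")
  invisible(x)
}

#' Transition probability matrix P = exp(Q * rho * t)
#'
#' @param model a `cd_model`.
#' @param t branch length (expected substitutions per site), `t >= 0`.
#' @param rho non-negative rate-scale factor applied to the branch.
#' @return a 4x4 row-stochastic matrix over A, C, G, T.
#' @export
transition_matrix <- function(model, t, rho = 1) {
  stopifnot(inherits(model, "cd_model"))
  if (!is.finite(t) || t < 0) stop("t must be finite and >= 0")
  if (!is.finite(rho) || rho < 0) stop("rho must be finite and >= 0")
  tt <- t * rho
  if (tt == 0) {
    P <- diag(4)
    dimnames(P) <- list(DNA_BASES, DNA_BASES)
    return(P)
  }
  e <- model$eig
  P <- e$A %*% (exp(e$values * tt) * e$B)
  P[P < 0] <- 0
  dimnames(P) <- list(DNA_BASES, DNA_BASES)
  P
}

#' Serialize a substitution model (plus optional tree scale) to text
#'
#' Small key-value format: lines `pi A 0.3`, `s AC 1.0`, `tree_scale 1.0`.
#'
#' @param model a `cd_model`.
#' @param path output file.
#' @param tree_scale optional global branch-length multiplier to record.
#' @export
write_model <- function(model, path, tree_scale = 1) {
  pairs <- c("AC", "AG", "AT", "CG", "CT", "GT")
  lines <- c(
    sprintf("pi %s %.10g", DNA_BASES, model$pi),
    sprintf("s %s %.10g", pairs, model$s),
    sprintf("tree_scale %.10g", tree_scale)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a substitution model written by [write_model()]
#'
#' @param path input file.
#' @return list with `model` (a `cd_model`) and `tree_scale`.
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "\\s+")
  pi <- setNames(numeric(4), DNA_BASES)
  s <- setNames(numeric(6), c("AC", "AG", "AT", "CG", "CT", "GT"))
  tree_scale <- 1
  for (tk in toks) {
    if (tk[1] == "pi") pi[tk[2]] <- as.numeric(tk[3])
    else if (tk[1] == "s") s[tk[2]] <- as.numeric(tk[3])
    else if (tk[1] == "tree_scale") tree_scale <- as.numeric(tk[2])
    else stop("unrecognized model line: ", paste(tk, collapse = " "))
  }
  list(model = rev_model(unname(s), unname(pi)), tree_scale = tree_scale)
}
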