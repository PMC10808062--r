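# -- neutral model fitting ----------------------------------------------------

#' Fit the neutral substitution model to designated neutral columns
#'
#' EM-style fit of a general reversible model plus one global branch-length
#' multiplier, holding the input tree's relative branch lengths fixed.
#' Equilibrium frequencies are set from the observed symbol frequencies
#' (expected sufficient statistics under the reversible model at
#' stationarity); each iteration then runs a short bounded quasi-Newton
#' M-step over log-exchangeabilities and the log tree scale. The
#' log-likelihood trace is monotone non-decreasing; convergence is declared
#' when an iteration improves it by less than `tol`.
#'
#' @param x a `cd_alignment` of putatively neutral columns.
#' @param phy a `cd_phylogeny`.
#' @param init optional initial `cd_model` (default: equal exchangeabilities
#'   at the observed base frequencies).
#' @param min_columns minimum number of informative columns required.
#' @param max_iter,tol convergence controls.
#' @return a `cd_neutral_fit`: `model`, `tree_scale`, `loglik`,
#'   `loglik_trace`, `iterations`, `converged`.
#' @export
fit_neutral_model <- function(x, phy, init = NULL, min_columns = 1000,
                              max_iter = 500, tol = 1e-6) {
  codes <- code_columns(x, species = phy$tree$tip.label)
  informative <- colSums(codes != 0L) > 0L
  if (sum(informative) < min_columns) {
    stop("only ", sum(informative), " informative columns; need >= ",
         min_columns, " (set min_columns to override)")
  }
  codes <- codes[, informative, drop = FALSE]
  cp <- compress_patterns(codes)
  phy$.prep <- prepare_pruning(phy)

  counts <- tabulate(codes[codes != 0L], nbins = 4L)
  pi <- (counts + 1) / sum(counts + 4) # pseudocount keeps pi > 0
  if (is.null(init)) init <- rev_model(rep(1, 6), pi)

  # Parameters: log s[1:5] relative to s[6], log tree scale.
  loglik_of <- function(par) {
    s <- c(exp(par[1:5]), 1)
    scale <- exp(par[6])
    m <- rev_model(s, pi)
    pmats <- edge_pmats(m, phy$tree, rep(scale, nrow(phy$tree$edge)))
    res <- prune_loglik(cp$codes, phy, m, pmats)
    ll <- sum(res$per_column * cp$weights)
    # degenerate corners of the search box can zero out a column pattern;
    # a large finite penalty keeps finite-difference gradients defined
    if (!is.finite(ll)) ll <- -1e12
    ll
  }
  s0 <- pmax(init$s, 1e-8)
  par <- c(log(s0[1:5] / s0[6]), 0)
  ll <- loglik_of(par)
  trace <- ll
  converged <- FALSE
  iters <- 0L
  # All-identical columns (no substitutions) push the scale to the floor.
  lower <- c(rep(log(1e-6), 5), log(1e-6))
  upper <- c(rep(log(1e6), 5), log(1e3))
  for (it in seq_len(max_iter)) {
    iters <- it
    opt <- try(optim(par, function(p) -loglik_of(p),
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = 10)), silent = TRUE)
    if (inherits(opt, "try-error")) break
    new_ll <- -opt$value
    if (new_ll < ll) { # guard monotonicity against line-search wobble
      trace <- c(trace, ll)
      converged <- TRUE
      break
    }
    par <- opt$par
    trace <- c(trace, new_ll)
    if (new_ll - ll < tol) {
      ll <- new_ll
      converged <- TRUE
      break
    }
    ll <- new_ll
  }
  s <- c(exp(par[1:5]), 1)
  structure(list(
    model = rev_model(s, pi),
    tree_scale = exp(par[6]),
    loglik = ll,
    loglik_trace = trace,
    iterations = iters,
    converged = converged,
    n_columns = sum(informative)
  ), class = "cd_neutral_fit")
}

#' @export
print.cd_neutral_fit <- function(x, ...) {
  cat("Neutral model fit:", x$n_columns, "columns, logLik", round(x$loglik, 2),
      "\n  tree scale", signif(x$tree_scale, 4),
      "| iterations", x$iterations,
      "| converged:", x$converged, "\n")
  invisible(x)
}

#' Fit regional neutral models in sliding windows
#'
#' For each window of `window_size` reference bases, columns inside the
#' provided neutral intervals with at most `max_missing_frac` missing species
#' are pooled; a seeded random subsample of up to `sample_size` columns is
#' fitted with [fit_neutral_model()]. Windows with fewer than `min_columns`
#' eligible columns are flagged and fall back to the supplied global fit.
#'
#' @param x a `cd_alignment`.
#' @param phy a `cd_phylogeny`.
#' @param neutral_intervals `cd_elements` (or data.frame with start/end)
#'   marking putatively neutral regions.
#' @param window_size window width in reference bp.
#' @param sample_size columns sampled per window.
#' @param max_missing_frac per-column missing-species tolerance.
#' @param min_columns minimum eligible columns before falling back.
#' @param global_fit fallback `cd_neutral_fit` (fitted here if missing).
#' @param seed integer seed for the subsampling.
#' @return list of per-window records: `start`, `end`, `fit`, `fallback`.
#' @export
fit_regional_models <- function(x, phy, neutral_intervals,
                                window_size = 10000L, sample_size = 2000L,
                                max_missing_frac = 0.2, min_columns = 200L,
                                global_fit = NULL, seed = 1L) {
  set.seed(as.integer(seed))
  in_neutral <- rep(FALSE, length(x$coords))
  for (i in seq_len(nrow(neutral_intervals))) {
    in_neutral <- in_neutral |
      (x$coords >= neutral_intervals$start[i] &
         x$coords < neutral_intervals$end[i])
  }
  codes <- code_columns(x, species = phy$tree$tip.label)
  missing_frac <- colSums(codes == 0L) / nrow(codes)
  eligible <- in_neutral & missing_frac <= max_missing_frac
  if (is.null(global_fit)) {
    sub <- which(eligible)
    if (length(sub) > sample_size) sub <- sort(sample(sub, sample_size))
    global_fit <- fit_neutral_model(subset_by_index(x, sub), phy,
                                    min_columns = min(min_columns, length(sub)))
  }
  lo <- min(x$coords); hi <- max(x$coords) + 1L
  starts <- seq(lo, hi - 1L, by = window_size)
  lapply(starts, function(ws) {
    we <- min(ws + window_size, hi)
    idx <- which(eligible & x$coords >= ws & x$coords < we)
    if (length(idx) < min_columns) {
      return(list(start = ws, end = we, fit = global_fit, fallback = TRUE))
    }
    if (length(idx) > sample_size) idx <- sort(sample(idx, sample_size))
    fit <- fit_neutral_model(subset_by_index(x, idx), phy,
                             min_columns = min(min_columns, length(idx)))
    list(start = ws, end = we, fit = fit, fallback = FALSE)
  })
}

#' Fit the neutral model from a seeded subsample of a neutral region
#'
#' Convenience used by the pipeline: restrict to `[start, end)`, drop
#' columns with more than `max_missing_frac` missing species, sample up to
#' `sample_size` of the remainder (seeded) and fit. Mirrors the windowed
#' subsampling recipe used for regional background models.
#'
#' @inheritParams fit_neutral_model
#' @param start,end 0-based half-open neutral region on the reference.
#' @param sample_size maximum columns fitted.
#' @param max_missing_frac per-column missing-species tolerance.
#' @param seed integer seed for the subsample.
#' @return a `cd_neutral_fit`.
#' @export
fit_neutral_subsample <- function(x, phy, start, end, sample_size = 2000L,
                                  max_missing_frac = 0.2, seed = 1L,
                                  min_columns = 500L) {
  region <- slice_columns(x, start, end)
  codes <- code_columns(region, species = phy$tree$tip.label)
  ok <- which(colSums(codes == 0L) / nrow(codes) <= max_missing_frac)
  if (length(ok) > sample_size) {
    set.seed(as.integer(seed))
    ok <- sort(sample(ok, sample_size))
  }
  fit_neutral_model(subset_by_index(region, ok), phy,
                    min_columns = min(min_columns, length(ok)))
}

subset_by_index <- function(x, idx) {
  alignment_columns(x$symbols[, idx, drop = FALSE], x$coords[idx],
                    x$ref_name, x$ref_species)
}
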