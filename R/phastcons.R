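# -- phylo-HMM conserved-element segmentation --------------------------------

#' Two-state phylo-HMM transition parameterization
#'
#' The conserved state has expected sojourn length `expected_length` bp
#' (`mu = 1/L` per-bp exit rate) and prior coverage `target_coverage`
#' (`nu = gamma * mu / (1 - gamma)` entry rate), so the stationary conserved
#' fraction of the chain is exactly `gamma`. Conserved-state emissions use
#' the neutral model with all branches scaled by `rho`.
#'
#' Defaults are the segmentation settings used throughout the pipeline:
#' expected length 45 bp, target coverage 0.3, conserved rate scale 0.31.
#'
#' @param expected_length expected conserved sojourn length L (bp), `>= 1`.
#' @param target_coverage prior conserved fraction gamma, in (0, 1).
#' @param rho conserved-state branch scale, in (0, 1].
#' @return a `cd_hmm_params` list with `mu`, `nu` and the inputs.
#' @export
hmm_params <- function(expected_length = 45, target_coverage = 0.3,
                       rho = 0.31) {
  stopifnot(expected_length >= 1, target_coverage > 0, target_coverage < 1,
            rho > 0, rho <= 1)
  mu <- 1 / expected_length
  nu <- target_coverage * mu / (1 - target_coverage)
  structure(list(expected_length = expected_length,
                 target_coverage = target_coverage, rho = rho,
                 mu = mu, nu = nu), class = "cd_hmm_params")
}

#' @export
print.cd_hmm_params <- function(x, ...) {
  cat(sprintf(
    "phylo-HMM: L=%g bp, gamma=%g, rho=%g (mu=%.6f, nu=%.6f)\n",
    x$expected_length, x$target_coverage, x$rho, x$mu, x$nu))
  invisible(x)
}

#' Simulate the two-state transition chain
#'
#' Draws a state path of length `n` from the HMM transition prior (state 1 =
#' conserved, 0 = neutral), starting from the stationary distribution. Used
#' to check the sojourn-length and coverage implications of a
#' parameterization by simulation.
#'
#' @param params a `cd_hmm_params`.
#' @param n number of steps.
#' @return integer vector of 0/1 states.
#' @export
simulate_state_chain <- function(params, n) {
  stopifnot(n >= 1)
  mu <- params$mu; nu <- params$nu
  stat_c <- nu / (nu + mu)
  states <- integer(n)
  states[1] <- rbinom(1, 1, stat_c)
  u <- runif(n - 1)
  for (i in seq_len(n - 1)) {
    states[i + 1] <- if (states[i] == 1L) {
      if (u[i] < mu) 0L else 1L
    } else {
      if (u[i] < nu) 1L else 0L
    }
  }
  states
}

#' Mean length of completed conserved sojourns in a state path
#'
#' @param states integer 0/1 vector.
#' @return list: `mean_length`, `n_runs`, `se` (standard error of the mean).
#' @export
conserved_sojourns <- function(states) {
  r <- rle(states)
  runs <- r$lengths[r$values == 1L]
  # drop runs truncated by the path boundaries
  if (length(runs) && states[1] == 1L) runs <- runs[-1]
  if (length(runs) && states[length(states)] == 1L) {
    runs <- runs[-length(runs)]
  }
  list(mean_length = mean(runs), n_runs = length(runs),
       se = sd(runs) / sqrt(length(runs)))
}

log_sum_exp <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log(exp(a - m) + exp(b - m)))
}

# Forward-backward + Viterbi for the 2-state chain, log space.
# emis: 2 x n matrix of per-column log emission likelihoods
# (row 1 = neutral, row 2 = conserved).
hmm_decode <- function(emis, params) {
  n <- ncol(emis)
  mu <- params$mu; nu <- params$nu
  lt <- log(matrix(c(1 - nu, nu, mu, 1 - mu), 2, 2, byrow = TRUE))
  stat <- c(mu, nu) / (mu + nu) # (neutral, conserved)
  linit <- log(stat)
  fwd <- matrix(-Inf, 2, n); bwd <- matrix(-Inf, 2, n)
  fwd[, 1] <- linit + emis[, 1]
  for (i in seq_len(n - 1)) {
    fwd[1, i + 1] <- log_sum_exp(fwd[1, i] + lt[1, 1], fwd[2, i] + lt[2, 1]) + emis[1, i + 1]
    fwd[2, i + 1] <- log_sum_exp(fwd[1, i] + lt[1, 2], fwd[2, i] + lt[2, 2]) + emis[2, i + 1]
  }
  bwd[, n] <- 0
  if (n > 1) {
    for (i in (n - 1):1) {
      bwd[1, i] <- log_sum_exp(lt[1, 1] + emis[1, i + 1] + bwd[1, i + 1],
                               lt[1, 2] + emis[2, i + 1] + bwd[2, i + 1])
      bwd[2, i] <- log_sum_exp(lt[2, 1] + emis[1, i + 1] + bwd[1, i + 1],
                               lt[2, 2] + emis[2, i + 1] + bwd[2, i + 1])
    }
  }
  ll_fwd <- log_sum_exp(fwd[1, n], fwd[2, n])
  ll_bwd <- log_sum_exp(linit[1] + emis[1, 1] + bwd[1, 1],
                        linit[2] + emis[2, 1] + bwd[2, 1])
  post <- exp(fwd[2, ] + bwd[2, ] - ll_fwd)
  # Viterbi
  vit <- matrix(-Inf, 2, n); ptr <- matrix(0L, 2, n)
  vit[, 1] <- linit + emis[, 1]
  for (i in seq_len(n - 1)) {
    for (s in 1:2) {
      cand <- vit[, i] + lt[, s]
      ptr[s, i + 1] <- which.max(cand)
      vit[s, i + 1] <- cand[ptr[s, i + 1]] + emis[s, i + 1]
    }
  }
  path <- integer(n)
  path[n] <- which.max(vit[, n])
  if (n > 1) for (i in (n - 1):1) path[i] <- ptr[path[i + 1], i + 1]
  list(posterior_conserved = post, viterbi = path - 1L, # 1 = conserved
       loglik_forward = ll_fwd, loglik_backward = ll_bwd)
}

#' Segment an alignment into conserved elements (phylo-HMM)
#'
#' Two-state hidden Markov model along the reference: the neutral state
#' emits columns under the neutral model, the conserved state under the
#' neutral model with every branch scaled by `params$rho`. Transition
#' probabilities come from [hmm_params()]. Elements are maximal runs of the
#' Viterbi path in the conserved state; per-base conserved posteriors come
#' from forward-backward in log space. Gaps in reference coverage split runs
#' (the chain restarts at each contiguous stretch).
#'
#' @param x a `cd_alignment`.
#' @param phy a `cd_phylogeny`.
#' @param neutral neutral `cd_model`.
#' @param params a `cd_hmm_params`.
#' @param tree_scale global branch-length multiplier from the neutral fit.
#' @param decode `"viterbi"` (default) or `"posterior"` (threshold 0.5).
#' @return list: `segments` (data.frame chrom/start/end/mean_posterior/score)
#'   and `posteriors` (data.frame chrom/pos/posterior), plus the forward and
#'   backward total log-likelihoods.
#' @export
phastcons_segment <- function(x, phy, neutral, params = hmm_params(),
                              tree_scale = 1,
                              decode = c("viterbi", "posterior")) {
  decode <- match.arg(decode)
  if (!ncol(x$symbols)) stop("empty alignment")
  phy$.prep <- prepare_pruning(phy)
  codes <- code_columns(x, species = phy$tree$tip.label)
  nedge <- nrow(phy$tree$edge)
  em_neutral <- prune_loglik(
    codes, phy, neutral,
    edge_pmats(neutral, phy$tree, rep(tree_scale, nedge)))$per_column
  em_cons <- prune_loglik(
    codes, phy, neutral,
    edge_pmats(neutral, phy$tree, rep(tree_scale * params$rho, nedge)))$per_column

  runs <- split_contiguous(x$coords)
  segs <- list(); post_all <- numeric(length(x$coords))
  llf <- 0; llb <- 0
  for (r in runs) {
    idx <- r$idx
    dec <- hmm_decode(rbind(em_neutral[idx], em_cons[idx]), params)
    post_all[idx] <- dec$posterior_conserved
    llf <- llf + dec$loglik_forward
    llb <- llb + dec$loglik_backward
    state <- if (decode == "viterbi") dec$viterbi else
      as.integer(dec$posterior_conserved > 0.5)
    rl <- rle(state)
    ends_i <- cumsum(rl$lengths)
    starts_i <- ends_i - rl$lengths + 1L
    for (k in which(rl$values == 1L)) {
      ii <- idx[starts_i[k]:ends_i[k]]
      mp <- mean(post_all[ii])
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = x$ref_name, start = x$coords[ii[1]],
        end = x$coords[ii[length(ii)]] + 1L,
        mean_posterior = mp,
        score = min(1000L, as.integer(round(1000 * mp))))
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               mean_posterior = numeric(), score = integer())
  list(segments = segments,
       posteriors = data.frame(chrom = x$ref_name, pos = x$coords,
                               posterior = post_all),
       loglik_forward = llf, loglik_backward = llb)
}
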