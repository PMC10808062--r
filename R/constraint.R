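# -- phyloP-style likelihood-ratio constraint/acceleration scoring -----------

#' Golden-section maximization on an interval
#'
#' Deterministic 1-D maximizer used for the rate-scale MLE; kept independent
#' of [stats::optimize()] so the optimizer can be cross-checked against a
#' grid search.
#'
#' @param f function of one numeric argument.
#' @param lower,upper search bounds.
#' @param tol absolute interval tolerance.
#' @return list with `maximum` and `objective`.
#' @keywords internal
golden_section_max <- function(f, lower, upper, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  if (f1 > f2) list(maximum = x1, objective = f1)
  else list(maximum = x2, objective = f2)
}

# Shared scoring context: precomputed codes, cached traversal, and the
# neutral (rho = 1) edge transition matrices, so element scans rebuild only
# the clade edges during the rho search.
scoring_context <- function(x, phy, neutral, clade = NULL, tree_scale = 1) {
  phy$.prep <- prepare_pruning(phy)
  codes <- code_columns(x, species = phy$tree$tip.label)
  ce <- clade_edges(phy, clade)
  base_scales <- rep(tree_scale, nrow(phy$tree$edge))
  pmats_null <- edge_pmats(neutral, phy$tree, base_scales)
  clade_sp <- intersect(clade_tips(phy, clade), rownames(codes))
  list(phy = phy, codes = codes, neutral = neutral, clade = clade,
       clade_edges = ce, base_scales = base_scales,
       pmats_null = pmats_null, clade_species = clade_sp,
       coords = x$coords)
}

context_loglik <- function(ctx, cols_idx, rho) {
  codes <- ctx$codes[, cols_idx, drop = FALSE]
  pmats <- ctx$pmats_null
  if (rho != 1) {
    e <- ctx$neutral$eig
    ce <- ctx$clade_edges
    tt <- ctx$phy$tree$edge.length[ce] * ctx$base_scales[ce] * rho
    block <- e$M %*% exp(outer(e$values, tt))
    block[block < 0] <- 0
    pmats[, ce] <- block
  }
  prune_loglik(codes, ctx$phy, ctx$neutral, pmats)$total
}

#' Maximum-likelihood rate-scale factor for a clade
#'
#' Bounded golden-section MLE of the factor `rho` scaling the clade's
#' branch lengths, on `[rho_min, rho_max]`. `rho < 1` indicates constraint,
#' `rho > 1` acceleration.
#'
#' @param x a `cd_alignment` (columns to score jointly).
#' @param phy a `cd_phylogeny`.
#' @param neutral neutral `cd_model`.
#' @param clade clade name or `NULL` (whole tree).
#' @param rho_min,rho_max,tol search bounds and tolerance.
#' @param tree_scale global branch-length multiplier from the neutral fit.
#' @return list: `rho`, `loglik`, `flat` (TRUE when the likelihood carries
#'   no information about rho, in which case `rho` is 1).
#' @export
estimate_scale <- function(x, phy, neutral, clade = NULL,
                           rho_min = 1e-4, rho_max = 20, tol = 1e-4,
                           tree_scale = 1) {
  ctx <- scoring_context(x, phy, neutral, clade, tree_scale)
  estimate_scale_ctx(ctx, seq_along(ctx$coords), rho_min, rho_max, tol)
}

estimate_scale_ctx <- function(ctx, cols_idx, rho_min = 1e-4, rho_max = 20,
                               tol = 1e-4) {
  f <- function(r) context_loglik(ctx, cols_idx, r)
  opt <- golden_section_max(f, rho_min, rho_max, tol)
  ll1 <- f(1)
  if (opt$objective - ll1 < 1e-9 && abs(f(rho_min) - f(rho_max)) < 1e-9) {
    return(list(rho = 1, loglik = ll1, flat = TRUE))
  }
  if (opt$objective < ll1) {
    return(list(rho = 1, loglik = ll1, flat = FALSE))
  }
  list(rho = opt$maximum, loglik = opt$objective, flat = FALSE)
}

make_constraint_result <- function(target, clade, lnl0, lnl1, rho, flags = character()) {
  lrt <- max(0, 2 * (lnl1 - lnl0))
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  p <- min(max(p, 1e-300), 1)
  score <- if (rho < 1) -log10(p) else if (rho > 1) log10(p) else 0
  structure(list(
    target = target, clade = if (is.null(clade)) "all" else clade,
    lnL_null = lnl0, lnL_alt = lnl1, rho = rho,
    lrt = lrt, p_value = p, score = score, flags = flags
  ), class = "cd_constraint_result")
}

#' @export
print.cd_constraint_result <- function(x, ...) {
  cat(sprintf(
    "constraint result [%s, clade %s]: rho=%.4g LRT=%.3f p=%.3g score=%.3f%s\n",
    x$target, x$clade, x$rho, x$lrt, x$p_value, x$score,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""
  ))
  invisible(x)
}

#' Per-base constraint/acceleration score
#'
#' Likelihood-ratio test of the neutral rate (`rho = 1`) against a free
#' non-negative rate-scale factor on the clade's branches, at a single
#' reference position. The p-value is from a chi-square with one degree of
#' freedom; the signed score is `-log10(p)`, positive for constraint
#' (`rho < 1`), negative for acceleration.
#'
#' @inheritParams estimate_scale
#' @param position 0-based reference coordinate covered by the alignment.
#' @return a `cd_constraint_result`.
#' @export
phylop_site <- function(x, phy, neutral, clade = NULL, position,
                        tree_scale = 1) {
  ctx <- scoring_context(x, phy, neutral, clade, tree_scale)
  i <- match(position, ctx$coords)
  if (is.na(i)) stop("position ", position, " not covered by the alignment")
  score_element_ctx(ctx, i, target = sprintf("%s:%d", x$ref_name, position))
}

score_element_ctx <- function(ctx, cols_idx, target) {
  sub <- ctx$codes[ctx$clade_species, cols_idx, drop = FALSE]
  informative <- sum(colSums(sub != 0L) > 0L)
  if (informative == 0L) {
    lnl0 <- context_loglik(ctx, cols_idx, 1)
    return(make_constraint_result(target, ctx$clade, lnl0, lnl0, 1,
                                  flags = "uninformative"))
  }
  flags <- character()
  if (min(colSums(sub != 0L)) < 3L) flags <- "low-coverage"
  lnl0 <- context_loglik(ctx, cols_idx, 1)
  est <- estimate_scale_ctx(ctx, cols_idx)
  make_constraint_result(target, ctx$clade, lnl0, max(est$loglik, lnl0),
                         est$rho, flags = flags)
}

#' Element-wise constraint/acceleration score
#'
#' As [phylop_site()], but a single shared rate-scale factor is fitted
#' jointly across all the element's columns (log-likelihoods are sums over
#' columns), increasing power relative to per-base tests.
#'
#' @inheritParams estimate_scale
#' @param element one row of a `cd_elements` data frame (or a list with
#'   `start`, `end`, `element_id`).
#' @return a `cd_constraint_result`.
#' @export
phylop_element <- function(x, phy, neutral, clade = NULL, element,
                           tree_scale = 1) {
  ctx <- scoring_context(x, phy, neutral, clade, tree_scale)
  idx <- which(ctx$coords >= element$start & ctx$coords < element$end)
  if (!length(idx)) stop("element does not overlap the alignment")
  score_element_ctx(ctx, idx, target = as.character(element$element_id))
}

#' Score many elements against one alignment
#'
#' Batch version of [phylop_element()] sharing one precomputed scoring
#' context (the neutral transition matrices are built once).
#'
#' @inheritParams estimate_scale
#' @param elements a `cd_elements` data frame.
#' @return data.frame: element_id, clade, rho, lrt, p_value, score, flags,
#'   n_columns.
#' @export
phylop_elements <- function(x, phy, neutral, clade = NULL, elements,
                            tree_scale = 1) {
  ctx <- scoring_context(x, phy, neutral, clade, tree_scale)
  rows <- lapply(seq_len(nrow(elements)), function(i) {
    idx <- which(ctx$coords >= elements$start[i] & ctx$coords < elements$end[i])
    if (!length(idx)) {
      return(data.frame(element_id = elements$element_id[i],
                        clade = if (is.null(clade)) "all" else clade,
                        rho = NA_real_, lrt = NA_real_, p_value = 1,
                        score = 0, flags = "no-coverage", n_columns = 0L))
    }
    r <- score_element_ctx(ctx, idx, elements$element_id[i])
    data.frame(element_id = r$target, clade = r$clade, rho = r$rho,
               lrt = r$lrt, p_value = r$p_value, score = r$score,
               flags = paste(r$flags, collapse = ","),
               n_columns = length(idx))
  })
  do.call(rbind, rows)
}

#' Per-base scores over a range, as a bedGraph-style data frame
#'
#' @inheritParams estimate_scale
#' @return data.frame with chrom, start, end (per-base), score, p_value, rho.
#' @export
phylop_scores <- function(x, phy, neutral, clade = NULL, tree_scale = 1) {
  ctx <- scoring_context(x, phy, neutral, clade, tree_scale)
  rows <- lapply(seq_along(ctx$coords), function(i) {
    r <- score_element_ctx(ctx, i, sprintf("%s:%d", x$ref_name, ctx$coords[i]))
    data.frame(chrom = x$ref_name, start = ctx$coords[i],
               end = ctx$coords[i] + 1L, score = r$score,
               p_value = r$p_value, rho = r$rho)
  })
  do.call(rbind, rows)
}
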