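# -- downstream enrichment statistics ----------------------------------------

#' Keep each variant's maximum PIP across traits/tissues
#'
#' When a variant is fine-mapped in multiple traits, tissues or genes, only
#' its highest posterior inclusion probability is retained before
#' enrichment.
#'
#' @param variants data.frame with `variant_id` and `PIP` (other columns are
#'   carried from the max-PIP row).
#' @return deduplicated data.frame.
#' @export
dedupe_max_pip <- function(variants) {
  stopifnot(all(c("variant_id", "PIP") %in% names(variants)))
  o <- order(variants$variant_id, -variants$PIP)
  v <- variants[o, , drop = FALSE]
  v[!duplicated(v$variant_id), , drop = FALSE]
}

#' Fine-mapped variant enrichment in an annotation
#'
#' Enrichment is the ratio of the proportion of likely-causal variants
#' (`PIP > hi`) inside the annotation to the proportion of likely-noncausal
#' variants (`PIP < lo`) inside it. Variants with `lo <= PIP <= hi` belong
#' to neither tail and are excluded. The odds ratio, exact confidence
#' interval and p-value come from Fisher's exact test on the 2x2 table
#' `[a, A-a; b, B-b]`.
#'
#' @param variants data.frame with `variant_id`, `PIP`, and a logical
#'   `in_annotation` column (deduplicate first with [dedupe_max_pip()]).
#' @param hi,lo PIP tail thresholds (strict inequalities).
#' @return a `cd_enrichment` list: counts a/A/b/B, `enrichment`, `odds_ratio`,
#'   `ci` (95%), `p_value`, `flags`.
#' @export
pip_enrichment <- function(variants, hi = 0.5, lo = 0.01) {
  stopifnot(all(c("PIP", "in_annotation") %in% names(variants)))
  high <- variants$PIP > hi
  low <- variants$PIP < lo
  A <- sum(high); B <- sum(low)
  if (A == 0 || B == 0) {
    stop("empty PIP tail: A=", A, " B=", B)
  }
  a <- sum(high & variants$in_annotation)
  b <- sum(low & variants$in_annotation)
  flags <- character()
  if (a == 0 || b == 0) flags <- "zero-cell"
  enrichment <- if (b == 0) Inf else (a / A) / (b / B)
  ft <- fisher.test(matrix(c(a, A - a, b, B - b), 2, 2, byrow = TRUE))
  structure(list(
    a = a, A = A, b = b, B = B,
    enrichment = enrichment,
    odds_ratio = unname(ft$estimate),
    ci = unname(ft$conf.int),
    p_value = ft$p.value,
    flags = flags
  ), class = "cd_enrichment")
}

#' @export
print.cd_enrichment <- function(x, ...) {
  cat(sprintf(
    "PIP enrichment: %d/%d high vs %d/%d low -> %.3f (OR %.3f [%.3f, %.3f], p=%.3g)\n",
    x$a, x$A, x$b, x$B, x$enrichment, x$odds_ratio, x$ci[1], x$ci[2],
    x$p_value))
  invisible(x)
}

woolf_log_or <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  list(log_or = log((a / b) / (c / d)),
       var = 1 / a + 1 / b + 1 / c + 1 / d)
}

#' Length-binned motif constraint odds ratios with fixed-effects meta-analysis
#'
#' For each motif, compares the proportion of primate-constrained footprints
#' matching the motif against the proportion of mammal-constrained
#' footprints matching it. Because short footprints are more often called
#' constrained in mammals, footprints are split into `n_bins` equal-sized
#' length bins (global quantile bins over the full footprint universe); the
#' Woolf log odds ratio (Haldane-Anscombe 0.5 correction on zero cells) is
#' computed per motif per bin and pooled by inverse-variance fixed-effects
#' meta-analysis. Two-sided p-values from the pooled z; Storey FDR across
#' motifs.
#'
#' @param footprints data.frame with columns `footprint_id`, `length`,
#'   `motif` (one row per footprint x motif match; footprints with several
#'   motifs appear on several rows), `primate_constrained`,
#'   `mammal_constrained` (logical).
#' @param n_bins number of length bins.
#' @param min_footprints motifs matched by fewer footprints are dropped.
#' @param alpha FDR threshold for the significance flag.
#' @return data.frame per motif: pooled log OR, SE, 95% CI, OR, z, p, q,
#'   significant, n_footprints, n_bins_used.
#' @export
motif_or_meta <- function(footprints, n_bins = 10L, min_footprints = 10L,
                          alpha = 0.05) {
  need <- c("footprint_id", "length", "motif",
            "primate_constrained", "mammal_constrained")
  stopifnot(all(need %in% names(footprints)))
  uni <- footprints[!duplicated(footprints$footprint_id),
                    c("footprint_id", "length")]
  xs <- sort(uni$length)
  n_uni <- length(xs)
  # equal-count length bins over the footprint universe (inverse-ECDF
  # breaks computed by index to dodge floating-point quantile wobble)
  idx <- pmax(1L, ceiling(n_uni * seq_len(n_bins - 1) / n_bins - 1e-9))
  qs <- unique(c(-Inf, xs[idx], Inf))
  bin_of <- cut(footprints$length, breaks = qs, labels = FALSE,
                include.lowest = TRUE)
  motifs <- sort(unique(footprints$motif))
  rows <- lapply(motifs, function(mo) {
    in_motif <- footprints$motif == mo
    n_fp <- length(unique(footprints$footprint_id[in_motif]))
    if (n_fp < min_footprints) return(NULL)
    lo <- 0; w <- 0; used <- 0L
    for (bn in sort(unique(bin_of))) {
      in_bin <- bin_of == bn
      a <- sum(in_bin & in_motif & footprints$primate_constrained)
      b <- sum(in_bin & !in_motif & footprints$primate_constrained)
      c_ <- sum(in_bin & in_motif & footprints$mammal_constrained)
      d <- sum(in_bin & !in_motif & footprints$mammal_constrained)
      if (a + c_ == 0 || b + d == 0) next # no information in this bin
      wl <- woolf_log_or(a, b, c_, d)
      lo <- lo + wl$log_or / wl$var
      w <- w + 1 / wl$var
      used <- used + 1L
    }
    if (w == 0) return(NULL)
    pooled <- lo / w
    se <- sqrt(1 / w)
    z <- pooled / se
    data.frame(motif = mo, log_or = pooled, se = se,
               ci_lo = pooled - qnorm(0.975) * se,
               ci_hi = pooled + qnorm(0.975) * se,
               or = exp(pooled), z = z,
               p_value = 2 * pnorm(-abs(z)),
               n_footprints = n_fp, n_bins_used = used,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res) || !nrow(res)) stop("no motif passed the minimum footprint filter")
  qv <- storey_qvalues(res$p_value)
  res$q_value <- qv$q_values
  res$significant <- res$q_value < alpha
  res
}

#' Correlate reporter-assay substitution effects with constraint scores
#'
#' Per element, the absolute per-nucleotide mean substitution effect is
#' correlated (Pearson) with constraint scores truncated below at zero
#' (negative scores indicate possible acceleration and are set to 0).
#' Elements where either vector has zero variance (or fewer than 3
#' positions) are flagged untestable and excluded from the FDR universe;
#' Storey q-values are computed across the testable elements.
#'
#' @param effects data.frame with `element_id`, `position`, `mean_effect`,
#'   `phylop` (aligned per nucleotide within each element).
#' @param use_absolute correlate `|mean_effect|` (default) rather than the
#'   signed effect.
#' @param alpha FDR threshold for the significance flag.
#' @return data.frame per element: r, p_value, q_value, n, untestable,
#'   significant.
#' @export
mpra_constraint_correlation <- function(effects, use_absolute = TRUE,
                                        alpha = 0.05) {
  need <- c("element_id", "position", "mean_effect", "phylop")
  stopifnot(all(need %in% names(effects)))
  ids <- unique(effects$element_id)
  rows <- lapply(ids, function(id) {
    e <- effects[effects$element_id == id, ]
    eff <- if (use_absolute) abs(e$mean_effect) else e$mean_effect
    sc <- pmax(e$phylop, 0)
    untestable <- length(eff) < 3 || sd(eff) == 0 || sd(sc) == 0
    if (untestable) {
      return(data.frame(element_id = id, r = NA_real_, p_value = NA_real_,
                        n = length(eff), untestable = TRUE))
    }
    ct <- stats::cor.test(eff, sc, method = "pearson")
    data.frame(element_id = id, r = unname(ct$estimate),
               p_value = ct$p.value, n = length(eff), untestable = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- NA_real_
  testable <- !res$untestable
  if (any(testable)) {
    res$q_value[testable] <- storey_qvalues(res$p_value[testable])$q_values
  }
  res$significant <- !is.na(res$q_value) & res$q_value < alpha
  res
}

#' Assembly mismatch-rate regression on heterozygosity
#'
#' Ordinary least squares of per-species assembly mismatch rate on
#' heterozygosity. The residual error rate attributable to assembly and
#' sequencing error is reported as the intercept (the mismatch rate at zero
#' heterozygosity), together with the variance explained (R^2).
#'
#' @param pairs data.frame with `mismatch` and `heterozygosity` columns
#'   (one row per assembly pair), rates >= 0.
#' @return list: `intercept` (= residual mismatch rate), `slope`,
#'   `r_squared`, `residual_rate`, `n`, and the `lm` fit.
#' @export
mismatch_regression <- function(pairs) {
  stopifnot(all(c("mismatch", "heterozygosity") %in% names(pairs)))
  if (nrow(pairs) < 3) stop("need at least 3 assembly pairs")
  if (any(pairs$mismatch < 0) || any(pairs$heterozygosity < 0)) {
    stop("rates must be >= 0")
  }
  if (var(pairs$heterozygosity) == 0) {
    stop("heterozygosity is constant; regression undefined")
  }
  fit <- lm(mismatch ~ heterozygosity, data = pairs)
  s <- summary(fit)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       r_squared = s$r.squared, residual_rate = unname(coef(fit)[1]),
       n = nrow(pairs), fit = fit)
}
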