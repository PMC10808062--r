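# -- ultraconserved element scanning -----------------------------------------

#' Relaxed missing-data tolerance per column
#'
#' `floor(fraction * n_species)` species may be missing per column in the
#' relaxed scan (e.g. 1% of 239 species = 2).
#'
#' @param n_species number of species in the alignment.
#' @param fraction tolerated missing fraction.
#' @return integer tolerance.
#' @export
relaxed_missing_tolerance <- function(n_species, fraction = 0.01) {
  as.integer(floor(fraction * n_species))
}

#' Perfectly conserved columns
#'
#' A column is perfect when every non-missing symbol is identical, at least
#' one species is non-missing, and the number of missing species (`-` or
#' `N`) does not exceed `max_missing` (strict mode: `max_missing = 0`).
#' A column missing in all species is never perfect.
#'
#' @param x a `cd_alignment`.
#' @param max_missing integer tolerance; see [relaxed_missing_tolerance()].
#' @return logical mask over the alignment's reference positions.
#' @export
perfect_columns <- function(x, max_missing = 0L) {
  m <- x$symbols
  is_missing <- m %in% MISSING_SYMBOLS
  dim(is_missing) <- dim(m)
  n_missing <- colSums(is_missing)
  n_species <- nrow(m)
  obs <- colSums(!is_missing)
  identical_col <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[!is_missing[, j], j]
    length(unique(v)) == 1L
  }, logical(1))
  obs > 0L & identical_col & n_missing <= max_missing
}

#' Scan a perfect-column mask for ultraconserved elements
#'
#' Maximal runs of TRUE positions at least `min_length` bp long; runs never
#' cross gaps in reference coverage.
#'
#' @param mask logical mask as from [perfect_columns()].
#' @param coords 0-based reference coordinates matching the mask.
#' @param chrom reference name for the output records.
#' @param min_length minimum run length in bp.
#' @param mode label stored on the records (`"strict"` or `"relaxed"`).
#' @return data.frame: chrom, start, end, length, mode.
#' @export
scan_uces <- function(mask, coords, chrom = "ref", min_length = 20L,
                      mode = "strict") {
  stopifnot(length(mask) == length(coords))
  recs <- list()
  for (r in split_contiguous(coords)) {
    sub <- mask[r$idx]
    rl <- rle(sub)
    ends_i <- cumsum(rl$lengths)
    starts_i <- ends_i - rl$lengths + 1L
    for (k in which(rl$values & rl$lengths >= min_length)) {
      ii <- r$idx[starts_i[k]:ends_i[k]]
      recs[[length(recs) + 1L]] <- data.frame(
        chrom = chrom, start = coords[ii[1]],
        end = coords[ii[length(ii)]] + 1L,
        length = length(ii), mode = mode)
    }
  }
  if (!length(recs)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer(),
                      mode = character()))
  }
  do.call(rbind, recs)
}

#' Ultraconserved elements of an alignment
#'
#' Convenience wrapper: [perfect_columns()] + [scan_uces()] in strict
#' (no missing data) or relaxed (at most `floor(tolerance * n_species)`
#' missing species per column) mode.
#'
#' @param x a `cd_alignment`.
#' @param min_length minimum element length (bp).
#' @param mode `"strict"` or `"relaxed"`.
#' @param tolerance missing-species fraction for relaxed mode.
#' @return data.frame as from [scan_uces()].
#' @export
find_uces <- function(x, min_length = 20L, mode = c("strict", "relaxed"),
                      tolerance = 0.01) {
  mode <- match.arg(mode)
  max_missing <- if (mode == "strict") 0L else
    relaxed_missing_tolerance(nrow(x$symbols), tolerance)
  mask <- perfect_columns(x, max_missing)
  scan_uces(mask, x$coords, chrom = x$ref_name, min_length = min_length,
            mode = mode)
}

#' Overlap fraction between a UCE set and external elements
#'
#' Fraction of `external` elements overlapped by at least `min_bp` bases of
#' some UCE (overlap strictly defined as >= `min_bp` shared bases).
#'
#' @param uces data.frame with chrom/start/end (0-based half-open).
#' @param external data.frame with chrom/start/end.
#' @param min_bp minimum shared bases to count as overlap.
#' @return list: `fraction` and per-external-record logical `flags`.
#' @export
uce_overlap <- function(uces, external, min_bp = 1L) {
  if (!nrow(external)) return(list(fraction = NA_real_, flags = logical(0)))
  if (!nrow(uces)) {
    return(list(fraction = 0, flags = rep(FALSE, nrow(external))))
  }
  gr_u <- GenomicRanges::GRanges(uces$chrom,
                                 IRanges::IRanges(uces$start + 1L, uces$end))
  gr_e <- GenomicRanges::GRanges(external$chrom,
                                 IRanges::IRanges(external$start + 1L,
                                                  external$end))
  hits <- GenomicRanges::findOverlaps(gr_e, gr_u, minoverlap = min_bp)
  flags <- rep(FALSE, nrow(external))
  flags[unique(S4Vectors::queryHits(hits))] <- TRUE
  list(fraction = mean(flags), flags = flags)
}
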