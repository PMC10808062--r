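DEPTH_CATEGORIES <- c("unconstrained (<65 Ma)", "primate (~65 Ma)",
                      "mammal (~100 Ma)", "vertebrate (160-400 Ma)",
                      "ambiguous-excluded")

#' Assign constraint-depth categories from per-clade q-values
#'
#' Implements the nested clade-exclusivity ladder: an element significantly
#' constrained (q < `alpha`) in primates but in neither mammals nor
#' vertebrates is called primate-specific (~65 Ma); significant in primates
#' and mammals but not vertebrates, mammal-depth (~100 Ma); significant in
#' all three, vertebrate-depth (160-400 Ma). Elements significant in no
#' clade are unconstrained (<65 Ma) unless they overlap a conserved-segment
#' (phastCons-style) element, in which case they are excluded as ambiguous
#' (a mixture of recent and deep constraint). Any non-nested significance
#' pattern (e.g. mammal without primate) is contradictory evidence and is
#' also excluded.
#'
#' @param primate_q,mammal_q,vertebrate_q q-value vectors (same length).
#' @param phastcons_overlap logical vector: overlaps a conserved segment.
#' @param alpha FDR threshold (default 0.05).
#' @param element_id optional identifiers.
#' @return data.frame: element_id, the three significance flags,
#'   phastcons_overlap, and `category` (factor over the five categories).
#' @export
classify_depth <- function(primate_q, mammal_q, vertebrate_q,
                           phastcons_overlap = FALSE, alpha = 0.05,
                           element_id = NULL) {
  n <- length(primate_q)
  if (length(mammal_q) != n || length(vertebrate_q) != n) {
    stop("q-value vectors must have equal length")
  }
  if (any(is.na(primate_q)) || any(is.na(mammal_q)) || any(is.na(vertebrate_q))) {
    stop("missing q-values: every element needs all three clades")
  }
  phastcons_overlap <- rep_len(as.logical(phastcons_overlap), n)
  if (is.null(element_id)) element_id <- paste0("el", seq_len(n))
  p <- primate_q < alpha
  m <- mammal_q < alpha
  v <- vertebrate_q < alpha
  category <- rep(DEPTH_CATEGORIES[5], n)
  category[p & !m & !v] <- DEPTH_CATEGORIES[2]
  category[p & m & !v] <- DEPTH_CATEGORIES[3]
  category[p & m & v] <- DEPTH_CATEGORIES[4]
  none <- !p & !m & !v
  category[none & !phastcons_overlap] <- DEPTH_CATEGORIES[1]
  category[none & phastcons_overlap] <- DEPTH_CATEGORIES[5]
  data.frame(
    element_id = element_id,
    primate_sig = p, mammal_sig = m, vertebrate_sig = v,
    phastcons_overlap = phastcons_overlap,
    category = factor(category, levels = DEPTH_CATEGORIES),
    stringsAsFactors = FALSE
  )
}

#' 40-bp core window around a summit
#'
#' Returns the `[summit - half, summit + half)` window on the reference
#' (default 40 bp total). Windows running off the contig start are clipped
#' at zero with a warning.
#'
#' @param elements a `cd_elements` data frame with summit positions.
#' @param width window width (bp).
#' @return a `cd_elements` data frame of core windows (class `DHS`).
#' @export
dhs_core_window <- function(elements, width = 40L) {
  if (any(is.na(elements$summit))) {
    stop("summit absent for ", elements$element_id[which(is.na(elements$summit))[1]],
         "; supply summits or use the element midpoint as a summit surrogate")
  }
  half <- as.integer(width %/% 2L)
  start <- elements$summit - half
  end <- elements$summit + (width - half)
  if (any(start < 0L)) {
    warning("core window clipped at contig start for ",
            sum(start < 0L), " element(s)")
    start <- pmax(start, 0L)
  }
  genomic_elements(elements$chrom, start, end,
                   paste0(elements$element_id, "_core"),
                   element_class = "DHS")
}

#' Nearest gene for each element
#'
#' Closest gene by interval distance (0 when overlapping); equidistant ties
#' are broken in favour of the gene with the smaller start coordinate.
#' Elements on a chromosome with no genes are unassigned (`NA`).
#'
#' @param elements a `cd_elements` data frame.
#' @param genes data.frame with chrom, start, end, gene_id (0-based
#'   half-open).
#' @return data.frame: element_id, gene_id, distance.
#' @export
nearest_gene <- function(elements, genes) {
  res <- data.frame(element_id = elements$element_id,
                    gene_id = NA_character_, distance = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(elements))) {
    g <- genes[genes$chrom == elements$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    # interval gap distance, 0 if overlapping (half-open arithmetic)
    d <- pmax(g$start - elements$end[i], elements$start[i] - g$end, 0L)
    best <- which(d == min(d))
    if (length(best) > 1L) best <- best[which.min(g$start[best])]
    res$gene_id[i] <- g$gene_id[best]
    res$distance[i] <- d[best]
  }
  res
}
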