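#' Reference-anchored alignment columns
#'
#' Stores one alignment column per reference position: a character matrix of
#' symbols in `{A,C,G,T,-,N}` with species as rows and reference positions as
#' columns. `-` (observed deletion) and `N` (no alignment / unknown base) are
#' distinguished in storage; both are treated as missing data by the
#' likelihood engine, but the relaxed ultraconserved-element scanner counts
#' them separately from substitutions.
#'
#' @param symbols character matrix, rows named by species, one column per
#'   reference position; symbols are uppercased on construction.
#' @param coords integer vector of 0-based reference positions, strictly
#'   increasing, one per column.
#' @param ref_name reference sequence name (e.g. `"chr1"`).
#' @param ref_species name of the reference species row.
#' @return an object of class `cd_alignment`.
#' @export
alignment_columns <- function(symbols, coords, ref_name = "ref",
                              ref_species = rownames(symbols)[1]) {
  stopifnot(is.matrix(symbols), !is.null(rownames(symbols)))
  symbols <- toupper(symbols)
  if (!all(symbols %in% ALN_SYMBOLS)) {
    bad <- setdiff(unique(as.vector(symbols)), ALN_SYMBOLS)
    stop("invalid alignment symbols: ", paste(bad, collapse = ", "))
  }
  coords <- as.integer(coords)
  if (length(coords) != ncol(symbols)) {
    stop("coords length must equal number of columns")
  }
  if (length(coords) > 1 && any(diff(coords) <= 0)) {
    stop("reference coordinates must be strictly increasing")
  }
  if (anyDuplicated(rownames(symbols))) stop("duplicate species names")
  if (!ref_species %in% rownames(symbols)) {
    stop("ref_species '", ref_species, "' not among rows")
  }
  structure(list(symbols = symbols, coords = coords, ref_name = ref_name,
                 ref_species = ref_species), class = "cd_alignment")
}

#' @export
print.cd_alignment <- function(x, ...) {
  cat("cd_alignment:", nrow(x$symbols), "species x", ncol(x$symbols),
      "reference-anchored columns on", x$ref_name, "\n")
  invisible(x)
}

#' @export
dim.cd_alignment <- function(x) dim(x$symbols)

aln_species <- function(x) rownames(x$symbols)

#' Subset alignment columns by reference coordinate
#'
#' @param x a `cd_alignment`.
#' @param start,end 0-based half-open reference interval.
#' @return a `cd_alignment` restricted to positions in `[start, end)`.
#' @export
slice_columns <- function(x, start, end) {
  keep <- x$coords >= start & x$coords < end
  alignment_columns(x$symbols[, keep, drop = FALSE], x$coords[keep],
                    x$ref_name, x$ref_species)
}

#' Restrict alignment columns to a named clade's species
#'
#' Used to build per-clade backgrounds, e.g. a mammal background excluding the
#' primate branch (`complement = TRUE` on the primate clade of a mammal tree).
#'
#' @param x a `cd_alignment`.
#' @param phy a `cd_phylogeny`.
#' @param clade clade name (see [clade_tips()]).
#' @param complement return the complement of the clade instead.
#' @return a `cd_alignment` whose rows are the selected tips (tips absent
#'   from the alignment are dropped; the reference row is kept only if it
#'   belongs to the selection).
#' @export
extract_clade_columns <- function(x, phy, clade = NULL, complement = FALSE) {
  tips <- clade_tips(phy, clade, complement = complement)
  keep <- intersect(aln_species(x), tips)
  if (!length(keep)) stop("no alignment rows match the requested clade")
  ref <- if (x$ref_species %in% keep) x$ref_species else keep[1]
  alignment_columns(x$symbols[keep, , drop = FALSE], x$coords,
                    x$ref_name, ref)
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A", `-` = "-", N = "N")

revcomp_chars <- function(v) unname(REVCOMP[v])

#' Read a reference-anchored MAF file into alignment columns
#'
#' Every block must contain the reference species; species absent from a
#' block receive `N` (absence of alignment, not an observed deletion).
#' Columns where the reference row carries a gap are dropped (the container
#' is reference-anchored). If a block's reference row is on the `-` strand
#' the whole block is reverse-complemented into reference orientation.
#'
#' @param path MAF file.
#' @param ref_species reference species name (the part of the `s` source
#'   field before the first `.`); default: species of the first `s` row.
#' @return a `cd_alignment`.
#' @export
read_maf <- function(path, ref_species = NULL) {
  lines <- readLines(path)
  blocks <- list(); cur <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "a")) {
      if (!is.null(cur) && length(cur)) blocks[[length(blocks) + 1L]] <- cur
      cur <- character()
    } else if (startsWith(ln, "s ") || startsWith(ln, "s\t")) {
      if (is.null(cur)) stop("MAF parse error at line ", i, ": 's' before 'a'")
      cur <- c(cur, ln)
    } else if (startsWith(ln, "#") || !nzchar(trimws(ln)) ||
               startsWith(ln, "i ") || startsWith(ln, "e ") ||
               startsWith(ln, "q ")) {
      next
    } else {
      stop("MAF parse error at line ", i, ": unrecognized record")
    }
  }
  if (!is.null(cur) && length(cur)) blocks[[length(blocks) + 1L]] <- cur
  if (!length(blocks)) stop("no alignment blocks in ", path)

  parse_block <- function(bl, bi) {
    f <- strsplit(trimws(bl), "\\s+")
    bad <- vapply(f, length, 1L) != 7L
    if (any(bad)) stop("MAF parse error: malformed 's' line in block ", bi)
    src <- vapply(f, `[[`, "", 2L)
    sp <- sub("\\..*$", "", src)
    contig <- ifelse(grepl("\\.", src), sub("^[^.]*\\.", "", src), src)
    start <- as.integer(vapply(f, `[[`, "", 3L))
    size <- as.integer(vapply(f, `[[`, "", 4L))
    strand <- vapply(f, `[[`, "", 5L)
    src_size <- as.integer(vapply(f, `[[`, "", 6L))
    text <- toupper(vapply(f, `[[`, "", 7L))
    if (length(unique(nchar(text))) != 1L) {
      stop("MAF parse error: ragged block ", bi)
    }
    list(sp = sp, contig = contig, start = start, size = size,
         strand = strand, src_size = src_size, text = text)
  }
  pblocks <- Map(parse_block, blocks, seq_along(blocks))
  if (is.null(ref_species)) ref_species <- pblocks[[1]]$sp[1]
  species <- unique(unlist(lapply(pblocks, `[[`, "sp")))
  if (!ref_species %in% species) stop("reference species not found in MAF")
  species <- c(ref_species, setdiff(species, ref_species))

  col_list <- list(); coord_list <- list(); ref_name <- NULL
  for (bi in seq_along(pblocks)) {
    b <- pblocks[[bi]]
    ri <- match(ref_species, b$sp)
    if (is.na(ri)) stop("block ", bi, " lacks the reference species")
    if (b$strand[ri] == "-") {
      # flip block into reference orientation
      b$text <- vapply(b$text, function(s) {
        paste(rev(revcomp_chars(strsplit(s, "")[[1]])), collapse = "")
      }, "")
      b$start <- b$src_size - b$start - b$size
      b$strand <- ifelse(b$strand == "-", "+", "-")
    }
    if (is.null(ref_name)) ref_name <- b$contig[ri]
    chars <- do.call(rbind, strsplit(b$text, ""))
    rownames(chars) <- b$sp
    ref_row <- chars[ri, ]
    keep <- ref_row != "-"
    if (!any(keep)) next
    coords <- b$start[ri] + cumsum(keep) - 1L
    chars <- chars[, keep, drop = FALSE]
    coords <- coords[keep]
    full <- matrix("N", length(species), ncol(chars),
                   dimnames = list(species, NULL))
    full[rownames(chars), ] <- chars
    col_list[[length(col_list) + 1L]] <- full
    coord_list[[length(coord_list) + 1L]] <- coords
  }
  coords <- unlist(coord_list)
  if (anyDuplicated(coords)) {
    stop("duplicate reference coverage at position ",
         coords[anyDuplicated(coords)], " (input should be single-copy)")
  }
  symbols <- do.call(cbind, col_list)
  o <- order(coords)
  alignment_columns(symbols[, o, drop = FALSE], coords[o],
                    ref_name = ref_name, ref_species = ref_species)
}

#' Write alignment columns as MAF
#'
#' One block is emitted per maximal run of contiguous reference coordinates.
#' Round-trips with [read_maf()]: column content is preserved for all species.
#'
#' @param x a `cd_alignment`.
#' @param path output file.
#' @export
write_maf <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##maf version=1 program=constraintdepth", con)
  runs <- split_contiguous(x$coords)
  sp <- aln_species(x)
  src_size <- max(x$coords) + 1L
  for (r in runs) {
    idx <- r$idx
    writeLines("", con)
    writeLines("a score=0.000000", con)
    for (s in sp) {
      row <- x$symbols[s, idx]
      if (s == x$ref_species) {
        start <- x$coords[idx[1]]
        size <- length(idx)
        src <- paste0(s, ".", x$ref_name)
      } else {
        start <- 0L
        size <- sum(!row %in% MISSING_SYMBOLS)
        src <- paste0(s, ".contig")
      }
      writeLines(sprintf("s %s %d %d + %d %s", src, start, size,
                         src_size, paste(row, collapse = "")), con)
    }
  }
  invisible(path)
}

# maximal runs of consecutive integers; returns list of list(idx=...)
split_contiguous <- function(coords) {
  if (!length(coords)) return(list())
  brk <- c(0L, which(diff(coords) != 1L), length(coords))
  lapply(seq_len(length(brk) - 1L), function(i) {
    list(idx = (brk[i] + 1L):brk[i + 1L])
  })
}

#' Write alignment columns as a FASTA slice
#'
#' One record per species; positions are the alignment's reference
#' coordinates (recorded in the description line of the reference record).
#'
#' @param x a `cd_alignment`.
#' @param path output file.
#' @export
write_fasta_columns <- function(x, path) {
  seqs <- apply(x$symbols, 1, paste, collapse = "")
  ds <- Biostrings::DNAStringSet(seqs)
  names(ds) <- aln_species(x)
  Biostrings::writeXStringSet(ds, path)
  invisible(path)
}
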