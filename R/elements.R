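ELEMENT_CLASSES <- c("DHS", "footprint", "exon", "UCE", "other")

#' Construct/validate a table of genomic elements
#'
#' Elements use 0-based half-open coordinates internally. An optional
#' `summit` (absolute position, used for DHS core windows) must lie inside
#' the element; an optional `motif` label is carried for footprints.
#'
#' @param chrom,start,end coordinates (0-based half-open).
#' @param element_id unique identifiers.
#' @param element_class one of `r paste(ELEMENT_CLASSES, collapse = ", ")`.
#' @param summit optional absolute summit positions (NA allowed).
#' @param motif optional motif labels (NA allowed).
#' @return a `data.frame` with class `cd_elements`.
#' @export
genomic_elements <- function(chrom, start, end, element_id,
                             element_class = "other",
                             summit = NA_integer_, motif = NA_character_) {
  df <- data.frame(
    chrom = as.character(chrom), start = as.integer(start),
    end = as.integer(end), element_id = as.character(element_id),
    element_class = as.character(element_class),
    summit = as.integer(summit), motif = as.character(motif),
    stringsAsFactors = FALSE
  )
  if (any(df$start >= df$end)) {
    stop("invalid element interval: start >= end for ",
         df$element_id[which(df$start >= df$end)[1]])
  }
  bad_class <- !df$element_class %in% ELEMENT_CLASSES
  if (any(bad_class)) {
    stop("unknown element_class: ", unique(df$element_class[bad_class])[1])
  }
  has_summit <- !is.na(df$summit)
  out_of_range <- has_summit & (df$summit < df$start | df$summit >= df$end)
  if (any(out_of_range)) {
    stop("summit outside interval for ", df$element_id[which(out_of_range)[1]])
  }
  class(df) <- c("cd_elements", "data.frame")
  df
}

#' Read genomic elements from BED or TSV
#'
#' BED columns: chrom, start, end, name, (score), (strand), (summit). TSV
#' must have a header with at least `chrom`, `start`, `end`, `element_id`;
#' optional `element_class`, `summit`, `motif`. TSV coordinates may be
#' declared 1-based inclusive via `one_based = TRUE`, in which case they are
#' converted to 0-based half-open on read (BED is always 0-based).
#'
#' @param path input file.
#' @param format `"bed"` or `"tsv"`.
#' @param element_class default class assigned when the file carries none.
#' @param one_based TSV dialect flag: 1-based inclusive coordinates.
#' @return a `cd_elements` data frame.
#' @export
read_elements <- function(path, format = c("bed", "tsv"),
                          element_class = "other", one_based = FALSE) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- read.table(path, header = FALSE, sep = "", comment.char = "#",
                     stringsAsFactors = FALSE)
    if (ncol(df) < 4) stop("BED must have at least 4 columns")
    summit <- if (ncol(df) >= 7) as.integer(df[[7]]) else NA_integer_
    genomic_elements(df[[1]], df[[2]], df[[3]], df[[4]],
                     element_class = element_class, summit = summit)
  } else {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "element_id")
    if (!all(need %in% names(df))) {
      stop("TSV must have header columns: ", paste(need, collapse = ", "))
    }
    start <- df$start; end <- df$end
    summit <- if ("summit" %in% names(df)) df$summit else NA_integer_
    if (one_based) {
      start <- start - 1L   # 1-based inclusive -> 0-based half-open
      summit <- summit - 1L
    }
    genomic_elements(
      df$chrom, start, end, df$element_id,
      element_class = if ("element_class" %in% names(df)) df$element_class else element_class,
      summit = summit,
      motif = if ("motif" %in% names(df)) df$motif else NA_character_
    )
  }
}

#' Write genomic elements as BED4 (+ optional summit column 7)
#'
#' @param x a `cd_elements` data frame.
#' @param path output file.
#' @param score optional numeric score vector (column 5; 0 if omitted).
#' @export
write_elements <- function(x, path, score = NULL) {
  out <- data.frame(x$chrom, x$start, x$end, x$element_id)
  if (!is.null(score) || any(!is.na(x$summit))) {
    out$score <- if (is.null(score)) 0 else score
    out$strand <- "+"
    out$summit <- ifelse(is.na(x$summit), -1L, x$summit)
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
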