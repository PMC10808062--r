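#' Phylogeny with named clades
#'
#' Wraps an [ape::read.tree()] `phylo` object together with a set of named
#' clades (e.g. `"primates"`, `"mammals"`). Branch lengths are expected
#' substitutions per site under the neutral model; clades are connected
#' subtrees identified by their tip sets.
#'
#' @param tree a rooted `phylo` object with branch lengths, or a path to a
#'   Newick file, or a Newick string.
#' @param clades named list; each entry is a character vector of tip labels
#'   spanning a monophyletic group in `tree`.
#' @return an object of class `cd_phylogeny`: the `phylo` object plus a
#'   validated `clades` attribute.
#' @export
phylogeny <- function(tree, clades = list()) {
  if (is.character(tree)) {
    tree <- if (length(tree) == 1L && file.exists(tree)) {
      ape::read.tree(tree)
    } else {
      ape::read.tree(text = tree)
    }
  }
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("tree must have branch lengths")
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed")
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("tip labels must be unique")
  }
  if (!ape::is.rooted(tree)) {
    stop("tree must be rooted")
  }
  if (length(clades)) {
    if (is.null(names(clades)) || any(!nzchar(names(clades)))) {
      stop("clades must be a named list")
    }
    for (nm in names(clades)) {
      tips <- clades[[nm]]
      if (!all(tips %in% tree$tip.label)) {
        stop("clade '", nm, "' names tips absent from the tree")
      }
      if (!is_monophyletic_set(tree, tips)) {
        stop("clade '", nm, "' is not a connected subtree")
      }
    }
  }
  structure(list(tree = tree, clades = clades), class = "cd_phylogeny")
}

is_monophyletic_set <- function(tree, tips) {
  if (length(tips) == length(tree$tip.label)) return(TRUE)
  if (length(tips) == 1L) return(TRUE)
  mrca <- ape::getMRCA(tree, tips)
  desc <- clade_descendant_tips(tree, mrca)
  setequal(desc, tips)
}

clade_descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, clade_descendant_tips, tree = tree))
}

#' @export
print.cd_phylogeny <- function(x, ...) {
  cat("cd_phylogeny:", length(x$tree$tip.label), "tips,",
      length(x$clades), "named clades\n")
  if (length(x$clades)) {
    for (nm in names(x$clades)) {
      cat("  clade", nm, ":", length(x$clades[[nm]]), "tips\n")
    }
  }
  invisible(x)
}

#' Tips belonging to a named clade
#'
#' @param phy a `cd_phylogeny`.
#' @param clade clade name, or `NULL` for the whole tree.
#' @param complement if `TRUE`, return the tips *outside* the clade
#'   (e.g. mammals-minus-primates background).
#' @return character vector of tip labels.
#' @export
clade_tips <- function(phy, clade = NULL, complement = FALSE) {
  stopifnot(inherits(phy, "cd_phylogeny"))
  all_tips <- phy$tree$tip.label
  if (is.null(clade)) {
    tips <- all_tips
  } else {
    if (!clade %in% names(phy$clades)) {
      stop("unknown clade: '", clade, "'")
    }
    tips <- phy$clades[[clade]]
  }
  if (complement) setdiff(all_tips, tips) else tips
}

#' Edge indices scaled by a clade rate factor
#'
#' Returns the indices (rows of `tree$edge`) of the branches belonging to a
#' named clade: all branches inside the clade's subtree plus the stem branch
#' leading to its most recent common ancestor. When `clade` spans the whole
#' tree every edge is returned. The same set is used by the scorer and the
#' simulator, so planted and tested scalings coincide.
#'
#' @param phy a `cd_phylogeny`.
#' @param clade clade name or `NULL` (whole tree).
#' @return integer vector of edge indices.
#' @export
clade_edges <- function(phy, clade = NULL) {
  tree <- phy$tree
  nedge <- nrow(tree$edge)
  tips <- clade_tips(phy, clade)
  if (length(tips) == length(tree$tip.label)) {
    return(seq_len(nedge))
  }
  ntip <- length(tree$tip.label)
  tip_idx <- match(tips, tree$tip.label)
  mrca <- if (length(tip_idx) == 1L) tip_idx else ape::getMRCA(tree, tips)
  in_clade <- logical(ntip + tree$Nnode)
  in_clade[mrca] <- TRUE
  # edges in preorder-ish sweep: mark descendants of mrca
  po <- rev(postorder_edges(tree))
  for (e in po) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (in_clade[p]) in_clade[ch] <- TRUE
  }
  which(in_clade[tree$edge[, 2]]) # includes stem edge (child == mrca)
}

postorder_edges <- function(tree) {
  if (nrow(tree$edge) <= 1L) return(seq_len(nrow(tree$edge)))
  ape::reorder.phylo(tree, "postorder", index.only = TRUE)
}
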