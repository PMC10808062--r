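# -- phylogenetic likelihood engine ------------------------------------------
#
# Columns are coded 1..4 for A,C,G,T and 0 for missing ('-' or 'N', both
# marginalized as a partial-likelihood vector of ones). Pruning is vectorized
# across columns: each edge contributes one 4x4 %*% 4xNcol product, with
# per-column rescaling to avoid underflow on deep trees (hundreds of tips).

code_columns <- function(x, species = aln_species(x)) {
  keep <- intersect(species, aln_species(x))
  m <- x$symbols[keep, , drop = FALSE]
  codes <- match(m, DNA_BASES)
  codes[is.na(codes)] <- 0L
  matrix(as.integer(codes), nrow = nrow(m), ncol = ncol(m),
         dimnames = list(keep, NULL))
}

# Precompute traversal structures for a phylogeny (cached on the object).
prepare_pruning <- function(phy) {
  if (!is.null(phy$.prep)) return(phy$.prep)
  tree <- phy$tree
  list(
    tree = tree,
    ntip = length(tree$tip.label),
    nnode = tree$Nnode,
    postorder = postorder_edges(tree),
    root = length(tree$tip.label) + 1L
  )
}

#' Build per-edge rate scales for a clade scaling
#'
#' @param phy a `cd_phylogeny`.
#' @param rho scale factor.
#' @param clade clade whose branches are scaled (`NULL` = whole tree).
#' @return numeric vector over edges.
#' @keywords internal
edge_scales <- function(phy, rho = 1, clade = NULL) {
  sc <- rep(1, nrow(phy$tree$edge))
  if (rho != 1) sc[clade_edges(phy, clade)] <- rho
  sc
}

# Flattened transition matrices for every edge given per-edge scales:
# a 16 x nedge matrix whose column e holds P_e in column-major order.
edge_pmats <- function(model, tree, scales) {
  e <- model$eig
  tt <- tree$edge.length * scales
  pm <- e$M %*% exp(outer(e$values, tt))
  pm[pm < 0] <- 0
  pm
}

# list-of-matrices view used by the pure-R pruning route
pmflat_to_list <- function(pm) {
  lapply(seq_len(ncol(pm)), function(i) matrix(pm[, i], 4, 4))
}

# Core pruning pass. codes: species x ncol integer matrix (0 = missing).
# Returns list(total = loglik, per_column = numeric). Dispatches to the
# compiled kernel; prune_loglik_r is the pure-R route kept as a
# cross-check oracle for the tests.
prune_loglik <- function(codes, phy, model, pmats) {
  prep <- prepare_pruning(phy)
  tree <- prep$tree
  ncol_ <- ncol(codes)
  if (ncol_ == 0L) return(list(total = 0, per_column = numeric(0)))
  po <- prep$postorder
  tip_codes <- matrix(0L, prep$ntip, ncol_)
  idx <- match(tree$tip.label, rownames(codes))
  present <- !is.na(idx)
  tip_codes[present, ] <- codes[idx[present], , drop = FALSE]
  pm <- as.numeric(pmats[, po, drop = FALSE])
  per_col <- prune_loglik_cpp(tree$edge[po, , drop = FALSE], pm, tip_codes,
                              model$pi, prep$ntip + prep$nnode, prep$root)
  list(total = sum(per_col), per_column = per_col)
}

prune_loglik_r <- function(codes, phy, model, pmats) {
  if (is.matrix(pmats) && nrow(pmats) == 16L) pmats <- pmflat_to_list(pmats)
  prep <- prepare_pruning(phy)
  tree <- prep$tree
  ntip <- prep$ntip
  ncol_ <- ncol(codes)
  if (ncol_ == 0L) return(list(total = 0, per_column = numeric(0)))
  nn <- ntip + prep$nnode
  partial <- vector("list", nn)
  logscale <- numeric(ncol_)
  tip_codes <- matrix(0L, ntip, ncol_)
  idx <- match(tree$tip.label, rownames(codes))
  present <- !is.na(idx)
  tip_codes[present, ] <- codes[idx[present], , drop = FALSE]
  unit <- diag(4)
  ones <- matrix(1, 4, ncol_)
  for (i in seq_len(ntip)) {
    v <- tip_codes[i, ]
    if (all(v == 0L)) {
      partial[[i]] <- ones
    } else {
      L <- matrix(1, 4, ncol_)
      obs <- v != 0L
      L[, obs] <- unit[, v[obs], drop = FALSE]
      partial[[i]] <- L
    }
  }
  for (e in prep$postorder) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    contrib <- pmats[[e]] %*% partial[[ch]]
    if (is.null(partial[[p]])) {
      partial[[p]] <- contrib
    } else {
      L <- partial[[p]] * contrib
      m <- pmax(L[1, ], L[2, ], L[3, ], L[4, ])
      bad <- m <= 0
      if (any(bad)) m[bad] <- 1 # impossible columns: keep zeros, log(0) later
      L <- L * rep(1 / m, each = 4)
      logscale <- logscale + log(m)
      partial[[p]] <- L
    }
  }
  lik <- colSums(model$pi * partial[[prep$root]])
  per_col <- log(lik) + logscale
  list(total = sum(per_col), per_column = per_col)
}

#' Log-likelihood of alignment columns on a phylogeny
#'
#' Felsenstein pruning under a reversible model, with optional rate scaling
#' of a named clade's branches (subtree plus stem). `-`/`N` symbols are
#' marginalized; species in the alignment but not on the tree are ignored,
#' and tree tips absent from the alignment are treated as missing.
#'
#' @param x a `cd_alignment` (or an integer code matrix from internal use).
#' @param phy a `cd_phylogeny`.
#' @param model a `cd_model`.
#' @param rho rate-scale factor applied to `clade`'s branches.
#' @param clade clade name or `NULL` for the whole tree.
#' @param tree_scale global branch-length multiplier.
#' @param per_column return the per-column vector instead of the sum.
#' @return total log-likelihood, or a numeric vector if `per_column`.
#' @export
column_loglik <- function(x, phy, model, rho = 1, clade = NULL,
                          tree_scale = 1, per_column = FALSE) {
  codes <- if (is.matrix(x)) x else {
    unknown <- setdiff(aln_species(x), phy$tree$tip.label)
    codes <- code_columns(x)
    if (length(unknown) == nrow(codes)) {
      stop("no alignment species found in the tree")
    }
    codes
  }
  scales <- edge_scales(phy, rho, clade) * tree_scale
  pmats <- edge_pmats(model, phy$tree, scales)
  res <- prune_loglik(codes, phy, model, pmats)
  if (per_column) res$per_column else res$total
}

# Collapse identical columns into unique patterns with weights (big speedup
# for neutral-model fitting on long alignments).
compress_patterns <- function(codes) {
  key <- apply(codes, 2, paste, collapse = ",")
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(codes = codes[, u, drop = FALSE],
       weights = as.numeric(tabulate(idx, nbins = sum(u))),
       index = idx)
}
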