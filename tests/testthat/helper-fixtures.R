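# Shared fixtures and independent oracles for the test suite.

fix_model <- function() rev_model(c(1, 4, 1, 1, 4, 1), c(0.3, 0.2, 0.2, 0.3))

tree4 <- function() phylogeny("((A:0.1,B:0.2):0.05,(C:0.3,D:0.15):0.07);")

# The same unrooted 4-tip tree rooted along two different edges: internal
# path between the (A,B) and (C,D) nodes is 0.05 + 0.07 = 0.12; D's
# terminal edge 0.15 is split 0.06/0.09 in the second rooting.
tree4_rerooted <- function() {
  list(
    phylogeny("((A:0.1,B:0.2):0.05,(C:0.3,D:0.15):0.07);"),
    phylogeny("(((A:0.1,B:0.2):0.12,C:0.3):0.06,D:0.09);")
  )
}

tree5_rerooted <- function() {
  list(
    phylogeny("(((A:0.1,B:0.2):0.05,C:0.25):0.04,(D:0.3,E:0.12):0.08);"),
    phylogeny("((((A:0.1,B:0.2):0.05,C:0.25):0.12,D:0.3):0.02,E:0.1);")
  )
}

# one-column alignment over the given species
aln1 <- function(symbols, species) {
  alignment_columns(matrix(symbols, length(species), 1,
                           dimnames = list(species, NULL)), 0L)
}

aln_from_rows <- function(rows) {
  # rows: named character vector of equal-length strings
  m <- do.call(rbind, strsplit(unname(rows), ""))
  rownames(m) <- names(rows)
  alignment_columns(m, seq_len(ncol(m)) - 1L)
}

# Brute-force likelihood oracle: enumerate all internal-node state
# assignments. Independent of the pruning code path.
brute_force_loglik <- function(aln, phy, model, rho = 1, clade = NULL) {
  tree <- phy$tree
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  scales <- rep(1, nrow(tree$edge))
  if (rho != 1) scales[clade_edges(phy, clade)] <- rho
  P <- lapply(seq_len(nrow(tree$edge)), function(i) {
    transition_matrix(model, tree$edge.length[i], scales[i])
  })
  codes <- match(aln$symbols[, 1], c("A", "C", "G", "T"))
  names(codes) <- rownames(aln$symbols)
  total <- 0
  states <- rep(1L, nint)
  repeat_lik <- 0
  grid <- as.matrix(expand.grid(rep(list(1:4), nint)))
  root <- ntip + 1L
  for (g in seq_len(nrow(grid))) {
    st <- grid[g, ]
    pr <- model$pi[st[1]] # root state prior (root = ntip + 1 = first internal)
    for (i in seq_len(nrow(tree$edge))) {
      par <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
      ps <- st[par - ntip]
      if (ch <= ntip) {
        cs <- codes[tree$tip.label[ch]]
        if (is.na(cs)) next # missing tip: marginalized, sum over = 1
        pr <- pr * P[[i]][ps, cs]
      } else {
        pr <- pr * P[[i]][ps, st[ch - ntip]]
      }
    }
    repeat_lik <- repeat_lik + pr
  }
  log(repeat_lik)
}

# Naive run scanner oracle for UCEs (regex-style on the mask).
naive_run_scan <- function(mask, coords, min_length) {
  out <- list()
  i <- 1L
  n <- length(mask)
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j + 1L <= n && mask[j + 1L] && coords[j + 1L] == coords[j] + 1L) {
        j <- j + 1L
      }
      if (j - i + 1L >= min_length) {
        out[[length(out) + 1L]] <- c(start = coords[i], end = coords[j] + 1L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# Brute-force pairwise interval overlap oracle (0-based half-open).
naive_overlap_flags <- function(query, subject, min_bp = 1L) {
  vapply(seq_len(nrow(query)), function(i) {
    any(vapply(seq_len(nrow(subject)), function(j) {
      if (query$chrom[i] != subject$chrom[j]) return(FALSE)
      ov <- min(query$end[i], subject$end[j]) -
        max(query$start[i], subject$start[j])
      ov >= min_bp
    }, logical(1)))
  }, logical(1))
}

# Benjamini-Hochberg oracle via p.adjust.
bh_oracle <- function(p) stats::p.adjust(p, method = "BH")

demo_phy_cache <- local({
  phy <- NULL
  function() {
    if (is.null(phy)) phy <<- demo_tree()
    phy
  }
})
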