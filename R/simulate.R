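# -- synthetic data generation -----------------------------------------------

#' Desk-scale demonstration phylogeny with nested clades
#'
#' Builds a deterministic rooted tree with a "primates" clade nested inside
#' a "mammals" clade, plus outgroup tips standing in for non-mammal
#' vertebrates (the whole tree is the "vertebrates" clade). Topologies are
#' coalescent draws under a fixed internal seed, so the tree is a constant
#' of the package; branch lengths are rescaled so the primate subtree, the
#' other-mammal subtree and the outgroup carry realistic total neutral
#' branch lengths (substitutions/site).
#'
#' @param n_primates,n_other_mammals,n_outgroup tip counts.
#' @param primate_length total branch length of the primate subtree.
#' @param mammal_length total branch length of the other-mammal subtree.
#' @param outgroup_length total branch length of the outgroup subtree.
#' @return a `cd_phylogeny` with clades `primates`, `mammals`,
#'   `vertebrates`.
#' @export
demo_tree <- function(n_primates = 24, n_other_mammals = 16, n_outgroup = 8,
                      primate_length = 1.6, mammal_length = 1.6,
                      outgroup_length = 1.2) {
  stopifnot(n_primates >= 2, n_other_mammals >= 2, n_outgroup >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(240239L)
  scale_to <- function(tr, total) {
    tr$edge.length <- tr$edge.length * total / sum(tr$edge.length)
    tr
  }
  prim <- scale_to(ape::rcoal(n_primates,
                              tip.label = sprintf("primate%02d", seq_len(n_primates))),
                   primate_length)
  mam <- scale_to(ape::rcoal(n_other_mammals,
                             tip.label = sprintf("mammal%02d", seq_len(n_other_mammals))),
                  mammal_length)
  out <- scale_to(ape::rcoal(n_outgroup,
                             tip.label = sprintf("outgroup%02d", seq_len(n_outgroup))),
                  outgroup_length)
  glue <- function(a, b, stem_a, stem_b) {
    txt_a <- sub(";$", "", ape::write.tree(a))
    txt_b <- sub(";$", "", ape::write.tree(b))
    ape::read.tree(text = sprintf("(%s:%g,%s:%g);", txt_a, stem_a, txt_b, stem_b))
  }
  mam_all <- glue(prim, mam, 0.08, 0.08)
  tree <- glue(mam_all, out, 0.15, 0.15)
  # planting clades (nested: primates < mammals < vertebrates) plus the
  # primate-excluded scoring clades used for depth classification, mirroring
  # backgrounds built "after excluding the primate branch"
  phylogeny(tree, clades = list(
    primates = prim$tip.label,
    mammals = c(prim$tip.label, mam$tip.label),
    vertebrates = tree$tip.label,
    mammals_np = mam$tip.label,
    outgroup = out$tip.label
  ))
}

#' Deterministic dense primate-scale tree
#'
#' A single-clade coalescent tree with `n_tips` tips (default 239,
#' emulating a densely sampled primate order) rescaled to `total_length`
#' expected substitutions per site of total branch length. Used for
#' smoke tests of per-column scoring at realistic tip counts; the default
#' desk-scale scenarios use the much smaller [demo_tree()].
#'
#' @param n_tips number of tips.
#' @param total_length total branch length (substitutions/site).
#' @return a `cd_phylogeny` with a single clade `primates` spanning the tree.
#' @export
primate_tree <- function(n_tips = 239, total_length = 4) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(651604L)
  tr <- ape::rcoal(n_tips, tip.label = sprintf("primate%03d", seq_len(n_tips)))
  tr$edge.length <- tr$edge.length * total_length / sum(tr$edge.length)
  phylogeny(tr, clades = list(primates = tr$tip.label))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Default neutral model for simulations
#'
#' Transition/transversion-biased reversible model (kappa ~ 4) at slightly
#' AT-rich base composition, a reasonable stand-in for neutral mammalian
#' sequence.
#'
#' @return a `cd_model`.
#' @export
default_neutral_model <- function() {
  rev_model(c(1, 4, 1, 1, 4, 1), c(0.3, 0.2, 0.2, 0.3))
}

#' Simulation configuration
#'
#' @param phy a `cd_phylogeny` (default [demo_tree()]).
#' @param model neutral `cd_model` (default [default_neutral_model()]).
#' @param length sequence length (reference bp).
#' @param elements data.frame with `start`, `end`, `rho`, `clade` describing
#'   planted rate-scaled intervals (may be empty/NULL); `rho = 0` freezes
#'   the clade at its ancestral state, `rho < 1` plants constraint.
#' @param uce_intervals optional data.frame with `start`, `end`: intervals
#'   forced to be invariant across all species (planted UCEs).
#' @param missing_rate per-(species, column) probability of replacing the
#'   simulated base with `N`.
#' @param missing_block_length if > 1, missingness is injected in
#'   geometric-length runs with this mean (assembly-gap regime) instead of
#'   i.i.d. per column.
#' @param seed integer seed; fully determines the output.
#' @return a `cd_sim_config` list.
#' @export
simulation_config <- function(phy = demo_tree(), model = default_neutral_model(),
                              length = 2000L, elements = NULL,
                              uce_intervals = NULL, missing_rate = 0.1,
                              missing_block_length = 1, seed = 1L) {
  if (is.null(elements)) {
    elements <- data.frame(start = integer(), end = integer(),
                           rho = numeric(), clade = character())
  }
  stopifnot(length >= 1, missing_rate >= 0, missing_rate < 1)
  if (nrow(elements)) {
    stopifnot(all(elements$start >= 0), all(elements$end <= length),
              all(elements$start < elements$end), all(elements$rho >= 0))
    for (cl in unique(elements$clade)) {
      if (!cl %in% names(phy$clades)) stop("planted clade not in tree: ", cl)
    }
  }
  structure(list(phy = phy, model = model, length = as.integer(length),
                 elements = elements, uce_intervals = uce_intervals,
                 missing_rate = missing_rate,
                 missing_block_length = missing_block_length,
                 seed = as.integer(seed)), class = "cd_sim_config")
}

#' Simulate a reference-anchored alignment with planted constraint
#'
#' Draws a root sequence from the model's equilibrium frequencies and
#' evolves it down the tree, edge by edge, under the reversible model.
#' Inside each planted element the branches of the element's clade (subtree
#' plus stem, the same edge set used by the scorer) are scaled by the
#' element's `rho`. Missing data is then injected per species as `N`.
#' Planted UCE intervals are overwritten with the root state in every
#' species (invariant blocks). The first primate tip is used as the
#' reference row; the truth table records every planted interval.
#'
#' @param config a `cd_sim_config`.
#' @return list: `alignment` (a `cd_alignment`), `truth` (data.frame of
#'   planted intervals with rho and clade), `config`.
#' @export
simulate_alignment <- function(config) {
  stopifnot(inherits(config, "cd_sim_config"))
  set.seed(config$seed)
  phy <- config$phy
  tree <- phy$tree
  model <- config$model
  L <- config$length
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L

  # per-column rho per clade-edge-set: group columns by (rho, clade)
  col_group <- rep(1L, L) # group 1 = neutral
  groups <- data.frame(rho = 1, clade = NA_character_)
  if (nrow(config$elements)) {
    for (i in seq_len(nrow(config$elements))) {
      e <- config$elements[i, ]
      key <- which(groups$rho == e$rho & (groups$clade %in% e$clade))
      if (!length(key)) {
        groups <- rbind(groups, data.frame(rho = e$rho, clade = e$clade))
        key <- nrow(groups)
      }
      col_group[(e$start + 1L):e$end] <- key
    }
  }
  states <- matrix(0L, nnode, L)
  states[root, ] <- sample.int(4L, L, replace = TRUE, prob = model$pi)
  edge_sets <- lapply(seq_len(nrow(groups)), function(g) {
    if (groups$rho[g] == 1 || is.na(groups$clade[g])) integer(0)
    else clade_edges(phy, groups$clade[g])
  })
  pm_groups <- lapply(seq_len(nrow(groups)), function(g) {
    scales <- rep(1, nrow(tree$edge))
    scales[edge_sets[[g]]] <- groups$rho[g]
    edge_pmats(model, tree, scales)
  })
  group_cols <- lapply(seq_len(nrow(groups)), function(g) {
    which(col_group == g)
  })
  preorder <- rev(postorder_edges(tree))
  for (e in preorder) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    for (g in seq_len(nrow(groups))) {
      cols <- group_cols[[g]]
      if (!length(cols)) next
      P <- matrix(pm_groups[[g]][, e], 4, 4)
      ps <- states[p, cols]
      for (s in 1:4) {
        sel <- cols[ps == s]
        if (!length(sel)) next
        states[ch, sel] <- sample.int(4L, length(sel), replace = TRUE,
                                      prob = P[s, ])
      }
    }
  }
  symbols <- matrix(DNA_BASES[states[seq_len(ntip), , drop = FALSE]],
                    ntip, L, dimnames = list(tree$tip.label, NULL))
  # planted invariant blocks: every species carries the root state
  if (!is.null(config$uce_intervals) && nrow(config$uce_intervals)) {
    for (i in seq_len(nrow(config$uce_intervals))) {
      u <- config$uce_intervals[i, ]
      idx <- (u$start + 1L):u$end
      symbols[, idx] <- matrix(DNA_BASES[states[root, idx]], ntip,
                               length(idx), byrow = TRUE)
    }
  }
  # missing data injection (reference row stays observed)
  ref_sp <- if (length(phy$clades)) clade_tips(phy, names(phy$clades)[1])[1]
            else tree$tip.label[1]
  if (config$missing_rate > 0) {
    for (sp in setdiff(tree$tip.label, ref_sp)) {
      if (config$missing_block_length > 1) {
        miss <- simulate_missing_blocks(L, config$missing_rate,
                                        config$missing_block_length)
      } else {
        miss <- runif(L) < config$missing_rate
      }
      symbols[sp, miss] <- "N"
    }
  }
  aln <- alignment_columns(symbols, seq_len(L) - 1L, ref_name = "chrSim",
                           ref_species = ref_sp)
  truth <- config$elements
  if (nrow(truth)) {
    truth$element_id <- sprintf("planted%03d", seq_len(nrow(truth)))
  }
  list(alignment = aln, truth = truth, config = config)
}

# geometric-length missing runs with approximately the requested coverage
simulate_missing_blocks <- function(L, rate, mean_len) {
  miss <- logical(L)
  n_blocks <- stats::rpois(1, L * rate / mean_len)
  if (n_blocks == 0) return(miss)
  starts <- sample.int(L, n_blocks, replace = TRUE)
  lens <- stats::rgeom(n_blocks, 1 / mean_len) + 1L
  for (i in seq_len(n_blocks)) {
    miss[starts[i]:min(L, starts[i] + lens[i] - 1L)] <- TRUE
  }
  miss
}

#' Simulate a fine-mapped variant PIP table with planted causal enrichment
#'
#' Causal variants fall inside the annotation at `causal_enrichment` times
#' the background membership rate; causal PIPs are drawn from a Beta skewed
#' towards one, non-causal PIPs from a Beta skewed towards zero, emulating
#' the two-tail structure that the PIP enrichment statistic compares.
#'
#' @param n_variants number of variants.
#' @param annotation_rate background probability of annotation membership.
#' @param causal_rate fraction of causal variants.
#' @param causal_enrichment relative annotation membership rate of causal
#'   variants (>= 0).
#' @param seed integer seed.
#' @return data.frame: variant_id, position, PIP, in_annotation, causal.
#' @export
simulate_pip_table <- function(n_variants = 20000L, annotation_rate = 0.1,
                               causal_rate = 0.02, causal_enrichment = 5,
                               seed = 1L) {
  stopifnot(causal_enrichment >= 0, annotation_rate > 0,
            annotation_rate * causal_enrichment <= 1)
  set.seed(as.integer(seed))
  causal <- runif(n_variants) < causal_rate
  p_annot <- ifelse(causal, annotation_rate * causal_enrichment,
                    annotation_rate)
  in_annotation <- runif(n_variants) < p_annot
  pip <- numeric(n_variants)
  pip[causal] <- rbeta(sum(causal), 5, 1.2)    # mass above 0.5
  pip[!causal] <- rbeta(sum(!causal), 0.08, 4) # mass below 0.01
  data.frame(variant_id = sprintf("var%06d", seq_len(n_variants)),
             position = seq_len(n_variants) * 100L,
             PIP = pip, in_annotation = in_annotation, causal = causal)
}

#' Simulate a TFBS footprint table with a length confounder
#'
#' Footprint lengths are uniform on `length_range`; each footprint is
#' assigned a motif with probability proportional to a Gaussian kernel
#' around the motif's preferred length, so motif identity is correlated
#' with length. Mammal-constraint calls depend on length through
#' `length_confounder` (shorter footprints more likely called constrained
#' in mammals, the detection bias the binned meta-analysis removes);
#' primate-constraint calls depend on the motif's planted effect.
#'
#' @param n number of footprints.
#' @param motifs character vector of motif names.
#' @param motif_effects named numeric: per-motif log-odds shift on the
#'   primate-constraint probability (default all zero).
#' @param length_confounder log-odds of mammal constraint per SD of
#'   (negative) length; 0 disables the bias.
#' @param length_range inclusive footprint length range (bp).
#' @param base_logit baseline log-odds of a constraint call.
#' @param seed integer seed.
#' @return data.frame: footprint_id, length, motif, primate_constrained,
#'   mammal_constrained, plus the per-motif truth effects as an attribute
#'   `effects`.
#' @export
simulate_footprints <- function(n = 4000L, motifs = paste0("motif", 1:8),
                                motif_effects = NULL, length_confounder = 0,
                                length_range = c(6L, 40L), base_logit = -1,
                                seed = 1L) {
  set.seed(as.integer(seed))
  effects <- setNames(rep(0, length(motifs)), motifs)
  if (!is.null(motif_effects)) {
    unknown <- setdiff(names(motif_effects), motifs)
    if (length(unknown)) stop("effects name unknown motifs: ",
                              paste(unknown, collapse = ", "))
    effects[names(motif_effects)] <- motif_effects
  }
  motif_effects <- effects
  len <- sample(length_range[1]:length_range[2], n, replace = TRUE)
  pref <- seq(length_range[1], length_range[2], length.out = length(motifs))
  motif <- vapply(len, function(l) {
    w <- stats::dnorm(l, pref, sd = 6)
    sample(motifs, 1, prob = w)
  }, "")
  z <- as.numeric(scale(len))
  p_mam <- stats::plogis(base_logit - length_confounder * z)
  p_pri <- stats::plogis(base_logit + motif_effects[motif])
  df <- data.frame(
    footprint_id = sprintf("fp%06d", seq_len(n)),
    length = len, motif = motif,
    primate_constrained = runif(n) < p_pri,
    mammal_constrained = runif(n) < p_mam,
    stringsAsFactors = FALSE
  )
  attr(df, "effects") <- motif_effects
  df
}

#' Build the default planted-element scenario
#'
#' The end-to-end benchmark: `n_planted` elements of `width` bp with the
#' clade's branches scaled by `rho`, plus `n_null` neutral decoys of the
#' same size, tiled along the sequence, with a leading neutral block of
#' `neutral_train` bp reserved for fitting the neutral background model.
#'
#' @param n_planted,n_null element counts.
#' @param width element width (bp).
#' @param rho planted rate-scale factor.
#' @param clade planted clade name.
#' @param gap spacing between consecutive elements (bp).
#' @param neutral_train leading neutral training region (bp).
#' @param missing_rate per-species missing-data rate.
#' @param seed integer seed.
#' @param phy phylogeny (default [demo_tree()]).
#' @return list: `config` (a `cd_sim_config`), `elements` (a `cd_elements`
#'   of all scored elements), `truth_ids` (ids of the planted ones),
#'   `neutral_region` (data.frame start/end).
#' @export
planted_scenario <- function(n_planted = 50L, n_null = 450L, width = 40L,
                             rho = 0.2, clade = "primates", gap = 10L,
                             neutral_train = 4000L, missing_rate = 0.1,
                             seed = 1L, phy = demo_tree()) {
  n <- n_planted + n_null
  starts <- neutral_train + (seq_len(n) - 1L) * (width + gap)
  ends <- starts + width
  # planted and null elements interleaved at random positions along the run
  set.seed(as.integer(seed))
  planted <- sample(rep(c(TRUE, FALSE), c(n_planted, n_null)))
  len <- ends[n] + gap
  elements_sim <- if (any(planted)) {
    data.frame(start = starts[planted], end = ends[planted],
               rho = rho, clade = clade)
  } else {
    NULL
  }
  config <- simulation_config(phy = phy, length = len,
                              elements = elements_sim,
                              missing_rate = missing_rate, seed = seed)
  ids <- sprintf("el%04d", seq_len(n))
  elements <- genomic_elements("chrSim", starts, ends, ids,
                               element_class = "DHS",
                               summit = as.integer((starts + ends) %/% 2L))
  list(config = config, elements = elements, truth_ids = ids[planted],
       neutral_region = data.frame(start = 0L, end = neutral_train))
}
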