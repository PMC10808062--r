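# -- pipeline orchestration ---------------------------------------------------

#' Run configuration
#'
#' Flat, typed key-value configuration for [run_pipeline()]. Defaults
#' reproduce the pipeline's standard settings: FDR alpha 0.05, Storey
#' lambda 0.5, HMM expected length 45 bp / target coverage 0.3 / conserved
#' rate scale 0.31.
#'
#' @param scenario simulation scenario (`"planted"` or `"null"`); real
#'   inputs can be supplied instead via `maf`, `tree`, `elements_bed`.
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param alpha FDR threshold.
#' @param lambda Storey pi0 tuning parameter.
#' @param expected_length,target_coverage,hmm_rho HMM segmentation settings.
#' @param n_planted,n_null,element_width,planted_rho,missing_rate planted
#'   scenario knobs.
#' @param maf,tree,elements_bed optional real input paths (overrides the
#'   simulation scenario).
#' @param uce_min_length,uce_tolerance UCE scan settings.
#' @return a `cd_run_config` list.
#' @export
run_config <- function(scenario = "planted", out_dir = "constraintdepth_run",
                       seed = 1L, alpha = 0.05, lambda = 0.5,
                       expected_length = 45, target_coverage = 0.3,
                       hmm_rho = 0.31, n_planted = 50L, n_null = 450L,
                       element_width = 40L, planted_rho = 0.2,
                       missing_rate = 0.1, maf = "", tree = "",
                       elements_bed = "", uce_min_length = 20L,
                       uce_tolerance = 0.01) {
  structure(list(
    scenario = scenario, out_dir = out_dir, seed = as.integer(seed),
    alpha = alpha, lambda = lambda, expected_length = expected_length,
    target_coverage = target_coverage, hmm_rho = hmm_rho,
    n_planted = as.integer(n_planted), n_null = as.integer(n_null),
    element_width = as.integer(element_width), planted_rho = planted_rho,
    missing_rate = missing_rate, maf = maf, tree = tree,
    elements_bed = elements_bed, uce_min_length = as.integer(uce_min_length),
    uce_tolerance = uce_tolerance
  ), class = "cd_run_config")
}

#' Write/read a run configuration (flat key=value text)
#'
#' @param config a `cd_run_config`.
#' @param path file path.
#' @return `read_run_config` returns a `cd_run_config` identical to the one
#'   written (round-trip contract).
#' @export
write_run_config <- function(config, path) {
  keys <- names(config)
  vals <- vapply(config, function(v) as.character(v), "")
  writeLines(paste0(keys, "=", vals), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), ""),
                   vapply(kv, `[[`, "", 1))
  def <- run_config()
  for (k in names(vals)) {
    if (!k %in% names(def)) stop("unknown config key: ", k)
    def[[k]] <- if (is.numeric(def[[k]])) {
      if (is.integer(def[[k]])) as.integer(vals[[k]]) else as.numeric(vals[[k]])
    } else {
      vals[[k]]
    }
  }
  class(def) <- "cd_run_config"
  def
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full constraint-depth pipeline
#'
#' Stages: simulate (or ingest) -> neutral model fit -> element-wise
#' constraint scores per clade -> phylo-HMM segmentation -> Storey FDR +
#' depth classification -> UCE scan -> truth comparison (simulated runs).
#' Outputs are written with deterministic names under `config$out_dir`,
#' together with a frozen copy of the resolved configuration and a manifest
#' (file, stage, md5 checksum).
#'
#' @param config a `cd_run_config`.
#' @param quiet suppress per-stage messages.
#' @return the manifest data.frame (invisibly gains attribute `summary`).
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_info <- function(...) if (!quiet) message("[constraintdepth] ", ...)
  manifest <- list()
  register <- function(path, stage) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = basename(path), stage = stage,
      md5 = unname(tools::md5sum(path)))
  }

  # stage: inputs
  if (nzchar(config$maf)) {
    if (!file.exists(config$maf)) {
      stop("pipeline stage 'ingest' failed: missing input ", config$maf)
    }
    aln <- pipeline_stage("ingest", read_maf(config$maf))
    phy <- pipeline_stage("ingest", {
      if (!file.exists(config$tree)) stop("missing tree file ", config$tree)
      tr <- ape::read.tree(config$tree)
      phylogeny(tr, clades = list(all = tr$tip.label))
    })
    elements <- pipeline_stage("ingest",
                               read_elements(config$elements_bed, "bed",
                                             element_class = "DHS"))
    truth_ids <- character(0)
    neutral_region <- data.frame(start = min(aln$coords),
                                 end = min(aln$coords) + 1000L)
    clades <- names(phy$clades)
  } else {
    scen <- pipeline_stage("simulate", {
      n_pl <- if (config$scenario == "null") 0L else config$n_planted
      planted_scenario(n_planted = n_pl, n_null = config$n_null,
                       width = config$element_width,
                       rho = config$planted_rho,
                       missing_rate = config$missing_rate,
                       seed = config$seed)
    })
    sim <- pipeline_stage("simulate", simulate_alignment(scen$config))
    aln <- sim$alignment
    phy <- scen$config$phy
    elements <- scen$elements
    truth_ids <- scen$truth_ids
    neutral_region <- scen$neutral_region
    # depth scoring uses disjoint clades: constraint "in mammals" is tested
    # on the non-primate mammals, "in vertebrates" on the outgroup, so a
    # primate-only signal does not leak into the deeper tests
    clades <- c("primates", "mammals_np", "outgroup")
    maf_path <- file.path(config$out_dir, "alignment.maf")
    write_maf(aln, maf_path); register(maf_path, "simulate")
    tree_path <- file.path(config$out_dir, "tree.nwk")
    ape::write.tree(phy$tree, tree_path); register(tree_path, "simulate")
    truth_path <- file.path(config$out_dir, "truth.tsv")
    truth <- data.frame(element_id = elements$element_id,
                        planted = elements$element_id %in% truth_ids)
    write.table(truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE); register(truth_path, "simulate")
    log_info("simulated ", nrow(elements), " elements (",
             length(truth_ids), " planted) over ", ncol(aln$symbols), " bp")
  }
  bed_path <- file.path(config$out_dir, "elements.bed")
  write_elements(elements, bed_path); register(bed_path, "inputs")

  # stage: neutral fit (seeded subsample of the designated neutral region)
  fit <- pipeline_stage("fit-neutral", {
    fit_neutral_subsample(aln, phy, neutral_region$start[1],
                          neutral_region$end[1], seed = config$seed)
  })
  model_path <- file.path(config$out_dir, "neutral_model.txt")
  write_model(fit$model, model_path, tree_scale = fit$tree_scale)
  register(model_path, "fit-neutral")
  log_info("neutral model fitted: logLik ", round(fit$loglik, 1),
           ", tree scale ", signif(fit$tree_scale, 3))

  # stage: phyloP element scores per clade
  scores <- pipeline_stage("phylop", {
    lapply(setNames(clades, clades), function(cl) {
      phylop_elements(aln, phy, fit$model, clade = cl, elements = elements,
                      tree_scale = fit$tree_scale)
    })
  })
  for (cl in clades) {
    p <- file.path(config$out_dir, paste0("phylop_", cl, ".tsv"))
    write.table(scores[[cl]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    register(p, "phylop")
  }

  # stage: phastCons segmentation
  seg <- pipeline_stage("phastcons", {
    phastcons_segment(aln, phy, fit$model,
                      hmm_params(config$expected_length,
                                 config$target_coverage, config$hmm_rho),
                      tree_scale = fit$tree_scale)
  })
  seg_path <- file.path(config$out_dir, "phastcons_segments.bed")
  write.table(seg$segments[, c("chrom", "start", "end", "mean_posterior",
                               "score")],
              seg_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  register(seg_path, "phastcons")
  log_info("phastCons: ", nrow(seg$segments), " conserved segments")

  # stage: classify (needs the three nested clades)
  calls <- if (length(clades) < 3) NULL else pipeline_stage("classify", {
    qs <- lapply(scores, function(s) {
      q <- storey_qvalues(s$p_value, lambda = config$lambda)$q_values
      q[s$rho >= 1 & !is.na(s$rho)] <- 1 # constraint calls only
      q
    })
    ov <- uce_overlap(seg$segments, elements)$flags
    classify_depth(qs[[1]], qs[[2]], qs[[3]],
                   phastcons_overlap = ov, alpha = config$alpha,
                   element_id = elements$element_id)
  })
  if (!is.null(calls)) {
    calls_path <- file.path(config$out_dir, "depth_calls.tsv")
    write.table(calls, calls_path, sep = "\t", quote = FALSE, row.names = FALSE)
    register(calls_path, "classify")
    log_info("depth calls: ",
             paste(names(table(calls$category)), as.integer(table(calls$category)),
                   sep = "=", collapse = ", "))
  }

  # stage: UCE scan
  uces <- pipeline_stage("uce", find_uces(aln, config$uce_min_length,
                                          mode = "relaxed",
                                          tolerance = config$uce_tolerance))
  uce_path <- file.path(config$out_dir, "uces.bed")
  write.table(uces, uce_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  register(uce_path, "uce")

  # stage: truth comparison (simulated runs only)
  summary <- NULL
  if (length(truth_ids)) {
    called <- calls$element_id[calls$category == DEPTH_CATEGORIES[2]]
    tp <- sum(called %in% truth_ids)
    summary <- data.frame(
      n_elements = nrow(elements), n_planted = length(truth_ids),
      n_called_primate = length(called), true_positives = tp,
      sensitivity = tp / max(1, length(truth_ids)),
      fdr = if (length(called)) 1 - tp / length(called) else 0)
    sum_path <- file.path(config$out_dir, "truth_comparison.tsv")
    write.table(summary, sum_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    register(sum_path, "compare")
    log_info("sensitivity ", round(summary$sensitivity, 3), ", FDR ",
             round(summary$fdr, 3))
  }

  cfg_path <- file.path(config$out_dir, "resolved_config.txt")
  write_run_config(config, cfg_path); register(cfg_path, "config")
  manifest <- do.call(rbind, manifest)
  man_path <- file.path(config$out_dir, "manifest.tsv")
  write.table(manifest, man_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  attr(manifest, "summary") <- summary
  invisible(manifest)
}
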