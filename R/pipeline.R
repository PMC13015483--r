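#' Default end-to-end pipeline configuration
#'
#' @param seed Root seed; every stage derives its own substream from it.
#' @param n_per_group Cohort sizes.
#' @param spec An [effect_spec()] for the synthetic matrices.
#' @param stages Stages to run, in dependency order.
#' @return A named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L,
                            n_per_group = c(EE = 21, RE = 24, CON = 12),
                            spec = NULL,
                            stages = c("simulate", "preprocess",
                                       "differential", "enrichment",
                                       "wgcna", "fcm", "ssec")) {
  list(seed = seed, n_per_group = n_per_group,
       spec = spec %||% effect_spec(seed = seed + 1L), stages = stages,
       fcm_clusters = 4L, wgcna_beta = 6, ssec_animals = 20L)
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the requested stages on a synthetic cohort in dependency
#' order: cohort + matrix simulation, preprocessing (count filter, TMM,
#' proteomics quantification filter), difference-in-changes differential
#' analysis, competitive set enrichment of the z-score matrix, baseline
#' co-expression modules, fuzzy c-means trajectories, and two-tissue Ssec
#' scoring. A stage failure halts its dependents with a clear message.
#' Deterministic given the config seed.
#'
#' @param config A [pipeline_config()].
#' @return A manifest list: per-stage outputs plus `seed` and timing.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t0 <- Sys.time()
  out <- list(seed = config$seed)
  need <- function(stage, dep) {
    if (is.null(out[[dep]])) {
      stop("stage '", stage, "' requires output of stage '", dep,
           "' which has not run")
    }
  }
  stages <- config$stages
  if ("simulate" %in% stages) {
    out$design <- generate_cohort(config$n_per_group, seed = config$seed)
    sim <- generate_omics(out$design, config$spec)
    out$matrices <- sim$matrices
    out$truth <- sim$truth
  }
  if ("preprocess" %in% stages) {
    need("preprocess", "matrices")
    counts <- out$matrices$transcript
    if (!is.null(counts)) {
      kept <- filter_low_expression(counts, rule = "conventional")
      out$logcpm <- normalize_tmm(kept)
      out$matrices$transcript_filtered <- kept
    }
    if (!is.null(out$matrices$protein)) {
      out$matrices$protein <- filter_min_quantified(out$matrices$protein)
    }
  }
  if ("differential" %in% stages) {
    need("differential", "matrices")
    m <- out$matrices$protein %||% out$matrices[[1L]]
    out$differential <- fit_differential(
      m, out$design, families = "difference_in_changes",
      covariates = c("age", "sex"))
    out$zscore <- build_zscore_matrix(
      dplyr::filter(out$differential, .data$testable))
  }
  if ("enrichment" %in% stages) {
    need("enrichment", "zscore")
    universe <- rownames(out$zscore)
    set.seed(config$seed + 2L)
    sets <- lapply(stats::setNames(seq_len(10L), paste0("SET", 1:10)),
                   function(i) sample(universe, min(25L, length(universe))))
    coll <- filter_sets(set_collection(sets, "pathway"), universe)
    out$enrichment <- camera_pr(out$zscore[, 1L], coll)
  }
  if ("wgcna" %in% stages) {
    need("wgcna", "matrices")
    m <- out$matrices$protein %||% out$matrices[[1L]]
    pre_ids <- out$design$sample_id[out$design$timepoint == "pre"]
    baseline <- values_of(m)[, intersect(colnames(m), pre_ids), drop = FALSE]
    baseline <- baseline[stats::complete.cases(baseline), , drop = FALSE]
    out$modules <- build_modules(baseline, beta = config$wgcna_beta,
                                 min_module_size = 10)
  }
  if ("fcm" %in% stages) {
    need("fcm", "zscore")
    Xs <- stack_and_scale(out$zscore)
    if (nrow(Xs) > config$fcm_clusters + 2L) {
      out$fcm <- fuzzy_cmeans(Xs, c = config$fcm_clusters,
                              seed = config$seed + 3L)
      out$fcm_labels <- hard_assign(out$fcm)
    }
  }
  if ("ssec" %in% stages) {
    tt <- generate_two_tissue(config$ssec_animals, n_origin_genes = 50,
                              n_target_genes = 100,
                              seed = config$seed + 4L)
    out$ssec <- ssec(tt$origin, tt$target, adjust = tt$sex)
    out$ssec_truth <- tt$truth
  }
  out$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  out$stages_run <- stages
  out
}
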