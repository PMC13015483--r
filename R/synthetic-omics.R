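# Trajectory archetypes over the three post-exercise timepoints
# (45min, 4hr, 24hr): early-transient, mid-peak, late-rise, sustained.
archetype_patterns <- function(n_clusters) {
  base <- rbind(c(1.0, 0.3, 0.0),
                c(0.3, 1.0, 0.2),
                c(0.0, 0.4, 1.0),
                c(0.8, 0.8, 0.8),
                c(1.0, -0.5, 0.0),
                c(-0.3, 1.0, 0.5))
  colnames(base) <- c("45min", "4hr", "24hr")
  base[rep_len(seq_len(nrow(base)), n_clusters), , drop = FALSE]
}

# Unit-variance latent noise with participant random intercept:
# within-participant correlation = ri_sd^2 / (1 + ri_sd^2).
latent_noise <- function(n_rows, design, ri_sd) {
  pid <- match(design$participant_id, unique(design$participant_id))
  U <- matrix(stats::rnorm(n_rows * max(pid)), n_rows)
  E <- matrix(stats::rnorm(n_rows * nrow(design)), n_rows)
  (ri_sd * U[, pid, drop = FALSE] + E) / sqrt(ri_sd^2 + 1)
}

#' Generate multi-omic matrices with planted structure
#'
#' Produces one feature-by-sample matrix per ome (transcript counts;
#' log-scale protein, phosphosite and metabolite abundances) whose
#' statistical structure matches what the downstream stages assume: a
#' participant random intercept, correlated module blocks, non-normal
#' marginals, difference-in-changes effects confined to the exercise
#' groups' post samples with temporal archetypes, sex effects, and optional
#' missingness. A truth table records every planted label for
#' parameter-recovery testing.
#'
#' @param design A cohort design from [generate_cohort()].
#' @param spec An [effect_spec()].
#' @return A list with `matrices` (named list of [omics_matrix()] objects)
#'   and `truth` (tibble: `feature_id`, `ome`, `gene_symbol`,
#'   `is_dd_affected`, `dd_effect`, `module_label`, `cluster_label`,
#'   `is_secreted`, `is_sex_affected`).
#' @export
generate_omics <- function(design, spec = effect_spec()) {
  stopifnot(inherits(spec, "exermap_effect_spec"))
  if (nrow(design) == 0L) stop("empty design")
  set.seed(spec$seed)
  cf <- fleishman_coef(spec$skew, spec$kurt)
  post_cols <- c("45min", "4hr", "24hr")
  arch <- archetype_patterns(spec$n_clusters)
  is_male <- design$sex == "M"
  is_ex_post <- design$group %in% c("EE", "RE") & design$timepoint != "pre"

  gen_ome <- function(ome, n_feat) {
    if (spec$n_modules * spec$module_size > n_feat) {
      stop("module_size x n_modules (", spec$n_modules * spec$module_size,
           ") exceeds n_features (", n_feat, ") for ome ", ome)
    }
    noise <- latent_noise(n_feat, design, spec$ri_sd)
    module_label <- rep(NA_character_, n_feat)
    if (spec$n_modules > 0L && spec$module_size > 0L) {
      shared <- latent_noise(spec$n_modules, design, spec$ri_sd)
      for (m in seq_len(spec$n_modules)) {
        idx <- seq.int((m - 1L) * spec$module_size + 1L, m * spec$module_size)
        noise[idx, ] <- sqrt(spec$module_cor) *
          matrix(shared[m, ], length(idx), nrow(design), byrow = TRUE) +
          sqrt(1 - spec$module_cor) * noise[idx, , drop = FALSE]
        module_label[idx] <- paste0("M", m)
      }
    }
    # non-normal marginals (polynomial transform of the standard-normal latent)
    X <- cf["a"] + cf["b"] * noise + cf["c"] * noise^2 + cf["d"] * noise^3

    n_dd <- round(spec$frac_dd_affected * n_feat)
    dd_idx <- if (n_dd > 0) sample.int(n_feat, n_dd) else integer()
    dd_eff <- rep(0, n_feat)
    cluster_label <- rep(NA_character_, n_feat)
    if (n_dd > 0) {
      sgn <- rep_len(c(1, -1), n_dd)
      dd_eff[dd_idx] <- sgn * spec$dd_effect
      cl <- rep_len(seq_len(spec$n_clusters), n_dd)
      cluster_label[dd_idx] <- paste0("C", cl)
      tp_mult <- arch[cl, , drop = FALSE]
      for (k in seq_along(dd_idx)) {
        f <- dd_idx[k]
        mult <- tp_mult[k, match(design$timepoint, post_cols)]
        mult[is.na(mult)] <- 0
        X[f, ] <- X[f, ] + dd_eff[f] * mult * is_ex_post
      }
    }
    n_sex <- round(0.05 * n_feat)
    sex_idx <- if (n_sex > 0) sample.int(n_feat, n_sex) else integer()
    if (n_sex > 0) {
      X[sex_idx, ] <- X[sex_idx, , drop = FALSE] +
        spec$sex_effect * matrix(is_male, n_sex, nrow(design), byrow = TRUE)
    }

    prefix <- c(transcript = "TX", protein = "PR", phosphosite = "PH",
                metabolite = "MB")[[ome]]
    feature_id <- sprintf("%s%04d", prefix, seq_len(n_feat))
    gene <- sprintf("GENE%04d", seq_len(n_feat))
    if (ome == "phosphosite") {
      feature_id <- sprintf("%s_S%d", gene, 100 + seq_len(n_feat))
    }
    rownames(X) <- feature_id
    colnames(X) <- design$sample_id

    if (ome == "transcript") {
      mu <- exp(stats::runif(n_feat, log(2), log(2000)))
      u <- stats::pnorm(scale_rows(X))
      u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
      X <- matrix(stats::qnbinom(u, size = 2, mu = mu), n_feat,
                  dimnames = dimnames(u))
      scale <- "raw"
    } else {
      scale <- "log2"
      if (spec$missing_frac > 0 && ome %in% c("protein", "phosphosite")) {
        X[stats::runif(length(X)) < spec$missing_frac] <- NA_real_
      }
    }
    meta <- tibble::tibble(
      feature_id = feature_id,
      gene_symbol = if (ome == "metabolite") NA_character_ else gene,
      refmet_id = if (ome == "metabolite") paste0("REFMET:", feature_id)
                  else NA_character_,
      class = if (ome == "metabolite") {
        sample(c("Saturated fatty acids", "Ceramides", "Amino acids",
                 "Phosphatidylcholines", "Acyl carnitines"),
               n_feat, replace = TRUE)
      } else NA_character_,
      platform = if (ome == "metabolite") {
        sample(c("hilicpos", "rppos"), n_feat, replace = TRUE)
      } else NA_character_
    )
    secreted <- if (ome %in% c("transcript", "protein")) {
      stats::runif(n_feat) < 0.1
    } else rep(FALSE, n_feat)
    truth <- tibble::tibble(
      feature_id = feature_id, ome = ome, gene_symbol = meta$gene_symbol,
      is_dd_affected = dd_eff != 0, dd_effect = dd_eff,
      module_label = module_label, cluster_label = cluster_label,
      is_secreted = secreted,
      is_sex_affected = seq_len(n_feat) %in% sex_idx
    )
    list(mat = omics_matrix(X, ome = ome, scale = scale, feature_meta = meta),
         truth = truth)
  }

  omes <- names(spec$n_features_per_ome)
  out <- purrr::map(omes, function(o) gen_ome(o, spec$n_features_per_ome[[o]]))
  names(out) <- omes
  list(matrices = purrr::map(out, "mat"),
       truth = purrr::list_rbind(purrr::map(out, "truth")))
}

#' Generate a two-tissue expression pair with one planted endocrine driver
#'
#' Simulates origin-tissue and target-tissue gene-by-animal expression
#' matrices in which exactly one origin gene (the planted driver) correlates
#' with a stated fraction of target genes at the requested strength; all
#' other origin genes are independent of the target tissue. Sex is a
#' balanced covariate; `sex_confound > 0` adds a shared sex shift to both
#' tissues, planting a spurious correlation that sex adjustment should
#' remove.
#'
#' @param n_animals Number of animals (columns); at least 6.
#' @param n_origin_genes,n_target_genes Gene counts.
#' @param driver_strength Correlation in `(0, 1)` between the driver and
#'   each affected target gene (use 0 for a null dataset).
#' @param affected_frac Fraction of target genes driven by the driver.
#' @param sex_confound Standardized sex shift added to every gene in both
#'   tissues (0 = none).
#' @param seed Integer seed.
#' @return List with `origin`, `target` (gene x animal matrices), `sex`
#'   (character vector), and `truth` (`driver`, `affected_targets`).
#' @export
generate_two_tissue <- function(n_animals, n_origin_genes = 200,
                                n_target_genes = 500, driver_strength = 0.8,
                                affected_frac = 0.5, sex_confound = 0,
                                seed = 1L) {
  if (n_animals < 6) stop("n_animals must be at least 6")
  if (driver_strength < 0 || driver_strength >= 1) {
    stop("driver_strength must lie in [0, 1)")
  }
  set.seed(seed)
  sex <- rep_len(c("F", "M"), n_animals)
  origin <- matrix(stats::rnorm(n_origin_genes * n_animals), n_origin_genes,
                   dimnames = list(sprintf("OG%04d", seq_len(n_origin_genes)),
                                   sprintf("A%03d", seq_len(n_animals))))
  target <- matrix(stats::rnorm(n_target_genes * n_animals), n_target_genes,
                   dimnames = list(sprintf("TG%04d", seq_len(n_target_genes)),
                                   colnames(origin)))
  driver <- sample(rownames(origin), 1L)
  n_aff <- round(affected_frac * n_target_genes)
  affected <- if (n_aff > 0) sample(rownames(target), n_aff) else character()
  if (driver_strength > 0 && n_aff > 0) {
    d <- as.numeric(scale(origin[driver, ]))
    target[affected, ] <- driver_strength *
      matrix(d, n_aff, n_animals, byrow = TRUE) +
      sqrt(1 - driver_strength^2) * target[affected, , drop = FALSE]
  }
  if (sex_confound != 0) {
    shift <- sex_confound * (sex == "M")
    origin <- origin + matrix(shift, n_origin_genes, n_animals, byrow = TRUE)
    target <- target + matrix(shift, n_target_genes, n_animals, byrow = TRUE)
  }
  list(origin = origin, target = target, sex = sex,
       truth = list(driver = driver, affected_targets = affected))
}

# row-standardize (mean 0, sd 1); constant rows pass through as zeros
scale_rows <- function(X) {
  m <- rowMeans(X)
  s <- apply(X, 1L, stats::sd)
  s[s == 0] <- 1
  (X - m) / s
}
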