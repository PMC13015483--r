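# QC bookkeeping: one row per step, input = output + removed at every step.
qc_step <- function(step, n_in, n_removed, note = "") {
  tibble::tibble(step = step, n_in = n_in, n_removed = n_removed,
                 n_out = n_in - n_removed, note = note)
}

values_of <- function(m) {
  if (inherits(m, "exermap_omics")) unclass(m) else as.matrix(m)
}

#' Clean a raw metabolomics matrix
#'
#' Applies the metabolomics cleaning steps in order: rows sharing a feature
#' ID are averaged; zero and negative intensities become missing; features
#' missing in more than `max_missing` of samples are removed; remaining
#' missing values are imputed (K-nearest-neighbour over samples when the
#' dataset has more than `knn_min_features` features, half-minimum
#' otherwise); values are `log2(x + 1)` transformed so intensities in (0, 1)
#' stay positive on the log scale.
#'
#' @param m Raw-scale matrix (features x samples); duplicated rownames are
#'   allowed and averaged.
#' @param max_missing Maximum tolerated missing fraction per feature.
#' @param knn_min_features KNN imputation is used when the retained feature
#'   count exceeds this; otherwise each feature's missing values are set to
#'   half its minimum observed value.
#' @param k Neighbour count for KNN imputation.
#' @return List with `matrix` (cleaned log2-scale matrix) and `qc` (tibble
#'   of per-step feature counts).
#' @export
clean_metabolites <- function(m, max_missing = 0.20, knn_min_features = 12,
                              k = 10) {
  X <- values_of(m)
  qc <- qc_step("input", nrow(X), 0L)
  if (anyDuplicated(rownames(X))) {
    ids <- rownames(X)
    X <- rowsum(X, ids, na.rm = TRUE) / rowsum((!is.na(X)) * 1, ids)
    X[!is.finite(X)] <- NA_real_
    qc <- rbind(qc, qc_step("average_duplicates", qc$n_out[nrow(qc)],
                            qc$n_out[nrow(qc)] - nrow(X),
                            "rows with the same ID averaged"))
  }
  X[X <= 0] <- NA_real_
  miss <- rowMeans(is.na(X))
  keep <- miss <= max_missing
  qc <- rbind(qc, qc_step("missingness_filter", nrow(X), sum(!keep),
                          paste0("> ", 100 * max_missing, "% missing")))
  X <- X[keep, , drop = FALSE]
  if (nrow(X) == 0L) stop("all features removed by the missingness filter")
  if (anyNA(X)) {
    if (nrow(X) > knn_min_features) {
      X <- knn_impute(X, k = k)
      note <- paste0("KNN, k=", k)
    } else {
      hm <- apply(X, 1L, function(v) min(v, na.rm = TRUE) / 2)
      idx <- which(is.na(X), arr.ind = TRUE)
      X[idx] <- hm[idx[, 1L]]
      note <- "half-minimum"
    }
    qc <- rbind(qc, qc_step("imputation", nrow(X), 0L, note))
  }
  X <- log2(X + 1)
  qc <- rbind(qc, qc_step("log2", nrow(X), 0L, "log2(x + 1)"))
  list(matrix = X, qc = qc)
}

# KNN imputation over samples: a missing value of feature f in sample s is
# the mean of that feature in the k nearest samples (Euclidean distance on
# shared features) that observe it.
knn_impute <- function(X, k = 10) {
  D <- as.matrix(stats::dist(t(scale_rows_na(X))))
  diag(D) <- Inf
  for (s in which(colSums(is.na(X)) > 0)) {
    ord <- order(D[, s])
    for (f in which(is.na(X[, s]))) {
      donors <- ord[!is.na(X[f, ord])]
      if (length(donors) == 0L) {
        X[f, s] <- mean(X[f, ], na.rm = TRUE)
      } else {
        X[f, s] <- mean(X[f, donors[seq_len(min(k, length(donors)))]])
      }
    }
  }
  X
}

scale_rows_na <- function(X) {
  m <- rowMeans(X, na.rm = TRUE)
  s <- apply(X, 1L, stats::sd, na.rm = TRUE)
  s[!is.finite(s) | s == 0] <- 1
  X <- (X - m) / s
  X[is.na(X)] <- 0
  X
}

#' Gated per-sample median/MAD normalization
#'
#' Normalizes each sample (centre by its median, scale by its MAD) only if
#' neither the sample medians nor the sample upper quartiles are associated
#' with sex or with sex-stratified exercise group (Kruskal-Wallis
#' p < `gate_p` blocks normalization). The gating decision and the four gate
#' p-values are recorded.
#'
#' @param m Log-scale matrix (features x samples).
#' @param design Sample design with `sample_id`, `sex`, `group`.
#' @param gate_p Gate threshold on the Kruskal-Wallis p-values.
#' @return List with `matrix`, `applied` (logical), and `gate` (tibble of
#'   statistic x factor p-values).
#' @export
conditional_median_mad_normalize <- function(m, design, gate_p = 0.01) {
  X <- values_of(m)
  design <- design[match(colnames(X), design$sample_id), ]
  meds <- apply(X, 2L, stats::median, na.rm = TRUE)
  uq <- apply(X, 2L, stats::quantile, probs = 0.75, na.rm = TRUE)
  kw <- function(y, g) {
    g <- factor(g)
    if (nlevels(g) < 2L) {
      warning("fewer than 2 levels for the normalization gate; gate skipped")
      return(1)
    }
    stats::kruskal.test(y, g)$p.value
  }
  strat <- interaction(design$sex, design$group, drop = TRUE)
  gate <- tibble::tibble(
    statistic = rep(c("median", "upper_quartile"), each = 2L),
    factor = rep(c("sex", "sex_by_group"), 2L),
    p = c(kw(meds, design$sex), kw(meds, strat),
          kw(uq, design$sex), kw(uq, strat))
  )
  applied <- all(gate$p >= gate_p)
  if (applied) {
    mads <- apply(X, 2L, stats::mad, na.rm = TRUE)
    mads[mads == 0] <- 1 # degenerate sample: centre only
    X <- sweep(sweep(X, 2L, meds, "-"), 2L, mads, "/")
  }
  list(matrix = X, applied = applied, gate = gate)
}

#' Flag principal-component outlier samples
#'
#' Projects samples onto principal components, and for every retained
#' component (variance explained at least `var_min`) flags samples falling
#' outside the boxplot whiskers extended to `iqr_mult` times the
#' interquartile range. The union over components is returned.
#'
#' @param m Complete (imputed) matrix, features x samples.
#' @param iqr_mult Whisker multiplier on the IQR (default 5).
#' @param var_min Minimum fraction of variance for a component to be
#'   examined.
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
flag_pc_outliers <- function(m, iqr_mult = 5, var_min = 0.01) {
  X <- values_of(m)
  if (ncol(X) < 3L) {
    warning("fewer than 3 samples; no outlier flagging")
    return(character())
  }
  pc <- stats::prcomp(t(X), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- which(ve >= var_min)
  flagged <- character()
  for (j in keep) {
    s <- pc$x[, j]
    q <- stats::quantile(s, c(0.25, 0.75))
    iqr <- q[2L] - q[1L]
    out <- s < q[1L] - iqr_mult * iqr | s > q[2L] + iqr_mult * iqr
    flagged <- union(flagged, colnames(X)[out])
  }
  flagged
}

#' Resolve metabolites measured on multiple platforms
#'
#' When the same RefMet ID is quantified on several platforms, keeps the
#' platform with the lowest mean coefficient of variation across reference
#' standards; ties break to the lexicographically first platform, and a
#' missing CV entry falls back to keeping the first platform (with a
#' warning).
#'
#' @param features Tibble with `refmet_id` and `platform` (one row per
#'   measured feature).
#' @param standards_cv Tibble with `platform` and `cv` (one row per
#'   reference standard measurement).
#' @return `features` with logical `keep` and a `reason` column.
#' @export
resolve_platform_redundancy <- function(features, standards_cv) {
  mean_cv <- standards_cv |>
    dplyr::group_by(.data$platform) |>
    dplyr::summarise(cv = mean(.data$cv), .groups = "drop")
  features |>
    dplyr::group_by(.data$refmet_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) == 1L) {
        return(dplyr::mutate(d, keep = TRUE, reason = "single platform"))
      }
      d <- dplyr::arrange(d, .data$platform)
      cvs <- mean_cv$cv[match(d$platform, mean_cv$platform)]
      if (anyNA(cvs)) {
        warning("missing CV for refmet ", key$refmet_id,
                "; keeping first platform")
        pick <- 1L
        reason <- "fallback: missing CV"
      } else {
        pick <- which.min(cvs) # which.min takes the first on ties
        reason <- if (sum(cvs == min(cvs)) > 1L) {
          "tie: lexicographically first platform"
        } else "lowest mean CV"
      }
      dplyr::mutate(d, keep = dplyr::row_number() == pick, reason = reason)
    }) |>
    dplyr::ungroup()
}

#' Filter lowly expressed genes from a count matrix
#'
#' Default (`rule = "literal"`) removes a gene when its counts per million
#' are at or below `cpm_threshold` in at least `sample_frac` of samples.
#' `rule = "conventional"` applies the usual reading — keep a gene only if
#' it exceeds the CPM threshold in at least `sample_frac` of samples.
#'
#' @param counts Raw count matrix (genes x samples).
#' @param cpm_threshold CPM threshold (default 0.5).
#' @param sample_frac Sample fraction (default 0.10).
#' @param rule `"literal"` or `"conventional"` (see Details).
#' @return The filtered count matrix.
#' @export
filter_low_expression <- function(counts, cpm_threshold = 0.5,
                                  sample_frac = 0.10,
                                  rule = c("literal", "conventional")) {
  rule <- match.arg(rule)
  X <- values_of(counts)
  lib <- colSums(X)
  if (any(lib == 0)) stop("sample(s) with zero library size: ",
                          paste(colnames(X)[lib == 0], collapse = ", "))
  cpm <- sweep(X, 2L, lib, "/") * 1e6
  low_frac <- rowMeans(cpm <= cpm_threshold)
  keep <- if (rule == "literal") low_frac < sample_frac
          else (1 - low_frac) >= sample_frac
  out <- X[keep, , drop = FALSE]
  if (inherits(counts, "exermap_omics")) out <- rewrap_omics(out, counts)
  out
}

#' Filter proteomics features by quantification rate
#'
#' Removes features quantified in fewer than `min_frac` of samples; the
#' boundary (exactly `min_frac`) is kept.
#'
#' @param m Log-ratio matrix with missing cells.
#' @param min_frac Minimum quantified fraction (default 0.30).
#' @return The filtered matrix.
#' @export
filter_min_quantified <- function(m, min_frac = 0.30) {
  X <- values_of(m)
  keep <- rowMeans(!is.na(X)) >= min_frac
  out <- X[keep, , drop = FALSE]
  if (inherits(m, "exermap_omics")) out <- rewrap_omics(out, m)
  out
}

#' TMM normalization to log counts per million
#'
#' Trimmed-mean-of-M-values scaling factors followed by log2-CPM, via edgeR.
#'
#' @param counts Raw count matrix.
#' @return Log2-CPM matrix.
#' @export
normalize_tmm <- function(counts) {
  X <- values_of(counts)
  # the TMM asymptotic-variance weights emit NaN warnings for zero counts
  # at small sample counts; the scaling factors themselves are finite
  d <- suppressWarnings(edgeR::calcNormFactors(edgeR::DGEList(X)))
  edgeR::cpm(d, log = TRUE)
}

#' Remove technical covariate effects while protecting the design
#'
#' Estimates technical-covariate coefficients jointly with the protected
#' biological design (so biological variance is not absorbed), then
#' subtracts only the technical contribution. A technical covariate that is
#' collinear with the protected design is skipped with a warning — its
#' effect cannot be separated from biology.
#'
#' @param m Matrix, features x samples (log scale).
#' @param technical Data frame of technical covariates (one row per sample,
#'   aligned to `colnames(m)` via a `sample_id` column or row order).
#' @param protected Data frame of protected design columns, same alignment.
#' @return List with `matrix` (residualized) and `skipped` (character
#'   vector of technical covariates left untouched).
#' @export
regress_technical <- function(m, technical, protected) {
  X <- values_of(m)
  align <- function(d) {
    d <- as.data.frame(d)
    if ("sample_id" %in% names(d)) {
      d <- d[match(colnames(X), d$sample_id), setdiff(names(d), "sample_id"),
             drop = FALSE]
    }
    stopifnot(nrow(d) == ncol(X))
    d
  }
  protected <- align(protected)
  P <- stats::model.matrix(~ ., data = protected)
  if (is.null(technical) || ncol(as.data.frame(technical)) == 0L) {
    return(list(matrix = X, skipped = character()))
  }
  technical <- align(technical)
  skipped <- character()
  tech_blocks <- list()
  for (nm in names(technical)) {
    Tm <- stats::model.matrix(~ ., data = technical[nm])[, -1L, drop = FALSE]
    if (qr(cbind(P, Tm))$rank < qr(P)$rank + ncol(Tm)) {
      warning("technical covariate '", nm,
              "' is collinear with the protected design; skipped")
      skipped <- c(skipped, nm)
    } else {
      tech_blocks[[nm]] <- Tm
      P <- cbind(P, Tm) # keep later collinearity checks cumulative
    }
  }
  if (length(tech_blocks) == 0L) return(list(matrix = X, skipped = skipped))
  Pb <- stats::model.matrix(~ ., data = protected)
  Tmat <- do.call(cbind, tech_blocks)
  D <- cbind(Pb, Tmat)
  coef <- t(qr.coef(qr(D), t(X)))
  coef[is.na(coef)] <- 0
  tech_cols <- seq.int(ncol(Pb) + 1L, ncol(D))
  res <- X - coef[, tech_cols, drop = FALSE] %*% t(Tmat)
  list(matrix = res, skipped = skipped)
}
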