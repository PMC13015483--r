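cell_name <- function(group, timepoint) paste(group, timepoint, sep = "_")

# Cell-means fixed-effect design (group x timepoint indicators) plus
# centred covariate columns; factors expand to treatment-coded dummies.
build_cellmeans_X <- function(design, covariates) {
  cell <- factor(cell_name(design$group, design$timepoint))
  X <- stats::model.matrix(~ 0 + cell)
  colnames(X) <- levels(cell)
  for (cv in covariates) {
    v <- design[[cv]]
    if (is.null(v)) stop("covariate '", cv, "' not found in design")
    if (is.numeric(v)) {
      M <- matrix(v - mean(v), ncol = 1L, dimnames = list(NULL, cv))
      X <- cbind(X, M)
    } else {
      f <- factor(v)
      if (nlevels(f) < 2L) next
      M <- stats::model.matrix(~ f)[, -1L, drop = FALSE]
      colnames(M) <- paste0(cv, levels(f)[-1L])
      X <- cbind(X, M)
    }
  }
  as.matrix(X)
}

#' Fit the per-feature cell-means mixed model
#'
#' Fits one molecular feature's abundances with fixed group-by-timepoint
#' cell means plus demographic covariates and a participant random
#' intercept, by REML (profiled variance ratio). Contrast tests use
#' Satterthwaite denominator degrees of freedom. A boundary fit
#' (random-intercept variance estimated at zero) is flagged `singular` and
#' reduces to (weighted) ordinary least squares.
#'
#' @param y Numeric feature values, aligned with `design` rows (names, if
#'   present, must match `design$sample_id`).
#' @param design Sample design tibble (see [generate_cohort()]).
#' @param covariates Character vector of design columns to adjust for.
#' @param weights Optional per-observation precision weights.
#' @return An `exermap_lmmfit` object; see [contrast_cellmeans()].
#' @export
fit_feature <- function(y, design, covariates = c("age", "sex", "bmi", "site"),
                        weights = NULL) {
  if (!is.null(names(y))) {
    stopifnot(all(design$sample_id %in% names(y)))
    y <- y[design$sample_id]
  }
  ok <- is.finite(y)
  y <- y[ok]
  design <- design[ok, , drop = FALSE]
  if (!is.null(weights)) weights <- weights[ok]
  if (sum(table(design$participant_id) >= 2L) < 2L) {
    stop("need at least 2 participants with repeated measures")
  }
  X <- build_cellmeans_X(design, covariates)
  d <- ri_design(X, design$participant_id, w = weights)
  fit <- ri_fit(d, y)
  attr(fit, "cells") <- grep("_", names(fit$beta), value = TRUE)
  fit
}

# Contrast vector over the fitted coefficients; NULL if a cell is missing.
contrast_vector <- function(fit, family, group, timepoint) {
  cn <- names(fit$beta)
  cvec <- stats::setNames(numeric(length(cn)), cn)
  add <- function(cell, wt) {
    if (!cell %in% cn) return(FALSE)
    cvec[cell] <<- cvec[cell] + wt
    TRUE
  }
  ok <- switch(family,
    difference_in_changes =
      add(cell_name(group, timepoint), 1) &&
      add(cell_name(group, "pre"), -1) &&
      add(cell_name("CON", timepoint), -1) &&
      add(cell_name("CON", "pre"), 1),
    group_specific =
      add(cell_name(group, timepoint), 1) &&
      add(cell_name(group, "pre"), -1),
    modality =
      add(cell_name("EE", timepoint), 1) &&
      add(cell_name("EE", "pre"), -1) &&
      add(cell_name("RE", timepoint), -1) &&
      add(cell_name("RE", "pre"), 1),
    stop("unknown contrast family: ", family)
  )
  if (!ok) NULL else cvec
}

#' Test a contrast of cell means
#'
#' Evaluates one of the three contrast families on a fitted cell-means
#' model: `difference_in_changes` (the "delta-delta" — an exercise group's
#' pre-to-post change minus the control group's change over the same
#' interval), `group_specific` (a group's own pre-to-post change), or
#' `modality` (endurance change minus resistance change). Sign conventions:
#' post minus pre, exercise minus control, EE minus RE.
#'
#' @param fit An `exermap_lmmfit` from [fit_feature()].
#' @param family Contrast family.
#' @param group Exercise group for the first two families.
#' @param timepoint Post timepoint.
#' @return One-row tibble: `contrast`, `family`, `group`, `timepoint`,
#'   `estimate`, `se`, `statistic`, `df`, `p_value`, `testable`.
#' @export
contrast_cellmeans <- function(fit,
                               family = c("difference_in_changes",
                                          "group_specific", "modality"),
                               group = NULL, timepoint) {
  family <- match.arg(family)
  gname <- if (family == "modality") "EEvsRE" else group
  label <- paste(family, gname, timepoint, sep = ":")
  cvec <- contrast_vector(fit, family, group, timepoint)
  if (is.null(cvec)) {
    return(tibble::tibble(contrast = label, family = family, group = gname,
                          timepoint = timepoint, estimate = NA_real_,
                          se = NA_real_, statistic = NA_real_, df = NA_real_,
                          p_value = NA_real_, testable = FALSE))
  }
  est <- sum(cvec * fit$beta)
  se <- sqrt(as.numeric(t(cvec) %*% fit$C %*% cvec))
  df <- if (fit$singular) fit$n - fit$p else satterthwaite_df(fit, cvec)
  tstat <- est / se
  tibble::tibble(contrast = label, family = family, group = gname,
                 timepoint = timepoint, estimate = est, se = se,
                 statistic = tstat, df = df,
                 p_value = 2 * stats::pt(-abs(tstat), df), testable = TRUE)
}

#' Count paired participants per feature, group and timepoint
#'
#' For every feature and every (group, post-timepoint) cell, counts the
#' participants with that feature observed at both their pre and their post
#' sample. A feature-contrast is testable only when every group involved
#' has at least `min_pairs` such participants.
#'
#' @param design Sample design.
#' @param observed Logical matrix (features x samples), `TRUE` where the
#'   value is present; or a numeric matrix (non-NA = observed).
#' @param min_pairs Minimum paired participants per involved group.
#' @return Tibble: `feature_id`, `group`, `timepoint`, `n_pairs`,
#'   `testable`.
#' @export
min_pairs_filter <- function(design, observed, min_pairs = 3) {
  if (!is.logical(observed)) observed <- !is.na(values_of(observed))
  pre <- design[design$timepoint == "pre", ]
  post <- design[design$timepoint != "pre", ]
  m <- match(post$participant_id, pre$participant_id)
  paired <- observed[, pre$sample_id[m], drop = FALSE] &
    observed[, post$sample_id, drop = FALSE]
  key <- paste(post$group, post$timepoint, sep = "\r")
  counts <- t(rowsum(t(paired) * 1, key))  # features x (group,timepoint)
  parts <- strsplit(colnames(counts), "\r", fixed = TRUE)
  tibble::tibble(
    feature_id = rep(rownames(observed), times = ncol(counts)),
    group = rep(vapply(parts, `[`, "", 1L), each = nrow(counts)),
    timepoint = rep(vapply(parts, `[`, "", 2L), each = nrow(counts)),
    n_pairs = as.integer(counts),
    testable = as.integer(counts) >= min_pairs
  )
}

# Testability of a contrast given the per-(group, timepoint) pair counts
# of one feature.
contrast_testable <- function(pairs, family, group, timepoint,
                              min_pairs = 3) {
  ok <- function(g) {
    n <- pairs$n_pairs[pairs$group == g & pairs$timepoint == timepoint]
    length(n) > 0 && n[1L] >= min_pairs
  }
  switch(family,
         difference_in_changes = ok(group) && ok("CON"),
         group_specific = ok(group),
         modality = ok("EE") && ok("RE"),
         FALSE)
}

#' Differential analysis across a feature matrix
#'
#' Runs [fit_feature()] and the requested contrast families for every
#' feature of an omics matrix, applies the minimum-pairs testability rule,
#' and adjusts p-values within strata via [adjust_stratified()].
#'
#' @param m Feature-by-sample matrix ([omics_matrix()] or plain matrix,
#'   log-scale values or anything directly modelled).
#' @param design Sample design.
#' @param families Contrast families to compute.
#' @param covariates Columns of `design` to adjust for (`NULL` for none).
#' @param weights Optional feature-by-sample precision weight matrix (from
#'   [estimate_precision_weights()]).
#' @param min_pairs Minimum paired participants per involved group.
#' @param adjust Adjust p-values within strata and flag significance.
#' @param alpha FDR threshold for the significance flag.
#' @return Tibble with one row per feature x contrast.
#' @export
fit_differential <- function(m, design,
                             families = c("difference_in_changes",
                                          "group_specific", "modality"),
                             covariates = c("age", "sex", "bmi", "site"),
                             weights = NULL, min_pairs = 3, adjust = TRUE,
                             alpha = 0.05) {
  X <- values_of(m)
  stopifnot(all(colnames(X) %in% design$sample_id))
  design <- design[match(colnames(X), design$sample_id), ]
  timepoints <- setdiff(unique(design$timepoint), "pre")
  groups_ex <- intersect(c("EE", "RE"), unique(design$group))
  plan <- dplyr::bind_rows(
    if ("difference_in_changes" %in% families)
      tidyr::crossing(family = "difference_in_changes", group = groups_ex,
                      timepoint = timepoints),
    if ("group_specific" %in% families)
      tidyr::crossing(family = "group_specific",
                      group = unique(design$group), timepoint = timepoints),
    if ("modality" %in% families && length(groups_ex) == 2L)
      tidyr::crossing(family = "modality", group = NA_character_,
                      timepoint = timepoints)
  )
  pair_tbl <- min_pairs_filter(design, !is.na(X), min_pairs)
  res <- purrr::map(rownames(X), function(f) {
    y <- X[f, ]
    pairs_f <- pair_tbl[pair_tbl$feature_id == f, ]
    w <- if (!is.null(weights)) weights[f, ] else NULL
    fit <- tryCatch(
      fit_feature(y, design, covariates = covariates, weights = w),
      error = function(e) NULL)
    rows <- purrr::pmap(plan, function(family, group, timepoint) {
      if (!contrast_testable(pairs_f, family, group, timepoint, min_pairs) ||
          is.null(fit)) {
        gname <- if (family == "modality") "EEvsRE" else group
        return(tibble::tibble(
          contrast = paste(family, gname, timepoint, sep = ":"),
          family = family, group = gname, timepoint = timepoint,
          estimate = NA_real_, se = NA_real_, statistic = NA_real_,
          df = NA_real_, p_value = NA_real_, testable = FALSE))
      }
      contrast_cellmeans(fit, family, group = group, timepoint = timepoint)
    })
    dplyr::bind_rows(rows) |>
      dplyr::mutate(feature_id = f, .before = 1L)
  })
  out <- dplyr::bind_rows(res) |>
    dplyr::mutate(ome = ome_of(m))
  if (adjust) out <- adjust_stratified(out, alpha = alpha)
  out
}

#' Stratified Benjamini-Hochberg adjustment
#'
#' Applies BH independently within each (contrast family, group, ome,
#' timepoint) stratum — so each unique contrast-group-ome-timepoint
#' combination controls its own FDR — and flags significance at `alpha`.
#'
#' @param results Tibble with a `p_value` column and any of the stratum
#'   columns `family`, `group`, `ome`, `timepoint`.
#' @param alpha FDR threshold.
#' @return `results` with `adj_p_value`, `significant` and `stratum` added.
#' @export
adjust_stratified <- function(results, alpha = 0.05) {
  strat_cols <- intersect(c("family", "group", "ome", "timepoint"),
                          names(results))
  results$stratum <- do.call(paste, c(results[strat_cols], sep = ":"))
  results |>
    dplyr::group_by(.data$stratum) |>
    dplyr::mutate(adj_p_value = stats::p.adjust(.data$p_value, "BH"),
                  significant = !is.na(.data$adj_p_value) &
                    .data$adj_p_value < alpha) |>
    dplyr::ungroup()
}

#' Baseline sex-difference model
#'
#' Per-feature linear model with participant sex as the single covariate,
#' fitted on pre-exercise samples. The sign convention is male minus
#' female. BH adjustment is across features.
#'
#' @param m Feature-by-sample matrix of pre-exercise values.
#' @param sex Character/factor vector aligned to columns (`"F"`/`"M"`).
#' @param alpha FDR threshold for the significance flag.
#' @return Tibble: `feature_id`, `estimate`, `se`, `statistic`, `df`,
#'   `p_value`, `adj_p_value`, `significant`.
#' @export
sex_difference <- function(m, sex, alpha = 0.05) {
  X <- values_of(m)
  sex <- as.character(sex)
  if (length(unique(sex[!is.na(sex)])) < 2L) {
    stop("both sexes must be present")
  }
  male <- sex == "M"
  res <- purrr::map(rownames(X), function(f) {
    y <- X[f, ]
    ok <- is.finite(y)
    n1 <- sum(ok & male); n0 <- sum(ok & !male)
    if (n1 < 2L || n0 < 2L) {
      return(tibble::tibble(feature_id = f, estimate = NA_real_,
                            se = NA_real_, statistic = NA_real_,
                            df = NA_real_, p_value = NA_real_))
    }
    m1 <- mean(y[ok & male]); m0 <- mean(y[ok & !male])
    s2 <- (sum((y[ok & male] - m1)^2) + sum((y[ok & !male] - m0)^2)) /
      (n1 + n0 - 2)
    se <- sqrt(s2 * (1 / n1 + 1 / n0))
    tstat <- (m1 - m0) / se
    tibble::tibble(feature_id = f, estimate = m1 - m0, se = se,
                   statistic = tstat, df = n1 + n0 - 2,
                   p_value = 2 * stats::pt(-abs(tstat), n1 + n0 - 2))
  })
  dplyr::bind_rows(res) |>
    dplyr::mutate(adj_p_value = stats::p.adjust(.data$p_value, "BH"),
                  significant = !is.na(.data$adj_p_value) &
                    .data$adj_p_value < alpha)
}

#' Precision weights from the count mean-variance trend
#'
#' Computes log2-CPM (0.5 offset), fits the fixed-effect cell-means model
#' per gene, smooths the square-root residual standard deviation against
#' average log2 count with lowess, and returns per-observation weights equal
#' to the inverse fourth power of the predicted square-root SD at each
#' observation's fitted log-count.
#'
#' @param counts Raw count matrix (genes x samples).
#' @param design Sample design.
#' @param covariates Design columns for the trend-fitting model.
#' @return List with `weights` (genes x samples matrix), `logcpm`, and
#'   `trend` (tibble of the lowess curve).
#' @export
estimate_precision_weights <- function(counts, design,
                                       covariates = c("age", "sex")) {
  X <- values_of(counts)
  if (ncol(X) < 2L) stop("need at least 2 samples")
  design <- design[match(colnames(X), design$sample_id), ]
  lib <- colSums(X)
  y <- t(log2(t(X + 0.5) / (lib + 1) * 1e6))
  if (nrow(X) < 10L) {
    warning("fewer than 10 features; mean-variance trend unreliable, ",
            "returning unit weights")
    return(list(weights = array(1, dim(X), dimnames = dimnames(X)),
                logcpm = y, trend = NULL))
  }
  D <- build_cellmeans_X(design, covariates)
  qrD <- qr(D)
  fitted <- t(qr.fitted(qrD, t(y)))
  sd_res <- sqrt(rowSums((y - fitted)^2) / (ncol(y) - qrD$rank))
  sx <- rowMeans(y) + mean(log2(lib + 1)) - log2(1e6)  # mean log2 count
  sy <- sqrt(sd_res)
  lo <- stats::lowess(sx, sy, f = 0.5)
  f_obs <- fitted + matrix(log2(lib + 1), nrow(y), ncol(y), byrow = TRUE) -
    log2(1e6)
  pred <- stats::approx(lo$x, lo$y, xout = as.numeric(f_obs), rule = 2)$y
  w <- matrix(1 / pmax(pred, 1e-4)^4, nrow(y), dimnames = dimnames(y))
  list(weights = w, logcpm = y,
       trend = tibble::tibble(mean_log_count = lo$x, sqrt_sd = lo$y))
}

#' Collapse differential results to a z-score matrix
#'
#' Converts two-sided p-values and effect signs into signed standard-normal
#' deviates `z = sign(estimate) * qnorm(1 - p/2)`, maps features to row
#' identifiers (gene symbols, RefMet IDs or single phosphosites), optionally
#' expands multi-site phosphopeptides (`PROT_S1;S2` contributes rows
#' `PROT_S1` and `PROT_S2` with identical values), and keeps the most
#' extreme z (maximum absolute value) per row x contrast. `p = 0` is capped
#' at `z_cap`.
#'
#' @param results Differential results with `feature_id`, `contrast`,
#'   `estimate`, `p_value`.
#' @param mapping Tibble `feature_id` -> `symbol` (unmapped features are
#'   dropped and counted in the `n_unmapped` attribute). `NULL` uses
#'   `feature_id` itself.
#' @param phospho_expand Expand `;`-separated multi-site identifiers.
#' @param z_cap Cap on `|z|`.
#' @return Numeric matrix, rows = identifiers, columns = contrasts.
#' @export
build_zscore_matrix <- function(results, mapping = NULL,
                                phospho_expand = FALSE, z_cap = 38) {
  r <- results |>
    dplyr::filter(!is.na(.data$p_value)) |>
    dplyr::select("feature_id", "contrast", "estimate", "p_value")
  if (is.null(mapping)) {
    r$symbol <- r$feature_id
    n_unmapped <- 0L
  } else {
    r <- dplyr::left_join(r, mapping, by = "feature_id")
    n_unmapped <- sum(is.na(r$symbol))
    r <- dplyr::filter(r, !is.na(.data$symbol))
  }
  if (phospho_expand) {
    r <- r |>
      dplyr::mutate(.base = sub("_[^_]*$", "", .data$symbol),
                    .sites = sub(".*_", "", .data$symbol)) |>
      tidyr::separate_rows(".sites", sep = ";") |>
      dplyr::mutate(symbol = paste0(.data$.base, "_", .data$.sites)) |>
      dplyr::select(-".base", -".sites")
  }
  r <- r |>
    dplyr::mutate(z = sign(.data$estimate) *
                    pmin(stats::qnorm(.data$p_value / 2,
                                      lower.tail = FALSE), z_cap),
                  z = ifelse(.data$p_value >= 1, 0, .data$z)) |>
    dplyr::group_by(.data$symbol, .data$contrast) |>
    dplyr::slice_max(abs(.data$z), n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  wide <- tidyr::pivot_wider(r[, c("symbol", "contrast", "z")],
                             names_from = "contrast", values_from = "z")
  out <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(out) <- wide$symbol
  attr(out, "n_unmapped") <- n_unmapped
  out
}
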