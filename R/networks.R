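#' Biweight midcorrelation
#'
#' Robust correlation based on Tukey biweight-weighted deviations from the
#' median: `u_i = (x_i - med(x)) / (9 * mad(x))` (unscaled MAD), weights
#' `(1 - u^2)^2` for `|u| < 1` and 0 otherwise. A margin with zero MAD
#' falls back to Pearson weighting for that margin (flagged). The p-value
#' uses the t approximation on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (>= 4), non-constant.
#' @return Tibble: `estimate`, `statistic`, `p_value`, `n`, `fallback`.
#' @export
bicor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input vector")
  wd <- function(v) {
    med <- stats::median(v)
    madv <- stats::mad(v, constant = 1)
    if (madv == 0) return(list(d = v - mean(v), fb = TRUE))
    u <- (v - med) / (9 * madv)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    list(d = (v - med) * w, fb = FALSE)
  }
  a <- wd(x); b <- wd(y)
  r <- sum(a$d * b$d) / sqrt(sum(a$d^2) * sum(b$d^2))
  r <- min(max(r, -1), 1)
  tstat <- r * sqrt((n - 2) / (1 - r^2 + 1e-300))
  tibble::tibble(estimate = r, statistic = tstat,
                 p_value = 2 * stats::pt(-abs(tstat), n - 2), n = n,
                 fallback = a$fb || b$fb)
}

# Column-wise biweight transform of a samples x features matrix.
bicor_prep <- function(M) {
  med <- apply(M, 2L, stats::median)
  madv <- apply(M, 2L, stats::mad, constant = 1)
  fb <- madv == 0
  D <- sweep(M, 2L, med)
  if (any(!fb)) {
    u <- sweep(D[, !fb, drop = FALSE], 2L, 9 * madv[!fb], "/")
    w <- (1 - u^2)^2 * (abs(u) < 1)
    D[, !fb] <- D[, !fb, drop = FALSE] * w
  }
  if (any(fb)) {
    D[, fb] <- sweep(M[, fb, drop = FALSE], 2L, colMeans(M[, fb, drop = FALSE]))
  }
  D <- sweep(D, 2L, sqrt(colSums(D^2)), "/")
  attr(D, "fallback") <- fb
  D
}

#' Biweight midcorrelation matrix
#'
#' All pairwise biweight midcorrelations between the columns of `X` and the
#' columns of `Y` (or of `X` with itself); complete data required.
#'
#' @param X Samples x features matrix.
#' @param Y Optional second matrix with the same rows.
#' @return Correlation matrix.
#' @export
bicor_matrix <- function(X, Y = NULL) {
  A <- bicor_prep(as.matrix(X))
  B <- if (is.null(Y)) A else bicor_prep(as.matrix(Y))
  r <- crossprod(A, B)
  pmin(pmax(r, -1), 1)
}

# two-sided p for a correlation via the t approximation, df = n - 2
cor_pvalue <- function(r, n) {
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  2 * stats::pt(-abs(tstat), n - 2)
}

#' Choose the soft-threshold power for a signed network
#'
#' For each candidate power, builds the signed adjacency
#' `a_ij = ((1 + cor_ij)/2)^beta`, computes connectivity
#' `k_i = sum_j a_ij`, and measures scale-free topology fit as the signed
#' R-squared of the log-log regression of the binned degree distribution.
#' Returns the smallest power reaching `fit_target`; if none does, the
#' power with the best fit, flagged.
#'
#' @param m Feature-by-sample matrix (complete).
#' @param powers Candidate powers.
#' @param fit_target Scale-free fit R-squared target (default 0.8).
#' @param n_bins Histogram bins for the degree distribution.
#' @return List: `power`, `reached_target`, `table` (per-power fit).
#' @export
pick_soft_power <- function(m, powers = c(1:10, 12, 14, 16, 18, 20),
                            fit_target = 0.8, n_bins = 10) {
  X <- values_of(m)
  if (nrow(X) < 30L) stop("need at least 30 features")
  A0 <- (1 + stats::cor(t(X))) / 2
  diag(A0) <- 0
  fits <- vapply(powers, function(b) {
    k <- rowSums(A0^b)
    br <- seq(min(k), max(k), length.out = n_bins + 1L) # equal-width bins
    if (length(unique(br)) < 3L) return(NA_real_)
    bin <- cut(k, br, include.lowest = TRUE)
    dk <- tapply(k, bin, mean)
    pk <- tapply(k, bin, length) / length(k)
    ok <- is.finite(dk) & pk > 0 & dk > 0
    if (sum(ok) < 3L) return(NA_real_)
    fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
    r2 <- summary(fit)$r.squared
    -sign(stats::coef(fit)[2L]) * r2
  }, 0)
  tbl <- tibble::tibble(power = powers, fit = fits)
  reached <- which(fits >= fit_target)
  if (length(reached) > 0L) {
    list(power = powers[reached[1L]], reached_target = TRUE, table = tbl)
  } else {
    list(power = powers[which.max(fits)], reached_target = FALSE, table = tbl)
  }
}

# Topological overlap dissimilarity of a signed adjacency (diag 0).
tom_dissimilarity <- function(A) {
  k <- rowSums(A)
  L <- A %*% A
  num <- L + A
  den <- outer(k, k, pmin) + 1 - A
  TOM <- num / den
  diag(TOM) <- 1
  1 - TOM
}

#' Build signed co-expression modules
#'
#' Signed adjacency `((1 + cor)/2)^beta`, topological-overlap
#' dissimilarity, average-linkage clustering, a height-based dynamic cut
#' (tree cut at the `cut_quantile` quantile of merge heights), and
#' iterative merging of modules whose eigengenes correlate above
#' `1 - merge_threshold`. Features in clusters smaller than
#' `min_module_size` fall into module 0 (unassigned). Module labels are
#' ordered by size. kME is each feature's correlation with every module
#' eigengene.
#'
#' @param m Feature-by-sample matrix (complete; typically baseline
#'   samples).
#' @param beta Soft-threshold power (see [pick_soft_power()]).
#' @param merge_threshold Eigengene dissimilarity below which modules
#'   merge (default 0.3).
#' @param min_module_size Minimum module size (default 30).
#' @param cut_quantile Quantile of merge heights at which the tree is cut.
#' @param kme_min Features whose correlation with their own module
#'   eigengene falls below this are released to module 0.
#' @return Object of class `exermap_modules`: `assignment` tibble
#'   (`feature_id`, `module`, `kME`), `eigengenes` (module x sample),
#'   `kME` (feature x module), `beta`, `merges`.
#' @export
build_modules <- function(m, beta = 6, merge_threshold = 0.3,
                          min_module_size = 30, cut_quantile = 0.90,
                          kme_min = 0.3) {
  X <- values_of(m)
  n_feat <- nrow(X)
  if (n_feat < min_module_size) {
    assignment <- tibble::tibble(feature_id = rownames(X), module = 0L,
                                 kME = NA_real_)
    return(structure(list(assignment = assignment, eigengenes = NULL,
                          kME = NULL, beta = beta, merges = 0L),
                     class = "exermap_modules"))
  }
  A <- ((1 + stats::cor(t(X))) / 2)^beta
  diag(A) <- 0
  dTOM <- tom_dissimilarity(A)
  hc <- stats::hclust(stats::as.dist(dTOM), method = "average")
  h <- stats::quantile(hc$height, cut_quantile)
  cl <- stats::cutree(hc, h = h)
  sizes <- table(cl)
  small <- as.integer(names(sizes)[sizes < min_module_size])
  cl[cl %in% small] <- 0L
  # eigengenes + merge loop
  Xs <- scale_rows(X)
  eigengene <- function(idx) {
    sv <- svd(t(Xs[idx, , drop = FALSE]), nu = 1L, nv = 0L)
    e <- sv$u[, 1L]
    if (mean(stats::cor(t(Xs[idx, , drop = FALSE]), e)) < 0) e <- -e
    e / stats::sd(e)
  }
  merges <- 0L
  repeat {
    mods <- setdiff(unique(cl), 0L)
    if (length(mods) < 2L) break
    ME <- vapply(mods, function(mm) eigengene(which(cl == mm)),
                 numeric(ncol(X)))
    CME <- stats::cor(ME)
    diag(CME) <- 0
    mx <- which(CME == max(CME), arr.ind = TRUE)[1L, ]
    if (max(CME) <= 1 - merge_threshold) break
    cl[cl == mods[mx[2L]]] <- mods[mx[1L]]
    merges <- merges + 1L
  }
  # kME cleanup: release weakly connected members to module 0
  mods <- setdiff(unique(cl), 0L)
  if (length(mods) > 0L) {
    ME0 <- vapply(mods, function(mm) eigengene(which(cl == mm)),
                  numeric(ncol(X)))
    kme0 <- stats::cor(t(Xs), ME0)
    for (j in seq_along(mods)) {
      weak <- cl == mods[j] & kme0[, j] < kme_min
      cl[weak] <- 0L
    }
    sizes <- table(cl[cl != 0L])
    cl[cl %in% as.integer(names(sizes)[sizes < min_module_size])] <- 0L
  }
  # relabel by decreasing size, 0 stays unassigned
  mods <- setdiff(unique(cl), 0L)
  ord <- mods[order(-table(factor(cl, levels = mods))[as.character(mods)])]
  relab <- stats::setNames(seq_along(ord), ord)
  cl_new <- ifelse(cl == 0L, 0L, relab[as.character(cl)])
  mods_new <- sort(unique(cl_new[cl_new != 0L]))
  ME <- vapply(mods_new, function(mm) eigengene(which(cl_new == mm)),
               numeric(ncol(X)))
  colnames(ME) <- paste0("ME", mods_new)
  rownames(ME) <- colnames(X)
  kME <- stats::cor(t(Xs), ME)
  rownames(kME) <- rownames(X)
  own <- vapply(seq_len(n_feat), function(i) {
    if (cl_new[i] == 0L) NA_real_ else kME[i, paste0("ME", cl_new[i])]
  }, 0)
  assignment <- tibble::tibble(feature_id = rownames(X),
                               module = as.integer(cl_new), kME = own)
  structure(list(assignment = assignment, eigengenes = t(ME), kME = kME,
                 beta = beta, merges = merges),
            class = "exermap_modules")
}

#' @export
print.exermap_modules <- function(x, ...) {
  tab <- table(x$assignment$module)
  cat("<exermap_modules> beta=", x$beta, ", ",
      sum(names(tab) != "0"), " modules (+module 0: ",
      if ("0" %in% names(tab)) tab[["0"]] else 0L, " unassigned)\n", sep = "")
  invisible(x)
}

#' @export
tidy.exermap_modules <- function(x, ...) x$assignment

#' @export
glance.exermap_modules <- function(x, ...) {
  tab <- table(x$assignment$module)
  tibble::tibble(n_modules = sum(names(tab) != "0"),
                 n_unassigned = sum(x$assignment$module == 0L),
                 beta = x$beta, merges = x$merges)
}

#' @export
autoplot.exermap_modules <- function(object, ...) {
  object$assignment |>
    dplyr::count(.data$module) |>
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$module), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "module (0 = unassigned)", y = "features") +
    ggplot2::theme_minimal()
}

#' Correlate module eigengenes with traits
#'
#' Biweight midcorrelation of each module eigengene with each (z-scored)
#' trait, optionally residualizing both sides on covariates first.
#' Traits missing in more than half the samples are skipped.
#'
#' @param modules An `exermap_modules` object (or an eigengene matrix,
#'   modules x samples).
#' @param traits Data frame of traits, one row per sample (aligned via a
#'   `sample_id` column or row order).
#' @param adjust_for Optional data frame of covariates, same alignment.
#' @return Tibble: `module`, `trait`, `estimate`, `p_value`, `stars`.
#' @export
module_trait <- function(modules, traits, adjust_for = NULL) {
  E <- if (inherits(modules, "exermap_modules")) modules$eigengenes
       else as.matrix(modules)
  traits <- as.data.frame(traits)
  sample_ids <- colnames(E)
  if ("sample_id" %in% names(traits)) {
    traits <- traits[match(sample_ids, traits$sample_id),
                     setdiff(names(traits), "sample_id"), drop = FALSE]
  }
  stopifnot(nrow(traits) == ncol(E))
  resid_on <- NULL
  if (!is.null(adjust_for)) {
    adjust_for <- as.data.frame(adjust_for)
    if ("sample_id" %in% names(adjust_for)) {
      adjust_for <- adjust_for[match(sample_ids, adjust_for$sample_id),
                               setdiff(names(adjust_for), "sample_id"),
                               drop = FALSE]
    }
    resid_on <- stats::model.matrix(~ ., data = adjust_for)
  }
  out <- purrr::map(rownames(E), function(mod) {
    purrr::map(names(traits), function(tr) {
      v <- traits[[tr]]
      if (!is.numeric(v) || mean(is.na(v)) > 0.5) return(NULL)
      ok <- is.finite(v)
      vz <- as.numeric(scale(v[ok]))
      e <- E[mod, ok]
      if (!is.null(resid_on)) {
        R <- resid_on[ok, , drop = FALSE]
        e <- stats::lsfit(R, e, intercept = FALSE)$residuals
        vz <- stats::lsfit(R, vz, intercept = FALSE)$residuals
      }
      b <- bicor(e, vz)
      tibble::tibble(module = mod, trait = tr, estimate = b$estimate,
                     p_value = b$p_value)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  out$stars <- cut(out$p_value, c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  out
}
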