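#' Stack z-score matrices and apply zero-baseline scaling
#'
#' Row-binds per-ome z-score matrices sharing the same contrast-timepoint
#' columns, then divides each row by the sample standard deviation computed
#' with two zero columns temporarily appended to represent the pre-exercise
#' timepoints (the zeros anchor the scale to baseline and are discarded
#' before clustering). All-zero rows are dropped.
#'
#' @param z_matrices List of numeric matrices with identical column names.
#' @param n_zero_cols Number of temporary zero columns (default 2).
#' @return The stacked, scaled feature x timepoint matrix; dropped row
#'   count in attribute `n_dropped`.
#' @export
stack_and_scale <- function(z_matrices, n_zero_cols = 2) {
  if (is.matrix(z_matrices)) z_matrices <- list(z_matrices)
  cn <- colnames(z_matrices[[1L]])
  stopifnot(all(vapply(z_matrices, function(m) identical(colnames(m), cn),
                       TRUE)))
  X <- do.call(rbind, z_matrices)
  zero <- rowSums(X != 0, na.rm = TRUE) == 0
  X <- X[!zero, , drop = FALSE]
  # sample SD of (0, ..., 0, z_1, ..., z_T) per row
  Tn <- ncol(X) + n_zero_cols
  mu <- rowSums(X) / Tn
  ss <- rowSums((X - mu)^2) + n_zero_cols * mu^2
  sdv <- sqrt(ss / (Tn - 1))
  out <- X / sdv
  attr(out, "n_dropped") <- sum(zero)
  out
}

#' Fuzzifier estimate for fuzzy c-means
#'
#' Empirical estimate of the fuzziness parameter `m` as a function of
#' feature count `N` and dimensionality `D`:
#' `m = 1 + (1418/N + 22.05) D^-2 + (12.33/N + 0.243) D^(-0.0406 ln N - 0.1134)`.
#' Always greater than 1; decreases with `N` at fixed `D`.
#'
#' @param n_features Number of rows to be clustered (>= 3).
#' @param n_dims Number of columns.
#' @return The fuzzifier `m`.
#' @export
estimate_fuzzifier <- function(n_features, n_dims) {
  stopifnot(n_features >= 3, n_dims >= 1)
  N <- n_features; D <- n_dims
  1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
}

#' Fuzzy c-means clustering
#'
#' Standard FCM with Euclidean distances: alternating updates of centroids
#' `v_k = sum_f u_fk^m x_f / sum_f u_fk^m` and memberships
#' `u_fk = 1 / sum_j (d_fk / d_fj)^(2/(m-1))`, iterated until the largest
#' membership change falls below `tol` (the objective `sum u^m d^2` is
#' traced and non-increasing). Memberships are initialized
#' randomly (deterministic given `seed`); a centroid that collapses onto
#' another is re-initialized. Cluster labels are stabilized by sorting
#' centroids lexicographically.
#'
#' @param X Feature x dimension matrix.
#' @param c Number of clusters (>= 2).
#' @param m Fuzzifier (> 1); default from [estimate_fuzzifier()].
#' @param seed Integer seed for the membership initialization.
#' @param tol Objective-change convergence tolerance.
#' @param max_iter Iteration cap.
#' @return Object of class `exermap_fcm`: `centroids` (c x dims),
#'   `membership` (features x c), `m`, `objective`, `objective_trace`,
#'   `iterations`.
#' @export
fuzzy_cmeans <- function(X, c, m = NULL, seed = 1L, tol = 1e-6,
                         max_iter = 500) {
  X <- as.matrix(X)
  stopifnot(c >= 2, nrow(X) > c)
  if (is.null(m)) m <- estimate_fuzzifier(nrow(X), ncol(X))
  stopifnot(m > 1)
  set.seed(seed)
  n <- nrow(X)
  U <- matrix(stats::runif(n * c), n, c)
  U <- U / rowSums(U)
  obj_trace <- numeric()
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    Um <- U^m
    V <- (t(Um) %*% X) / colSums(Um)
    # squared Euclidean distances features x clusters
    D2 <- outer(rowSums(X^2), rep(1, c)) - 2 * X %*% t(V) +
      outer(rep(1, n), rowSums(V^2))
    D2 <- pmax(D2, 1e-12)
    # collapsed centroids: re-initialize duplicates
    dup <- duplicated(round(V, 10))
    if (any(dup)) {
      V[dup, ] <- X[sample.int(n, sum(dup)), , drop = FALSE] +
        stats::rnorm(sum(dup) * ncol(X), sd = 1e-3)
      D2 <- outer(rowSums(X^2), rep(1, c)) - 2 * X %*% t(V) +
        outer(rep(1, n), rowSums(V^2))
      D2 <- pmax(D2, 1e-12)
    }
    W <- D2^(-1 / (m - 1))
    U_new <- W / rowSums(W)
    obj <- sum(U_new^m * D2)
    obj_trace <- c(obj_trace, obj)
    delta_u <- max(abs(U_new - U))
    U <- U_new
    if (delta_u < tol) break
    obj_old <- obj
  }
  ord <- do.call(order, as.data.frame(V))
  V <- V[ord, , drop = FALSE]
  U <- U[, ord, drop = FALSE]
  rownames(V) <- colnames(U) <- paste0("cluster", seq_len(c))
  colnames(V) <- colnames(X)
  rownames(U) <- rownames(X)
  structure(list(centroids = V, membership = U, m = m,
                 objective = obj_trace[length(obj_trace)],
                 objective_trace = obj_trace, iterations = length(obj_trace)),
            class = "exermap_fcm")
}

#' @export
print.exermap_fcm <- function(x, ...) {
  cat("<exermap_fcm> ", nrow(x$centroids), " clusters, m=",
      signif(x$m, 4), ", objective=", signif(x$objective, 6),
      " (", x$iterations, " iterations)\n", sep = "")
  invisible(x)
}

#' @export
tidy.exermap_fcm <- function(x, ...) {
  tibble::as_tibble(x$membership, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "cluster",
                        values_to = "membership")
}

#' @export
glance.exermap_fcm <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$centroids), m = x$m,
                 objective = x$objective, iterations = x$iterations,
                 min_centroid_distance = min(stats::dist(x$centroids)))
}

#' @export
autoplot.exermap_fcm <- function(object, ...) {
  tibble::as_tibble(object$centroids, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "timepoint",
                        values_to = "z") |>
    dplyr::mutate(timepoint = factor(.data$timepoint,
                                     levels = colnames(object$centroids))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$timepoint, y = .data$z,
                                 group = .data$cluster)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::facet_wrap(~ cluster) +
    ggplot2::labs(x = NULL, y = "scaled z") +
    ggplot2::theme_minimal()
}

#' Cluster-number scree over minimum centroid distance
#'
#' Runs FCM for each candidate cluster number and records the minimum
#' pairwise centroid distance (the cluster validity index); the final
#' choice is made by inspecting the scree, not automatically.
#'
#' @param X Feature x dimension matrix.
#' @param c_range Candidate cluster numbers (default 3:14).
#' @param m Fuzzifier; default from [estimate_fuzzifier()].
#' @param seed Integer seed.
#' @return Tibble: `c`, `min_centroid_distance`, `objective`.
#' @export
choose_c <- function(X, c_range = 3:14, m = NULL, seed = 1L) {
  purrr::map_dfr(c_range, function(cc) {
    f <- fuzzy_cmeans(X, c = cc, m = m, seed = seed)
    tibble::tibble(c = cc,
                   min_centroid_distance = min(stats::dist(f$centroids)),
                   objective = f$objective)
  })
}

#' Scree plot of minimum centroid distances
#'
#' @param scree Tibble from [choose_c()].
#' @return A ggplot object.
#' @export
plot_scree <- function(scree) {
  ggplot2::ggplot(scree, ggplot2::aes(x = .data$c,
                                      y = .data$min_centroid_distance)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters",
                  y = "minimum centroid distance") +
    ggplot2::theme_minimal()
}

#' Hard cluster assignment from fuzzy memberships
#'
#' Assigns each feature to its maximum-membership cluster when that
#' membership reaches `threshold`; features below the threshold stay
#' unassigned (`NA`).
#'
#' @param fcm An `exermap_fcm` object.
#' @param threshold Minimum membership (default 0.3).
#' @return Tibble: `feature_id`, `cluster`, `membership`.
#' @export
hard_assign <- function(fcm, threshold = 0.3) {
  U <- fcm$membership
  best <- max.col(U, ties.method = "first")
  bm <- U[cbind(seq_len(nrow(U)), best)]
  tibble::tibble(
    feature_id = rownames(U),
    cluster = ifelse(bm >= threshold, colnames(U)[best], NA_character_),
    membership = bm
  )
}
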