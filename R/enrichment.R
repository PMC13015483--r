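#' Read and write GMT gene-set files
#'
#' One set per line: name, description, then tab-separated members.
#'
#' @param path File path.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[`, "", 1L))
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Construct a set collection
#'
#' @param sets Named list of member identifier vectors.
#' @param provenance Collection type; controls the retention filter (gene
#'   sets only) and the significance threshold (0.1 for kinase sets,
#'   0.05 otherwise).
#' @return List of class `exermap_sets` with `sets`, `provenance`,
#'   `original_sizes`, `filtered` flag.
#' @export
set_collection <- function(sets,
                           provenance = c("pathway", "cell_marker",
                                          "refmet_class", "kinase",
                                          "ptm_signature")) {
  provenance <- match.arg(provenance)
  stopifnot(is.list(sets), !is.null(names(sets)))
  structure(list(sets = lapply(sets, unique), provenance = provenance,
                 original_sizes = lengths(lapply(sets, unique)),
                 filtered = FALSE, dropped = tibble::tibble()),
            class = "exermap_sets")
}

#' Filter a set collection against a measured universe
#'
#' Intersects every set with the universe of measured identifiers, then
#' drops sets with fewer than `min_size` members present. For gene-type
#' collections (pathway, cell_marker, kinase, ptm_signature) a set must
#' additionally retain at least `min_retention` of its original members;
#' RefMet metabolite classes are exempt from the retention rule. There is
#' no maximum-size restriction.
#'
#' @param collection An [set_collection()].
#' @param universe Character vector of measured identifiers.
#' @param min_size Minimum members present (default 5).
#' @param min_retention Minimum retained fraction for gene sets (0.70).
#' @param apply_retention Override the provenance-based retention default.
#' @return The filtered collection; dropped sets logged in `$dropped`.
#' @export
filter_sets <- function(collection, universe, min_size = 5,
                        min_retention = 0.70, apply_retention = NULL) {
  stopifnot(inherits(collection, "exermap_sets"))
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  if (is.null(apply_retention)) {
    apply_retention <- collection$provenance != "refmet_class"
  }
  inter <- lapply(collection$sets, intersect, universe)
  size_ok <- lengths(inter) >= min_size
  retention <- lengths(inter) / pmax(collection$original_sizes, 1L)
  ret_ok <- if (apply_retention) retention >= min_retention else TRUE
  keep <- size_ok & ret_ok
  collection$dropped <- tibble::tibble(
    set = names(inter)[!keep],
    n_present = lengths(inter)[!keep],
    retention = retention[!keep],
    reason = ifelse(!size_ok[!keep], "below min_size", "below min_retention")
  )
  collection$sets <- inter[keep]
  collection$original_sizes <- collection$original_sizes[keep]
  collection$filtered <- TRUE
  collection
}

#' Pre-ranked competitive set test (CAMERA-PR)
#'
#' For each set of size `m` in a universe of `n` statistics: the in-set
#' minus out-of-set mean difference `delta` is tested with a two-sample
#' pooled-variance t statistic whose in-set variance term is inflated by
#' `VIF = 1 + (m - 1) * inter_feature_cor`, on `n - 2` degrees of freedom.
#' With `inter_feature_cor = 0` this reduces exactly to the classical
#' pooled two-sample t test. The directional summary
#' `z.std = sign(delta) * qnorm(1 - p/2)` is positive for upregulated sets.
#' BH adjustment is within the collection; significance at 0.05
#' (0.1 for kinase collections).
#'
#' @param z Named numeric vector of z-scores over the measured universe.
#' @param collection An [set_collection()], ideally filtered.
#' @param inter_feature_cor Assumed mean inter-feature correlation within
#'   sets (default 0.01, the established convention for this test).
#' @param alpha Base significance threshold.
#' @return Tibble: `set`, `n_members`, `delta`, `statistic`, `p_value`,
#'   `adj_p_value`, `z_std`, `significant`.
#' @export
camera_pr <- function(z, collection, inter_feature_cor = 0.01,
                      alpha = NULL) {
  stopifnot(inherits(collection, "exermap_sets"))
  if (is.null(names(z))) stop("z must be named by identifier")
  z <- z[is.finite(z)]
  n <- length(z)
  if (is.null(alpha)) {
    alpha <- if (collection$provenance == "kinase") 0.1 else 0.05
  }
  res <- purrr::imap(collection$sets, function(members, nm) {
    inset <- names(z) %in% members
    m <- sum(inset)
    if (m < 1L || m == n) {
      warning("set '", nm, "' covers none or all of the universe; skipped")
      return(NULL)
    }
    delta <- mean(z[inset]) - mean(z[!inset])
    s2 <- (sum((z[inset] - mean(z[inset]))^2) +
             sum((z[!inset] - mean(z[!inset]))^2)) / (n - 2)
    vif <- 1 + (m - 1) * inter_feature_cor
    se <- sqrt(s2) * sqrt(vif / m + 1 / (n - m))
    tstat <- if (se == 0) 0 else delta / se # degenerate: all z identical
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    tibble::tibble(set = nm, n_members = m, delta = delta, statistic = tstat,
                   p_value = p,
                   z_std = sign(delta) *
                     pmin(stats::qnorm(p / 2, lower.tail = FALSE), 38))
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) return(out)
  out$adj_p_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$adj_p_value < alpha
  out
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a selected
#' identifier list and each set, against the measured universe as
#' background; BH adjustment within the collection.
#'
#' @param selected Selected identifiers (must lie within `universe`).
#' @param universe Background identifiers.
#' @param collection An [set_collection()].
#' @param alpha Significance threshold (default by provenance, as in
#'   [camera_pr()]).
#' @return Tibble: `set`, `n_set`, `n_overlap`, `expected`, `p_value`,
#'   `adj_p_value`, `significant`.
#' @export
ora <- function(selected, universe, collection, alpha = NULL) {
  stopifnot(inherits(collection, "exermap_sets"))
  universe <- unique(universe)
  selected <- unique(selected)
  if (!all(selected %in% universe)) {
    stop("selected identifiers must be a subset of the universe")
  }
  if (is.null(alpha)) {
    alpha <- if (collection$provenance == "kinase") 0.1 else 0.05
  }
  N <- length(universe)
  k <- length(selected)
  res <- purrr::imap(collection$sets, function(members, nm) {
    members <- intersect(members, universe)
    m <- length(members)
    ov <- length(intersect(members, selected))
    p <- if (k == 0L) 1 else
      stats::phyper(ov - 1L, m, N - m, k, lower.tail = FALSE)
    tibble::tibble(set = nm, n_set = m, n_overlap = ov,
                   expected = k * m / N, p_value = p)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) return(out)
  out$adj_p_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$adj_p_value < alpha
  out
}

#' Bubble plot of enrichment results
#'
#' @param results Tibble from [camera_pr()] (optionally row-bound over
#'   contrasts with a `contrast` column).
#' @param max_sets Show at most this many sets (by smallest adjusted p).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(results, max_sets = 30) {
  if (!"contrast" %in% names(results)) results$contrast <- "contrast"
  top <- results |>
    dplyr::group_by(.data$set) |>
    dplyr::summarise(best = min(.data$adj_p_value), .groups = "drop") |>
    dplyr::slice_min(.data$best, n = max_sets, with_ties = FALSE)
  results |>
    dplyr::filter(.data$set %in% top$set) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$contrast, y = .data$set,
                                 size = -log10(.data$adj_p_value),
                                 colour = .data$z_std)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient2(low = "#2166ac", mid = "grey85",
                                    high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, size = "-log10 adj. p",
                  colour = "z.std") +
    ggplot2::theme_minimal()
}
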