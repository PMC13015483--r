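#' Build the candidate secreted-factor list
#'
#' The secreted reference is the union of a plasma-detected protein panel
#' and a curated secreted-protein atlas; candidates are the differentially
#' regulated transcripts/proteins (given as gene symbols) that overlap the
#' reference, deduplicated to unique proteins.
#'
#' @param candidates Gene symbols of differentially regulated features
#'   (transcripts and proteins may repeat a gene; duplicates collapse).
#' @param plasma_panel,secreted_atlas Character vectors of gene symbols.
#' @return Tibble: `gene`, `in_plasma_panel`, `in_secreted_atlas`.
#' @export
build_secretome <- function(candidates, plasma_panel, secreted_atlas) {
  reference <- union(plasma_panel, secreted_atlas)
  if (length(reference) == 0L) stop("empty secreted reference list")
  genes <- unique(candidates)
  hits <- genes[genes %in% reference]
  tibble::tibble(gene = hits,
                 in_plasma_panel = hits %in% plasma_panel,
                 in_secreted_atlas = hits %in% secreted_atlas)
}

#' Extracellular localization score
#'
#' The maximum subcellular-compartment confidence score (0-5) over the
#' four extracellular categories: extracellular region, extracellular
#' space, extracellular exosome, extracellular vesicle. Genes with no
#' extracellular annotation score 0.
#'
#' @param compartment_rows Tibble with `gene`, `category`, `score`
#'   (scores in 0-5).
#' @return Tibble: `gene`, `extracellular_score`.
#' @export
extracellular_score <- function(compartment_rows) {
  cats <- c("Extracellular region", "Extracellular space",
            "Extracellular exosome", "Extracellular vesicle")
  stopifnot(all(compartment_rows$score >= 0 & compartment_rows$score <= 5))
  compartment_rows |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      extracellular_score =
        max(c(0, .data$score[.data$category %in% cats])),
      .groups = "drop")
}

# residualize gene x sample matrix rows on a covariate (plus intercept)
residualize_rows <- function(M, covariate) {
  X <- stats::model.matrix(~ covariate)
  Q <- qr(X)
  t(stats::resid(stats::lm.fit(X, t(M))))
}

#' Endocrine connectivity (Ssec) scores
#'
#' For each origin-tissue gene, computes biweight midcorrelations against
#' every target-tissue gene, converts them to two-sided p-values (t
#' approximation, df n-2), and sums `-ln(p)` over target genes to give the
#' raw Ssec; the normalized Ssec divides by the number of target genes, so
#' under independence its null mean is 1. When `adjust` is given, both
#' matrices are residualized on the covariate before correlation. Ranks
#' are descending (rank 1 = strongest endocrine connectivity). Constant
#' genes are excluded and counted.
#'
#' @param origin Origin-tissue gene x sample matrix (secretory genes).
#' @param target Target-tissue gene x sample matrix (same samples).
#' @param adjust Optional covariate vector (e.g. sex) for residualization.
#' @param log_base Base of the log in the score; `exp(1)` per the score's
#'   definition, `10` gives the same ranks scaled by `1/ln 10`.
#' @return Object of class `exermap_ssec`: tibble with `gene`,
#'   `ssec_raw`, `ssec`, `rank`, plus attributes `n_target`,
#'   `n_excluded`.
#' @export
ssec <- function(origin, target, adjust = NULL, log_base = exp(1)) {
  origin <- as.matrix(origin); target <- as.matrix(target)
  stopifnot(ncol(origin) == ncol(target))
  n <- ncol(origin)
  if (n < 6L) stop("need at least 6 shared samples")
  const_o <- apply(origin, 1L, stats::sd) == 0
  const_t <- apply(target, 1L, stats::sd) == 0
  origin <- origin[!const_o, , drop = FALSE]
  target <- target[!const_t, , drop = FALSE]
  if (!is.null(adjust)) {
    stopifnot(length(adjust) == n)
    adjust <- factor(adjust)
    origin <- residualize_rows(origin, adjust)
    target <- residualize_rows(target, adjust)
  }
  R <- bicor_matrix(t(origin), t(target))   # origin x target correlations
  P <- cor_pvalue(R, n)
  P <- pmax(P, 1e-300)
  raw <- unname(rowSums(-log(P, base = log_base)))
  tbl <- tibble::tibble(gene = rownames(origin), ssec_raw = raw,
                        ssec = raw / nrow(target))
  tbl$rank <- rank(-tbl$ssec, ties.method = "first")
  structure(tbl, class = c("exermap_ssec", class(tbl)),
            n_target = nrow(target),
            n_excluded = sum(const_o) + sum(const_t))
}

#' @export
tidy.exermap_ssec <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.exermap_ssec <- function(x, ...) {
  tibble::tibble(n_origin = nrow(x), n_target = attr(x, "n_target"),
                 mean_ssec = mean(x$ssec), max_ssec = max(x$ssec),
                 top_gene = x$gene[which.min(x$rank)])
}

#' @export
autoplot.exermap_ssec <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$ssec)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "normalized Ssec", y = "density") +
    ggplot2::theme_minimal()
}

#' Compare candidate Ssec ranks between two conditions
#'
#' Paired Wilcoxon signed-rank and paired t tests on the Ssec ranks of
#' candidate genes present in both conditions (e.g. untrained control vs
#' trained), with per-gene rank changes. With fewer than 5 candidates the
#' Wilcoxon test uses its exact distribution.
#'
#' @param ssec_a,ssec_b `exermap_ssec` tables for the two conditions.
#' @param candidates Gene identifiers to compare.
#' @return List: `wilcoxon_p`, `paired_t_p`, `rank_deltas` (tibble with
#'   `gene`, `rank_a`, `rank_b`, `delta`).
#' @export
rank_shift_test <- function(ssec_a, ssec_b, candidates) {
  a <- ssec_a[match(candidates, ssec_a$gene), ]
  b <- ssec_b[match(candidates, ssec_b$gene), ]
  ok <- !is.na(a$rank) & !is.na(b$rank)
  if (!any(ok)) stop("no candidates present in both tables")
  a <- a[ok, ]; b <- b[ok, ]
  deltas <- tibble::tibble(gene = a$gene, rank_a = a$rank, rank_b = b$rank,
                           delta = b$rank - a$rank)
  wp <- if (all(deltas$delta == 0)) 1 else
    stats::wilcox.test(a$rank, b$rank, paired = TRUE,
                       exact = nrow(deltas) < 5)$p.value
  tp <- if (all(deltas$delta == 0)) 1 else
    stats::t.test(a$rank, b$rank, paired = TRUE)$p.value
  list(wilcoxon_p = wp, paired_t_p = tp, rank_deltas = deltas)
}

#' Correlation enrichment of one origin gene in a target tissue
#'
#' Biweight midcorrelations of the origin gene against every target-tissue
#' gene are z-scored and fed to the pre-ranked competitive set test. If
#' the origin gene itself appears among the target genes, its
#' self-correlation row is excluded.
#'
#' @param origin_gene Named numeric vector (expression across samples),
#'   or a one-row matrix; the name is used for the self-correlation guard.
#' @param target Target gene x sample matrix.
#' @param collection A [set_collection()] filtered against the target
#'   genes.
#' @param adjust Optional covariate for residualization.
#' @param inter_feature_cor Passed to [camera_pr()].
#' @return Tibble from [camera_pr()].
#' @export
gene_correlation_enrichment <- function(origin_gene, target, collection,
                                        adjust = NULL,
                                        inter_feature_cor = 0.01) {
  if (is.matrix(origin_gene)) {
    gname <- rownames(origin_gene)[1L]
    origin_gene <- origin_gene[1L, ]
  } else {
    gname <- names(origin_gene)[1L]
  }
  target <- as.matrix(target)
  if (!is.null(gname) && gname %in% rownames(target)) {
    message("origin gene '", gname,
            "' present in target matrix; self-correlation row excluded")
    target <- target[setdiff(rownames(target), gname), , drop = FALSE]
  }
  if (!is.null(adjust)) {
    adjust <- factor(adjust)
    origin_gene <- as.numeric(residualize_rows(rbind(origin_gene), adjust))
    target <- residualize_rows(target, adjust)
  }
  r <- as.numeric(bicor_matrix(cbind(origin_gene), t(target)))
  names(r) <- rownames(target)
  z <- as.numeric(scale(r))
  names(z) <- rownames(target)
  camera_pr(z, collection, inter_feature_cor = inter_feature_cor)
}
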