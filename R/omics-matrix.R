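#' Construct an omics matrix
#'
#' Light-weight container for one ome's feature-by-sample abundances: a
#' numeric matrix with feature metadata, the ome label, and the value scale
#' carried as attributes. Rows are features, columns are samples; column
#' names must match `sample_id`s of a sample design table.
#'
#' @param values Numeric matrix, features x samples, with dimnames.
#' @param ome One of `"transcript"`, `"protein"`, `"phosphosite"`,
#'   `"metabolite"`.
#' @param scale Value scale: `"raw"`, `"log2"` or `"normalized"`.
#' @param feature_meta Optional tibble with a `feature_id` column matching
#'   `rownames(values)`; typically carries `gene_symbol`, `refmet_id`,
#'   `platform` or `class` columns.
#' @return The matrix with class `exermap_omics` and the metadata attached.
#' @export
omics_matrix <- function(values,
                         ome = c("transcript", "protein", "phosphosite",
                                 "metabolite"),
                         scale = c("raw", "log2", "normalized"),
                         feature_meta = NULL) {
  ome <- match.arg(ome)
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature_ids in values")
  }
  if (!is.null(feature_meta)) {
    feature_meta <- tibble::as_tibble(feature_meta)
    stopifnot("feature_id" %in% names(feature_meta))
  }
  structure(values, class = c("exermap_omics", class(values)),
            ome = ome, value_scale = scale, feature_meta = feature_meta)
}

#' @export
print.exermap_omics <- function(x, ...) {
  cat("<exermap_omics> ome=", attr(x, "ome"),
      " scale=", attr(x, "value_scale"),
      " [", nrow(x), " features x ", ncol(x), " samples]\n", sep = "")
  invisible(x)
}

# Rebuild the container after a row/column subset or value transform.
rewrap_omics <- function(values, template, scale = NULL) {
  fm <- attr(template, "feature_meta")
  if (!is.null(fm)) fm <- fm[match(rownames(values), fm$feature_id), ]
  omics_matrix(values, ome = attr(template, "ome"),
               scale = scale %||% attr(template, "value_scale"),
               feature_meta = fm)
}

ome_of <- function(m) attr(m, "ome") %||% "unknown"
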