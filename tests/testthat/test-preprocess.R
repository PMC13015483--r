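read_toy <- function(name) {
  path <- system.file("extdata", name, package = "exermap")
  if (path == "") path <- file.path("../../inst/extdata", name)
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d[[1]]
  m
}

toy_matrix <- function() {
  path <- system.file("extdata", "metabolite_toy.tsv", package = "exermap")
  if (path == "") path <- "../../inst/extdata/metabolite_toy.tsv"
  lines <- strsplit(readLines(path), "\t")
  header <- lines[[1]][-1]
  m <- do.call(rbind, lapply(lines[-1], function(x)
    suppressWarnings(as.numeric(x[-1]))))
  rownames(m) <- vapply(lines[-1], `[`, "", 1)
  colnames(m) <- header
  m
}

test_that("metabolomics cleaning applies the steps in order", {
  m <- toy_matrix()
  out <- clean_metabolites(m)
  X <- out$matrix
  # duplicate M01 rows averaged: (10+14)/2 = 12 before log2(x+1)
  expect_equal(unname(X["M01", "S01"]), log2(12 + 1))
  # M02 missing 30% > 20% -> removed
  expect_false("M02" %in% rownames(X))
  # M03 at exactly 20% missing -> kept
  expect_true("M03" %in% rownames(X))
  # half-minimum path (10 features <= 12): M03 min observed 4 -> imputed 2
  expect_equal(unname(X["M03", "S01"]), log2(2 + 1))
  # M04's -3 and 0 became missing (20%) -> kept, half-min = 6/2 = 3
  expect_equal(unname(X["M04", "S01"]), log2(3 + 1))
  expect_false(anyNA(X))
  # conservation at every step
  expect_true(all(out$qc$n_in == out$qc$n_out + out$qc$n_removed))
})

test_that("a complete positive matrix passes through as log2(x + 1)", {
  m <- matrix(1:20, 4, 5, dimnames = list(paste0("f", 1:4), paste0("s", 1:5)))
  out <- clean_metabolites(m)
  expect_equal(out$matrix, log2(m + 1))
})

test_that("KNN imputation is used above the feature-count threshold", {
  set.seed(1)
  m <- matrix(rexp(30 * 12, 0.2) + 1, 30, 12,
              dimnames = list(paste0("f", 1:30), paste0("s", 1:12)))
  m[1, 1] <- NA
  out <- clean_metabolites(m)
  expect_equal(out$qc$note[out$qc$step == "imputation"], "KNN, k=10")
  expect_false(anyNA(out$matrix))
  # imputed value is plausible, not the half-minimum
  expect_gt(2^out$matrix[1, 1] - 1, min(m[1, ], na.rm = TRUE) / 2 + 1e-9)
})

test_that("all features removed raises an explicit error", {
  m <- matrix(NA_real_, 3, 10,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:10)))
  m[, 1] <- 1 # 90% missing everywhere
  expect_error(clean_metabolites(m), "all features removed")
})

test_that("median/MAD normalization is gated on sex and group association", {
  design <- tiny_design(n = 10, groups = c("EE", "RE", "CON"))
  set.seed(2)
  m <- matrix(rnorm(40 * nrow(design), mean = 8), 40,
              dimnames = list(paste0("f", 1:40), design$sample_id))
  out <- conditional_median_mad_normalize(m, design)
  expect_true(out$applied)
  expect_equal(unname(apply(out$matrix, 2, median)), rep(0, ncol(m)),
               tolerance = 1e-12)
  # plant a strong sex shift in the sample medians -> gate blocks
  shift <- ifelse(design$sex == "M", 4, 0)
  m2 <- sweep(m, 2, shift, "+")
  out2 <- conditional_median_mad_normalize(m2, design)
  expect_false(out2$applied)
  expect_equal(out2$matrix, m2)
  expect_lt(min(out2$gate$p), 0.01)
})

test_that("the normalization gate is invariant to sample order", {
  design <- tiny_design(n = 8, groups = c("EE", "CON"))
  set.seed(3)
  m <- matrix(rnorm(30 * nrow(design), 8), 30,
              dimnames = list(paste0("f", 1:30), design$sample_id))
  out1 <- conditional_median_mad_normalize(m, design)
  perm <- sample(ncol(m))
  out2 <- conditional_median_mad_normalize(m[, perm], design)
  expect_equal(out1$applied, out2$applied)
  expect_equal(out1$gate$p, out2$gate$p, tolerance = 1e-12)
})

test_that("a constant sample is centred but not rescaled", {
  design <- tiny_design(n = 4, groups = c("EE", "CON"))
  set.seed(4)
  m <- matrix(rnorm(20 * nrow(design), 5), 20,
              dimnames = list(paste0("f", 1:20), design$sample_id))
  m[, 1] <- 7
  out <- conditional_median_mad_normalize(m, design)
  if (out$applied) expect_equal(unname(out$matrix[, 1]), rep(0, 20))
})

test_that("principal-component outliers are flagged by the 5x IQR rule", {
  set.seed(5)
  m <- matrix(rnorm(40 * 50), 40, dimnames = list(paste0("f", 1:40),
                                                  paste0("s", 1:50)))
  # displace one sample far along the dominant direction
  m[, 1] <- m[, 1] + 30
  flagged <- flag_pc_outliers(m, iqr_mult = 5)
  expect_true("s1" %in% flagged)
  # brute-force check of the boxplot bound on PC1
  pc <- prcomp(t(m))$x[, 1]
  q <- quantile(pc, c(.25, .75)); iqr <- q[2] - q[1]
  expect_true(pc["s1"] < q[1] - 5 * iqr || pc["s1"] > q[2] + 5 * iqr)
})

test_that("spherical data produce no flags at mult 5 and many at mult 0", {
  set.seed(6)
  m <- matrix(rnorm(30 * 100), 30, dimnames = list(paste0("f", 1:30),
                                                   paste0("s", 1:100)))
  expect_length(flag_pc_outliers(m, iqr_mult = 5), 0)
  expect_gt(length(flag_pc_outliers(m, iqr_mult = 0)), 30)
  expect_warning(res <- flag_pc_outliers(m[, 1:2]), "fewer than 3")
  expect_length(res, 0)
})

test_that("platform redundancy resolves to the lowest-CV platform", {
  feats <- tibble::tibble(
    refmet_id = c("X", "X", "Y"),
    platform = c("A", "B", "B"))
  cvs <- tibble::tibble(platform = c("A", "A", "B", "B"),
                        cv = c(0.06, 0.10, 0.12, 0.18))
  out <- resolve_platform_redundancy(feats, cvs)
  expect_true(out$keep[out$refmet_id == "X" & out$platform == "A"])
  expect_false(out$keep[out$refmet_id == "X" & out$platform == "B"])
  expect_true(out$keep[out$refmet_id == "Y"]) # single platform kept
  # tie breaks lexicographically
  tie <- resolve_platform_redundancy(
    tibble::tibble(refmet_id = c("Z", "Z"), platform = c("Q", "B")),
    tibble::tibble(platform = c("Q", "B"), cv = c(0.1, 0.1)))
  expect_true(tie$keep[tie$platform == "B"])
  expect_match(tie$reason[1], "tie")
  # missing CV falls back with a warning
  expect_warning(
    fb <- resolve_platform_redundancy(
      tibble::tibble(refmet_id = c("W", "W"), platform = c("A", "C")),
      cvs),
    "missing CV")
  expect_equal(sum(fb$keep), 1)
})

test_that("platform redundancy works on the packaged fixture", {
  path <- system.file("extdata", "platform_features_toy.tsv",
                      package = "exermap")
  if (path == "") path <- "../../inst/extdata/platform_features_toy.tsv"
  feats <- tibble::as_tibble(utils::read.delim(path))
  cvp <- system.file("extdata", "standards_cv_toy.tsv", package = "exermap")
  if (cvp == "") cvp <- "../../inst/extdata/standards_cv_toy.tsv"
  cvs <- tibble::as_tibble(utils::read.delim(cvp))
  out <- resolve_platform_redundancy(feats, cvs)
  # REFMET:X -> hilicpos (mean CV 0.08 < 0.15); REFMET:Z tie -> hilicpos
  expect_true(out$keep[out$feature_id == "f1"])
  expect_false(out$keep[out$feature_id == "f2"])
  expect_true(out$keep[out$feature_id == "f3"])
  expect_true(out$keep[out$feature_id == "f4"])
  expect_false(out$keep[out$feature_id == "f5"])
})

test_that("the low-expression filter applies the literal boundary rule", {
  lib <- 1e6 # CPM == count
  counts <- rbind(
    g_low10 = c(rep(0.5, 1), rep(100, 9)),  # CPM <= 0.5 in exactly 10%
    g_high = rep(100, 10),
    g_low9 = c(rep(0.4, 0), rep(100, 10)))
  counts <- counts * 1
  colnames(counts) <- paste0("s", 1:10)
  # pad library sizes to 1e6 with a filler gene so CPM equals count
  filler <- lib - colSums(counts)
  m <- rbind(counts, filler = filler)
  out <- filter_low_expression(m, rule = "literal")
  expect_false("g_low10" %in% rownames(out)) # boundary: >= 10% removed
  expect_true("g_high" %in% rownames(out))
  out2 <- filter_low_expression(m, rule = "conventional")
  expect_true("g_low10" %in% rownames(out2)) # exceeds 0.5 in 90% of samples
  zero <- m; zero[, 1] <- 0
  expect_error(filter_low_expression(zero), "zero library")
})

test_that("the proteomics quantification filter keeps the 30% boundary", {
  m <- matrix(NA_real_, 3, 10, dimnames = list(c("p29", "p30", "p100"),
                                               paste0("s", 1:10)))
  m["p29", 1:2] <- 1     # 20% quantified (spec example: 29% -> removed)
  m["p30", 1:3] <- 1     # exactly 30% -> kept
  m["p100", ] <- 1
  out <- filter_min_quantified(m, 0.30)
  expect_equal(rownames(out), c("p30", "p100"))
})

test_that("filters are idempotent on their own output", {
  set.seed(7)
  m <- matrix(rpois(200 * 10, 5), 200,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:10)))
  f1 <- filter_low_expression(m, rule = "conventional")
  expect_equal(filter_low_expression(f1, rule = "conventional"), f1)
  p <- matrix(rnorm(100 * 10), 100,
              dimnames = list(paste0("p", 1:100), paste0("s", 1:10)))
  p[sample(length(p), 600)] <- NA
  f2 <- filter_min_quantified(p)
  expect_equal(filter_min_quantified(f2), f2)
})

test_that("technical regression removes an orthogonal batch exactly", {
  design <- tiny_design(n = 8, groups = c("EE", "CON"))
  n <- nrow(design)
  set.seed(8)
  # noiseless ground truth that depends only on the protected design, so
  # the jointly estimated batch coefficient is exact
  cellmate <- interaction(design$group, design$timepoint)
  cell_eff <- matrix(rnorm(50 * nlevels(cellmate)), 50)
  clean <- cell_eff[, as.integer(cellmate)]
  dimnames(clean) <- list(paste0("f", 1:50), design$sample_id)
  batch <- unsplit(lapply(split(seq_len(n), cellmate), function(i)
    rep_len(c("b1", "b2"), length(i))), cellmate)
  dirty <- clean + outer(rep(1, 50), ifelse(batch == "b2", 1, 0))
  out <- regress_technical(dirty, technical = data.frame(batch = batch),
                           protected = design[, c("group", "timepoint")])
  expect_equal(out$matrix, clean, tolerance = 1e-8)
  # with noise: protected-effect estimates are unchanged when re-fit on
  # the residualized data (up to the removed batch contribution)
  noisy <- dirty + matrix(rnorm(50 * n, sd = 0.5), 50)
  res <- regress_technical(noisy, technical = data.frame(batch = batch),
                           protected = design[, c("group", "timepoint")])
  P <- model.matrix(~ group + timepoint, design)
  cf_before <- qr.coef(qr(cbind(P, batch == "b2")), t(noisy))[1:ncol(P), ]
  cf_after <- qr.coef(qr(P), t(res$matrix))
  expect_equal(cf_before, cf_after, tolerance = 1e-6)
})

test_that("no technical covariates means identity; collinear batch is skipped", {
  design <- tiny_design(n = 4, groups = c("EE", "CON"))
  m <- matrix(rnorm(10 * nrow(design)), 10,
              dimnames = list(paste0("f", 1:10), design$sample_id))
  out <- regress_technical(m, technical = NULL,
                           protected = design[, c("group", "timepoint")])
  expect_identical(out$matrix, m)
  # batch identical to group -> confounded, skipped with warning
  expect_warning(
    out2 <- regress_technical(m, technical = data.frame(batch = design$group),
                              protected = design[, c("group", "timepoint")]),
    "collinear")
  expect_equal(out2$matrix, m)
  expect_equal(out2$skipped, "batch")
})
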