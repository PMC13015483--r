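test_that("balanced complete data recover per-cell averages and the raw
           delta-delta arithmetic", {
  design <- tiny_design(n = 8, groups = c("EE", "CON"))
  set.seed(1)
  y <- rnorm(nrow(design), mean = ifelse(design$group == "EE" &
                                           design$timepoint == "4hr", 2, 0))
  names(y) <- design$sample_id
  fit <- fit_feature(y, design, covariates = character())
  cells <- split(y, paste(design$group, design$timepoint, sep = "_"))
  for (cn in names(cells)) {
    expect_equal(unname(fit$beta[cn]), mean(cells[[cn]]), tolerance = 1e-6)
  }
  ct <- contrast_cellmeans(fit, "difference_in_changes", "EE", "4hr")
  raw_dd <- (mean(cells$EE_4hr) - mean(cells$EE_pre)) -
    (mean(cells$CON_4hr) - mean(cells$CON_pre))
  expect_equal(ct$estimate, raw_dd, tolerance = 1e-8)
})

test_that("equal weights reproduce the unweighted fit", {
  design <- tiny_design(n = 6, groups = c("EE", "CON"))
  set.seed(2)
  y <- rnorm(nrow(design))
  f1 <- fit_feature(y, design, covariates = character())
  f2 <- fit_feature(y, design, covariates = character(),
                    weights = rep(2, nrow(design)))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  c1 <- contrast_cellmeans(f1, "difference_in_changes", "EE", "4hr")
  c2 <- contrast_cellmeans(f2, "difference_in_changes", "EE", "4hr")
  expect_equal(c1$p_value, c2$p_value, tolerance = 1e-6)
})

test_that("variance components are recovered across simulated features", {
  design <- tiny_design(n = 25, groups = c("EE", "CON"))
  pid <- match(design$participant_id, unique(design$participant_id))
  set.seed(3)
  est <- t(replicate(100, {
    u <- rnorm(max(pid), sd = 2)      # random-intercept variance 4
    y <- u[pid] + rnorm(nrow(design)) # residual variance 1
    fit <- fit_feature(y, design, covariates = character())
    c(fit$tau2, fit$sigma2)
  }))
  expect_equal(mean(est[, 1]), 4, tolerance = 0.25 * 4)
  expect_equal(mean(est[, 2]), 1, tolerance = 0.25)
})

test_that("estimates, SEs and variance components match the established
           mixed-model implementation", {
  skip_if_not_installed("lmerTest")
  design <- tiny_design(n = 10, groups = c("EE", "RE", "CON"))
  pid <- match(design$participant_id, unique(design$participant_id))
  set.seed(4)
  for (rep in 1:3) {
    y <- rnorm(max(pid), sd = 1.2)[pid] + rnorm(nrow(design))
    fit <- fit_feature(y, design, covariates = c("age", "sex")[rep %% 2 + 1])
    cov_used <- c("age", "sex")[rep %% 2 + 1]
    df <- data.frame(y = y, design)
    df$cell <- paste(df$group, df$timepoint, sep = "_")
    form <- if (cov_used == "age") {
      y ~ 0 + cell + scale(age, scale = FALSE) + (1 | participant_id)
    } else y ~ 0 + cell + sex + (1 | participant_id)
    lf <- suppressMessages(lmerTest::lmer(form, data = df, REML = TRUE))
    fe <- lme4::fixef(lf)
    cellnames <- grep("^cell", names(fe), value = TRUE)
    expect_equal(unname(fit$beta[sub("^cell", "", cellnames)]),
                 unname(fe[cellnames]), tolerance = 1e-5)
    expect_equal(fit$sigma2, sigma(lf)^2, tolerance = 1e-4)
    expect_equal(fit$tau2, unname(unlist(lme4::VarCorr(lf))),
                 tolerance = 1e-3)
    # Satterthwaite p agrees closely (expected vs observed information)
    L <- setNames(numeric(length(fe)), names(fe))
    L[c("cellEE_4hr", "cellEE_pre", "cellCON_4hr", "cellCON_pre")] <-
      c(1, -1, -1, 1)
    ref <- lmerTest::contest(lf, L, joint = FALSE)
    ct <- contrast_cellmeans(fit, "difference_in_changes", "EE", "4hr")
    expect_equal(ct$estimate, ref$Estimate, tolerance = 1e-5)
    expect_equal(ct$se, ref$`Std. Error`, tolerance = 1e-5)
    expect_equal(ct$p_value, ref$`Pr(>|t|)`, tolerance = 0.02)
  }
})

test_that("the three contrast families estimate their targets", {
  d <- generate_cohort(c(EE = 20, RE = 20, CON = 20),
                       profile_weights = c(0, 1, 0), seed = 5)
  pid <- match(d$participant_id, unique(d$participant_id))
  is_post <- d$timepoint == "4hr"
  set.seed(6)
  reps <- t(replicate(40, {
    base <- rnorm(max(pid), sd = 1)[pid] + rnorm(nrow(d), sd = 0.5)
    # planted dd effect +1 in EE and RE; plus a global time shift 0.5
    y <- base + 1 * (is_post & d$group != "CON") + 0.5 * is_post
    fit <- fit_feature(y, d, covariates = character())
    c(dd = contrast_cellmeans(fit, "difference_in_changes", "EE",
                              "4hr")$estimate,
      gs_con = contrast_cellmeans(fit, "group_specific", "CON",
                                  "4hr")$estimate,
      mod = contrast_cellmeans(fit, "modality", timepoint = "4hr")$estimate)
  }))
  expect_equal(mean(reps[, "dd"]), 1, tolerance = 0.15)
  # control change picks up only the global circadian-like shift
  expect_equal(mean(reps[, "gs_con"]), 0.5, tolerance = 0.15)
  # identical EE and RE effects: modality contrast centred at zero
  expect_equal(mean(reps[, "mod"]), 0, tolerance = 0.15)
})

test_that("a global time-of-day shift is significant group-specifically but
           null in the difference-in-changes family", {
  d <- generate_cohort(c(EE = 25, RE = 0, CON = 25),
                       profile_weights = c(0, 1, 0), seed = 7)
  pid <- match(d$participant_id, unique(d$participant_id))
  set.seed(8)
  pg <- replicate(30, {
    y <- rnorm(max(pid))[pid] + rnorm(nrow(d), sd = 0.3) +
      1 * (d$timepoint == "4hr")
    fit <- fit_feature(y, d, covariates = character())
    c(contrast_cellmeans(fit, "group_specific", "EE", "4hr")$p_value,
      contrast_cellmeans(fit, "difference_in_changes", "EE", "4hr")$p_value)
  })
  expect_gt(mean(pg[1, ] < 0.05), 0.9)  # time effect detected within group
  expect_lt(mean(pg[2, ] < 0.05), 0.2)  # but nulled by the control arm
})

test_that("minimum-pairs rule marks contrasts testable at >= 3 paired
           participants per involved group", {
  d <- generate_cohort(c(EE = 4, RE = 4, CON = 4),
                       profile_weights = c(0, 1, 0), seed = 9)
  obs <- matrix(TRUE, 2, nrow(d), dimnames = list(c("f1", "f2"), d$sample_id))
  # f2: only 2 EE participants have complete pairs
  ee_parts <- unique(d$participant_id[d$group == "EE"])
  drop <- d$sample_id[d$participant_id %in% ee_parts[1:2] &
                        d$timepoint != "pre"]
  obs["f2", drop] <- FALSE
  pairs <- min_pairs_filter(d, obs)
  p1 <- pairs[pairs$feature_id == "f1", ]
  p2 <- pairs[pairs$feature_id == "f2", ]
  expect_true(all(p1$testable))
  expect_equal(p2$n_pairs[p2$group == "EE"], 2L)
  expect_false(p2$testable[p2$group == "EE"])
  expect_false(contrast_testable(p2, "difference_in_changes", "EE", "4hr"))
  expect_true(contrast_testable(p2, "difference_in_changes", "RE", "4hr"))
  expect_false(contrast_testable(p2, "modality", NULL, "4hr"))
  # boundary: exactly 3 pairs is testable
  obs["f2", drop[1]] <- TRUE
  pairs3 <- min_pairs_filter(d, obs)
  p23 <- pairs3[pairs3$feature_id == "f2", ]
  expect_equal(p23$n_pairs[p23$group == "EE"], 3L)
  expect_true(p23$testable[p23$group == "EE"])
})

test_that("stratified BH matches the hand computation and stays within
           strata", {
  r <- tibble::tibble(
    feature_id = paste0("f", 1:4), family = "difference_in_changes",
    group = "EE", ome = "protein", timepoint = "4hr",
    p_value = c(0.01, 0.02, 0.03, 0.04))
  out <- adjust_stratified(r)
  expect_equal(out$adj_p_value, rep(0.04, 4))
  # two strata adjusted independently
  r2 <- dplyr::bind_rows(
    tibble::tibble(feature_id = c("a", paste0("n", 1:99)), family = "dd",
                   group = "EE", ome = "p", timepoint = "4hr",
                   p_value = c(0.01, runif(99, 0.2, 1))),
    tibble::tibble(feature_id = c("b", paste0("m", 1:99)), family = "dd",
                   group = "EE", ome = "p", timepoint = "24hr",
                   p_value = c(0.01, runif(99, 0.2, 1))))
  out2 <- adjust_stratified(r2)
  for (tp in c("4hr", "24hr")) {
    sub <- out2[out2$timepoint == tp, ]
    expect_equal(sort(sub$adj_p_value),
                 sort(p.adjust(sub$p_value, "BH")))
  }
  # single feature: adjusted equals raw
  single <- adjust_stratified(tibble::tibble(
    feature_id = "x", family = "dd", group = "EE", ome = "p",
    timepoint = "4hr", p_value = 0.2))
  expect_equal(single$adj_p_value, 0.2)
})

test_that("sex differences use the male-minus-female convention and are
           calibrated under permutation", {
  set.seed(10)
  n <- 160
  sex <- rep(c("F", "M"), each = n / 2)
  X <- matrix(rnorm(400 * n), 400, dimnames = list(paste0("f", 1:400),
                                                   paste0("s", 1:n)))
  X[1:20, sex == "M"] <- X[1:20, sex == "M"] + 1 # male-up features
  res <- sex_difference(X, sex)
  expect_gt(min(res$estimate[1:20]), 0) # positive = up in males
  expect_gte(sum(res$significant[1:20]), 19) # power at n=80/group, effect 1
  null_p <- res$p_value[-(1:20)]
  expect_lt(abs(mean(null_p < 0.05) - 0.05), 0.03)
  expect_error(sex_difference(X, rep("F", n)), "both sexes")
})

test_that("z-score matrix collapses by extreme z and expands multi-site
           phosphopeptides", {
  r <- tibble::tibble(
    feature_id = c("tx1", "tx2", "p1", "p2"),
    contrast = "dd:EE:4hr",
    estimate = c(1, -2, 1, 1),
    p_value = c(2 * pnorm(-1.2), 2 * pnorm(-2.5), 0.5, 1))
  mapping <- tibble::tibble(feature_id = c("tx1", "tx2", "p1", "p2"),
                            symbol = c("G", "G", "H", "H"))
  z <- build_zscore_matrix(r, mapping)
  # G carries the more extreme of +1.2 / -2.5
  expect_equal(unname(z["G", 1]), -2.5, tolerance = 1e-6)
  # p = 1 maps to z = 0
  expect_equal(unname(z["H", 1]), qnorm(0.75), tolerance = 1e-6)
  # multi-site expansion duplicates the row information
  rp <- tibble::tibble(feature_id = "PROT_S1;S2", contrast = "c",
                       estimate = 3, p_value = 2 * pnorm(-3))
  zp <- build_zscore_matrix(rp, phospho_expand = TRUE)
  expect_setequal(rownames(zp), c("PROT_S1", "PROT_S2"))
  expect_equal(unname(zp["PROT_S1", 1]), unname(zp["PROT_S2", 1]))
  expect_equal(unname(zp["PROT_S1", 1]), 3, tolerance = 1e-6)
  # p = 0 capped; unmapped dropped and counted
  r0 <- tibble::tibble(feature_id = c("a", "b"), contrast = "c",
                       estimate = c(1, 1), p_value = c(0, 0.5))
  z0 <- build_zscore_matrix(r0, tibble::tibble(feature_id = "a",
                                               symbol = "A"))
  expect_equal(unname(z0["A", 1]), 38)
  expect_equal(attr(z0, "n_unmapped"), 1L)
})

test_that("precision weights are flat for homoscedastic data and
           monotone for overdispersed counts", {
  design <- tiny_design(n = 12, groups = c("EE", "CON"))
  n <- nrow(design)
  set.seed(11)
  # homoscedastic surrogate: equal-mean Poisson-like counts
  flat <- matrix(rpois(300 * n, 500), 300,
                 dimnames = list(paste0("g", 1:300), design$sample_id))
  wf <- estimate_precision_weights(flat, design, covariates = character())
  expect_lt(sd(wf$weights) / mean(wf$weights), 0.25)
  # negative-binomial counts across a wide mean range
  mu <- exp(runif(300, log(2), log(2000)))
  nb <- matrix(rnbinom(300 * n, mu = mu, size = 2), 300,
               dimnames = list(paste0("g", 1:300), design$sample_id))
  wnb <- estimate_precision_weights(nb, design, covariates = character())
  mw <- rowMeans(wnb$weights)
  expect_gt(cor(log(mu + 1), log(mw), method = "spearman"), 0.5)
  expect_error(estimate_precision_weights(nb[, 1, drop = FALSE], design),
               "2 samples")
  expect_warning(estimate_precision_weights(nb[1:5, ], design),
                 "fewer than 10")
})

test_that("fit_differential runs end to end with stratified adjustment and
           testability flags", {
  d <- generate_cohort(c(EE = 8, RE = 8, CON = 8), seed = 12)
  sim <- generate_omics(d, effect_spec(
    n_features_per_ome = c(protein = 30), n_modules = 0, module_size = 0,
    frac_dd_affected = 0.3, dd_effect = 2, missing_frac = 0.1, seed = 13))
  res <- fit_differential(sim$matrices$protein, d,
                          families = "difference_in_changes",
                          covariates = c("age", "sex"))
  expect_true(all(c("adj_p_value", "significant", "stratum") %in% names(res)))
  expect_true(any(!res$testable) || all(res$testable))
  tr <- res[res$testable, ]
  expect_true(all(tr$p_value >= 0 & tr$p_value <= 1))
  expect_true(all(abs(tr$statistic - tr$estimate / tr$se) < 1e-8))
})
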