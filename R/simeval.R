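#' Specification for the repeated-measures simulation study
#'
#' Describes the generative model used to evaluate candidate longitudinal
#' analysis strategies: a three-group design over `n_timepoints` occasions
#' (pre plus post occasions), within-participant covariance, non-normal
#' marginals, temporal-profile missingness (each participant keeps pre plus
#' exactly one post occasion), and an alternative-hypothesis effect size
#' for power. Defaults are the adipose-like configuration: group sizes
#' 12/21/24 (CON/EE/RE), within-participant correlation 0.5, marginal
#' skewness 1 and excess kurtosis 3.
#'
#' @param group_sizes Named participant counts.
#' @param n_timepoints Total occasions (first is pre).
#' @param within_cor Within-participant correlation (compound symmetric).
#' @param sd Marginal standard deviation.
#' @param skew,kurt Marginal skewness / excess kurtosis.
#' @param means Optional group x timepoint mean matrix (default all zero).
#' @param effect_size Alternative-hypothesis difference-in-changes effect
#'   (added to the EE group's post occasions), in SD units.
#' @param missingness `"profile"` (pre + one post per participant) or
#'   `"none"` (complete).
#' @param n_reps Replicates per hypothesis.
#' @param alpha Test level.
#' @param seed Integer seed.
#' @return List of class `exermap_simspec`.
#' @export
simulation_spec <- function(group_sizes = c(CON = 12, EE = 21, RE = 24),
                            n_timepoints = 3, within_cor = 0.5, sd = 1,
                            skew = 1, kurt = 3, means = NULL,
                            effect_size = 1,
                            missingness = c("profile", "none"),
                            n_reps = 1000, alpha = 0.05, seed = 1L) {
  missingness <- match.arg(missingness)
  stopifnot(n_reps >= 1, within_cor > -1, within_cor < 1, sd > 0)
  if (is.null(means)) {
    means <- matrix(0, length(group_sizes), n_timepoints,
                    dimnames = list(names(group_sizes), NULL))
  }
  structure(as.list(environment()), class = "exermap_simspec")
}

# Fixed per-spec layout: participant table, observation rows, design
# matrix, and index structures shared by all strategies and replicates.
sim_layout <- function(spec) {
  g <- rep(names(spec$group_sizes), spec$group_sizes)
  n_sub <- length(g)
  post_tp <- seq.int(2L, spec$n_timepoints)
  # deterministic even split of participants over post profiles, per group
  profile <- unsplit(lapply(split(seq_len(n_sub), g),
                            function(i) rep_len(post_tp, length(i))), g)
  if (spec$missingness == "none") {
    obs <- data.frame(sub = rep(seq_len(n_sub), each = spec$n_timepoints),
                      tp = rep(seq_len(spec$n_timepoints), n_sub))
  } else {
    obs <- data.frame(sub = rep(seq_len(n_sub), each = 2L),
                      tp = as.vector(rbind(1L, profile)))
  }
  obs$group <- g[obs$sub]
  tp_lab <- c("pre", paste0("post", post_tp - 1L))
  design <- tibble::tibble(
    sample_id = paste0("S", seq_len(nrow(obs))),
    participant_id = paste0("P", obs$sub),
    group = obs$group, timepoint = tp_lab[obs$tp]
  )
  X <- build_cellmeans_X(design, character())
  # focal difference-in-changes contrast: EE at the first post occasion
  cvec <- stats::setNames(numeric(ncol(X)), colnames(X))
  cvec[c("EE_post1", "EE_pre", "CON_post1", "CON_pre")] <- c(1, -1, -1, 1)
  list(obs = obs, design = design, X = X, cvec = cvec, n_sub = n_sub,
       profile = profile, tp_lab = tp_lab)
}

# Draw all replicates at once: list of y matrices (obs x reps).
sim_draw <- function(spec, lay, effect, n_reps) {
  R <- matrix(spec$within_cor, spec$n_timepoints, spec$n_timepoints)
  diag(R) <- 1
  wide <- rnonnorm(n_reps * lay$n_sub, mean = 0, cov = R * spec$sd^2,
                   skew = spec$skew, kurt = spec$kurt)
  # reshape: row block r of `wide` holds the participants of replicate r
  Y <- matrix(0, nrow(lay$obs), n_reps)
  for (r in seq_len(n_reps)) {
    block <- wide[seq.int((r - 1L) * lay$n_sub + 1L, r * lay$n_sub), ,
                  drop = FALSE]
    Y[, r] <- block[cbind(lay$obs$sub, lay$obs$tp)]
  }
  base_mu <- spec$means[cbind(match(lay$obs$group, rownames(spec$means)),
                              lay$obs$tp)]
  eff <- effect * (lay$obs$group == "EE" & lay$obs$tp > 1L) * spec$sd
  Y + base_mu + eff
}

# --- strategy fitters: each returns the two-sided p for the focal contrast

strat_lmm_ri <- function(y, ctx) {
  fit <- ri_fit(ctx$d, y)
  est <- sum(ctx$cvec * fit$beta)
  se <- sqrt(as.numeric(t(ctx$cvec) %*% fit$C %*% ctx$cvec))
  df <- if (fit$singular) fit$n - fit$p else satterthwaite_df(fit, ctx$cvec)
  2 * stats::pt(-abs(est / se), df)
}

strat_ols <- function(y, ctx) {
  beta <- ctx$ols_H %*% y
  res <- y - ctx$X %*% beta
  s2 <- sum(res^2) / (nrow(ctx$X) - ncol(ctx$X))
  tstat <- sum(ctx$cvec * beta) / sqrt(s2 * ctx$ols_q)
  2 * stats::pt(-abs(tstat), nrow(ctx$X) - ncol(ctx$X))
}

strat_paired_t <- function(y, ctx) {
  dif <- y[ctx$pt_post] - y[ctx$pt_pre]
  if (length(dif) < 2L) return(NA_real_)
  stats::t.test(dif)$p.value
}

strat_gee_ar1 <- function(y, ctx) {
  p <- ncol(ctx$X)
  i1 <- ctx$pair1; i2 <- ctx$pair2          # first/second obs of each cluster
  lag <- ctx$pair_lag
  alpha <- 0
  beta <- ctx$ols_H %*% y
  X1 <- ctx$X[i1, , drop = FALSE]; X2 <- ctx$X[i2, , drop = FALSE]
  y1c <- y[i1]; y2c <- y[i2]
  for (it in 1:20) {
    e <- as.numeric(y - ctx$X %*% beta)
    phi <- sum(e^2) / (length(y) - p)
    # AR(1) parameter by least squares on the standardized residual
    # cross-products against alpha^lag, over all within-cluster pairs
    cp <- e[i1] * e[i2] / phi
    alpha <- stats::optimize(function(a) sum((cp - a^lag)^2),
                             c(-0.95, 0.95))$minimum
    r <- alpha^lag
    w <- 1 / (1 - r^2)
    # X' R^-1 X and X' R^-1 y accumulated over two-observation clusters
    B <- crossprod(X1, w * X1) + crossprod(X2, w * X2) -
      crossprod(X1, (w * r) * X2) - crossprod(X2, (w * r) * X1)
    bv <- crossprod(X1, w * (y1c - r * y2c)) +
      crossprod(X2, w * (y2c - r * y1c))
    beta_new <- solve(B, bv)
    done <- max(abs(beta_new - beta)) < 1e-8
    beta <- beta_new
    if (done) break
  }
  e <- as.numeric(y - ctx$X %*% beta)
  r <- alpha^lag
  w <- 1 / (1 - r^2)
  X1 <- ctx$X[i1, , drop = FALSE]; X2 <- ctx$X[i2, , drop = FALSE]
  U <- w * ((e[i1] - r * e[i2]) * X1 + (e[i2] - r * e[i1]) * X2)
  B <- crossprod(X1, w * X1) + crossprod(X2, w * X2) -
    crossprod(X1, (w * r) * X2) - crossprod(X2, (w * r) * X1)
  Binv <- solve(B)
  V <- Binv %*% crossprod(U) %*% Binv
  z <- sum(ctx$cvec * beta) / sqrt(as.numeric(t(ctx$cvec) %*% V %*% ctx$cvec))
  2 * stats::pnorm(-abs(z))
}

strat_mmrm_un <- function(y, ctx) {
  # moment-based GLS with unstructured occasion covariance (two-observation
  # clusters; Sigma estimated from residual cross-products per occasion pair)
  p <- ncol(ctx$X)
  beta <- ctx$ols_H %*% y
  tp <- ctx$obs_tp
  nt <- max(tp)
  for (it in 1:3) {
    e <- as.numeric(y - ctx$X %*% beta)
    S <- diag(stats::ave(e^2, tp, FUN = mean)[match(seq_len(nt), tp)], nt)
    for (a in seq_len(nt - 1L)) for (b in seq.int(a + 1L, nt)) {
      sel <- (tp[ctx$pair1] == a & tp[ctx$pair2] == b) |
        (tp[ctx$pair1] == b & tp[ctx$pair2] == a)
      if (any(sel)) {
        S[a, b] <- S[b, a] <- mean(e[ctx$pair1[sel]] * e[ctx$pair2[sel]])
      }
    }
    lim <- sqrt(diag(S))
    # keep the pairwise moment estimate a valid covariance
    for (a in seq_len(nt - 1L)) for (b in seq.int(a + 1L, nt)) {
      cap <- 0.99 * lim[a] * lim[b]
      S[a, b] <- S[b, a] <- min(max(S[a, b], -cap), cap)
    }
    i1 <- ctx$pair1; i2 <- ctx$pair2
    v11 <- diag(S)[tp[i1]]; v22 <- diag(S)[tp[i2]]
    v12 <- S[cbind(tp[i1], tp[i2])]
    det2 <- v11 * v22 - v12^2
    X1 <- ctx$X[i1, , drop = FALSE]; X2 <- ctx$X[i2, , drop = FALSE]
    y1 <- y[i1]; y2 <- y[i2]
    B <- crossprod(X1, (v22 / det2) * X1) + crossprod(X2, (v11 / det2) * X2) -
      crossprod(X1, (v12 / det2) * X2) - crossprod(X2, (v12 / det2) * X1)
    bv <- crossprod(X1, (v22 * y1 - v12 * y2) / det2) +
      crossprod(X2, (v11 * y2 - v12 * y1) / det2)
    beta <- solve(B, bv)
  }
  se <- sqrt(as.numeric(t(ctx$cvec) %*% solve(B) %*% ctx$cvec))
  tstat <- sum(ctx$cvec * beta) / se
  2 * stats::pt(-abs(tstat), length(unique(ctx$obs_sub)) - p)
}

sim_context <- function(spec, lay) {
  d <- ri_design(lay$X, lay$obs$sub)
  XtXinv <- solve(crossprod(lay$X))
  ols_H <- XtXinv %*% t(lay$X)
  ols_q <- as.numeric(t(lay$cvec) %*% XtXinv %*% lay$cvec)
  # two-observation clusters (profile missingness): first and second row
  sub_rows <- split(seq_len(nrow(lay$obs)), lay$obs$sub)
  pairs <- sub_rows[vapply(sub_rows, length, 1L) == 2L]
  pair1 <- vapply(pairs, `[`, 1L, 1L)
  pair2 <- vapply(pairs, `[`, 1L, 2L)
  pair_lag <- abs(lay$obs$tp[pair2] - lay$obs$tp[pair1])
  # paired-t indices: EE participants with a post1 observation
  ee_post <- which(lay$obs$group == "EE" & lay$obs$tp == 2L)
  ee_sub <- lay$obs$sub[ee_post]
  ee_pre <- vapply(ee_sub, function(s) {
    which(lay$obs$sub == s & lay$obs$tp == 1L)[1L]
  }, 1L)
  list(d = d, X = lay$X, cvec = lay$cvec, ols_H = ols_H, ols_q = ols_q,
       pair1 = pair1, pair2 = pair2, pair_lag = pair_lag,
       pt_post = ee_post, pt_pre = ee_pre,
       obs_tp = lay$obs$tp, obs_sub = lay$obs$sub)
}

sim_strategies <- function() {
  list(paired_t = strat_paired_t, ols = strat_ols,
       lmm_ri_weighted = strat_lmm_ri, lmm_ri = strat_lmm_ri,
       mmrm_unstructured = strat_mmrm_un, gee_ar1 = strat_gee_ar1)
}

#' Evaluate candidate longitudinal strategies by simulation
#'
#' Generates `n_reps` null replicates (and, when `effect_size > 0`,
#' `n_reps` alternative replicates) from a [simulation_spec()], fits every
#' requested strategy to each replicate, tests the focal
#' difference-in-changes contrast at `alpha`, and reports the rejection
#' fractions: type-I error on null data, power on alternative data.
#' Replicates where a strategy fails to produce a finite p-value are
#' excluded from that strategy's denominator and counted.
#'
#' @param spec A [simulation_spec()].
#' @param strategies Subset of `paired_t`, `ols`, `lmm_ri_weighted`,
#'   `lmm_ri`, `mmrm_unstructured`, `gee_ar1`.
#' @return Tibble: `strategy`, `type_I_error`, `power`, `n_converged_null`,
#'   `n_converged_alt`, `mc_se` (binomial SE of the type-I estimate).
#' @export
evaluate_strategies <- function(spec,
                                strategies = names(sim_strategies())) {
  all_s <- sim_strategies()
  strategies <- match.arg(strategies, names(all_s), several.ok = TRUE)
  lay <- sim_layout(spec)
  ctx <- sim_context(spec, lay)
  set.seed(spec$seed)
  run <- function(effect) {
    Y <- sim_draw(spec, lay, effect, spec$n_reps)
    P <- matrix(NA_real_, spec$n_reps, length(strategies),
                dimnames = list(NULL, strategies))
    for (r in seq_len(spec$n_reps)) {
      y <- Y[, r]
      for (s in strategies) {
        P[r, s] <- tryCatch(all_s[[s]](y, ctx), error = function(e) NA_real_)
      }
    }
    P
  }
  P0 <- run(0)
  P1 <- if (spec$effect_size != 0) run(spec$effect_size) else NULL
  purrr::map_dfr(strategies, function(s) {
    p0 <- P0[, s]
    t1 <- mean(p0 < spec$alpha, na.rm = TRUE)
    pow <- if (is.null(P1)) t1 else mean(P1[, s] < spec$alpha, na.rm = TRUE)
    tibble::tibble(
      strategy = s, type_I_error = t1, power = pow,
      n_converged_null = sum(is.finite(p0)),
      n_converged_alt = if (is.null(P1)) sum(is.finite(p0))
                        else sum(is.finite(P1[, s])),
      mc_se = sqrt(t1 * (1 - t1) / sum(is.finite(p0)))
    )
  })
}

#' Summarize repeated-measures moments from data
#'
#' Extracts the generative summary a simulation needs from an observed
#' matrix: per group-by-timepoint means, the pooled available-case
#' covariance across timepoints, and pooled marginal skewness and excess
#' kurtosis.
#'
#' @param m Feature-by-sample matrix (a single feature row also works).
#' @param design Sample design.
#' @param n_reps,alpha,seed Passed through to the returned spec.
#' @return A [simulation_spec()] whose moments match the data.
#' @export
summarize_moments <- function(m, design, n_reps = 1000, alpha = 0.05,
                              seed = 1L) {
  X <- values_of(m)
  design <- design[match(colnames(X), design$sample_id), ]
  tps <- unique(design$timepoint)
  tps <- c("pre", setdiff(tps, "pre"))
  groups <- unique(design$group)
  centered <- X - rowMeans(X, na.rm = TRUE)
  pooled <- as.numeric(centered)
  if (all(!is.finite(pooled))) stop("no finite values")
  sk <- sample_skew(pooled)
  ku <- sample_kurt(pooled)
  means <- matrix(NA_real_, length(groups), length(tps),
                  dimnames = list(groups, tps))
  for (g in groups) for (tp in tps) {
    sel <- design$group == g & design$timepoint == tp
    if (sum(sel) < 1L) stop("no observations in cell ", g, ":", tp)
    cellv <- X[, sel, drop = FALSE]
    if (stats::sd(cellv, na.rm = TRUE) == 0 && length(cellv) > 1L) {
      stop("zero variance in cell ", g, ":", tp)
    }
    means[g, tp] <- mean(cellv, na.rm = TRUE)
  }
  # available-case within-participant covariance, pooled over features
  wc <- matrix(NA_real_, length(tps), length(tps))
  diag(wc) <- stats::var(pooled, na.rm = TRUE)
  pre <- design[design$timepoint == "pre", ]
  post <- design[design$timepoint != "pre", ]
  idx <- match(post$participant_id, pre$participant_id)
  covs <- numeric()
  for (k in seq_len(nrow(post))) {
    a <- centered[, pre$sample_id[idx[k]]]
    b <- centered[, post$sample_id[k]]
    covs <- c(covs, mean(a * b, na.rm = TRUE))
  }
  rho <- mean(covs, na.rm = TRUE) / diag(wc)[1L]
  simulation_spec(
    group_sizes = c(table(pre$group)[groups]),
    n_timepoints = length(tps),
    within_cor = min(max(rho, -0.9), 0.9),
    sd = sqrt(diag(wc)[1L]), skew = sk, kurt = ku,
    means = means, n_reps = n_reps, alpha = alpha, seed = seed)
}
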