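# Random-intercept linear mixed model, V = sigma2 * W^-1 + tau2 * Z Z',
# fitted by REML with the ratio lambda = tau2/sigma2 profiled out.
#
# The per-cluster structure (W^-1 + lambda * 1 1') is inverted with
# Sherman-Morrison, so one criterion evaluation is O(n p + g p^2); this is
# what makes 20,000-replicate simulations and per-feature fits over
# thousands of features practical. Satterthwaite denominator degrees of
# freedom use the analytic gradient of the contrast variance in
# (sigma2, tau2) and the inverse REML information.

# Precompute design structures shared across many response vectors.
ri_design <- function(X, id, w = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  id <- as.integer(factor(id))
  if (is.null(w)) w <- rep(1, n)
  stopifnot(length(id) == n, length(w) == n, all(w > 0))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]
    warning("dropping collinear column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
  }
  list(X = X, id = id, w = w, n = n, p = ncol(X), g = max(id),
       WX = w * X, sw = as.numeric(rowsum(w, id)),
       blocks = split(seq_len(n), id))
}

# REML criterion pieces at a given lambda; returns sufficient statistics.
ri_profile <- function(d, y, lambda) {
  wy <- d$w * y
  S <- rowsum(d$WX, d$id)                  # g x p block sums of W X
  sy <- as.numeric(rowsum(wy, d$id))       # g     block sums of W y
  cc <- lambda / (1 + lambda * d$sw)       # Sherman-Morrison factors
  A <- crossprod(d$X, d$WX) - crossprod(S, cc * S)
  b <- as.numeric(crossprod(d$X, wy) - crossprod(S, cc * sy))
  yty <- sum(wy * y) - sum(cc * sy^2)
  beta <- solve(A, b)
  rq <- max(yty - sum(b * beta), 1e-300)   # residual quadratic form
  logdetV0 <- -sum(log(d$w)) + sum(log1p(lambda * d$sw))
  crit <- (d$n - d$p) * log(rq) + logdetV0 + determinant(A)$modulus[1L]
  list(crit = crit, A = A, beta = beta, rq = rq)
}

# Full REML fit for one response vector.
ri_fit <- function(d, y, interval = c(-12, 8)) {
  obj <- function(ll) ri_profile(d, y, exp(ll))$crit
  opt <- stats::optimize(obj, interval = interval, tol = 1e-8)
  lambda <- exp(opt$minimum)
  singular <- opt$minimum <= interval[1L] + 1e-6
  if (singular) lambda <- 0
  pr <- ri_profile(d, y, lambda)
  sigma2 <- pr$rq / (d$n - d$p)
  tau2 <- lambda * sigma2
  Ainv <- solve(pr$A)
  C <- sigma2 * Ainv                       # cov(beta)
  # structures for Satterthwaite: Q = V0^-1 X, and the projection traces
  cc <- lambda / (1 + lambda * d$sw)
  Sb <- rowsum(d$WX, d$id)[d$id, , drop = FALSE]
  Q <- d$WX - (d$w * cc[d$id]) * Sb        # V0^-1 X
  # M_j = X' V^-1 (dV_j) V^-1 X  for dV_1 = W^-1, dV_2 = Z Z'
  M1 <- crossprod(Q, Q / d$w) / sigma2^2
  ZQ <- rowsum(Q, d$id)                    # g x p
  M2 <- crossprod(ZQ) / sigma2^2
  # REML information in (sigma2, tau2) via the projection matrix P
  Vi <- diag(d$w, d$n)
  for (i in seq_len(d$g)) {
    r <- d$blocks[[i]]
    Vi[r, r] <- Vi[r, r] - cc[i] * tcrossprod(d$w[r])
  }
  Vi <- Vi / sigma2
  ViX <- Q / sigma2                        # V^-1 X
  P <- Vi - ViX %*% (sigma2 * Ainv) %*% t(ViX)
  PW <- P / rep(d$w, each = d$n)           # P %*% W^-1 (column scaling)
  PZ <- t(rowsum(t(P), d$id))              # n x g, = P %*% Z
  I11 <- 0.5 * sum(PW * t(PW))             # tr(P W^-1 P W^-1) / 2
  I22 <- 0.5 * sum(rowsum(PZ, d$id)^2)     # tr(P ZZ' P ZZ') / 2
  I12 <- 0.5 * sum((PZ / d$w) * PZ)        # tr(P W^-1 P ZZ') / 2
  info <- matrix(c(I11, I12, I12, I22), 2L)
  Iinv <- tryCatch(solve(info), error = function(e) {
    matrix(c(1 / max(I11, 1e-12), 0, 0, 0), 2L)
  })
  structure(list(beta = stats::setNames(pr$beta, colnames(d$X)), C = C,
                 sigma2 = sigma2, tau2 = tau2, lambda = lambda,
                 M1 = M1, M2 = M2, Iinv = Iinv, n = d$n, p = d$p,
                 singular = singular),
            class = "exermap_lmmfit")
}

# Satterthwaite denominator df for contrast vector cvec (length p).
satterthwaite_df <- function(fit, cvec) {
  f <- as.numeric(t(cvec) %*% fit$C %*% cvec)
  Cc <- fit$C %*% cvec
  g1 <- as.numeric(t(Cc) %*% fit$M1 %*% Cc)
  g2 <- as.numeric(t(Cc) %*% fit$M2 %*% Cc)
  g <- c(g1, g2)
  denom <- as.numeric(t(g) %*% fit$Iinv %*% g)
  if (!is.finite(denom) || denom <= 0) return(fit$n - fit$p)
  df <- 2 * f^2 / denom
  min(max(df, 1), fit$n - fit$p)
}

#' @export
print.exermap_lmmfit <- function(x, ...) {
  cat("<exermap_lmmfit> p=", x$p, " n=", x$n,
      " sigma2=", signif(x$sigma2, 4), " tau2=", signif(x$tau2, 4),
      if (x$singular) " (singular: tau2 at boundary)", "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.exermap_lmmfit <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta),
                 std.error = sqrt(diag(x$C)))
}

#' @export
glance.exermap_lmmfit <- function(x, ...) {
  tibble::tibble(sigma2 = x$sigma2, tau2 = x$tau2,
                 icc = x$tau2 / (x$tau2 + x$sigma2),
                 n = x$n, p = x$p, singular = x$singular)
}
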