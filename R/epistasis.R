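#' Additive 1/-1 design coding of an inbred genotype column
#'
#' The two-locus epistatic model codes the two homozygous genotypes at each
#' marker as +1 (reference/major homozygote, code 0) and -1 (alternative
#' homozygote, code 1); the additive-by-additive interaction code is the
#' elementwise product, +1 for the coupling two-locus genotypes (AABB,
#' aabb) and -1 for the repulsion ones (AAbb, aaBB). Missing genotypes
#' propagate. Estimates of the interaction term and all p-values are
#' invariant to the sign convention.
#'
#' @param g Integer code vector in `{0, 1, NA}`.
#' @return Numeric vector in `{+1, -1, NA}`.
#' @export
#' @examples
#' encode_additive(c(0, 1, NA)) # +1 -1 NA
encode_additive <- function(g) {
  ifelse(is.na(g), NA_real_, ifelse(g == 0, 1, -1))
}

# Core OLS of y on [1, a1, a2, a1 a2] with aliasing handling via pivoted QR.
.fit_epi_core <- function(y, a1, a2) {
  X <- cbind("(Intercept)" = 1, a1 = a1, a2 = a2, "a1:a2" = a1 * a2)
  fit <- stats::lm.fit(X, y)
  r <- fit$rank
  n <- length(y)
  beta <- fit$coefficients # NA for aliased terms
  rss <- sum(fit$residuals^2)
  df <- n - r
  sigma2 <- if (df > 0) rss / df else NA_real_
  se <- rep(NA_real_, 4L)
  piv <- fit$qr$pivot[seq_len(r)]
  R <- qr.R(fit$qr)[seq_len(r), seq_len(r), drop = FALSE]
  cov_unscaled <- chol2inv(R)
  se[piv] <- sqrt(pmax(diag(cov_unscaled), 0) * sigma2)
  names(se) <- colnames(X)
  stat <- beta / se
  p <- 2 * stats::pt(-abs(stat), df = df)
  tss <- sum((y - mean(y))^2)
  list(
    beta = beta, se = se, statistic = stat, p = p,
    n_used = n, df_residual = df, sigma2 = sigma2,
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    aliased = is.na(beta)
  )
}

.new_epi_fit <- function(core, corrected = FALSE, lambda = NA_real_,
                         sigma_g2 = NA_real_, sigma_e2 = NA_real_) {
  structure(
    list(
      coefficients = tibble::tibble(
        term = c("(Intercept)", "a1", "a2", "a1:a2"),
        estimate = unname(core$beta),
        std.error = unname(core$se),
        statistic = unname(core$statistic),
        p.value = unname(core$p)
      ),
      n_used = core$n_used,
      df_residual = core$df_residual,
      sigma2 = core$sigma2,
      r_squared = core$r_squared,
      aliased = unname(core$aliased),
      corrected = corrected,
      lambda = lambda,
      sigma_g2 = sigma_g2,
      sigma_e2 = sigma_e2
    ),
    class = "epi_fit"
  )
}

#' Fit the two-locus statistical-epistasis model
#'
#' Ordinary least squares of a quantitative phenotype on the additive codes
#' of two inbred bi-allelic markers and their product:
#' \deqn{Y = \beta_0 + a_1\beta_1 + a_2\beta_2 + a_1 a_2\beta_{12} + e,}
#' with \eqn{a_1, a_2 \in \{+1, -1\}} (see [encode_additive()]). A nonzero
#' interaction estimate \eqn{\beta_{12}} is *statistical* epistasis: it can
#' arise from functional interaction, but equally from high-order LD of the
#' marker pair with a single unobserved causal locus. Pairs with an empty
#' two-locus genotype class have a collinear interaction column; the
#' aliased terms are reported with `NA` standard errors and p-values and
#' the fit is flagged, not dropped.
#'
#' @param y Numeric phenotype vector aligned with the genotype columns
#'   (use [align_phenotype()] to align a phenotype table with a panel).
#' @param g1,g2 Integer genotype code vectors in `{0, 1, NA}`.
#' @return An object of class `epi_fit`; see [tidy.epi_fit()] and
#'   [glance.epi_fit()].
#' @export
fit_two_locus_model <- function(y, g1, g2) {
  if (length(y) != length(g1) || length(y) != length(g2)) {
    stop("phenotype and genotype columns differ in length", call. = FALSE)
  }
  ok <- !is.na(y) & !is.na(g1) & !is.na(g2)
  if (sum(ok) < 5L) stop("fewer than 5 complete observations", call. = FALSE)
  g1c <- g1[ok]
  g2c <- g2[ok]
  if (length(unique(g1c)) < 2L || length(unique(g2c)) < 2L) {
    stop("both loci must be polymorphic among complete observations", call. = FALSE)
  }
  core <- .fit_epi_core(y[ok], encode_additive(g1c), encode_additive(g2c))
  .new_epi_fit(core)
}

#' @export
print.epi_fit <- function(x, ...) {
  cat(
    "<epi_fit> two-locus", if (x$corrected) "mixed-model (kinship-corrected)" else "OLS",
    "fit, n =", x$n_used, "\n"
  )
  print(x$coefficients)
  if (any(x$aliased)) cat("  aliased terms present (empty genotype class)\n")
  invisible(x)
}

#' Tidy / summarise a two-locus epistasis fit
#' @param x An `epi_fit` object.
#' @param ... Unused.
#' @return `tidy()`: one row per model term (estimate, std.error,
#'   statistic, p.value). `glance()`: a one-row model summary.
#' @export
tidy.epi_fit <- function(x, ...) x$coefficients

#' @rdname tidy.epi_fit
#' @export
glance.epi_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = sqrt(x$sigma2),
    n_used = x$n_used,
    df.residual = x$df_residual,
    corrected = x$corrected,
    lambda = x$lambda,
    aliased = any(x$aliased)
  )
}

#' Interaction p-value of a fit
#' @param fit An `epi_fit`.
#' @return The two-sided p-value of the `a1:a2` term.
#' @export
p_interaction <- function(fit) {
  fit$coefficients$p.value[fit$coefficients$term == "a1:a2"]
}

#' Exhaustive two-locus statistical-epistasis scan
#'
#' Fits the two-locus model ([fit_two_locus_model()]) to every unordered
#' pair of markers in a panel (OLS, no population-structure correction —
#' the first stage of the two-stage procedure; see [refit_with_kinship()]
#' for the second) and returns the pairs whose interaction p-value falls
#' below `p_threshold`, sorted by p-value. Pairs with an aliased
#' interaction term (empty two-locus class) are flagged and never
#' significant.
#'
#' @param y Numeric phenotype aligned with the rows of `G`.
#' @param G A [geno_matrix()].
#' @param p_threshold Significance threshold on the interaction p-value
#'   (see [bonferroni_threshold()]).
#' @return An object of class `epi_scan`: tibble of significant pairs with
#'   attributes `n_tests` and `p_threshold`.
#' @export
epistasis_scan <- function(y, G, p_threshold) {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  codes <- G$codes
  if (length(y) != nrow(codes)) stop("phenotype not aligned with panel", call. = FALSE)
  m <- ncol(codes)
  n_tests <- m * (m - 1) / 2
  has_na <- anyNA(codes) || anyNA(y)

  rows <- list()
  if (!has_na) {
    A <- matrix(encode_additive(codes), nrow = nrow(codes))
    n <- length(y)
    S <- crossprod(A) # sums a_i a_j
    s1 <- colSums(A)
    Sy <- as.numeric(crossprod(A, y)) # sums a_i y
    Sxy <- crossprod(A * y, A) # sums a_i a_j y
    sy <- sum(y)
    syy <- sum(y * y)
  }

  k <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (!has_na) {
        xtx <- matrix(c(
          n, s1[i], s1[j], S[i, j],
          s1[i], n, S[i, j], s1[j],
          s1[j], S[i, j], n, s1[i],
          S[i, j], s1[j], s1[i], n
        ), 4L, 4L)
        xty <- c(sy, Sy[i], Sy[j], Sxy[i, j])
        # the design is full rank iff all four two-locus classes are occupied
        cells <- c(
          n + s1[i] + s1[j] + S[i, j], n + s1[i] - s1[j] - S[i, j],
          n - s1[i] + s1[j] - S[i, j], n - s1[i] - s1[j] + S[i, j]
        ) / 4
        ch <- if (all(cells > 0)) chol(xtx) else NULL
        if (!is.null(ch)) {
          beta <- backsolve(ch, forwardsolve(t(ch), xty))
          rss <- max(syy - sum(beta * xty), 0)
          df <- n - 4L
          sigma2 <- rss / df
          cov_un <- chol2inv(ch)
          se <- sqrt(pmax(diag(cov_un), 0) * sigma2)
          p12 <- 2 * stats::pt(-abs(beta[4] / se[4]), df = df)
          core <- list(
            beta = beta, se = se, p12 = p12, aliased = FALSE,
            n_used = n,
            p1 = 2 * stats::pt(-abs(beta[2] / se[2]), df = df),
            p2 = 2 * stats::pt(-abs(beta[3] / se[3]), df = df)
          )
        } else {
          f <- .fit_epi_core(y, A[, i], A[, j])
          core <- list(
            beta = f$beta, se = f$se, p12 = f$p[4], aliased = any(f$aliased),
            n_used = f$n_used, p1 = f$p[2], p2 = f$p[3]
          )
        }
      } else {
        ok <- !is.na(y) & !is.na(codes[, i]) & !is.na(codes[, j])
        if (sum(ok) < 5L) next
        f <- .fit_epi_core(
          y[ok],
          encode_additive(codes[ok, i]), encode_additive(codes[ok, j])
        )
        core <- list(
          beta = f$beta, se = f$se, p12 = f$p[4], aliased = any(f$aliased),
          n_used = f$n_used, p1 = f$p[2], p2 = f$p[3]
        )
      }
      if (!is.na(core$p12) && core$p12 < p_threshold) {
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          marker_i = G$map$marker_id[i], marker_j = G$map$marker_id[j],
          chrom_i = G$map$chromosome[i], pos_i = G$map$position[i],
          chrom_j = G$map$chromosome[j], pos_j = G$map$position[j],
          beta1 = core$beta[2], beta2 = core$beta[3], beta12 = core$beta[4],
          se12 = core$se[4], p1 = core$p1, p2 = core$p2, p12 = core$p12,
          n_used = core$n_used, aliased = core$aliased
        )
      }
    }
  }
  empty <- tibble::tibble(
    marker_i = character(), marker_j = character(),
    chrom_i = character(), pos_i = integer(),
    chrom_j = character(), pos_j = integer(),
    beta1 = numeric(), beta2 = numeric(), beta12 = numeric(),
    se12 = numeric(), p1 = numeric(), p2 = numeric(), p12 = numeric(),
    n_used = numeric(), aliased = logical()
  )
  out <- dplyr::arrange(dplyr::bind_rows(empty, rows), .data$p12)
  attr(out, "n_tests") <- n_tests
  attr(out, "p_threshold") <- p_threshold
  class(out) <- c("epi_scan", class(out))
  out
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / n_tests`; [n_marker_pairs()] gives the all-pairs test count for
#' a panel of `m` markers. The effective number of tests may instead be
#' supplied directly (e.g. an externally estimated number of independent LD
#' blocks), giving a more liberal threshold than the all-pairs correction.
#'
#' @param alpha Nominal familywise level (e.g. 0.05).
#' @param n_tests Number of tests (`>= 1`).
#' @return The per-test p-value threshold.
#' @export
#' @examples
#' bonferroni_threshold(0.05, n_marker_pairs(1.6e6)) # ~3.9e-14
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' @rdname bonferroni_threshold
#' @param m Marker count.
#' @export
n_marker_pairs <- function(m) m * (m - 1) / 2

#' Genomic kinship (allele-sharing relatedness) matrix
#'
#' Cross-product of the column-standardised genotype matrix divided by the
#' number of markers used. Missing genotypes are mean-imputed per marker
#' for this computation only; monomorphic markers carry no information and
#' are dropped. The result is symmetric positive semi-definite, and
#' duplicated individuals share their diagonal value off-diagonally.
#'
#' @param G A [geno_matrix()].
#' @return An `n x n` numeric matrix with individual ids as dimnames.
#' @export
genomic_kinship <- function(G) {
  if (n_individuals(G) < 2L || n_markers(G) < 2L) {
    stop("need at least 2 individuals and 2 markers", call. = FALSE)
  }
  Z <- G$codes * 1.0
  if (anyNA(Z)) {
    mu <- colMeans(Z, na.rm = TRUE)
    na_idx <- which(is.na(Z), arr.ind = TRUE)
    Z[na_idx] <- mu[na_idx[, 2]]
  }
  sds <- apply(Z, 2L, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all markers monomorphic", call. = FALSE)
  Z <- scale(Z[, keep, drop = FALSE])
  K <- tcrossprod(Z) / sum(keep)
  dimnames(K) <- list(G$individual_ids, G$individual_ids)
  K
}

#' Kinship-corrected refit of a two-locus epistasis model
#'
#' Linear mixed model \eqn{y = X\beta + u + e} with
#' \eqn{u \sim N(0, \sigma_g^2 K)} for a genomic kinship matrix `K`, the
#' second stage of the scan pipeline: pairs passing the uncorrected OLS
#' scan are refitted with a polygenic random effect to correct for
#' population structure. The model is rotated by the eigendecomposition of
#' `K`, the variance ratio \eqn{\lambda = \sigma_g^2/\sigma_e^2} is
#' estimated by REML with a bounded scalar search (tolerance 1e-8), and
#' fixed effects get Wald tests (t reference with residual degrees of
#' freedom). `lambda = 0` reproduces the OLS fit exactly.
#'
#' @inheritParams fit_two_locus_model
#' @param K Kinship matrix aligned to the genotype rows (symmetric PSD).
#' @param lambda Optional fixed variance ratio; `NULL` (default) estimates
#'   it by REML.
#' @return An `epi_fit` with `corrected = TRUE` and variance components.
#' @export
refit_with_kinship <- function(y, g1, g2, K, lambda = NULL) {
  if (length(y) != length(g1) || length(y) != length(g2)) {
    stop("phenotype and genotype columns differ in length", call. = FALSE)
  }
  if (!is.matrix(K) || nrow(K) != ncol(K) || nrow(K) != length(y)) {
    stop("`K` must be a square matrix aligned with the phenotype", call. = FALSE)
  }
  if (max(abs(K - t(K))) > 1e-8) stop("`K` is not symmetric", call. = FALSE)
  ok <- !is.na(y) & !is.na(g1) & !is.na(g2)
  if (sum(ok) < 5L) stop("fewer than 5 complete observations", call. = FALSE)
  yv <- y[ok]
  a1 <- encode_additive(g1[ok])
  a2 <- encode_additive(g2[ok])
  Ks <- K[ok, ok, drop = FALSE]

  eg <- eigen(Ks, symmetric = TRUE)
  d <- eg$values
  if (any(d < -1e-6 * max(abs(d)))) {
    stop("`K` is not positive semi-definite", call. = FALSE)
  }
  d <- pmax(d, 0)
  X <- cbind("(Intercept)" = 1, a1 = a1, a2 = a2, "a1:a2" = a1 * a2)
  qrx <- qr(X)
  if (qrx$rank < 4L) {
    # aliased interaction: report the OLS fit flagged, no mixed model
    core <- .fit_epi_core(yv, a1, a2)
    return(.new_epi_fit(core, corrected = TRUE, lambda = NA_real_))
  }
  n <- length(yv)
  p <- 4L
  yt <- crossprod(eg$vectors, yv)
  Xt <- crossprod(eg$vectors, X)

  gls <- function(lam) {
    v <- lam * d + 1
    w <- 1 / v
    XtWX <- crossprod(Xt, Xt * w)
    XtWy <- crossprod(Xt, yt * w)
    beta <- solve(XtWX, XtWy)
    resid <- yt - Xt %*% beta
    rss <- sum(w * resid^2)
    sigma_e2 <- rss / (n - p)
    list(
      beta = as.numeric(beta), XtWX = XtWX, sigma_e2 = sigma_e2,
      neg2reml = (n - p) * log(sigma_e2) + sum(log(v)) +
        as.numeric(determinant(XtWX, logarithm = TRUE)$modulus)
    )
  }

  if (is.null(lambda)) {
    obj <- function(loglam) gls(exp(loglam))$neg2reml
    opt <- stats::optimize(obj, interval = c(log(1e-8), log(1e8)), tol = 1e-8)
    lambda <- exp(opt$minimum)
    # prefer the no-structure boundary when it is at least as good
    if (gls(0)$neg2reml <= opt$objective + 1e-8) lambda <- 0
  }
  fit <- gls(lambda)
  se <- sqrt(pmax(diag(solve(fit$XtWX)), 0) * fit$sigma_e2)
  stat <- fit$beta / se
  pvals <- 2 * stats::pt(-abs(stat), df = n - p)
  tss <- sum((yv - mean(yv))^2)
  core <- list(
    beta = stats::setNames(fit$beta, colnames(X)),
    se = se, statistic = stat, p = pvals,
    n_used = n, df_residual = n - p, sigma2 = fit$sigma_e2,
    r_squared = NA_real_, aliased = rep(FALSE, 4L)
  )
  .new_epi_fit(core,
    corrected = TRUE, lambda = lambda,
    sigma_g2 = lambda * fit$sigma_e2, sigma_e2 = fit$sigma_e2
  )
}
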