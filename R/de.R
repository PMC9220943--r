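#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: for each sample, the median over
#' features (restricted to features with nonzero counts in every sample) of
#' the ratio of that sample's count to the feature's geometric mean across
#' samples. Normalized count = raw / factor.
#'
#' @param counts a [count_matrix()] or a numeric matrix (features x samples).
#' @return named numeric vector of positive factors, one per sample.
#' @export
compute_size_factors <- function(counts) {
  m <- if (inherits(counts, "CountMatrix")) counts$counts else as.matrix(counts)
  if (ncol(m) == 1L) return(stats::setNames(1, colnames(m)))
  all_nonzero <- rowSums(m > 0) == ncol(m)
  if (!any(all_nonzero)) {
    abort_input("cannot compute size factors: no feature has nonzero counts in all samples")
  }
  mm <- m[all_nonzero, , drop = FALSE]
  geo <- exp(rowMeans(log(mm)))
  sf <- apply(mm, 2L, function(x) stats::median(x / geo))
  stats::setNames(sf, colnames(m))
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean. Used on
#' size-factor-normalized counts across the tumor samples to flag miRNAs
#' with unstable expression across tumors.
#'
#' @param values numeric vector of normalized counts for one feature.
#' @return a nonnegative ratio, or `NA` when fewer than 2 values or the mean
#'   is not positive.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) return(NA_real_)
  m <- mean(values)
  if (m <= 0) return(NA_real_)
  stats::sd(values) / m
}

#' Log2 fold change of geometric means
#'
#' `log2(geomean(tumor + pc) / geomean(normal + pc))`, the statistic used to
#' rank tumor types by miRNA induction relative to matched non-tumor tissue.
#'
#' @param tumor,normal numeric vectors of expression values (both nonempty).
#' @param pseudocount nonnegative offset; defaults to 1 when either group
#'   contains a zero and 0 otherwise. A zero with `pseudocount = 0` is an
#'   error.
#' @return a single log2 ratio; the pseudocount used is attached as
#'   attribute `pseudocount`.
#' @export
geometric_mean_log2fc <- function(tumor, normal, pseudocount = NULL) {
  if (!length(tumor) || !length(normal)) {
    abort_usage("both groups must be nonempty")
  }
  has_zero <- any(c(tumor, normal) == 0)
  if (is.null(pseudocount)) pseudocount <- if (has_zero) 1 else 0
  if (pseudocount < 0) abort_usage("pseudocount must be >= 0")
  if (pseudocount == 0 && has_zero) {
    abort_usage("zero values present: a positive pseudocount is required")
  }
  out <- mean(log2(tumor + pseudocount)) - mean(log2(normal + pseudocount))
  attr(out, "pseudocount") <- pseudocount
  out
}

## ---- negative-binomial Wald test -------------------------------------------

## Method-of-moments dispersion per feature from normalized counts, computed
## within design cells (condition x batch), then pooled with (n_c - 1)
## weights. Var(K/sf) = q/sf + alpha q^2 for K ~ NB(q*sf, alpha), hence
## alpha_c = (var_c - mean_c * mean(1/sf_c)) / mean_c^2.
estimate_dispersion_mom <- function(norm, cells, sf) {
  lv <- split(seq_along(cells), cells)
  lv <- lv[vapply(lv, length, 1L) >= 2L]
  if (!length(lv)) abort_usage("dispersion estimation needs a cell with >= 2 replicates")
  est <- matrix(0, nrow(norm), 2L)  # weighted sum of alpha, sum of weights
  for (idx in lv) {
    mns <- rowMeans(norm[, idx, drop = FALSE])
    vars <- apply(norm[, idx, drop = FALSE], 1L, stats::var)
    inv_sf <- mean(1 / sf[idx])
    ok <- mns > 0
    a <- rep(NA_real_, nrow(norm))
    a[ok] <- (vars[ok] - mns[ok] * inv_sf) / mns[ok]^2
    w <- length(idx) - 1
    upd <- ok & !is.na(a)
    est[upd, 1L] <- est[upd, 1L] + w * a[upd]
    est[upd, 2L] <- est[upd, 2L] + w
  }
  alpha <- ifelse(est[, 2L] > 0, est[, 1L] / est[, 2L], NA_real_)
  pmin(pmax(alpha, 1e-8), 20)
}

## Parametric mean-dispersion trend alpha(mu) = a0 + a1/mu, fit by trimmed
## least squares; falls back to a flat median trend when the fit degenerates.
fit_dispersion_trend <- function(alpha_mom, base_mean) {
  use <- !is.na(alpha_mom) & alpha_mom > 1e-7 & base_mean > 5
  flat <- stats::median(alpha_mom[!is.na(alpha_mom) & alpha_mom > 1e-7])
  if (!is.finite(flat) || flat <= 0) flat <- 0.1
  if (sum(use) < 20) {
    return(function(mu) rep(flat, length(mu)))
  }
  x <- 1 / base_mean[use]
  y <- alpha_mom[use]
  a0 <- flat; a1 <- 0
  for (i in 1:3) {
    pred <- pmax(a0 + a1 * x, 1e-8)
    keep <- y / pred > 0.1 & y / pred < 10
    if (sum(keep) < 10) break
    fit <- stats::lm.fit(cbind(1, x[keep]), y[keep])
    a0 <- max(fit$coefficients[1], 1e-6)
    a1 <- max(fit$coefficients[2], 0)
  }
  function(mu) pmin(pmax(a0 + a1 / pmax(mu, 0.5), 1e-6), 20)
}

## IRLS fit of per-feature NB GLMs with log link, shared design matrix and
## known per-feature dispersion; offsets log(sf). Returns coefficients and
## standard errors (Fisher information at convergence).
fit_nb_glm_matrix <- function(Y, X, sf, alpha, max_iter = 40L, tol = 1e-8) {
  n_f <- nrow(Y); n_s <- ncol(Y); p <- ncol(X)
  off <- log(sf)
  norm <- sweep(Y, 2L, sf, "/")
  ## init from log-linear regression on log(norm + 0.5)
  L <- log(norm + 0.5)
  B <- t(solve(crossprod(X), crossprod(X, t(L))))
  B <- pmin(pmax(B, -25), 25)
  active <- rep(TRUE, n_f)
  XtWX_last <- vector("list", n_f)
  pair_i <- rep(seq_len(p), times = p)
  pair_j <- rep(seq_len(p), each = p)
  for (iter in seq_len(max_iter)) {
    idx <- which(active)
    if (!length(idx)) break
    eta <- B[idx, , drop = FALSE] %*% t(X) +
      matrix(off, length(idx), n_s, byrow = TRUE)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    W <- mu / (1 + matrix(alpha[idx], length(idx), n_s) * mu)
    Z <- eta - matrix(off, length(idx), n_s, byrow = TRUE) +
      (Y[idx, , drop = FALSE] - mu) / mu
    ## per-feature normal equations, built vectorized then solved per feature
    XtWX <- W %*% (X[, pair_i, drop = FALSE] * X[, pair_j, drop = FALSE])
    XtWZ <- (W * Z) %*% X
    newB <- B[idx, , drop = FALSE]
    conv <- logical(length(idx))
    for (k in seq_along(idx)) {
      A <- matrix(XtWX[k, ], p, p)
      bvec <- XtWZ[k, ]
      sol <- tryCatch(solve(A + diag(1e-10, p), bvec), error = function(e) NULL)
      if (is.null(sol)) { conv[k] <- TRUE; next }
      sol <- pmin(pmax(sol, -25), 25)
      conv[k] <- max(abs(sol - newB[k, ])) < tol
      newB[k, ] <- sol
      XtWX_last[[idx[k]]] <- A
    }
    B[idx, ] <- newB
    active[idx[conv]] <- FALSE
  }
  SE <- matrix(NA_real_, n_f, p)
  for (f in seq_len(n_f)) {
    A <- XtWX_last[[f]]
    if (is.null(A)) next
    V <- tryCatch(solve(A), error = function(e) NULL)
    if (!is.null(V)) SE[f, ] <- sqrt(pmax(diag(V), 0))
  }
  list(beta = B, se = SE)
}

#' Negative-binomial Wald differential test with a batch covariate
#'
#' Per-feature NB generalized linear model (log link, median-of-ratios size
#' factors as offsets) on `~ condition + batch`; dispersion is estimated per
#' feature by method of moments within design cells and shrunk on the log
#' scale toward a parametric mean-dispersion trend; the condition
#' coefficient is tested with a Wald statistic referred to a t distribution
#' on the residual degrees of freedom, and p-values are BH
#' adjusted across tested features. Features with all-zero counts are
#' reported with absent statistics and excluded from the adjustment.
#'
#' @param counts a [count_matrix()].
#' @param test_level,ref_level condition labels contrasted as
#'   `test_level` vs `ref_level` (default tumor vs normal); samples with
#'   other condition labels are dropped, which is how primary-vs-normal and
#'   metastatic-vs-normal analyses reuse this operation.
#' @param use_batch include the batch covariate (default TRUE; ignored when
#'   a single batch is present).
#' @param size_factors optional named per-sample factors overriding the
#'   median-of-ratios computation (e.g. genome-wide signal totals for
#'   nascent-transcription loci).
#' @param prior_df strength of dispersion shrinkage toward the trend.
#' @return a `DeTable` data.frame with columns feature, baseMean,
#'   mean_tumor, mean_normal, log2fc, se (of log2fc), p, padj, cov_tumor
#'   (CoV of normalized counts across `test_level` samples).
#' @export
nb_wald_de <- function(counts, test_level = "tumor", ref_level = "normal",
                       use_batch = TRUE, size_factors = NULL, prior_df = 15) {
  stopifnot(inherits(counts, "CountMatrix"))
  keep <- counts$meta$condition %in% c(test_level, ref_level)
  if (!all(keep)) counts <- subset_samples(counts, counts$meta$sample[keep])
  meta <- counts$meta
  cond <- factor(meta$condition, levels = c(ref_level, test_level))
  if (any(table(cond) < 2L)) {
    abort_input("each condition needs at least 2 samples")
  }
  batch <- factor(meta$batch)
  if (use_batch && nlevels(batch) > 1L) {
    X <- stats::model.matrix(~ cond + batch)
    if (qr(X)$rank < ncol(X)) {
      abort_input("design is confounded: batch is collinear with condition")
    }
  } else {
    X <- stats::model.matrix(~ cond)
  }
  Y <- counts$counts
  if (is.null(size_factors)) {
    sf <- compute_size_factors(Y)
  } else {
    sf <- size_factors[colnames(Y)]
    if (anyNA(sf) || any(sf <= 0)) abort_usage("invalid size_factors")
  }
  norm <- sweep(Y, 2L, sf, "/")
  base_mean <- rowMeans(norm)
  mean_test <- rowMeans(norm[, cond == test_level, drop = FALSE])
  mean_ref <- rowMeans(norm[, cond == ref_level, drop = FALSE])
  cov_test <- apply(norm[, cond == test_level, drop = FALSE], 1L,
                    coefficient_of_variation)

  tested <- rowSums(Y) > 0
  cells <- interaction(cond, batch, drop = TRUE)
  alpha_mom <- rep(NA_real_, nrow(Y))
  alpha_mom[tested] <- estimate_dispersion_mom(norm[tested, , drop = FALSE],
                                               cells, sf)
  trend_fn <- fit_dispersion_trend(alpha_mom[tested], base_mean[tested])
  trend <- trend_fn(base_mean)
  df_resid <- ncol(Y) - nlevels(cells)
  w <- df_resid / (df_resid + prior_df)
  amom <- pmin(pmax(ifelse(is.na(alpha_mom), trend, alpha_mom),
                    trend / 30), trend * 30)
  alpha <- exp(w * log(amom) + (1 - w) * log(trend))

  res <- data.frame(feature = rownames(Y), baseMean = base_mean,
                    mean_tumor = mean_test, mean_normal = mean_ref,
                    log2fc = NA_real_, se = NA_real_, p = NA_real_,
                    padj = NA_real_, cov_tumor = cov_test,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (any(tested)) {
    fit <- fit_nb_glm_matrix(Y[tested, , drop = FALSE], X, sf, alpha[tested])
    lfc <- fit$beta[, 2L] / log(2)
    se <- fit$se[, 2L] / log(2)
    z <- fit$beta[, 2L] / fit$se[, 2L]
    ## t reference with residual df: small-sample correction for the plug-in
    ## (shrunken) dispersion; normal reference is anticonservative at n ~ 20
    p <- 2 * stats::pt(-abs(z), df = max(ncol(Y) - ncol(X), 1L))
    res$log2fc[tested] <- lfc
    res$se[tested] <- se
    res$p[tested] <- p
    res$padj[tested] <- stats::p.adjust(p, method = "BH")
  }
  attr(res, "size_factors") <- sf
  attr(res, "dispersion") <- alpha
  res
}

#' Parameters for miRNA selection
#'
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param min_group_mean normalized-count floor required in at least one of
#'   the two groups (default 1000).
#' @param max_cov maximum coefficient of variation across tumor samples
#'   (default 2.0).
#' @param min_abs_log2fc optional absolute log2fc floor; default 0 (off) —
#'   the +/-2 dashed lines on the volcano plots are treated as
#'   visualization, not selection.
#' @return a list of class `DeParams`.
#' @export
de_params <- function(alpha = 0.05, min_group_mean = 1000, max_cov = 2.0,
                      min_abs_log2fc = 0) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort_usage("DeParams field 'alpha' must be in (0, 1)")
  }
  if (min_group_mean < 0) abort_usage("DeParams field 'min_group_mean' must be >= 0")
  if (max_cov <= 0) abort_usage("DeParams field 'max_cov' must be > 0")
  if (min_abs_log2fc < 0) abort_usage("DeParams field 'min_abs_log2fc' must be >= 0")
  structure(list(alpha = alpha, min_group_mean = min_group_mean,
                 max_cov = max_cov, min_abs_log2fc = min_abs_log2fc),
            class = "DeParams")
}

#' Select differentially expressed miRNAs
#'
#' Keeps features with `padj < alpha`, average normalized counts above
#' `min_group_mean` in either group, and CoV across tumor samples below
#' `max_cov`; splits the survivors by fold-change sign. Features with
#' absent padj or CoV fail the corresponding condition. Output order is
#' deterministic (padj, then feature id) and independent of input row
#' order.
#'
#' @param de a `DeTable` from [nb_wald_de()].
#' @param params a [de_params()] object.
#' @return list with `up` and `down` DeTable subsets.
#' @export
select_de_mirnas <- function(de, params = de_params()) {
  stopifnot(is.data.frame(de))
  keep <- !is.na(de$padj) & de$padj < params$alpha &
    (de$mean_tumor > params$min_group_mean |
       de$mean_normal > params$min_group_mean) &
    !is.na(de$cov_tumor) & de$cov_tumor < params$max_cov &
    !is.na(de$log2fc)
  if (params$min_abs_log2fc > 0) {
    keep <- keep & abs(de$log2fc) >= params$min_abs_log2fc
  }
  sel <- de[keep, , drop = FALSE]
  sel <- sel[order(sel$padj, sel$feature), , drop = FALSE]
  rownames(sel) <- NULL
  list(up = sel[sel$log2fc > 0, , drop = FALSE],
       down = sel[sel$log2fc < 0, , drop = FALSE])
}

#' Variance-stabilized, batch-adjusted matrix for ordination
#'
#' `log2(normalized + pseudocount)` transform of the counts, followed by
#' per-feature removal of the fitted batch term (linear regression on
#' centered batch indicators, so the grand mean of each feature is
#' preserved). With a single batch the adjustment is the identity. The
#' output is suitable for PCA and Euclidean-distance clustering.
#'
#' @param counts a [count_matrix()].
#' @param pseudocount added before the log (default 1).
#' @return numeric matrix, features x samples.
#' @export
vst_batch_adjust <- function(counts, pseudocount = 1) {
  stopifnot(inherits(counts, "CountMatrix"))
  sf <- compute_size_factors(counts)
  Y <- log2(sweep(counts$counts, 2L, sf, "/") + pseudocount)
  batch <- factor(counts$meta$batch)
  if (nlevels(batch) < 2L) return(Y)
  Xb <- stats::model.matrix(~ batch)[, -1L, drop = FALSE]
  Xc <- scale(Xb, center = TRUE, scale = FALSE)
  beta <- t(solve(crossprod(Xc), crossprod(Xc, t(Y))))
  Y - beta %*% t(Xc)
}
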