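#' Build a design matrix for the two-group comparison
#'
#' Constructs `~ group (+ age) (+ subject)` with `HC` as the reference
#' level, so the `groupAD` coefficient is the AD-minus-HC difference
#' (`logfc`). A subject blocking term is honored only when at least one
#' subject contributes more than one sample; with one sample per subject
#' the term is confounded with group and is dropped with a warning.
#'
#' @param sample_sheet Sample sheet data.frame (`sample_id`, `group`,
#'   `age`, optional `subject_id`).
#' @param covariates Character vector of additional covariate columns to
#'   adjust for (default `"age"`).
#' @param subject Request subject blocking via the `subject_id` column.
#' @return Design matrix with an attribute `coef` naming the group
#'   contrast column.
#' @export
build_design <- function(sample_sheet, covariates = "age", subject = FALSE) {
  ss <- validate_sample_sheet(sample_sheet)
  if (any(table(ss$group) < 2L)) stop("each group needs at least 2 samples")
  terms <- c("group", covariates)
  if (subject) {
    if (is.null(ss$subject_id)) stop("subject blocking requested but no subject_id column")
    if (max(table(ss$subject_id)) > 1L) {
      ss$subject_id <- factor(ss$subject_id)
      with_subject <- stats::model.matrix(
        stats::reformulate(c(terms, "subject_id")), data = ss)
      if (qr(with_subject)$rank == ncol(with_subject)) {
        terms <- c(terms, "subject_id")
      } else {
        warning("subject term is not estimable alongside group (confounded); dropped")
      }
    } else {
      warning("one sample per subject: subject term is confounded with group and was dropped")
    }
  }
  fml <- stats::reformulate(terms)
  design <- stats::model.matrix(fml, data = ss)
  if (qr(design)$rank < ncol(design)) stop("design matrix is not full rank")
  rownames(design) <- ss$sample_id
  attr(design, "coef") <- "groupAD"
  design
}

#' Per-feature ordinary least squares
#'
#' Fits the same linear model to every row of `x` by OLS and extracts the
#' group-contrast coefficient (`logfc`), the residual variance `s_g^2`, and
#' the residual degrees of freedom `d_g`. Features with missing values are
#' fitted on their complete samples; a feature whose residual df falls
#' below 1 (or whose reduced design loses rank) is flagged `tested = FALSE`
#' and excluded from moderation.
#'
#' @param x Feature-by-sample numeric matrix (columns matching the design
#'   rows).
#' @param design Design matrix from [build_design()].
#' @param coef Name of the contrast column (default: the design's `coef`
#'   attribute).
#' @return List of class `"feature_fit"`: `logfc`, `s2` (residual
#'   variance), `df` (residual df), `v` (unscaled variance of the contrast
#'   coefficient), `tested` (logical), `coef`, `feature_ids`.
#' @export
fit_feature_lm <- function(x, design, coef = attr(design, "coef")) {
  stopifnot(is.matrix(x), ncol(x) == nrow(design))
  if (is.null(coef)) coef <- "groupAD"
  j <- match(coef, colnames(design))
  if (is.na(j)) stop("contrast column '", coef, "' not in design")
  n <- nrow(design)
  p <- ncol(design)
  m <- nrow(x)
  logfc <- s2 <- rep(NA_real_, m)
  dfres <- rep(NA_real_, m)
  vj <- rep(NA_real_, m)
  tested <- rep(FALSE, m)

  complete <- !rowSums(is.na(x))
  if (any(complete)) {
    qrD <- qr(design)
    fit <- lm.fit(design, t(x[complete, , drop = FALSE]))
    cf <- fit$coefficients
    res <- as.matrix(fit$residuals)
    d <- n - qrD$rank
    xtxinv <- chol2inv(qr.R(qrD))
    v1 <- xtxinv[j, j]
    cfj <- if (is.matrix(cf)) cf[j, ] else cf[j]
    logfc[complete] <- cfj
    s2[complete] <- colSums(res^2) / d
    dfres[complete] <- d
    vj[complete] <- v1
    tested[complete] <- d >= 1L
  }
  for (i in which(!complete)) {
    ok <- !is.na(x[i, ])
    Di <- design[ok, , drop = FALSE]
    qri <- qr(Di)
    if (qri$rank < p || sum(ok) - qri$rank < 1L) next
    fi <- lm.fit(Di, x[i, ok])
    logfc[i] <- fi$coefficients[j]
    dfres[i] <- sum(ok) - p
    s2[i] <- sum(fi$residuals^2) / dfres[i]
    vj[i] <- chol2inv(qr.R(qri))[j, j]
    tested[i] <- TRUE
  }
  structure(
    list(logfc = logfc, s2 = s2, df = dfres, v = vj, tested = tested,
         coef = coef, feature_ids = rownames(x)),
    class = "feature_fit"
  )
}

#' Newton inversion of the trigamma function
#' @keywords internal
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(NA_real_)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (iter in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) < 1e-10 * x) break
    }
    x
  }, numeric(1L))
}

#' Estimate the empirical-Bayes variance prior
#'
#' Models per-feature residual variances as scaled F-distributed around a
#' common prior variance `s0^2` with prior degrees of freedom `d0`, and
#' estimates (`d0`, `s0^2`) by moment matching on log variances: the excess
#' spread of `log s_g^2` beyond its chi-square sampling floor determines
#' `d0` through a Newton inversion of the trigamma function. When the
#' empirical spread does not exceed the sampling floor, `d0 = Inf` (all
#' features share one variance). Estimates of `d0` above 1e6 are treated
#' as infinite.
#'
#' @param s2 Vector of residual variances (positive; features with zero
#'   variance are excluded from estimation).
#' @param df Residual degrees of freedom (scalar or vector).
#' @return List of class `"variance_prior"`: `d0`, `s0_sq`, `n_used`.
#' @export
estimate_prior <- function(s2, df) {
  if (length(df) == 1L) df <- rep(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & is.finite(df) & df >= 1
  if (sum(is.finite(s2)) > 0 && all(s2[is.finite(s2)] == 0)) {
    stop("all residual variances are zero; prior is undefined")
  }
  if (sum(ok) < 10L) stop("need at least 10 features with positive residual variance")
  z <- log(s2[ok])
  d <- df[ok]
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(d / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    if (!is.finite(d0) || d0 > 1e6) d0 <- Inf
  } else {
    d0 <- Inf
  }
  s0_sq <- if (is.finite(d0)) {
    exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    exp(emean)
  }
  structure(list(d0 = d0, s0_sq = s0_sq, n_used = sum(ok)),
            class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat("Empirical-Bayes variance prior: d0 =", format(x$d0),
      " s0^2 =", format(x$s0_sq), " (", x$n_used, "features )\n")
  invisible(x)
}

#' Moderated t-test from a feature fit and a variance prior
#'
#' Shrinks each feature's residual variance toward the prior,
#' `s~^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, forms the moderated
#' statistic `t = logfc / (s~ sqrt(v_g))` on `d0 + d_g` degrees of freedom,
#' and applies two-sided p-values with Benjamini-Hochberg adjustment over
#' all tested features. With `d0 = 0` this is exactly the classical
#' (covariate-adjusted) t-test; with `d0 = Inf` every feature is tested
#' against the common prior variance.
#'
#' @param fit A `"feature_fit"` from [fit_feature_lm()].
#' @param prior A `"variance_prior"` from [estimate_prior()], or a list
#'   with `d0` and `s0_sq`.
#' @return data.frame of class `"diff_table"`: `feature_id`, `logfc`,
#'   `t_mod`, `df_total`, `p`, `p_bh`, `direction`, `tested`. The prior is
#'   attached as attribute `"prior"`.
#' @export
moderated_test <- function(fit, prior) {
  d0 <- prior$d0
  s0 <- prior$s0_sq
  d <- fit$df
  s2_post <- if (!is.finite(d0)) {
    rep(s0, length(d))
  } else if (d0 == 0) {
    fit$s2
  } else {
    (d0 * s0 + d * fit$s2) / (d0 + d)
  }
  df_total <- if (is.finite(d0)) d0 + d else rep(Inf, length(d))
  t_mod <- fit$logfc / sqrt(s2_post * fit$v)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[!fit$tested] <- NA_real_
  t_mod[!fit$tested] <- NA_real_
  p_bh <- rep(NA_real_, length(p))
  p_bh[fit$tested] <- bh_adjust(p[fit$tested])
  out <- data.frame(
    feature_id = fit$feature_ids,
    logfc = fit$logfc,
    t_mod = t_mod,
    df_total = df_total,
    p = p,
    p_bh = p_bh,
    direction = sign(fit$logfc),
    tested = fit$tested,
    stringsAsFactors = FALSE
  )
  attr(out, "prior") <- prior
  class(out) <- c("diff_table", "data.frame")
  out
}

#' Two-group differential analysis with empirical-Bayes moderation
#'
#' One-call wrapper: builds the design, fits per-feature OLS, estimates the
#' variance prior, and returns the moderated-test table. Used identically
#' for CpG M-values and log2 miRNA expression; `logfc` is always AD - HC on
#' the analysis scale.
#'
#' @param x Feature-by-sample matrix.
#' @param sample_sheet Sample sheet matching the columns of `x`.
#' @param covariates Additional model covariates (default `"age"`).
#' @param subject Request subject blocking (see [build_design()]).
#' @return A `"diff_table"` (see [moderated_test()]).
#' @export
diff_test <- function(x, sample_sheet, covariates = "age", subject = FALSE) {
  ss <- validate_sample_sheet(sample_sheet)
  stopifnot(identical(colnames(x), ss$sample_id))
  design <- build_design(ss, covariates = covariates, subject = subject)
  fit <- fit_feature_lm(x, design)
  prior <- estimate_prior(fit$s2[fit$tested], fit$df[fit$tested])
  moderated_test(fit, prior)
}

#' @export
print.diff_table <- function(x, n = 10L, ...) {
  pr <- attr(x, "prior")
  cat("Differential table:", nrow(x), "features,",
      sum(x$tested), "tested,", sum(x$p_bh < 0.05, na.rm = TRUE),
      "at BH p < 0.05\n")
  if (!is.null(pr)) cat("  prior: d0 =", format(pr$d0),
                        " s0^2 =", format(signif(pr$s0_sq, 4)), "\n")
  ord <- order(x$p)
  print.data.frame(utils::head(as.data.frame(x)[ord, ], n))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (capped at 1, monotone in p-rank, original
#' order restored), computed through `stats::p.adjust(method = "BH")`
#' after validating the input.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially methylated/expressed features
#'
#' @param diff_table A `"diff_table"`.
#' @param alpha BH-adjusted p threshold (default 0.05).
#' @param direction Optional: keep only `+1` (up in AD) or `-1` (down).
#' @return The significant rows, sorted by p.
#' @export
call_dmps <- function(diff_table, alpha = 0.05, direction = NULL) {
  keep <- !is.na(diff_table$p_bh) & diff_table$p_bh < alpha
  if (!is.null(direction)) keep <- keep & diff_table$direction == direction
  out <- diff_table[keep, , drop = FALSE]
  out[order(out$p), , drop = FALSE]
}
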