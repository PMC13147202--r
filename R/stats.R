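## Group-comparison and association statistics: two-factor ANCOVA with
## Type-III sums of squares and estimated-marginal-means contrasts, a
## Wilks MANCOVA omnibus, chi-square/Fisher dispatch under the
## 20%-expected-cell rule, Benjamini-Hochberg adjustment, partial
## correlations, multiple regression, ICC(2,1) and percent agreement.

.as_sum_factor <- function(x) {
  f <- as.factor(x)
  contrasts(f) <- contr.sum(nlevels(f))
  f
}

#' Two-factor ANCOVA with Type-III tests
#'
#' Fits `y ~ covariate + diagnosis * sex` with sum-to-zero factor coding
#' and tests each term by comparing residual sums of squares of nested
#' models (Type-III style: each main effect is dropped while the
#' interaction is retained). Reports F, degrees of freedom, p, and
#' partial eta squared `SS_effect / (SS_effect + SS_resid)`.
#'
#' @param y Numeric outcome.
#' @param diagnosis,sex Two-level (or more) factors.
#' @param covariate Numeric covariate (e.g. verbal IQ), or `NULL` for a
#'   plain two-way ANOVA.
#' @param min_cell Warn when any design cell has fewer observations.
#' @return Object of class `"pl_ancova"`: a result `table` (one row per
#'   effect: diagnosis, sex, interaction, and the covariate), the full
#'   `lm` fit, and the model frame.
#' @export
factorial_ancova <- function(y, diagnosis, sex, covariate = NULL,
                             min_cell = 5L) {
  df <- data.frame(y = y, A = .as_sum_factor(diagnosis),
                   B = .as_sum_factor(sex))
  if (!is.null(covariate)) df$z <- covariate
  df <- df[complete.cases(df), ]
  cells <- table(df$A, df$B)
  if (any(cells == 0)) stop("empty design cell", call. = FALSE)
  if (any(cells < min_cell)) {
    warning("design cell(s) with fewer than ", min_cell, " observations",
            call. = FALSE)
  }
  full_rhs <- if (is.null(covariate)) "A * B" else "z + A * B"
  full <- lm(stats::as.formula(paste("y ~", full_rhs)), data = df)
  if (any(is.na(coef(full)))) {
    stop("rank-deficient design; aliased term(s): ",
         paste(names(coef(full))[is.na(coef(full))], collapse = ", "),
         call. = FALSE)
  }
  rss_full <- sum(resid(full)^2)
  df_res <- full$df.residual
  ## Type III: drop the columns of each term from the sum-coded model
  ## matrix while keeping every other term (incl. the interaction)
  X <- model.matrix(full)
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(full), "term.labels")
  drop_terms <- c(diagnosis = "A", sex = "B", interaction = "A:B")
  if (!is.null(covariate)) drop_terms <- c(drop_terms, covariate = "z")
  rows <- lapply(names(drop_terms), function(eff) {
    tr <- drop_terms[[eff]]
    cols <- which(asgn == match(tr, labels))
    red <- stats::lm.fit(X[, -cols, drop = FALSE], df$y)
    ss <- sum(red$residuals^2) - rss_full
    df1 <- length(cols)
    y_ss <- sum((df$y - mean(df$y))^2)
    if (rss_full <= 1e-12 * (y_ss + 1) && ss <= 1e-12 * (y_ss + 1)) {
      ## outcome fit exactly (e.g. constant y): no effect evidence
      return(data.frame(effect = eff, F = 0, df1 = df1, df2 = df_res,
                        p = 1, eta_p2 = 0, stringsAsFactors = FALSE))
    }
    Fv <- (ss / df1) / (rss_full / df_res)
    data.frame(effect = eff, F = Fv, df1 = df1, df2 = df_res,
               p = pf(Fv, df1, df_res, lower.tail = FALSE),
               eta_p2 = ss / (ss + rss_full), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, fit = full, data = df,
                 has_covariate = !is.null(covariate)),
            class = "pl_ancova")
}

#' @export
print.pl_ancova <- function(x, ...) {
  cat("Two-factor", if (x$has_covariate) "ANCOVA" else "ANOVA",
      "(Type-III tests, sum-to-zero coding)\n")
  tab <- x$table
  tab$F <- round(tab$F, 3); tab$p <- signif(tab$p, 3)
  tab$eta_p2 <- round(tab$eta_p2, 4)
  print(tab)
  invisible(x)
}

#' Estimated-marginal-means pairwise contrasts
#'
#' Marginal means of one factor at the covariate mean, equally weighted
#' over the levels of the other factor, with pairwise t contrasts using
#' the ANCOVA residual variance.
#'
#' @param model A `"pl_ancova"` fit.
#' @param factor `"diagnosis"` or `"sex"`.
#' @param by Optional conditioning factor name: contrasts are then formed
#'   within each level of `by` (simple effects).
#' @return List with `emmeans` (data frame of level, emm, se) and
#'   `contrasts` (data frame of contrast, estimate, se, t, df, p).
#' @export
emm_pairwise <- function(model, factor = c("diagnosis", "sex"), by = NULL) {
  factor <- match.arg(factor)
  fac <- c(diagnosis = "A", sex = "B")[[factor]]
  other <- setdiff(c("A", "B"), fac)
  df <- model$data
  if (any(table(df$A, df$B) == 0)) stop("empty design cell", call. = FALSE)
  grid <- expand.grid(A = levels(df$A), B = levels(df$B))
  if (model$has_covariate) grid$z <- mean(df$z)
  grid$A <- base::factor(grid$A, levels = levels(df$A))
  grid$B <- base::factor(grid$B, levels = levels(df$B))
  contrasts(grid$A) <- contrasts(df$A)
  contrasts(grid$B) <- contrasts(df$B)
  Xg <- model.matrix(stats::delete.response(stats::terms(model$fit)), grid)
  beta <- coef(model$fit)
  V <- vcov(model$fit)
  df2 <- model$fit$df.residual
  avg_rows <- function(sel) colMeans(Xg[sel, , drop = FALSE])
  if (is.null(by)) {
    lvls <- levels(df[[fac]])
    L <- t(vapply(lvls, function(l) avg_rows(grid[[fac]] == l),
                  numeric(ncol(Xg))))
    emms <- data.frame(level = lvls, emm = as.vector(L %*% beta),
                       se = sqrt(diag(L %*% V %*% t(L))))
    prs <- utils::combn(seq_along(lvls), 2, simplify = FALSE)
    ctr <- do.call(rbind, lapply(prs, function(ij) {
      cvec <- L[ij[1], ] - L[ij[2], ]
      est <- sum(cvec * beta)
      se <- sqrt(drop(t(cvec) %*% V %*% cvec))
      data.frame(contrast = paste(lvls[ij[1]], "-", lvls[ij[2]]),
                 estimate = est, se = se, t = est / se, df = df2,
                 p = 2 * pt(abs(est / se), df2, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }))
    return(list(emmeans = emms, contrasts = ctr))
  }
  byfac <- c(diagnosis = "A", sex = "B")[[by]]
  out <- lapply(levels(df[[byfac]]), function(bl) {
    lvls <- levels(df[[fac]])
    L <- t(vapply(lvls, function(l) {
      avg_rows(grid[[fac]] == l & grid[[byfac]] == bl)
    }, numeric(ncol(Xg))))
    prs <- utils::combn(seq_along(lvls), 2, simplify = FALSE)
    do.call(rbind, lapply(prs, function(ij) {
      cvec <- L[ij[1], ] - L[ij[2], ]
      est <- sum(cvec * beta)
      se <- sqrt(drop(t(cvec) %*% V %*% cvec))
      data.frame(by = bl,
                 contrast = paste(lvls[ij[1]], "-", lvls[ij[2]]),
                 estimate = est, se = se, t = est / se, df = df2,
                 p = 2 * pt(abs(est / se), df2, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }))
  })
  list(contrasts = do.call(rbind, out))
}

#' Wilks MANCOVA omnibus tests
#'
#' Multivariate tests of diagnosis, sex, and their interaction (adjusting
#' for an optional covariate) via Wilks' Lambda computed from hypothesis
#' and error SSCP matrices of nested multivariate linear models, with
#' Rao's F approximation.
#'
#' @param Y Numeric outcome matrix (n x d).
#' @param diagnosis,sex Factors.
#' @param covariate Optional numeric covariate.
#' @return Data frame with one row per effect: Wilks Lambda, approximate
#'   F, df1, df2, p.
#' @export
mancova_wilks <- function(Y, diagnosis, sex, covariate = NULL) {
  Y <- as.matrix(Y)
  df <- data.frame(A = .as_sum_factor(diagnosis), B = .as_sum_factor(sex))
  if (!is.null(covariate)) df$z <- covariate
  cc <- complete.cases(df) & complete.cases(Y)
  df <- df[cc, , drop = FALSE]; Y <- Y[cc, , drop = FALSE]
  d <- ncol(Y); n <- nrow(Y)
  full_rhs <- if (is.null(covariate)) "A * B" else "z + A * B"
  full <- lm(stats::as.formula(paste("Y ~", full_rhs)), data = df)
  E <- crossprod(resid(full))
  if (abs(det(E)) < 1e-300) stop("singular error SSCP", call. = FALSE)
  ve <- full$df.residual
  X <- model.matrix(full)
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(full), "term.labels")
  drop_terms <- c(diagnosis = "A", sex = "B", interaction = "A:B")
  rows <- lapply(names(drop_terms), function(eff) {
    tr <- drop_terms[[eff]]
    cols <- which(asgn == match(tr, labels))
    red <- stats::lm.fit(X[, -cols, drop = FALSE], Y)
    H <- crossprod(red$residuals) - E
    q <- length(cols)
    lambda <- det(E) / det(E + H)
    tt <- if (d^2 + q^2 - 5 > 0) sqrt((d^2 * q^2 - 4) / (d^2 + q^2 - 5)) else 1
    w <- ve + q - (d + q + 1) / 2
    df1 <- d * q
    df2 <- w * tt - (d * q - 2) / 2
    Fv <- ((1 - lambda^(1 / tt)) / lambda^(1 / tt)) * df2 / df1
    data.frame(effect = eff, wilks = lambda, F = Fv, df1 = df1, df2 = df2,
               p = pf(Fv, df1, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

#' Chi-square or Fisher's exact test with the 20%-expected-cell rule
#'
#' Computes the expected counts from the margins; when 20% or more of
#' cells have expected count below 5, Fisher's exact test is used
#' (two-sided by the point-probability rule), otherwise Pearson's
#' chi-square without continuity correction.
#'
#' @param tbl Matrix of non-negative counts (2+ rows/columns, positive
#'   margins).
#' @return List: `method` ("chisq" or "fisher"), `statistic` (chi-square
#'   value, `NA` for Fisher), `df`, `p`, `expected`, and the share of
#'   small-expected cells `prop_small`.
#' @export
chi_or_fisher <- function(tbl) {
  tbl <- as.matrix(tbl)
  if (any(tbl < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)) {
    stop("zero margin in contingency table", call. = FALSE)
  }
  expected <- outer(rowSums(tbl), colSums(tbl)) / sum(tbl)
  prop_small <- mean(expected < 5)
  if (prop_small >= 0.2) {
    p <- fisher.test(tbl, workspace = 2e6)$p.value
    list(method = "fisher", statistic = NA_real_, df = NA_integer_,
         p = p, expected = expected, prop_small = prop_small)
  } else {
    ct <- suppressWarnings(chisq.test(tbl, correct = FALSE))
    list(method = "chisq", statistic = unname(ct$statistic),
         df = unname(ct$parameter), p = ct$p.value,
         expected = expected, prop_small = prop_small)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (`p * m / rank` with enforced monotonicity,
#' capped at 1) and rejection flags at false-discovery rate `q`.
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @param q False discovery rate (default 0.10).
#' @return Data frame with `p`, `p_adj`, `reject`.
#' @export
bh_adjust <- function(p, q = 0.10) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  adj <- p.adjust(p, method = "BH")
  data.frame(p = p, p_adj = adj, reject = !is.na(adj) & adj <= q)
}

#' Partial Pearson correlation
#'
#' Correlation of the residuals of `x` and `y` after regressing each on
#' the covariate(s) `z`, with a t-based p-value on `n - 2 - q` degrees of
#' freedom (q = number of covariates).
#'
#' @param x,y Numeric vectors.
#' @param z Numeric vector or matrix of covariates.
#' @return List: `r`, `p`, `df`, `n` (`r = NA` when a residual vector is
#'   constant).
#' @export
partial_correlation <- function(x, y, z) {
  z <- as.matrix(z)
  cc <- complete.cases(x, y, z)
  x <- x[cc]; y <- y[cc]; z <- z[cc, , drop = FALSE]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete observations", call. = FALSE)
  rx <- resid(lm(x ~ z))
  ry <- resid(lm(y ~ z))
  if (sd(rx) <= 1e-10 * (sd(x) + 1e-30) ||
      sd(ry) <= 1e-10 * (sd(y) + 1e-30)) {
    return(list(r = NA_real_, p = NA_real_, df = n - 2 - ncol(z), n = n))
  }
  r <- cor(rx, ry)
  df <- n - 2 - ncol(z)
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(abs(tstat), df, lower.tail = FALSE), df = df,
       n = n)
}

#' Multiple linear regression with overall-model gating
#'
#' Ordinary least squares with per-coefficient t tests, R-squared and the
#' overall F test. Individual predictors are flagged for interpretation
#' only when the overall model is significant (`assess_predictors`).
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @param alpha Significance level for the overall-model gate.
#' @param max_kappa Condition-number threshold for the collinearity
#'   error.
#' @return Object of class `"pl_regression"`: coefficient table,
#'   `r_squared`, `overall_F`, `overall_p`, `assess_predictors`, and the
#'   `lm` fit.
#' @export
multiple_regression <- function(formula, data, alpha = 0.05,
                                max_kappa = 1e8) {
  fit <- lm(formula, data = data)
  X <- model.matrix(fit)
  kappa_x <- kappa(X, exact = TRUE)
  if (any(is.na(coef(fit))) || kappa_x > max_kappa) {
    stop("collinear design (condition number ", format(kappa_x, digits = 3),
         ")", call. = FALSE)
  }
  sm <- summary(fit)
  ctab <- as.data.frame(sm$coefficients)
  names(ctab) <- c("estimate", "se", "t", "p")
  fstat <- sm$fstatistic
  overall_p <- pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(list(coefficients = ctab,
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 overall_F = unname(fstat[1]),
                 overall_df = unname(fstat[2:3]),
                 overall_p = unname(overall_p),
                 assess_predictors = unname(overall_p) < alpha,
                 fit = fit),
            class = "pl_regression")
}

#' @export
print.pl_regression <- function(x, ...) {
  cat("Multiple regression: R2 =", round(x$r_squared, 4),
      " F(", x$overall_df[1], ",", x$overall_df[2], ") =",
      round(x$overall_F, 3), " p =", signif(x$overall_p, 3), "\n")
  if (!x$assess_predictors) {
    cat("overall model not significant; predictor tests not interpreted\n")
  }
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from
#' the two-way ANOVA decomposition, with the conventional agreement
#' label (moderate .5-.75, good .75-.9, excellent > .9).
#'
#' @param ratings Numeric matrix, items in rows and raters in columns
#'   (typically 2 raters).
#' @return List: `icc`, `label`, and the mean squares (`NA` when the
#'   between-item variance is zero).
#' @export
icc <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need >= 2 items and >= 2 raters", call. = FALSE)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_row <- k * sum((row_m - grand)^2)
  ss_col <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_row - ss_col
  msr <- ss_row / (n - 1)
  msc <- ss_col / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (ss_tot == 0 || ss_row == 0) {
    ## no between-item variance: the coefficient is undefined
    return(list(icc = NA_real_, label = NA_character_,
                msr = msr, msc = msc, mse = mse))
  }
  val <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  if (!is.finite(val)) val <- NA_real_
  label <- if (is.na(val)) NA_character_
    else if (val > 0.9) "excellent"
    else if (val >= 0.75) "good"
    else if (val >= 0.5) "moderate"
    else "poor"
  list(icc = val, label = label, msr = msr, msc = msc, mse = mse)
}

#' Percent agreement between two raters
#'
#' @param a,b Equal-length categorical label vectors.
#' @return Percent of exactly matching elements.
#' @export
percent_agreement <- function(a, b) {
  if (!length(a) || length(a) != length(b)) {
    stop("need two nonempty vectors of equal length", call. = FALSE)
  }
  100 * mean(a == b)
}
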