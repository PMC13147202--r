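## Latent profile analysis: diagonal-covariance Gaussian mixtures fit by
## EM (best of several kmeans++-seeded restarts), information criteria,
## normalized classification entropy, the parametric bootstrap likelihood
## ratio test, and a model-selection report over a range of profile
## counts.

#' Z-score a feature table
#'
#' Column-standardizes continuous indicators after listwise deletion of
#' incomplete rows, retaining the transformation parameters as
#' attributes `center` and `scale`.
#'
#' @param x Numeric matrix or data frame of indicators (named columns).
#' @return Numeric matrix with (approximately) zero-mean, unit-SD
#'   columns; attributes `center`, `scale` and `dropped` (number of
#'   incomplete rows removed).
#' @export
zscore_matrix <- function(x) {
  x <- as.matrix(as.data.frame(x))
  if (!is.numeric(x)) stop("all indicator columns must be numeric",
                           call. = FALSE)
  cc <- complete.cases(x)
  dropped <- sum(!cc)
  if (dropped > 0) {
    message("zscore_matrix: listwise deletion removed ", dropped, " row(s)")
    x <- x[cc, , drop = FALSE]
  }
  if (nrow(x) < 2) stop("need at least 2 complete rows", call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  zero <- scl == 0 | !is.finite(scl)
  if (any(zero)) {
    stop("zero-variance column(s): ",
         paste(colnames(x)[zero], collapse = ", "), call. = FALSE)
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  attr(z, "center") <- ctr
  attr(z, "scale") <- scl
  attr(z, "dropped") <- dropped
  z
}

.kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- X[sample.int(n, 1L), , drop = FALSE]
  if (k > 1L) {
    d2 <- rowSums(sweep(X, 2, centers[1L, ])^2)
    for (c in 2L:k) {
      idx <- if (all(d2 <= 0)) sample.int(n, 1L)
             else sample.int(n, 1L, prob = d2)
      centers <- rbind(centers, X[idx, , drop = FALSE])
      d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx, ])^2))
    }
  }
  centers
}

## n x k matrix of log( w_c * prod_j N(x_j; mu_cj, s2_cj) ), computed as
## two matrix products: -x'x/(2s2) + x'(mu/s2) + const_c
.log_dens <- function(X, w, mu, s2, X2 = X * X) {
  const <- log(w) - 0.5 * rowSums(log(2 * pi * s2)) -
    0.5 * rowSums(mu * mu / s2)
  L <- X2 %*% t(-0.5 / s2) + X %*% t(mu / s2)
  sweep(L, 2, const, "+")
}

.loglik_resp <- function(L) {
  k <- ncol(L)
  m <- L[, 1]
  if (k > 1) for (c in 2:k) m <- pmax(m, L[, c])
  lse <- m + log(rowSums(exp(L - m)))
  list(loglik = sum(lse), R = exp(L - lse))
}

.em_once <- function(X, k, tol, var_floor, max_iter, equal_variances) {
  n <- nrow(X); d <- ncol(X)
  X2 <- X * X
  centers <- .kmeanspp_centers(X, k)
  dmat <- vapply(seq_len(k),
                 function(c) rowSums(sweep(X, 2, centers[c, ])^2),
                 numeric(n))
  assign <- max.col(-dmat, ties.method = "first")
  w <- as.vector(table(factor(assign, levels = 1:k))) / n
  w[w == 0] <- 1 / n; w <- w / sum(w)
  mu <- centers
  s2 <- matrix(0, k, d)
  for (c in 1:k) {
    Xi <- X[assign == c, , drop = FALSE]
    if (nrow(Xi) > 1) {
      mu[c, ] <- colMeans(Xi)
      s2[c, ] <- colMeans(sweep(Xi, 2, mu[c, ])^2)
    } else {
      s2[c, ] <- apply(X, 2, var)
    }
  }
  s2 <- pmax(s2, var_floor)
  trace <- numeric(max_iter + 1L)
  n_it <- 0L
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    lr <- .loglik_resp(.log_dens(X, w, mu, s2, X2))
    n_it <- it
    trace[it] <- lr$loglik
    R <- lr$R
    Nc <- colSums(R)
    if (any(Nc < 1)) return(list(ok = FALSE))  # degenerate cluster
    w <- Nc / n
    mu <- crossprod(R, X) / Nc
    s2 <- crossprod(R, X2) / Nc - mu * mu
    if (equal_variances) {
      pooled <- colSums(s2 * Nc) / n
      s2 <- matrix(pooled, k, d, byrow = TRUE)
    }
    s2 <- pmax(s2, var_floor)
    if (lr$loglik - prev < tol && it > 1) break
    prev <- lr$loglik
  }
  lr <- .loglik_resp(.log_dens(X, w, mu, s2, X2))
  list(ok = TRUE, w = w, mu = mu, s2 = s2, loglik = lr$loglik, R = lr$R,
       trace = c(trace[seq_len(n_it)], lr$loglik), iter = n_it)
}

#' Fit a latent profile model
#'
#' Diagonal-covariance Gaussian mixture with `k` profiles, fit by EM.
#' Each of `restarts` runs is seeded by kmeans++ center selection and the
#' best run by log-likelihood is kept; runs producing a degenerate
#' profile (expected membership below one observation) are discarded.
#' For `k = 1` the closed-form single-Gaussian fit is returned.
#'
#' @param X Numeric matrix of indicators, typically from
#'   [zscore_matrix()].
#' @param k Number of profiles (>= 1; must satisfy `n > k`).
#' @param restarts Number of EM restarts (default 20).
#' @param seed Integer seed; the fit is deterministic given it.
#' @param tol EM convergence tolerance on the log-likelihood gain.
#' @param var_floor Lower bound on every profile variance (default 1e-4,
#'   on z-scored data).
#' @param equal_variances Constrain variances to be equal across profiles
#'   (they still vary by indicator).
#' @param max_iter EM iteration cap per restart.
#' @return Object of class `"lpa"`: mixing `weights`, `means` (k x d),
#'   `variances` (k x d), `loglik`, `posteriors` (n x k), modal
#'   `assignments`, `aic`, `bic`, `entropy` (NA for k = 1), `n_parameters`,
#'   `loglik_trace` of the winning run, plus call metadata.
#' @export
lpa <- function(X, k, restarts = 20L, seed = 1L, tol = 1e-6,
                var_floor = 1e-4, equal_variances = FALSE,
                max_iter = 500L) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (n <= k) stop("need n > k", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(d))
  if (k == 1L) {
    mu <- matrix(colMeans(X), 1, d, dimnames = list(NULL, colnames(X)))
    s2 <- matrix(pmax(colMeans(sweep(X, 2, mu[1, ])^2), var_floor), 1, d,
                 dimnames = list(NULL, colnames(X)))
    ll <- .loglik_resp(.log_dens(X, 1, mu, s2))$loglik
    best <- list(w = 1, mu = mu, s2 = s2, loglik = ll,
                 R = matrix(1, n, 1), trace = ll, iter = 1L)
  } else {
    set.seed(seed)
    best <- NULL
    for (r in seq_len(restarts)) {
      fit <- .em_once(X, k, tol, var_floor, max_iter, equal_variances)
      if (!fit$ok) next
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    if (is.null(best)) {
      stop("all ", restarts, " restarts produced a degenerate profile",
           call. = FALSE)
    }
  }
  p <- (k - 1) + k * d + if (equal_variances) d else k * d
  colnames(best$mu) <- colnames(X)
  colnames(best$s2) <- colnames(X)
  m <- structure(list(
    k = k, n = n, d = d,
    weights = as.vector(best$w),
    means = best$mu, variances = best$s2,
    loglik = best$loglik,
    posteriors = best$R,
    assignments = max.col(best$R, ties.method = "first"),
    n_parameters = p,
    aic = -2 * best$loglik + 2 * p,
    bic = -2 * best$loglik + p * log(n),
    entropy = NA_real_,
    loglik_trace = best$trace,
    seed = seed, restarts = restarts,
    equal_variances = equal_variances,
    var_floor = var_floor, tol = tol,
    indicator_names = colnames(X)),
    class = "lpa")
  m$entropy <- classification_entropy(m)
  m
}

#' Information criteria of a fitted profile model
#'
#' `AIC = -2 loglik + 2p` and `BIC = -2 loglik + p log(n)` with
#' `p = (k - 1) + kd + kd` free parameters for the class-varying
#' diagonal model (`(k - 1) + kd + d` under equal variances).
#'
#' @param m An `"lpa"` fit.
#' @return Named numeric vector `c(aic, bic)`.
#' @export
information_criteria <- function(m) c(aic = m$aic, bic = m$bic)

#' Normalized classification entropy
#'
#' `1 - sum_ic(-p_ic log p_ic) / (n log k)`; 1 for a perfectly crisp
#' classification, 0 for uniform posteriors, `NA` for `k = 1`.
#'
#' @param m An `"lpa"` fit (or an n x k posterior matrix).
#' @return Scalar in `[0, 1]`, or `NA` for a single profile.
#' @export
classification_entropy <- function(m) {
  R <- if (inherits(m, "lpa")) m$posteriors else as.matrix(m)
  k <- ncol(R); n <- nrow(R)
  if (k < 2) return(NA_real_)
  h <- -R * log(R)
  h[!is.finite(h)] <- 0
  1 - sum(h) / (n * log(k))
}

## S3 methods ---------------------------------------------------------------

#' @export
print.lpa <- function(x, ...) {
  cat("Latent profile model: k = ", x$k, " profiles, n = ", x$n,
      ", ", x$d, " indicators\n", sep = "")
  cat("  loglik ", format(x$loglik, digits = 6),
      "  AIC ", format(x$aic, digits = 6),
      "  BIC ", format(x$bic, digits = 6),
      "  entropy ", ifelse(is.na(x$entropy), "--",
                           format(x$entropy, digits = 3)), "\n", sep = "")
  cat("  profile proportions: ",
      paste(format(x$weights, digits = 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.lpa <- function(object, ...) {
  print(object)
  cat("\nProfile means (z-score units):\n")
  print(round(object$means, 3))
  cat("\nProfile variances:\n")
  print(round(object$variances, 3))
  invisible(object)
}

#' @export
coef.lpa <- function(object, ...) {
  list(weights = object$weights, means = object$means,
       variances = object$variances)
}

#' @export
logLik.lpa <- function(object, ...) {
  structure(object$loglik, df = object$n_parameters, nobs = object$n,
            class = "logLik")
}

#' Posterior profile membership for new observations
#'
#' @param object An `"lpa"` fit.
#' @param newdata Matrix on the same (z-scored) scale as the training
#'   data; defaults to returning the training posteriors.
#' @param type `"posterior"` (n x k matrix) or `"class"` (modal profile).
#' @param ... Unused.
#' @return Posterior matrix or integer class vector.
#' @export
predict.lpa <- function(object, newdata = NULL,
                        type = c("posterior", "class"), ...) {
  type <- match.arg(type)
  R <- if (is.null(newdata)) {
    object$posteriors
  } else {
    .loglik_resp(.log_dens(as.matrix(newdata), object$weights,
                           object$means, object$variances))$R
  }
  if (type == "class") max.col(R, ties.method = "first") else R
}

#' Simulate from a fitted profile model
#'
#' @param object An `"lpa"` fit.
#' @param nsim Number of observations to draw.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Matrix of draws with attribute `"class_labels"` holding the
#'   latent profile labels.
#' @export
simulate.lpa <- function(object, nsim = object$n, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  z <- sample.int(object$k, nsim, replace = TRUE, prob = object$weights)
  X <- matrix(rnorm(nsim * object$d), nsim, object$d)
  X <- X * sqrt(object$variances[z, , drop = FALSE]) +
    object$means[z, , drop = FALSE]
  colnames(X) <- object$indicator_names
  attr(X, "class_labels") <- z
  X
}

#' @export
plot.lpa <- function(x, ...) {
  matplot(t(x$means), type = "b", pch = 19, lty = 1,
          xlab = "indicator", ylab = "profile mean (z)",
          xaxt = "n", main = paste0("Latent profiles (k = ", x$k, ")"), ...)
  axis(1, at = seq_len(x$d), labels = x$indicator_names, las = 2,
       cex.axis = 0.8)
  legend("topright", legend = paste0("profile ", seq_len(x$k),
                                     " (", round(100 * x$weights), "%)"),
         col = seq_len(x$k), lty = 1, pch = 19, cex = 0.8)
  invisible(x)
}

## BLRT and model selection -------------------------------------------------

#' Bootstrap likelihood ratio test for k vs k - 1 profiles
#'
#' Parametric bootstrap: the (k-1)-profile model is fit to the data, and
#' `n_boot` datasets of the same size are simulated from it; both models
#' are refit to each and the null distribution of
#' `2 (loglik_k - loglik_{k-1})` yields an add-one p-value.
#'
#' @param X Indicator matrix.
#' @param k Profile count under the alternative (>= 2).
#' @param n_boot Number of bootstrap datasets (default 100).
#' @param seed Integer seed.
#' @param restarts EM restarts for the data fits.
#' @param boot_restarts EM restarts for each bootstrap fit. Defaults to
#'   `restarts`: the bootstrap statistic must be produced by the same
#'   fitting protocol as the observed one, otherwise the null
#'   distribution is shifted and the test loses its level.
#' @param ... Passed to [lpa()] (tolerances etc.).
#' @return Object of class `"blrt"`: `k`, `observed_lrt`, `boot_lrts`,
#'   `p_value`, `n_boot`, `seed`, and the two data fits.
#' @export
blrt <- function(X, k, n_boot = 100L, seed = 1L, restarts = 20L,
                 boot_restarts = restarts, ...) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  X <- as.matrix(X)
  n <- nrow(X)
  fit0 <- lpa(X, k - 1L, restarts = restarts, seed = seed, ...)
  fit1 <- lpa(X, k, restarts = restarts, seed = seed + 1L, ...)
  observed <- 2 * (fit1$loglik - fit0$loglik)
  boot_lrts <- numeric(0)
  attempts <- 0L
  set.seed(seed + 2L)
  seeds <- sample.int(.Machine$integer.max - 1L, 3L * n_boot)
  while (length(boot_lrts) < n_boot) {
    attempts <- attempts + 1L
    if (attempts > 3L * n_boot) {
      stop("too many bootstrap fit failures in blrt", call. = FALSE)
    }
    s <- seeds[attempts]
    stat <- tryCatch({
      Xb <- simulate(fit0, nsim = n, seed = s)
      b0 <- lpa(Xb, k - 1L, restarts = boot_restarts, seed = s + 1L, ...)
      b1 <- lpa(Xb, k, restarts = boot_restarts, seed = s + 2L, ...)
      2 * (b1$loglik - b0$loglik)
    }, error = function(e) NULL)
    if (!is.null(stat)) boot_lrts <- c(boot_lrts, stat)
  }
  p <- (1 + sum(boot_lrts >= observed)) / (1 + n_boot)
  structure(list(k = k, observed_lrt = observed, boot_lrts = boot_lrts,
                 p_value = p, n_boot = n_boot, seed = seed,
                 fit_null = fit0, fit_alt = fit1),
            class = "blrt")
}

#' @export
print.blrt <- function(x, ...) {
  cat("Bootstrap likelihood ratio test: ", x$k - 1, " vs ", x$k,
      " profiles\n  observed LRT = ", format(x$observed_lrt, digits = 4),
      ", p = ", format(x$p_value, digits = 4), " (", x$n_boot,
      " bootstraps)\n", sep = "")
  invisible(x)
}

#' Model-selection report over a range of profile counts
#'
#' Fits models for each `k` and tabulates AIC, BIC, entropy, the smallest
#' and largest profile proportions, and (optionally) the BLRT p-value —
#' the usual fit table for choosing a profile solution. The BIC-minimal
#' model is flagged, as are models containing a profile below
#' `min_prop`; the final choice is left to the analyst.
#'
#' @param X Indicator matrix.
#' @param ks Profile counts to evaluate (default 1:6).
#' @param restarts,seed,... Passed to [lpa()].
#' @param n_boot BLRT bootstrap count per k (0 skips the BLRT column).
#' @param min_prop Minimum acceptable profile proportion (default 0.05).
#' @return Object of class `"lpa_selection"`: the fit table (`table`),
#'   the fitted models (`models`), `bic_optimal` k, and `small_profile`
#'   flags.
#' @export
lpa_select <- function(X, ks = 1:6, restarts = 20L, seed = 1L,
                       n_boot = 0L, min_prop = 0.05, ...) {
  X <- as.matrix(X)
  models <- list()
  rows <- list()
  for (k in ks) {
    m <- lpa(X, k, restarts = restarts, seed = seed + k, ...)
    models[[as.character(k)]] <- m
    bp <- NA_real_
    if (n_boot > 0 && k >= 2) {
      bp <- blrt(X, k, n_boot = n_boot, seed = seed + 100L + k,
                 restarts = restarts, ...)$p_value
    }
    rows[[as.character(k)]] <- data.frame(
      k = k, loglik = m$loglik, aic = m$aic, bic = m$bic,
      entropy = m$entropy,
      smallest_prop = if (k == 1) NA_real_ else min(m$weights),
      largest_prop = if (k == 1) NA_real_ else max(m$weights),
      blrt_p = bp)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 models = models,
                 bic_optimal = tab$k[which.min(tab$bic)],
                 small_profile = tab$k[!is.na(tab$smallest_prop) &
                                         tab$smallest_prop < min_prop],
                 min_prop = min_prop),
            class = "lpa_selection")
}

#' @export
print.lpa_selection <- function(x, ...) {
  tab <- x$table
  tab$aic <- round(tab$aic, 2); tab$bic <- round(tab$bic, 2)
  tab$entropy <- round(tab$entropy, 2)
  tab$smallest_prop <- round(tab$smallest_prop, 2)
  tab$largest_prop <- round(tab$largest_prop, 2)
  print(tab)
  cat("BIC-minimal model: k =", x$bic_optimal, "\n")
  if (length(x$small_profile)) {
    cat("models with a profile below", x$min_prop, ": k =",
        paste(x$small_profile, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Profile over/under-representation tests
#'
#' For each profile, tests whether the composition of the grouping
#' variable inside the profile differs from the remaining sample, using
#' the chi-square / Fisher dispatch rule of [chi_or_fisher()].
#'
#' @param assignments Modal profile assignments (integer or factor).
#' @param labels Group labels aligned to `assignments` (e.g. the four
#'   diagnosis-by-sex cells).
#' @return Data frame with one row per profile: profile, n, test method,
#'   statistic, p-value, and the most over-represented group label.
#' @export
profile_membership_test <- function(assignments, labels) {
  if (length(assignments) != length(labels)) {
    stop("assignments and labels must be aligned", call. = FALSE)
  }
  assignments <- as.factor(assignments)
  labels <- as.factor(labels)
  rows <- lapply(levels(assignments), function(p) {
    inside <- assignments == p
    tab <- rbind(`in` = table(labels[inside]),
                 out = table(labels[!inside]))
    res <- chi_or_fisher(tab)
    prop_in <- prop.table(tab[1, ])
    prop_all <- prop.table(table(labels))
    data.frame(profile = p, n = sum(inside), method = res$method,
               statistic = res$statistic, p = res$p,
               over_represented = names(which.max(prop_in - prop_all)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
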