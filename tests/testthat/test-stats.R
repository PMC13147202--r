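make_design <- function(n = 120, seed = 40, effect = 0) {
  set.seed(seed)
  data.frame(
    diagnosis = sample(c("asd", "non_asd"), n, TRUE),
    sex = sample(c("male", "female"), n, TRUE),
    viq = rnorm(n, 105, 12),
    e = rnorm(n)) |>
    transform(y = e + effect * (diagnosis == "asd"))
}

test_that("Type-III ANCOVA matches the car oracle to 1e-8", {
  skip_if_not_installed("car")
  df <- make_design(effect = 0.4)
  res <- factorial_ancova(df$y, df$diagnosis, df$sex, df$viq)
  fit <- lm(y ~ viq + A * B,
            data = transform(df, A = factor(diagnosis), B = factor(sex)),
            contrasts = list(A = "contr.sum", B = "contr.sum"))
  ora <- car::Anova(fit, type = 3)
  for (pair in list(c("diagnosis", "A"), c("sex", "B"),
                    c("interaction", "A:B"), c("covariate", "viq"))) {
    row <- res$table[res$table$effect == pair[1], ]
    expect_equal(row$F, ora[pair[2], "F value"], tolerance = 1e-8)
    expect_equal(row$p, ora[pair[2], "Pr(>F)"], tolerance = 1e-8)
  }
  expect_true(all(res$table$eta_p2 >= 0 & res$table$eta_p2 <= 1))
})

test_that("with an orthogonal covariate and balanced design, ANCOVA equals ANOVA on residualized y", {
  set.seed(41)
  cells <- expand.grid(diagnosis = c("asd", "non_asd"),
                       sex = c("male", "female"))
  df <- cells[rep(1:4, each = 25), ]
  z <- rnorm(100)
  z <- resid(lm(z ~ factor(df$diagnosis) * factor(df$sex)))  # orthogonalize
  y <- rnorm(100) + 2 * z
  a1 <- factorial_ancova(y, df$diagnosis, df$sex, z)
  yr <- resid(lm(y ~ z))
  a2 <- factorial_ancova(yr, df$diagnosis, df$sex, covariate = NULL)
  for (eff in c("diagnosis", "sex", "interaction")) {
    f1 <- a1$table$F[a1$table$effect == eff]
    f2 <- a2$table$F[a2$table$effect == eff]
    expect_equal(f1, f2, tolerance = 0.02)
  }
  # constant outcome: all F = 0 in the no-covariate ANOVA
  flat <- factorial_ancova(rep(1, 100), df$diagnosis, df$sex,
                           covariate = NULL)
  expect_true(all(flat$table$F == 0))
  expect_true(all(flat$table$p == 1))
})

test_that("estimated marginal means match the emmeans oracle", {
  skip_if_not_installed("emmeans")
  df <- make_design(seed = 42, effect = 0.5)
  res <- factorial_ancova(df$y, df$diagnosis, df$sex, df$viq)
  e <- emm_pairwise(res, "diagnosis")
  fit <- lm(y ~ viq + A * B,
            data = transform(df, A = factor(diagnosis), B = factor(sex)),
            contrasts = list(A = "contr.sum", B = "contr.sum"))
  ora <- summary(emmeans::emmeans(fit, pairwise ~ A)$contrasts)
  expect_equal(e$contrasts$estimate, ora$estimate, tolerance = 1e-8)
  expect_equal(e$contrasts$se, ora$SE, tolerance = 1e-8)
  expect_equal(e$contrasts$p, ora$p.value, tolerance = 1e-8)
  emm_ora <- summary(emmeans::emmeans(fit, ~A))
  expect_equal(e$emmeans$emm, emm_ora$emmean, tolerance = 1e-8)
  # identical groups give t = 0
  df2 <- df; df2$y <- df2$e
  r2 <- factorial_ancova(df2$y, rep(c("a", "b"), 60), df2$sex, df2$viq)
  same <- emm_pairwise(r2, "diagnosis")
  expect_lt(abs(same$contrasts$t), 3)  # no systematic effect
  # balanced covariate-centered data: EMMs equal cell means
  cells <- rep(c("asd", "non_asd"), each = 50)
  sx <- rep(c("male", "female"), 50)
  yy <- rnorm(100)
  r3 <- factorial_ancova(yy, cells, sx, covariate = NULL)
  e3 <- emm_pairwise(r3, "diagnosis")
  cellm <- tapply(yy, list(cells, sx), mean)
  expect_equal(e3$emmeans$emm, unname(rowMeans(cellm)), tolerance = 1e-10)
})

test_that("the Wilks MANCOVA matches the anova.mlm oracle and degenerates to the univariate F", {
  set.seed(43)
  n <- 90
  dg <- sample(c("a", "b"), n, TRUE); sx <- sample(c("m", "f"), n, TRUE)
  z <- rnorm(n)
  Y <- cbind(rnorm(n) + (dg == "a"), rnorm(n), rnorm(n) + 0.5 * z)
  got <- mancova_wilks(Y, dg, sx, z)
  df <- data.frame(A = factor(dg), B = factor(sx), z = z)
  full <- lm(Y ~ z + A * B, data = df,
             contrasts = list(A = "contr.sum", B = "contr.sum"))
  X <- model.matrix(full)
  asgn <- attr(X, "assign")
  labels <- attr(terms(full), "term.labels")
  for (pair in list(c("diagnosis", "A"), c("sex", "B"),
                    c("interaction", "A:B"))) {
    cols <- which(asgn == match(pair[2], labels))
    Xr <- X[, -cols, drop = FALSE]
    ora <- anova(full, lm(Y ~ Xr - 1), test = "Wilks")
    row <- got[got$effect == pair[1], ]
    expect_equal(row$wilks, ora$Wilks[2], tolerance = 1e-8)
    expect_equal(row$F, ora$`approx F`[2], tolerance = 1e-8)
    expect_equal(row$p, ora$`Pr(>F)`[2], tolerance = 1e-8)
  }
  expect_true(all(got$wilks > 0 & got$wilks <= 1))
  # d = 1 equals the univariate ANCOVA F
  uni <- mancova_wilks(Y[, 1, drop = FALSE], dg, sx, z)
  anc <- factorial_ancova(Y[, 1], dg, sx, z)
  expect_equal(uni$F[uni$effect == "diagnosis"],
               anc$table$F[anc$table$effect == "diagnosis"],
               tolerance = 1e-8)
})

test_that("the 20%-expected-cell rule selects the branch and Fisher matches enumeration", {
  low <- matrix(c(3, 1, 1, 3), 2)
  res <- chi_or_fisher(low)
  expect_equal(res$method, "fisher")
  expect_true(all(res$expected == 2))
  # one-sided enumeration for this fixture: P(X >= 3) = 17/70
  expect_equal(sum(dhyper(3:4, 4, 4, 4)), 17 / 70)
  expect_equal(res$p, fisher_oracle_2x2(low), tolerance = 1e-10)
  big <- matrix(c(50, 50, 50, 50), 2)
  res2 <- chi_or_fisher(big)
  expect_equal(res2$method, "chisq")
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p, 1)
  # 2x3 with a zero-heavy column trips the rule
  tbl <- matrix(c(20, 18, 1, 2, 0, 1), 2)
  expect_gte(mean(outer(rowSums(tbl), colSums(tbl)) / sum(tbl) < 5), 0.2)
  expect_equal(chi_or_fisher(tbl)$method, "fisher")
  expect_error(chi_or_fisher(matrix(c(0, 0, 1, 2), 2)), "margin")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04))$p_adj,
               rep(0.04, 4))
  expect_equal(bh_adjust(0.73)$p_adj, 0.73)
  set.seed(44)
  for (i in 1:50) {
    p <- runif(sample(2:20, 1))
    got <- bh_adjust(p, q = 0.10)
    expect_equal(got$p_adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(diff(got$p_adj[order(p)]) >= -1e-12))
    # BH never rejects more than raw testing at the same threshold
    expect_lte(sum(got$p_adj <= 0.05), sum(p <= 0.05))
  }
})

test_that("partial correlation matches the closed form and its edge cases", {
  set.seed(45)
  n <- 60
  z <- rnorm(n); x <- 0.5 * z + rnorm(n); y <- -0.3 * z + rnorm(n)
  got <- partial_correlation(x, y, z)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(got$r, closed, tolerance = 1e-10)
  expect_equal(got$df, n - 3)
  # z unrelated to both: equals the plain correlation
  z2 <- rep(c(0, 1), n / 2)[sample(n)]
  x2 <- rnorm(n); y2 <- rnorm(n)
  x2 <- resid(lm(x2 ~ z2)); y2 <- resid(lm(y2 ~ z2))
  expect_equal(partial_correlation(x2, y2, z2)$r, cor(x2, y2),
               tolerance = 1e-10)
  # x = z: residual correlation about zero, constant residual gives NA
  expect_lt(abs(partial_correlation(z + 1e-8 * rnorm(n), y, z)$r), 0.5)
  expect_true(is.na(partial_correlation(z, y, z)$r))
})

test_that("multiple regression reproduces the normal equations and gates predictors", {
  set.seed(46)
  df <- data.frame(x1 = rnorm(50), x2 = rnorm(50), x3 = rnorm(50))
  df$y <- 2 + 3 * df$x1 + rnorm(50, sd = 0.5)
  fit <- multiple_regression(y ~ x1 + x2 + x3, df)
  X <- cbind(1, as.matrix(df[c("x1", "x2", "x3")]))
  beta <- solve(crossprod(X), crossprod(X, df$y))
  expect_equal(fit$coefficients$estimate, as.vector(beta),
               tolerance = 1e-10)
  expect_true(fit$assess_predictors)
  # exact linear outcome: R^2 = 1
  df$y2 <- 1 + df$x1
  expect_equal(suppressWarnings(multiple_regression(y2 ~ x1, df))$r_squared,
               1)
  # collinear design errors
  df$x4 <- df$x1
  expect_error(multiple_regression(y ~ x1 + x4, df), "collinear")
})

test_that("ICC(2,1) matches the variance-component formula on a 6-item fixture", {
  ratings <- cbind(r1 = c(9, 6, 8, 7, 10, 6), r2 = c(2, 1, 4, 1, 5, 2))
  got <- icc(ratings)
  n <- 6; k <- 2
  grand <- mean(ratings)
  msr <- k * sum((rowMeans(ratings) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(ratings) - grand)^2) / (k - 1)
  mse <- (sum((ratings - grand)^2) - (n - 1) * msr / k * k -
            (k - 1) * msc / n * n) / ((n - 1) * (k - 1))
  want <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  expect_equal(got$icc, want, tolerance = 1e-10)
  # identical raters: 1; with the conventional label
  same <- cbind(c(1, 2, 3, 5), c(1, 2, 3, 5))
  expect_equal(icc(same)$icc, 1)
  expect_equal(icc(same)$label, "excellent")
  expect_true(is.na(icc(cbind(c(1, 1, 1), c(1, 1, 1)))$icc))
  # independent ratings drift to zero
  set.seed(47)
  vals <- replicate(200, icc(cbind(rnorm(20), rnorm(20)))$icc)
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("percent agreement is the elementwise match rate", {
  expect_equal(percent_agreement(c("a", "b"), c("a", "b")), 100)
  expect_equal(percent_agreement(c("a", "b"), c("b", "a")), 0)
  set.seed(48)
  a <- sample(letters[1:3], 50, TRUE); b <- sample(letters[1:3], 50, TRUE)
  expect_equal(percent_agreement(a, b), 100 * sum(a == b) / 50)
  expect_error(percent_agreement(character(0), character(0)), "nonempty")
})
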