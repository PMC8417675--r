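test_that("imputation is a no-op on complete data and reproducible by seed", {
  d <- data.frame(a = rnorm(50), b = rnorm(50))
  out <- chained_imputation(d, m = 3, seed = 1)
  expect_length(out, 3)
  for (o in out) expect_identical(o, d)
  set.seed(2)
  d$a[sample(50, 10)] <- NA
  r1 <- chained_imputation(d, m = 2, seed = 9)
  r2 <- chained_imputation(d, m = 2, seed = 9)
  expect_identical(r1, r2)
  expect_false(identical(r1[[1]]$a, r1[[2]]$a))  # chains are independent
  # observed cells never altered
  obs <- !is.na(d$a)
  expect_identical(r1[[1]]$a[obs], d$a[obs])
  expect_error(chained_imputation(data.frame(a = NA_real_, b = 1:2 + 0.5)),
               "entirely missing")
})

test_that("imputation exploits a correlated predictor (beats mean imputation)", {
  set.seed(123)
  n <- 2000
  x <- rnorm(n)
  y <- 0.9 * x + sqrt(1 - 0.9^2) * rnorm(n)   # cor ~ 0.9
  truth <- y
  miss <- sample(n, round(0.2 * n))
  d <- data.frame(x = x, y = y)
  d$y[miss] <- NA
  out <- chained_imputation(d, m = 1, n_iter = 5, seed = 4)[[1]]
  rmse <- sqrt(mean((out$y[miss] - truth[miss])^2))
  expect_lt(rmse, sd(truth))   # mean imputation's RMSE is the marginal SD
})

test_that("binary columns are imputed by logistic draws", {
  set.seed(6)
  n <- 1500
  x <- rnorm(n)
  z <- runif(n) < plogis(2.5 * x)
  d <- data.frame(x = x, z = z)
  miss <- sample(n, 300)
  d$z[miss] <- NA
  out <- chained_imputation(d, m = 1, seed = 5)[[1]]
  expect_type(out$z, "logical")
  expect_false(anyNA(out$z))
  # imputed values track the predictor direction
  expect_gt(mean(out$z[miss][x[miss] > 1]), mean(out$z[miss][x[miss] < -1]))
})

test_that("VIF screening matches step-by-step manual recomputation", {
  set.seed(10)
  n <- 400
  ortho <- as.data.frame(qr.Q(qr(matrix(rnorm(n * 4), n))))
  scr <- vif_screen(ortho)
  expect_identical(scr$retained, names(ortho))
  expect_true(all(scr$vif < 1.05))   # near-orthogonal: VIF essentially 1
  # duplicated column: the later-listed member is removed
  dup <- data.frame(a = rnorm(n), c = rnorm(n))
  dup$b <- dup$a
  dup <- dup[c("a", "b", "c")]
  scr2 <- vif_screen(dup)
  expect_identical(scr2$dropped, "b")
  # six correlated columns against a manual iterative oracle
  z <- rnorm(n)
  x <- as.data.frame(sapply(1:6, function(i) z + rnorm(n, sd = 0.3 * i)))
  manual <- x
  dropped <- character(0)
  repeat {
    v <- vapply(seq_along(manual), function(j) {
      r2 <- summary(lm(manual[[j]] ~ ., data = manual[-j]))$r.squared
      1 / (1 - r2)
    }, 0)
    if (all(v <= 10)) break
    j <- max(which(v == max(v)))
    dropped <- c(dropped, names(manual)[j])
    manual <- manual[-j]
  }
  scr3 <- vif_screen(x, threshold = 10)
  expect_identical(scr3$dropped, dropped)
  expect_identical(scr3$retained, names(manual))
})

test_that("path model recovers planted odds ratios and respects the reference", {
  cfg <- sim_config(n_patients = 20000, baseline_ppd = 0.05, seed = 14)
  co <- generate_cohort(cfg)
  out <- generate_outcomes(cfg, co$truth)
  d <- data.frame(cluster = co$truth$latent_cluster, ppd = out$ppd,
                  age = co$patients$age)
  spec <- path_model_spec("age", reference_cluster = 3)
  fit <- fit_path_model(d, spec)
  expect_s3_class(fit, "path_model_fit")
  # OR = exp(coef) exactly
  expect_equal(fit$outcome_eq$or, exp(fit$outcome_eq$coef), tolerance = 1e-10)
  expect_true(all(fit$outcome_eq$p >= 0 & fit$outcome_eq$p <= 1))
  # no term for the reference cluster
  expect_false(any(grepl("cluster 3", fit$outcome_eq$term)))
  ors <- setNames(fit$outcome_eq$or, fit$outcome_eq$term)
  expect_lt(abs(ors[["cluster 1"]] - 6.3) / 6.3, 0.25)
  expect_lt(abs(ors[["cluster 2"]] - 2.43) / 2.43, 0.25)
  # cluster 1 skews older by construction: mediator effect positive
  med <- fit$mediator_eq
  expect_gt(med$or[med$cluster == "1" & med$term == "age"], 1)
  expect_error(fit_path_model(d, path_model_spec("age",
                                                 reference_cluster = 9)),
               "reference cluster")
})

test_that("equation-by-equation ML equals a direct joint-likelihood optimum", {
  set.seed(30)
  n <- 400
  x <- rnorm(n)
  cl <- vapply(seq_len(n), function(i) {
    eta <- c(0, 0.8 * x[i] - 0.2, -0.5 * x[i] + 0.1)   # ref, c1, c2
    sample(c(3, 1, 2), 1, prob = exp(eta) / sum(exp(eta)))
  }, 0)
  y <- runif(n) < plogis(-2 + 1.2 * (cl == 1) + 0.5 * (cl == 2))
  d <- data.frame(cluster = cl, ppd = y, x = x)
  fit <- fit_path_model(d, path_model_spec("x", reference_cluster = 3))
  nll <- function(par) {
    # par: a1,b1,a2,b2 (multinomial), g0,g1,g2 (outcome)
    e1 <- par[1] + par[2] * x; e2 <- par[3] + par[4] * x
    den <- 1 + exp(e1) + exp(e2)
    lm_ <- ifelse(cl == 1, e1, ifelse(cl == 2, e2, 0)) - log(den)
    eta <- par[5] + par[6] * (cl == 1) + par[7] * (cl == 2)
    lo <- ifelse(y, plogis(eta, log.p = TRUE),
                 plogis(-eta, log.p = TRUE))
    -sum(lm_ + lo)
  }
  joint <- optim(rep(0, 7), nll, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-12))
  med <- fit$mediator_eq
  expect_equal(med$coef[med$cluster == "1" & med$term == "x"], joint$par[2],
               tolerance = 1e-3)
  expect_equal(med$coef[med$cluster == "2" & med$term == "x"], joint$par[4],
               tolerance = 1e-3)
  oc <- fit$outcome_eq
  expect_equal(oc$coef[oc$term == "cluster 1"], joint$par[6],
               tolerance = 1e-3)
  expect_equal(oc$coef[oc$term == "cluster 2"], joint$par[7],
               tolerance = 1e-3)
})

test_that("Rubin pooling with one imputation equals the single fit", {
  set.seed(44)
  d <- data.frame(cluster = sample(1:3, 500, TRUE),
                  ppd = runif(500) < 0.1, x = rnorm(500))
  spec <- path_model_spec("x", reference_cluster = 3)
  f1 <- fit_path_model(d, spec)
  f2 <- fit_path_model(list(d), spec)
  expect_equal(f1$outcome_eq, f2$outcome_eq)
  # pooled variance grows with between-imputation spread
  d2 <- d; d2$x <- d$x + rnorm(500, 0, 0.3)
  f3 <- fit_path_model(list(d, d2), spec)
  expect_equal(f3$m, 2L)
  expect_true(all(f3$outcome_eq$se > 0))
})

test_that("separation in the outcome equation is reported as an error", {
  d <- data.frame(cluster = rep(1:3, each = 50),
                  ppd = rep(c(TRUE, FALSE, FALSE), each = 50))
  expect_error(
    fit_path_model(d, path_model_spec(character(0), reference_cluster = 3)),
    "separation")
})

test_that("group comparisons use the right test per variable type", {
  cl <- rep(1:3, times = c(1934, 4129, 2886))
  ppd <- c(rep(c(TRUE, FALSE), c(130, 1804)),
           rep(c(TRUE, FALSE), c(110, 4019)),
           rep(c(TRUE, FALSE), c(33, 2853)))
  set.seed(3)
  d <- data.frame(ppd = ifelse(ppd, "yes", "no"), age = rnorm(8949, 34, 4.6),
                  flat = 1.0, onelevel = "x")
  expect_warning(expect_warning(
    tab <- group_compare(d, cl), "constant"), "single-level")
  expect_setequal(tab$variable, c("ppd", "age"))
  expect_equal(tab$test[tab$variable == "ppd"], "chi-square")
  expect_equal(tab$test[tab$variable == "age"], "anova")
  # Pearson chi-square on the PPD x cluster table vs direct formula
  O <- rbind(c(130, 110, 33), c(1804, 4019, 2853))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  want <- sum((O - E)^2 / E)
  expect_equal(tab$statistic[tab$variable == "ppd"], want, tolerance = 1e-12)
  expect_equal(tab$df1[tab$variable == "ppd"], 2)
  # chi-square is invariant to permuting rows/columns of the table
  perm <- group_compare(d["ppd"], c(2, 3, 1)[cl])
  expect_equal(perm$statistic, want, tolerance = 1e-12)
  expect_error(group_compare(d, rep(1, 8949)), "two clusters")
})

test_that("unadjusted associations recover a planted log-linear effect", {
  set.seed(88)
  n <- 20000
  env <- data.frame(gini = rnorm(n, 0.4, 0.05), walk = rnorm(n))
  beta <- 0.4
  ppd <- runif(n) < plogis(-3 + beta * env$walk)
  tab <- unadjusted_env_associations(env, ppd, adjust = "gini")
  expect_equal(tab$variable, "walk")
  expect_lt(abs(tab$or - exp(beta)) / exp(beta), 0.15)
  # a variable identical to the adjustment is dropped by the guard
  env$gini2 <- env$gini
  tab2 <- unadjusted_env_associations(env, ppd, adjust = "gini")
  expect_false("gini2" %in% tab2$variable)
  expect_true("gini2" %in% attr(tab2, "dropped"))
})
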