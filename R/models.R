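#' Iterative variance-inflation-factor screen
#'
#' VIF_j = 1/(1 - R2_j) from regressing column j on the remaining columns.
#' While any VIF exceeds the threshold, the column with the largest VIF is
#' dropped (exactly collinear pairs give infinite VIFs; the later-listed
#' member goes first), then VIFs are recomputed.
#'
#' @param x data frame or matrix of numeric candidate covariates
#' @param threshold removal threshold (default 10)
#' @return list: `retained`, `dropped` (in removal order), `vif` (final
#'   VIFs of the retained set)
#' @export
vif_screen <- function(x, threshold = 10) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stopf("VIF screening needs at least two variables")
  if (nrow(x) <= ncol(x)) stopf("need more rows than variables")
  vif_of <- function(d) {
    vapply(seq_along(d), function(j) {
      fit <- stats::lm.fit(cbind(1, as.matrix(d[-j])), d[[j]])
      rss <- sum(fit$residuals^2)
      tss <- sum((d[[j]] - mean(d[[j]]))^2)
      if (tss == 0) return(Inf)
      r2 <- 1 - rss / tss
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 0)
  }
  dropped <- character(0)
  repeat {
    v <- vif_of(x)
    names(v) <- names(x)
    if (all(v <= threshold) || ncol(x) == 1) break
    worst <- max(v)
    # ties (incl. Inf/Inf): drop the later-listed member
    j <- max(which(v == worst))
    dropped <- c(dropped, names(x)[j])
    x <- x[-j]
  }
  v <- if (ncol(x) >= 2) {
    vv <- vif_of(x); names(vv) <- names(x); vv
  } else setNames(1, names(x))
  list(retained = names(x), dropped = dropped, vif = v)
}

#' Specification of the two-equation path model
#'
#' Mirrors the recursive mediation structure: a multinomial logistic
#' equation for care-pattern cluster membership on built-environment and
#' adjustment covariates, and a binary logistic equation for PPD on the
#' cluster indicators, with the reference cluster absorbed in the
#' intercepts.
#'
#' @param mediator_covariates covariate column names for the cluster
#'   equation
#' @param reference_cluster reference cluster label (default `3`)
#' @param cluster_col,outcome_col column names of cluster labels and the
#'   binary outcome
#' @param vif_threshold multicollinearity screen threshold
#' @param alpha significance threshold for flagging
#' @param n_imputations imputations when the data carry missing cells
#' @return object of class `path_model_spec`
#' @export
path_model_spec <- function(mediator_covariates,
                            reference_cluster = 3,
                            cluster_col = "cluster",
                            outcome_col = "ppd",
                            vif_threshold = 10,
                            alpha = 0.05,
                            n_imputations = 5) {
  if (vif_threshold <= 1) stopf("vif_threshold must exceed 1")
  structure(list(mediator_covariates = mediator_covariates,
                 reference_cluster = reference_cluster,
                 cluster_col = cluster_col, outcome_col = outcome_col,
                 vif_threshold = vif_threshold, alpha = alpha,
                 n_imputations = n_imputations),
            class = "path_model_spec")
}

# Wald z test and OR summary from coefficients and their SEs
wald_table <- function(est, se, level = 0.95) {
  z <- est / se
  q <- qnorm(1 - (1 - level) / 2)
  data.frame(coef = est, se = se, or = exp(est),
             ci_lo = exp(est - q * se), ci_hi = exp(est + q * se),
             p = 2 * pnorm(-abs(z)))
}

fit_path_model_once <- function(data, spec) {
  cl <- data[[spec$cluster_col]]
  if (!spec$reference_cluster %in% cl)
    stopf("reference cluster %s not observed", spec$reference_cluster)
  data$.cluster <- stats::relevel(factor(cl),
                                  ref = as.character(spec$reference_cluster))
  # outcome equation: PPD on cluster indicators (reference absorbed)
  ofit <- suppressWarnings(
    glm(stats::reformulate(".cluster", response = spec$outcome_col),
        family = binomial(), data = data))
  oco <- summary(ofit)$coefficients
  keep <- grep("^\\.cluster", rownames(oco))
  # separation guard: enormous SEs on an indicator signal separation
  if (any(oco[keep, 2] > 50))
    stopf("separation detected in outcome equation (term cluster %s)",
          sub("^\\.cluster", "", rownames(oco)[keep][which.max(oco[keep, 2])]))
  if (!ofit$converged) stopf("outcome equation did not converge")
  outcome_eq <- cbind(
    data.frame(term = paste0("cluster ",
                             sub("^\\.cluster", "", rownames(oco)[keep]))),
    wald_table(oco[keep, 1], oco[keep, 2]))

  mediator_eq <- NULL
  if (length(spec$mediator_covariates)) {
    f <- stats::reformulate(spec$mediator_covariates,
                            response = ".cluster")
    mfit <- suppressMessages(
      nnet::multinom(f, data = data, trace = FALSE, maxit = 500))
    if (mfit$convergence != 0) stopf("mediator equation did not converge")
    co <- coef(mfit); se <- summary(mfit)$standard.errors
    if (is.null(dim(co))) {  # two clusters: coerce to matrix
      co <- matrix(co, nrow = 1,
                   dimnames = list(levels(data$.cluster)[2], names(co)))
      se <- matrix(se, nrow = 1, dimnames = dimnames(co))
    }
    rows <- list()
    for (g in rownames(co)) {
      terms <- setdiff(colnames(co), "(Intercept)")
      rows[[g]] <- cbind(data.frame(cluster = g, term = terms),
                         wald_table(co[g, terms], se[g, terms]))
    }
    mediator_eq <- do.call(rbind, c(rows, make.row.names = FALSE))
  }
  list(outcome_eq = outcome_eq, mediator_eq = mediator_eq,
       n_used = nrow(data))
}

# Rubin's rules over a list of per-imputation Wald tables
rubin_pool <- function(tables) {
  m <- length(tables)
  if (m == 1) return(tables[[1]])
  base <- tables[[1]]
  est <- sapply(tables, function(t) t$coef)
  se <- sapply(tables, function(t) t$se)
  if (is.null(dim(est))) { est <- matrix(est, nrow = 1); se <- matrix(se, nrow = 1) }
  qbar <- rowMeans(est)
  ubar <- rowMeans(se^2)
  b <- apply(est, 1, var)
  tvar <- ubar + (1 + 1 / m) * b
  keep <- setdiff(names(base), c("coef", "se", "or", "ci_lo", "ci_hi", "p"))
  cbind(base[keep], wald_table(qbar, sqrt(tvar)))
}

#' Fit the recursive two-equation path model
#'
#' Equation 1 (mediator): multinomial logistic regression of cluster
#' membership (reference cluster absorbed) on the mediator covariates.
#' Equation 2 (outcome): binary logistic regression of PPD on the cluster
#' indicators. For a fully observed recursive system the joint likelihood
#' factorises, so equation-by-equation maximum likelihood is the joint
#' MLE. Given a list of imputed datasets, per-imputation fits are pooled
#' by Rubin's rules. Odds ratios are exp(coefficients) with Wald tests.
#'
#' @param data a data frame, or a list of completed data frames from
#'   [chained_imputation()]
#' @param spec a [path_model_spec()]
#' @return object of class `path_model_fit`: `outcome_eq`, `mediator_eq`
#'   data frames (term, coef, se, or, ci_lo, ci_hi, p), `n_used`, `m`
#' @export
fit_path_model <- function(data, spec) {
  stopifnot(inherits(spec, "path_model_spec"))
  datasets <- if (is.data.frame(data)) list(data) else data
  fits <- lapply(datasets, fit_path_model_once, spec = spec)
  out <- list(
    outcome_eq = rubin_pool(lapply(fits, `[[`, "outcome_eq")),
    mediator_eq = if (!is.null(fits[[1]]$mediator_eq))
      rubin_pool(lapply(fits, `[[`, "mediator_eq")),
    n_used = fits[[1]]$n_used, m = length(datasets),
    reference_cluster = spec$reference_cluster)
  class(out) <- "path_model_fit"
  out
}

#' @export
print.path_model_fit <- function(x, ...) {
  cat(sprintf("Recursive path model (n = %d, %d imputation%s; reference cluster %s)\n",
              x$n_used, x$m, if (x$m > 1) "s" else "", x$reference_cluster))
  cat("Outcome equation (PPD ~ cluster indicators):\n")
  print(x$outcome_eq[c("term", "or", "ci_lo", "ci_hi", "p")], digits = 3,
        row.names = FALSE)
  if (!is.null(x$mediator_eq)) {
    cat("Mediator equation (cluster ~ covariates), OR per cluster vs reference:\n")
    print(x$mediator_eq[c("cluster", "term", "or", "p")], digits = 3,
          row.names = FALSE)
  }
  invisible(x)
}

#' Compare variables across clusters
#'
#' Pearson chi-square tests (no continuity correction) for categorical
#' variables and one-way ANOVA F tests for continuous ones. Variables with
#' a single observed level or zero variance are skipped with a warning.
#'
#' @param table data frame of variables to compare
#' @param cluster_labels cluster membership, one per row
#' @param alpha flag threshold
#' @return data frame: variable, test, statistic, df1, df2, p, significant
#' @export
group_compare <- function(table, cluster_labels, alpha = 0.05) {
  cl <- factor(cluster_labels)
  if (nlevels(cl) < 2) stopf("need at least two clusters")
  if (any(table(cl) == 0)) stopf("every cluster must be non-empty")
  rows <- list()
  for (v in names(table)) {
    x <- table[[v]]
    if (is.numeric(x)) {
      if (length(unique(x[!is.na(x)])) < 2 || var(x, na.rm = TRUE) == 0) {
        warning(sprintf("skipping constant continuous variable %s", v))
        next
      }
      fit <- anova(lm(x ~ cl))
      rows[[v]] <- data.frame(variable = v, test = "anova",
                              statistic = fit$`F value`[1],
                              df1 = fit$Df[1], df2 = fit$Df[2],
                              p = fit$`Pr(>F)`[1])
    } else {
      x <- factor(x)
      if (nlevels(droplevels(x[!is.na(x)])) < 2) {
        warning(sprintf("skipping single-level categorical variable %s", v))
        next
      }
      tt <- table(x, cl)
      ct <- suppressWarnings(chisq.test(tt, correct = FALSE))
      rows[[v]] <- data.frame(variable = v, test = "chi-square",
                              statistic = unname(ct$statistic),
                              df1 = unname(ct$parameter), df2 = NA_integer_,
                              p = ct$p.value)
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(out)) return(data.frame(variable = character(0)))
  out$significant <- out$p < alpha
  out
}

#' Unadjusted built-environment / PPD associations
#'
#' One logistic model per built-environment variable, adjusted for the
#' tract GINI index. Variables (numerically) collinear with GINI are
#' dropped by a guard rather than fitted.
#'
#' @param built_env feature data frame containing `gini`
#' @param ppd logical outcome vector aligned with rows
#' @param adjust name of the adjustment column
#' @param variables variables to test; default all numeric columns except
#'   the adjustment and id columns
#' @return data frame: variable, or, ci_lo, ci_hi, p, plus a `dropped`
#'   attribute naming collinear variables
#' @export
unadjusted_env_associations <- function(built_env, ppd, adjust = "gini",
                                        variables = NULL) {
  if (!adjust %in% names(built_env))
    stopf("adjustment column %s not found", adjust)
  if (is.null(variables)) {
    variables <- names(built_env)[vapply(built_env, is.numeric, TRUE)]
    variables <- setdiff(variables, c(adjust, "patient_id"))
  }
  rows <- list(); droppedv <- character(0)
  for (v in variables) {
    x <- built_env[[v]]
    ok <- !is.na(x) & !is.na(built_env[[adjust]]) & !is.na(ppd)
    if (var(x[ok]) == 0 ||
        abs(stats::cor(x[ok], built_env[[adjust]][ok])) > 1 - 1e-10) {
      droppedv <- c(droppedv, v)
      next
    }
    d <- data.frame(y = ppd[ok], x = as.numeric(scale(x[ok], scale = FALSE)),
                    g = built_env[[adjust]][ok])
    fit <- glm(y ~ x + g, family = binomial(), data = d)
    co <- summary(fit)$coefficients
    rows[[v]] <- cbind(data.frame(variable = v),
                       wald_table(co["x", 1], co["x", 2]))
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(out)) out <- data.frame(variable = character(0))
  attr(out, "dropped") <- droppedv
  out
}
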