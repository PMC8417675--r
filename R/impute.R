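#' Multivariate imputation by chained equations
#'
#' Fills missing cells column-by-column with conditional-model draws:
#' numeric columns by a linear model on all other columns with a residual
#' noise draw, binary (logical or two-level factor/character) columns by a
#' logistic model draw. Missing cells are initialised by sampling observed
#' values, then the chain sweeps the incomplete columns `n_iter` times;
#' `m` independent chains give `m` completed copies. Observed cells are
#' never altered.
#'
#' @param table data frame; missingness allowed in any column that is
#'   numeric or binary
#' @param m number of completed datasets
#' @param n_iter chained-equation sweeps per dataset
#' @param seed integer seed (one substream per imputation)
#' @return list of `m` completed data frames
#' @export
chained_imputation <- function(table, m = 5, n_iter = 10, seed = 1L) {
  if (m < 1) stopf("m must be at least 1")
  miss_cols <- names(table)[vapply(table, anyNA, TRUE)]
  for (v in miss_cols) {
    if (all(is.na(table[[v]])))
      stopf("column %s is entirely missing and cannot be imputed", v)
  }
  if (!length(miss_cols)) return(replicate(m, table, simplify = FALSE))

  is_binary <- function(x) {
    u <- unique(x[!is.na(x)])
    is.logical(x) || length(u) == 2
  }
  # predictors: all other columns, model-matrix expanded
  predict_frame <- function(dat, v) {
    others <- setdiff(names(dat), v)
    stats::model.matrix(~ ., data = dat[others])[, -1, drop = FALSE]
  }

  impute_once <- function(sub_seed) {
    dat <- table
    na_idx <- lapply(miss_cols, function(v) which(is.na(table[[v]])))
    names(na_idx) <- miss_cols
    set.seed(sub_seed)
    for (v in miss_cols) {
      obs <- table[[v]][!is.na(table[[v]])]
      dat[[v]][na_idx[[v]]] <- sample(obs, length(na_idx[[v]]),
                                      replace = TRUE)
    }
    for (iter in seq_len(n_iter)) {
      for (v in miss_cols) {
        idx <- na_idx[[v]]
        X <- predict_frame(dat, v)
        obs_rows <- setdiff(seq_len(nrow(dat)), idx)
        if (is_binary(table[[v]])) {
          y <- dat[[v]]
          lev <- sort(unique(as.character(y[obs_rows])))
          yb <- as.integer(as.character(y[obs_rows]) == lev[length(lev)])
          fit <- suppressWarnings(
            stats::glm.fit(cbind(1, X[obs_rows, , drop = FALSE]), yb,
                           family = binomial()))
          beta <- coef(fit)
          beta[is.na(beta)] <- 0
          eta <- cbind(1, X[idx, , drop = FALSE]) %*% beta
          draw <- runif(length(idx)) < plogis(as.numeric(eta))
          if (is.logical(table[[v]])) {
            dat[[v]][idx] <- ifelse(draw, lev[length(lev)] == "TRUE",
                                    lev[1] == "TRUE")
          } else {
            dat[[v]][idx] <- ifelse(draw, lev[length(lev)], lev[1])
          }
        } else {
          yb <- dat[[v]][obs_rows]
          Xo <- cbind(1, X[obs_rows, , drop = FALSE])
          fit <- stats::lm.fit(Xo, yb)
          beta <- fit$coefficients
          beta[is.na(beta)] <- 0
          sigma <- sqrt(sum(fit$residuals^2) /
                          max(length(obs_rows) - ncol(Xo), 1))
          mu <- cbind(1, X[idx, , drop = FALSE]) %*% beta
          dat[[v]][idx] <- rnorm(length(idx), as.numeric(mu), sigma)
        }
      }
    }
    dat
  }
  lapply(seq_len(m), function(j)
    impute_once(derive_seed(seed, paste0("imputation_", j))))
}
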