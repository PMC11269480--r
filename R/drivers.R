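#' Pearson correlation with two-sided test
#'
#' Pairwise-deletes missing values and returns the sample correlation with
#' its two-sided t-based p-value.
#'
#' @param x,y Numeric vectors of equal length; at least 3 complete pairs and
#'   neither vector constant after deletion.
#' @return A one-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) {
    abort("need at least 3 complete pairs.", class = "enzlim_domain_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    bad <- if (sd(x) == 0) "x" else "y"
    abort(paste0("variable '", bad, "' is constant; correlation undefined."),
          class = "enzlim_domain_error")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Correlate a response against a set of candidate drivers
#'
#' Screens abiotic (or biotic) drivers by Pearson correlation, one row per
#' predictor, using pairwise deletion. Constant predictors are reported with
#' `NA` rather than aborting the screen.
#'
#' @param data A data frame.
#' @param response Name of the response column (string or bare name).
#' @param predictors Character vector of predictor column names; default is
#'   every other numeric column.
#' @return A tibble `predictor`, `r`, `p_value`, `n`, sorted by `p_value`.
#' @export
correlate_drivers <- function(data, response, predictors = NULL) {
  response <- as_name(enquo(response))
  if (!response %in% names(data)) {
    abort(paste0("response column '", response, "' not found."),
          class = "enzlim_schema_error")
  }
  if (is.null(predictors)) {
    num <- names(data)[vapply(data, is.numeric, logical(1))]
    predictors <- setdiff(num, response)
  }
  y <- data[[response]]
  purrr::map_dfr(predictors, function(p) {
    res <- tryCatch(pearson_cor(data[[p]], y),
                    enzlim_domain_error = function(e) {
                      tibble::tibble(r = NA_real_, p_value = NA_real_,
                                     n = sum(stats::complete.cases(data[[p]], y)))
                    })
    dplyr::mutate(res, predictor = p, .before = 1)
  }) |>
    dplyr::arrange(.data$p_value)
}

#' Ordinary least squares with adjusted R-squared
#'
#' Thin wrapper around [stats::lm()] that validates the design (full rank,
#' enough residual degrees of freedom), and carries the quantities the
#' driver screen reports: coefficients with p-values, R-squared, adjusted
#' R-squared `1 - (1 - R2)(n - 1)/(n - p - 1)`, and Gaussian AIC.
#'
#' @param formula Model formula.
#' @param data Data frame; rows with missing values in model variables are
#'   dropped (listwise).
#' @return An object of class `enzlim_ols`; see [tidy()] and [glance()]
#'   methods.
#' @examples
#' d <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
#' glance(fit_ols(y ~ x, d))
#' @export
fit_ols <- function(formula, data) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  fit <- lm(formula, data = mf)
  if (anyNA(coef(fit))) {
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
          class = "enzlim_domain_error")
  }
  n <- nrow(mf)
  p <- length(coef(fit)) - attr(terms(fit), "intercept")
  if (n <= p + 1) {
    abort("need n > number of predictors + 1.", class = "enzlim_domain_error")
  }
  sm <- summary(fit)
  structure(
    list(
      fit = fit,
      formula = formula,
      predictors = attr(terms(fit), "term.labels"),
      r2 = sm$r.squared,
      adj_r2 = sm$adj.r.squared,
      aic = stats::AIC(fit),
      n = n
    ),
    class = "enzlim_ols"
  )
}

#' @export
print.enzlim_ols <- function(x, ...) {
  cat("<enzlim_ols> ", deparse(x$formula), "\n  n = ", x$n,
      ", R2 = ", signif(x$r2, 4), ", adj R2 = ", signif(x$adj_r2, 4),
      ", AIC = ", signif(x$aic, 6), "\n", sep = "")
  invisible(x)
}

#' Tidy an OLS driver fit
#' @param x An `enzlim_ols` object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @method tidy enzlim_ols
#' @export
tidy.enzlim_ols <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = cf[, 1],
    std_error = cf[, 2],
    statistic = cf[, 3],
    p_value = cf[, 4]
  )
}

#' One-row summary of an OLS driver fit
#' @param x An `enzlim_ols` object.
#' @param ... Unused.
#' @return A tibble with `r2`, `adj_r2`, `aic`, `n`, `n_predictors`.
#' @method glance enzlim_ols
#' @export
glance.enzlim_ols <- function(x, ...) {
  tibble::tibble(r2 = x$r2, adj_r2 = x$adj_r2, aic = x$aic, n = x$n,
                 n_predictors = length(x$predictors))
}

#' One-way analysis of variance
#'
#' Classic between/within mean-square F test for differences among group
#' means (e.g. the two lake regions). With two groups, F equals the square
#' of the pooled two-sample t statistic.
#'
#' @param data A data frame, or a list of numeric vectors (one per group).
#' @param response,group Column names (bare or string) when `data` is a data
#'   frame.
#' @return A tibble `f_stat`, `df_between`, `df_within`, `p_value`.
#' @export
anova_oneway <- function(data, response = NULL, group = NULL) {
  if (is.data.frame(data)) {
    response <- as_name(enquo(response))
    group <- as_name(enquo(group))
    values <- data[[response]]
    g <- as.factor(data[[group]])
    groups <- split(values, g)
  } else {
    groups <- data
  }
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    abort("need >= 2 groups with >= 2 values each.",
          class = "enzlim_domain_error")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (sum(tapply(y, g, var) * (lengths(groups) - 1)) <= 0) {
    abort("zero within-group variance; F undefined.",
          class = "enzlim_domain_error")
  }
  ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
  tibble::tibble(
    f_stat = unname(ow$statistic),
    df_between = unname(ow$parameter[1]),
    df_within = unname(ow$parameter[2]),
    p_value = ow$p.value
  )
}

lower_tri <- function(m) m[lower.tri(m)]

#' Permutation Mantel test between two distance matrices
#'
#' Correlates the lower triangles of two distance matrices and assesses
#' significance by jointly permuting the rows and columns of the second
#' matrix. The one-tailed (greater) p-value uses the add-one rule
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)`.
#'
#' @param d1,d2 [stats::dist] objects or square symmetric matrices over the
#'   same samples, in the same order (checked via labels when present).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed for reproducible permutations.
#' @return An object of class `enzlim_mantel` with fields `r`, `p_value`,
#'   `n_perm`, `n`; see [glance()].
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL) {
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2)) || nrow(m1) != ncol(m1)) {
    abort("`d1` and `d2` must be square matrices of the same size.",
          class = "enzlim_schema_error")
  }
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    abort("sample ids of `d1` and `d2` do not match.",
          class = "enzlim_schema_error")
  }
  n <- nrow(m1)
  if (n < 4) abort("need at least 4 samples.", class = "enzlim_domain_error")
  if (n_perm < 1) abort("`n_perm` must be >= 1.",
                        class = "enzlim_domain_error")
  v1 <- lower_tri(m1)
  r_obs <- cor(v1, lower_tri(m2))
  r_perm <- with_opt_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      cor(v1, lower_tri(m2[p, p]))
    }, numeric(1))
  })
  structure(
    list(
      r = r_obs,
      p_value = (1 + sum(r_perm >= r_obs)) / (1 + n_perm),
      n_perm = n_perm,
      n = n
    ),
    class = "enzlim_mantel"
  )
}

#' @export
print.enzlim_mantel <- function(x, ...) {
  cat("<enzlim_mantel> r = ", signif(x$r, 4), ", p = ", signif(x$p_value, 4),
      " (", x$n_perm, " permutations, n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' One-row summary of a Mantel test
#' @param x An `enzlim_mantel` object.
#' @param ... Unused.
#' @return A tibble with `r`, `p_value`, `n_perm`, `n`.
#' @method glance enzlim_mantel
#' @export
glance.enzlim_mantel <- function(x, ...) {
  tibble::tibble(r = x$r, p_value = x$p_value, n_perm = x$n_perm, n = x$n)
}

#' Forward stepwise model selection by AIC
#'
#' Greedy forward selection starting from the intercept-only model: at each
#' step the candidate whose addition lowers AIC the most enters (ties broken
#' by candidate order); selection stops when no addition lowers AIC.
#'
#' @param data A data frame; rows with missing values in the response or any
#'   candidate are dropped so AIC is comparable across steps.
#' @param response Response column name (bare or string).
#' @param candidates Character vector of candidate predictor columns;
#'   default is every other numeric column.
#' @return An `enzlim_ols` fit of the selected model (possibly
#'   intercept-only, with zero predictors).
#' @export
forward_stepwise <- function(data, response, candidates = NULL) {
  response <- as_name(enquo(response))
  if (is.null(candidates)) {
    num <- names(data)[vapply(data, is.numeric, logical(1))]
    candidates <- setdiff(num, response)
  }
  if (length(candidates) < 1) {
    abort("need at least one candidate predictor.",
          class = "enzlim_domain_error")
  }
  d <- data[stats::complete.cases(data[, c(response, candidates)]),
            c(response, candidates)]
  null_fit <- lm(as.formula(paste(response, "~ 1")), data = d)
  scope <- as.formula(paste("~", paste(candidates, collapse = " + ")))
  sel <- step(null_fit, scope = list(lower = ~1, upper = scope),
              direction = "forward", trace = 0, k = 2)
  out <- fit_ols(stats::formula(sel), data = d)
  out$candidates <- candidates
  out
}

#' Model-agnostic permutation importance
#'
#' Quantifies each predictor's contribution as the mean increase in the
#' model's mean squared prediction error after randomly permuting that
#' predictor's column, averaged over `n_rep` shuffles — the permute-and-
#' measure notion of importance used for "relative contribution" rankings.
#' Importances are also normalised to percentages of their (positive) sum.
#'
#' @param fit An `enzlim_ols` model.
#' @param data Data used for evaluation; defaults to the fitting data.
#' @param n_rep Number of permutations per predictor (default 100).
#' @param seed Optional integer seed.
#' @param predictors Predictors to evaluate; default all model predictors.
#'   Requesting a predictor not in the model is an error.
#' @return A tibble `term`, `mse_increase`, `importance_pct`, sorted by
#'   importance. Negative chance-level increases are floored at zero before
#'   normalisation.
#' @export
permutation_importance <- function(fit, data = NULL, n_rep = 100, seed = NULL,
                                   predictors = NULL) {
  if (!inherits(fit, "enzlim_ols")) {
    abort("`fit` must come from fit_ols() or forward_stepwise().",
          class = "enzlim_schema_error")
  }
  if (n_rep < 1) abort("`n_rep` must be >= 1.", class = "enzlim_domain_error")
  predictors <- predictors %||% fit$predictors
  missing <- setdiff(predictors, fit$predictors)
  if (length(missing) > 0) {
    abort(paste0("predictor(s) not in the model: ",
                 paste(missing, collapse = ", ")),
          class = "enzlim_domain_error")
  }
  if (length(predictors) == 0) {
    return(tibble::tibble(term = character(), mse_increase = numeric(),
                          importance_pct = numeric()))
  }
  d <- if (is.null(data)) stats::model.frame(fit$fit) else
    data[stats::complete.cases(data[, all.vars(fit$formula)]), ]
  yname <- all.vars(fit$formula)[1]
  y <- d[[yname]]
  mse_base <- mean((y - predict(fit$fit, newdata = d))^2)
  inc <- with_opt_seed(seed, {
    vapply(predictors, function(p) {
      mean(vapply(seq_len(n_rep), function(i) {
        dp <- d
        dp[[p]] <- sample(dp[[p]])
        mean((y - predict(fit$fit, newdata = dp))^2)
      }, numeric(1))) - mse_base
    }, numeric(1))
  })
  pos <- pmax(inc, 0)
  pct <- if (sum(pos) > 0) 100 * pos / sum(pos) else rep(0, length(pos))
  tibble::tibble(term = predictors, mse_increase = unname(inc),
                 importance_pct = unname(pct)) |>
    dplyr::arrange(dplyr::desc(.data$importance_pct))
}
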