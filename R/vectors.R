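#' Vector length of enzymatic investment (microbial C limitation)
#'
#' The vector length of the investment point `(x, y)` — where
#' `x = C/(C+P)` and `y = C/(C+N)` — is the Euclidean norm
#' `VL = sqrt(x^2 + y^2)`. Longer vectors indicate a larger share of
#' enzymatic effort devoted to carbon acquisition, i.e. stronger relative
#' microbial carbon limitation.
#'
#' @param x,y Numeric vectors of investment proportions in `[0, 1]`
#'   (see [investment_xy()]); `NA` propagates.
#' @return Numeric vector of lengths in `[0, sqrt(2)]`.
#' @examples
#' vector_length(0.5, 0.75) # 0.9014
#' @export
vector_length <- function(x, y) {
  check_proportion(x, "x")
  check_proportion(y, "y")
  sqrt(x^2 + y^2)
}

#' Vector angle of enzymatic investment (microbial N vs P limitation)
#'
#' The angle of the investment point `(x, y)` from the x-axis, in degrees:
#' `VA = degrees(arctan(y / x))` on the first quadrant, with `VA = 90` when
#' `x = 0, y > 0`. Angles above 45 degrees indicate relative phosphorus
#' limitation (P-acquisition investment exceeds N-acquisition investment);
#' angles below 45 degrees indicate nitrogen limitation.
#'
#' @inheritParams vector_length
#' @return Numeric vector of angles in degrees, in `[0, 90]`. The origin
#'   `x = y = 0` has no direction: it yields `NA` with a warning and such
#'   samples are excluded from vector statistics.
#' @examples
#' vector_angle(0.5, 0.5)  # 45 exactly
#' vector_angle(0.5, 0.75) # 56.31
#' @export
vector_angle <- function(x, y) {
  check_proportion(x, "x")
  check_proportion(y, "y")
  k <- max(length(x), length(y))
  x <- rep_len(x, k)
  y <- rep_len(y, k)
  ang <- atan2(y, x) * 180 / pi
  undef <- !is.na(x) & !is.na(y) & x == 0 & y == 0
  if (any(undef)) {
    warn(paste0(sum(undef), " sample(s) at the origin have no defined angle."))
    ang[undef] <- NA_real_
  }
  ang
}

#' Classify nutrient limitation from the vector angle
#'
#' Applies the angle threshold rule: angles above the threshold (default 45
#' degrees, the equal-investment diagonal) are phosphorus-limited, angles
#' below it nitrogen-limited. Angles within `1e-9` of the threshold are
#' called `BALANCED` rather than forced to either side.
#'
#' @param angle_deg Numeric vector of vector angles in degrees.
#' @param threshold Classification threshold in degrees, strictly between 0
#'   and 90.
#' @return A factor with levels `N_LIMITED`, `BALANCED`, `P_LIMITED`.
#' @examples
#' classify_limitation(c(56.31, 33.69, 45))
#' @export
classify_limitation <- function(angle_deg, threshold = 45) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 90) {
    abort("`threshold` must be a single angle strictly between 0 and 90.",
          class = "enzlim_domain_error")
  }
  cls <- rep(NA_character_, length(angle_deg))
  tie <- !is.na(angle_deg) & abs(angle_deg - threshold) <= 1e-9
  cls[tie] <- "BALANCED"
  cls[!is.na(angle_deg) & !tie & angle_deg > threshold] <- "P_LIMITED"
  cls[!is.na(angle_deg) & !tie & angle_deg < threshold] <- "N_LIMITED"
  factor(cls, levels = c("N_LIMITED", "BALANCED", "P_LIMITED"))
}

check_proportion <- function(v, name, call = rlang::caller_env()) {
  if (!is.numeric(v)) {
    abort(paste0("`", name, "` must be numeric."),
          class = "enzlim_domain_error", call = call)
  }
  bad <- !is.na(v) & (v < 0 | v > 1)
  if (any(bad)) {
    abort(paste0("`", name, "` must be a proportion in [0, 1]."),
          class = "enzlim_domain_error", call = call)
  }
  invisible(v)
}

#' Per-sample vector analysis of a cohort
#'
#' Runs the full enzymatic-stoichiometry vector analysis on a cohort table:
#' pools activities ([add_enzyme_acquisitions()]), computes vector length
#' (carbon limitation) and angle (N vs P limitation) per sample, and
#' classifies each sample against the angle threshold.
#'
#' @inheritParams add_enzyme_acquisitions
#' @param threshold Angle threshold in degrees passed to
#'   [classify_limitation()].
#' @return A tibble of class `enzlim_vectors` with columns `sample_id`
#'   (plus `region` if present), `x`, `y`, `length`, `angle_deg`, `class`.
#'   Use [limitation_summary()] for the cohort summary.
#' @examples
#' tbl <- tibble::tibble(bg = 2, cbh = 1, nag = 0.5, lap = 0.5, ap = 3)
#' limitation_table(tbl)
#' @export
limitation_table <- function(data, ln_transform = FALSE, threshold = 45) {
  data <- add_enzyme_acquisitions(data, ln_transform = ln_transform)
  out <- dplyr::transmute(
    data,
    sample_id = .data$sample_id,
    x = .data$x, y = .data$y,
    length = vector_length(.data$x, .data$y),
    angle_deg = suppressWarnings(vector_angle(.data$x, .data$y)),
    class = classify_limitation(.data$angle_deg, threshold = threshold)
  )
  origin <- !is.na(out$x) & !is.na(out$y) & out$x == 0 & out$y == 0
  if (any(origin)) {
    inform(paste0(sum(origin),
                  " sample(s) with zero C acquisition excluded (no angle)."))
  }
  if ("region" %in% names(data)) {
    out <- dplyr::mutate(out, region = data$region, .after = "sample_id")
  }
  structure(out, class = c("enzlim_vectors", class(out)),
            threshold = threshold, ln_transform = ln_transform)
}

#' Cohort summary of the vector analysis
#'
#' Summarises a [limitation_table()] result: the phosphorus-limited fraction
#' (samples above the 1:1 enzymatic C:N vs C:P line, i.e. angle over the
#' threshold), mean vector length and angle, and the OLS regression of angle
#' on length (slope and adjusted R-squared) that describes how nutrient
#' limitation trades off against carbon limitation across the cohort.
#'
#' @param vectors A tibble from [limitation_table()].
#' @return A one-row tibble: `n`, `n_defined`, `p_limited_fraction`,
#'   `mean_length`, `mean_angle`, `slope_va_on_vl`, `adj_r2_va_on_vl`
#'   (regression fields are `NA` with fewer than 3 defined samples or a
#'   degenerate regressor).
#' @export
limitation_summary <- function(vectors) {
  if (!all(c("length", "angle_deg", "class") %in% names(vectors))) {
    abort("`vectors` must come from limitation_table().",
          class = "enzlim_schema_error")
  }
  ok <- !is.na(vectors$angle_deg)
  if (sum(ok) == 0) {
    abort("no samples with a defined vector.", class = "enzlim_domain_error")
  }
  v <- vectors[ok, ]
  slope <- adj_r2 <- NA_real_
  if (nrow(v) >= 3 && sd(v$length) > 0 && sd(v$angle_deg) > 0) {
    fit <- fit_ols(angle_deg ~ length, data = v)
    slope <- unname(coef(fit$fit)["length"])
    adj_r2 <- fit$adj_r2
  }
  tibble::tibble(
    n = nrow(vectors),
    n_defined = nrow(v),
    p_limited_fraction = mean(v$class == "P_LIMITED"),
    mean_length = mean(v$length),
    mean_angle = mean(v$angle_deg),
    slope_va_on_vl = slope,
    adj_r2_va_on_vl = adj_r2
  )
}
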