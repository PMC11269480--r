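#' Pool enzyme activities into C, N and P acquisition sums
#'
#' Extracellular enzyme activities are grouped by the resource they liberate:
#' beta-glucosidase (BG) and cellobiohydrolase (CBH) acquire carbon,
#' N-acetyl-glucosaminidase (NAG) and leucine aminopeptidase (LAP) acquire
#' nitrogen, and phosphatase (AP) acquires phosphorus. This adds the pooled
#' sums `c_acq = bg + cbh`, `n_acq = nag + lap`, `p_acq = ap` and the relative
#' investment proportions `x = C/(C+P)` and `y = C/(C+N)` used by the vector
#' analysis of [limitation_table()].
#'
#' @param data A data frame with numeric columns `bg`, `cbh`, `nag`, `lap`,
#'   `ap` (activities per g dry sediment per h; only ratios matter, so any
#'   consistent unit works). A `sample_id` column is added if absent.
#' @param ln_transform If `TRUE`, each pooled sum is natural-log transformed
#'   before the proportions are formed (`x = ln C / (ln C + ln P)`); all three
#'   sums must then be positive for a sample to have defined proportions.
#'   The default works on the raw sums, which makes `x` and `y` invariant to
#'   uniform rescaling of all five activities.
#' @return The input as a tibble with columns `c_acq`, `n_acq`, `p_acq`, `x`,
#'   `y` appended. Samples whose proportions are undefined (zero denominators,
#'   or non-positive logs under `ln_transform`) get `NA` in `x`/`y` and a
#'   message reports how many were excluded.
#' @seealso [stoich_summary()], [limitation_table()]
#' @examples
#' tbl <- tibble::tibble(bg = 2, cbh = 1, nag = 0.5, lap = 0.5, ap = 3)
#' add_enzyme_acquisitions(tbl)
#' @export
add_enzyme_acquisitions <- function(data, ln_transform = FALSE) {
  check_enzyme_columns(data)
  data <- ensure_sample_id(tibble::as_tibble(data))
  data <- dplyr::mutate(
    data,
    c_acq = .data$bg + .data$cbh,
    n_acq = .data$nag + .data$lap,
    p_acq = .data$ap
  )
  xy <- investment_xy(data$c_acq, data$n_acq, data$p_acq,
                      ln_transform = ln_transform)
  data$x <- xy$x
  data$y <- xy$y
  n_undef <- sum(!is.na(data$c_acq) & is.na(data$x))
  if (n_undef > 0) {
    inform(paste0(n_undef, " sample(s) have undefined investment proportions",
                  " and are excluded from vector statistics."))
  }
  data
}

#' Relative enzymatic investment proportions
#'
#' Computes the comparative carbon-versus-phosphorus investment
#' `x = C/(C+P)` and carbon-versus-nitrogen investment `y = C/(C+N)` from
#' pooled acquisition activities. These are the coordinates whose vector
#' length and angle quantify microbial metabolic limitation.
#'
#' @param c_acq,n_acq,p_acq Numeric vectors of pooled C-, N- and
#'   P-acquisition activities (recycled to a common length).
#' @inheritParams add_enzyme_acquisitions
#' @return A tibble with columns `x` and `y`, both in `[0, 1]` where defined;
#'   `NA` marks samples with zero (or, under `ln_transform`, non-positive-log)
#'   denominators.
#' @examples
#' investment_xy(3, 1, 3) # x = 0.5, y = 0.75
#' @export
investment_xy <- function(c_acq, n_acq, p_acq, ln_transform = FALSE) {
  k <- max(length(c_acq), length(n_acq), length(p_acq))
  c_acq <- rep_len(c_acq, k)
  n_acq <- rep_len(n_acq, k)
  p_acq <- rep_len(p_acq, k)
  if (any(c(c_acq, n_acq, p_acq) < 0, na.rm = TRUE)) {
    abort("acquisition sums must be non-negative.",
          class = "enzlim_domain_error")
  }
  if (isTRUE(ln_transform)) {
    ok <- !is.na(c_acq) & !is.na(n_acq) & !is.na(p_acq) &
      c_acq > 0 & n_acq > 0 & p_acq > 0
    lc <- ifelse(ok, log(c_acq), NA_real_)
    ln <- ifelse(ok, log(n_acq), NA_real_)
    lp <- ifelse(ok, log(p_acq), NA_real_)
    x <- lc / (lc + lp)
    y <- lc / (lc + ln)
    # ln of sub-unit activities can flip signs; such proportions are not
    # interpretable as investments and are marked undefined.
    x[!is.na(x) & (x < 0 | x > 1)] <- NA_real_
    y[!is.na(y) & (y < 0 | y > 1)] <- NA_real_
  } else {
    x <- ifelse(c_acq + p_acq > 0, c_acq / (c_acq + p_acq), NA_real_)
    y <- ifelse(c_acq + n_acq > 0, c_acq / (c_acq + n_acq), NA_real_)
  }
  tibble::tibble(x = x, y = y)
}

#' Cohort-level acquisition stoichiometry
#'
#' Summarises the pooled C:N:P acquisition stoichiometry of a cohort, with
#' carbon normalised to 1 — the scale on which a global reference near
#' 1:1:1 and departures from it (e.g. excess P-acquisition under phosphorus
#' limitation) are read. The headline ratios are ratios of cohort means,
#' which are robust to small per-sample denominators; the per-sample
#' mean-of-ratios is reported alongside.
#'
#' @param data A data frame with enzyme activity columns (or with
#'   `c_acq`/`n_acq`/`p_acq` already present, e.g. from
#'   [add_enzyme_acquisitions()]).
#' @return A one-row tibble: `n_samples`, `mean_c`, `mean_n`, `mean_p`,
#'   `ratio_n_to_c`, `ratio_p_to_c` (ratio of means, C = 1) and
#'   `mor_n_to_c`, `mor_p_to_c` (mean of per-sample ratios).
#' @examples
#' tbl <- tibble::tibble(
#'   bg = c(1, 3), cbh = 0, nag = c(1, 1), lap = 0, ap = c(1, 3)
#' )
#' stoich_summary(tbl) # means (2, 1, 2), ratio 1:0.5:1
#' @export
stoich_summary <- function(data) {
  if (!all(c("c_acq", "n_acq", "p_acq") %in% names(data))) {
    data <- add_enzyme_acquisitions(data)
  }
  keep <- stats::complete.cases(data[, c("c_acq", "n_acq", "p_acq")])
  data <- data[keep, ]
  if (nrow(data) == 0) {
    abort("no samples with defined acquisition sums.",
          class = "enzlim_domain_error")
  }
  mean_c <- mean(data$c_acq)
  mean_n <- mean(data$n_acq)
  mean_p <- mean(data$p_acq)
  if (mean_c <= 0) {
    abort("mean C acquisition is zero; stoichiometric ratios are undefined.",
          class = "enzlim_domain_error")
  }
  ok <- data$c_acq > 0
  tibble::tibble(
    n_samples = nrow(data),
    mean_c = mean_c, mean_n = mean_n, mean_p = mean_p,
    ratio_n_to_c = mean_n / mean_c,
    ratio_p_to_c = mean_p / mean_c,
    mor_n_to_c = mean(data$n_acq[ok] / data$c_acq[ok]),
    mor_p_to_c = mean(data$p_acq[ok] / data$c_acq[ok])
  )
}
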