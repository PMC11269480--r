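# Shared validation helpers. All user-facing errors are rlang conditions so
# callers can trap them by class.

ENZYMES <- c("bg", "cbh", "nag", "lap", "ap")

check_enzyme_columns <- function(data, call = rlang::caller_env()) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame of per-sample enzyme activities.",
          call = call)
  }
  missing <- setdiff(ENZYMES, names(data))
  if (length(missing) > 0) {
    abort(
      paste0("missing enzyme activity column(s): ",
             paste(missing, collapse = ", ")),
      class = "enzlim_schema_error", call = call
    )
  }
  for (col in ENZYMES) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      abort(paste0("enzyme column '", col, "' is not numeric."),
            class = "enzlim_schema_error", call = call)
    }
    bad <- which(!is.na(v) & (!is.finite(v) | v < 0))
    if (length(bad) > 0) {
      abort(
        paste0("enzyme column '", col,
               "' has negative or non-finite activities (rows ",
               paste(head(bad, 5), collapse = ", "), ")."),
        class = "enzlim_domain_error", call = call
      )
    }
  }
  invisible(data)
}

# Attach sample ids when a bare activity table is supplied.
ensure_sample_id <- function(data) {
  if (!"sample_id" %in% names(data)) {
    data <- dplyr::mutate(
      data,
      sample_id = sprintf("S%02d", seq_len(nrow(data))),
      .before = 1
    )
  }
  if (anyDuplicated(data$sample_id) > 0) {
    abort("duplicated sample_id values.", class = "enzlim_schema_error")
  }
  data
}

# Run `expr` under a fixed RNG state when `seed` is given, untouched otherwise.
with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
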