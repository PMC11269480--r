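#' Read a per-sample survey table
#'
#' Reads a delimited table of sites with region labels, physicochemistry and
#' the five enzyme activities. The delimiter is taken from the file
#' extension (`.tsv` = tab, otherwise comma) unless given. Decimal parsing
#' is locale-independent (dot decimal); empty cells and `NA` are explicit
#' missing values, never silent zeros. `water_n_to_p` / `sed_n_to_p` are
#' derived from TN and TP when absent.
#'
#' @param path Path to the table.
#' @param delim Optional delimiter override.
#' @return A tibble with one row per sample.
#' @export
read_sample_table <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "enzlim_io_error")
  }
  delim <- delim %||% if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           na = c("", "NA"), locale = readr::locale(decimal_mark = "."),
                           progress = FALSE)
  mandatory <- c("sample_id", "region", "depth_m", ENZYMES)
  missing <- setdiff(mandatory, names(raw))
  if (length(missing) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing, collapse = ", ")),
          class = "enzlim_schema_error")
  }
  numeric_cols <- setdiff(names(raw), c("sample_id", "region"))
  for (col in numeric_cols) {
    v <- raw[[col]]
    if (is.numeric(v)) next
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad) > 0) {
      abort(paste0("non-numeric value '", v[bad[1]], "' in column '", col,
                   "', row ", bad[1], "."),
            class = "enzlim_parse_error")
    }
    raw[[col]] <- parsed
  }
  bad_region <- setdiff(unique(raw$region), c("SXK", "LXK"))
  if (length(bad_region) > 0) {
    abort(paste0("unknown region label(s): ",
                 paste(bad_region, collapse = ", "),
                 " (expected SXK or LXK)."),
          class = "enzlim_schema_error")
  }
  raw <- ensure_sample_id(raw)
  derive_np <- function(d, out, tn, tp) {
    if (!out %in% names(d) && all(c(tn, tp) %in% names(d))) {
      d[[out]] <- ifelse(!is.na(d[[tp]]) & d[[tp]] > 0,
                         d[[tn]] / d[[tp]], NA_real_)
    }
    d
  }
  raw <- derive_np(raw, "water_n_to_p", "water_tn", "water_tp")
  raw <- derive_np(raw, "sed_n_to_p", "sed_tn", "sed_tp")
  raw
}

#' Read a classic OTU table with taxonomy
#'
#' Reads a tab-delimited OTU count table (default orientation: taxa in rows,
#' first column the OTU id, one column per sample) and a two-column
#' taxonomy file (`taxon_id`, `phylum` or a lineage string with a `p__`
#' field), returning a [community_table()]. Counts are rounded to integers;
#' taxa absent from the taxonomy become `Unclassified` with a warning.
#'
#' @param path Path to the OTU table.
#' @param taxonomy_path Path to the taxonomy file.
#' @param orientation `"taxa_rows"` (classic, default) or `"samples_rows"`.
#' @return An `enzlim_community`.
#' @export
read_otu_table <- function(path, taxonomy_path,
                           orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  for (p in c(path, taxonomy_path)) {
    if (!file.exists(p)) {
      abort(paste0("file not found: ", p), class = "enzlim_io_error")
    }
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids) > 0) {
    abort(paste0("duplicated id in first column of ", path),
          class = "enzlim_schema_error")
  }
  m <- as.matrix(raw[, -1])
  if (!is.numeric(m)) {
    abort("OTU counts must be numeric.", class = "enzlim_parse_error")
  }
  if (any(m < 0, na.rm = TRUE)) {
    abort("negative counts in OTU table.", class = "enzlim_domain_error")
  }
  m[is.na(m)] <- 0
  m <- round(m)
  rownames(m) <- ids
  if (orientation == "taxa_rows") m <- t(m)
  tax <- readr::read_tsv(taxonomy_path, show_col_types = FALSE,
                         progress = FALSE)
  names(tax)[1:2] <- c("taxon_id", "phylum")
  tax$taxon_id <- as.character(tax$taxon_id)
  community_table(m, tax)
}

#' Write result tables with a reproducibility manifest
#'
#' Writes one delimited file per result table (data frames as CSV, matrices
#' and distance objects as labelled TSV) plus `manifest.json` recording the
#' seed, configuration echo, package version and an MD5 checksum per file.
#' Re-running with the same seed and inputs reproduces identical numeric
#' payloads.
#'
#' @param results Named list of data frames, matrices or `dist` objects.
#' @param outdir Output directory (created if needed).
#' @param seed,config Optional values echoed into the manifest.
#' @param warnings Optional character vector of run warnings to record.
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(results, outdir, seed = NULL, config = NULL,
                          warnings = character()) {
  if (is.null(names(results)) || any(names(results) == "")) {
    abort("`results` must be a fully named list.",
          class = "enzlim_schema_error")
  }
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) {
    abort(paste0("cannot create output directory: ", outdir),
          class = "enzlim_io_error")
  }
  files <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "dist")) x <- as.matrix(x)
    if (is.matrix(x)) {
      path <- file.path(outdir, paste0(nm, ".tsv"))
      df <- tibble::as_tibble(x, rownames = "sample_id")
      readr::write_tsv(df, path)
      nrows <- nrow(df)
    } else {
      path <- file.path(outdir, paste0(nm, ".csv"))
      readr::write_csv(tibble::as_tibble(x), path)
      nrows <- nrow(x)
    }
    files[[nm]] <- list(file = basename(path), rows = nrows,
                        md5 = unname(tools::md5sum(path)))
  }
  manifest <- list(
    package = "enzlim",
    version = as.character(packageVersion("enzlim")),
    seed = seed,
    config = config,
    files = files,
    warnings = as.list(warnings)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(manifest)
}
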