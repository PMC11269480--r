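#' Run the full metabolic-limitation analysis pipeline
#'
#' Executes the survey workflow end-to-end: regional comparisons (one-way
#' ANOVA of abiotic, enzymatic and diversity characteristics between
#' regions), acquisition stoichiometry and the vector analysis of microbial
#' C/N/P limitation, alpha and beta diversity of the bacterial and fungal
#' communities, then the driver screen (Pearson correlations, the
#' angle-on-length regression, Mantel tests linking community dissimilarity
#' to limitation differences, forward-stepwise driver selection and
#' permutation importance). All result tables plus a JSON manifest are
#' written to `outdir`; any stage failure aborts with a stage-named error
#' and removes partial outputs.
#'
#' @param samples A cohort tibble (e.g. from [simulate_cohort()] or
#'   [read_sample_table()]) or a path to a sample table.
#' @param bacteria,fungi Optional community input: an [community_table()],
#'   or a length-2 character vector `c(otu_table, taxonomy)` of paths.
#'   Missing domains are skipped with a recorded warning.
#' @param outdir Output directory.
#' @param seed Integer seed driving rarefaction, Mantel permutations and
#'   permutation importance; fixed seed gives identical outputs.
#' @param n_perm Mantel permutation count (default 999).
#' @param threshold Vector-angle classification threshold in degrees.
#' @param ln_transform Passed to [limitation_table()].
#' @return Invisibly, the run manifest (list) with the written files, seed,
#'   configuration echo and accumulated warnings.
#' @export
run_pipeline <- function(samples, bacteria = NULL, fungi = NULL,
                         outdir = tempfile("enzlim_run_"), seed = 1,
                         n_perm = 999, threshold = 45,
                         ln_transform = FALSE) {
  if (n_perm < 1) abort("`n_perm` must be >= 1.",
                        class = "enzlim_config_error")
  if (threshold <= 0 || threshold >= 90) {
    abort("`threshold` must lie strictly between 0 and 90 degrees.",
          class = "enzlim_config_error")
  }
  run_warnings <- character()
  note <- function(msg) run_warnings <<- c(run_warnings, msg)
  created <- character()
  stage <- function(name, expr) {
    tryCatch(
      withCallingHandlers(expr, warning = function(w) {
        note(paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        unlink(created, recursive = TRUE)
        abort(paste0("pipeline stage '", name, "' failed: ",
                     conditionMessage(e)),
              class = "enzlim_pipeline_error", parent = e)
      }
    )
  }

  # -- inputs ----------------------------------------------------------
  samples <- stage("read", {
    if (is.character(samples)) read_sample_table(samples) else
      ensure_sample_id(tibble::as_tibble(samples))
  })
  load_comm <- function(x, dom) {
    if (is.null(x)) {
      note(paste0("no ", dom, " community supplied; ", dom,
                  " stages skipped."))
      return(NULL)
    }
    if (inherits(x, "enzlim_community")) return(x)
    if (is.character(x) && length(x) == 2) {
      return(read_otu_table(x[1], x[2]))
    }
    abort(paste0("`", dom,
                 "` must be an enzlim_community or c(otu_path, tax_path)."))
  }
  comms <- list(bacteria = stage("read", load_comm(bacteria, "bacteria")),
                fungi = stage("read", load_comm(fungi, "fungi")))

  results <- list()

  # -- regional comparisons --------------------------------------------
  abiotic <- setdiff(
    names(samples)[vapply(samples, is.numeric, logical(1))], ENZYMES
  )
  anova_tbl <- stage("regional_anova", {
    regions <- table(samples$region)
    if (length(regions) < 2 || any(regions < 2)) {
      note("fewer than two regions with >= 2 samples; ANOVA stage skipped.")
      NULL
    } else {
      purrr::map_dfr(c(abiotic, ENZYMES), function(v) {
        res <- tryCatch(
          anova_oneway(samples, response = !!rlang::sym(v),
                       group = region),
          error = function(e) tibble::tibble(
            f_stat = NA_real_, df_between = NA_real_,
            df_within = NA_real_, p_value = NA_real_
          )
        )
        dplyr::mutate(res, variable = v, .before = 1)
      })
    }
  })

  # -- stoichiometry and vectors ---------------------------------------
  acq <- stage("stoichiometry", add_enzyme_acquisitions(samples,
                                                        ln_transform = ln_transform))
  results$stoichiometry <- stage("stoichiometry", stoich_summary(acq))
  vectors <- stage("vectors", limitation_table(samples,
                                               ln_transform = ln_transform,
                                               threshold = threshold))
  results$vector_results <- tibble::as_tibble(vectors)
  results$vector_summary <- stage("vectors", limitation_summary(vectors))

  # -- diversity --------------------------------------------------------
  depths <- list()
  diversity <- list()
  distances <- list()
  for (dom in c("bacteria", "fungi")) {
    cm <- comms[[dom]]
    if (is.null(cm)) next
    stage(paste0("diversity_", dom), {
      rar <- rarefy_table(cm, seed = seed)
      depths[[dom]] <- min(rowSums(rar$counts))
      div <- diversity_table(rar)
      diversity[[dom]] <- div
      distances[[dom]] <- distance_matrix(rar)
      results[[paste0("diversity_", dom)]] <- div
      results[[paste0("bray_curtis_", dom)]] <- as.matrix(distances[[dom]])
      if (!is.null(anova_tbl)) {
        sh <- dplyr::left_join(div,
                               samples[, c("sample_id", "region")],
                               by = "sample_id")
        res <- tryCatch(
          anova_oneway(sh, response = shannon, group = region),
          error = function(e) NULL
        )
        if (!is.null(res)) {
          anova_tbl <- dplyr::bind_rows(
            anova_tbl,
            dplyr::mutate(res, variable = paste0("shannon_", dom),
                          .before = 1)
          )
        }
      }
    })
  }
  if (!is.null(anova_tbl)) results$anova_region <- anova_tbl

  # -- driver screen ----------------------------------------------------
  stage("drivers", {
    vt <- tibble::as_tibble(vectors)
    vt <- dplyr::left_join(vt, samples[, c("sample_id", abiotic)],
                           by = "sample_id")
    driver_vars <- setdiff(abiotic, character())
    cors <- dplyr::bind_rows(
      dplyr::mutate(correlate_drivers(vt, length, driver_vars),
                    response = "vector_length", .before = 1),
      dplyr::mutate(correlate_drivers(vt, angle_deg, driver_vars),
                    response = "vector_angle", .before = 1)
    )
    results$driver_correlations <- cors
    if (sum(!is.na(vt$angle_deg)) >= 3) {
      results$va_on_vl <- glance(fit_ols(angle_deg ~ length, data = vt))
    }
    candidates <- intersect(
      c("depth_m", "water_tds", "water_conductivity", "sed_tc", "sed_doc",
        "water_ph", "sed_ph", "water_salinity"),
      driver_vars
    )
    if (length(candidates) >= 1 && nrow(vt) > length(candidates) + 2) {
      sw <- forward_stepwise(vt, length, candidates)
      results$stepwise_vl <- dplyr::mutate(glance(sw),
                                            predictors = paste(sw$predictors,
                                                               collapse = "+"),
                                            .before = 1)
      imp <- permutation_importance(sw, n_rep = 100, seed = seed + 1)
      if (nrow(imp) > 0) results$importance_vl <- imp
    }
    mantels <- list()
    for (dom in names(distances)) {
      ids <- attr(distances[[dom]], "Labels")
      vv <- vt[match(ids, vt$sample_id), ]
      for (what in c("length", "angle_deg")) {
        ld <- stats::dist(matrix(vv[[what]], dimnames = list(ids, NULL)))
        mt <- mantel_test(distances[[dom]], ld, n_perm = n_perm,
                          seed = seed + 2)
        mantels[[paste(dom, what, sep = "_")]] <- dplyr::mutate(
          glance(mt), community = dom, limitation = what, .before = 1
        )
      }
    }
    if (length(mantels) > 0) results$mantel <- dplyr::bind_rows(mantels)
  })

  # -- write ------------------------------------------------------------
  manifest <- stage("write", {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    created <- file.path(outdir,
                          c(paste0(names(results), ".csv"),
                            paste0(names(results), ".tsv"), "manifest.json"))
    write_results(
      results, outdir, seed = seed,
      config = list(n_perm = n_perm, threshold = threshold,
                    ln_transform = ln_transform,
                    rarefaction_depth = depths),
      warnings = run_warnings
    )
  })
  invisible(manifest)
}
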