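test_that("config validation enforces the generator invariants", {
  expect_s3_class(cohort_config(), "enzlim_config")
  expect_error(cohort_config(n_sxk = 1, n_lxk = 2),
               class = "enzlim_config_error")
  expect_error(cohort_config(enzyme = list(target_ratio = c(n = -0.5))),
               class = "enzlim_config_error")
  expect_error(cohort_config(community = list(bacteria = list(read_depth = 0))),
               class = "enzlim_config_error")
  # partial overrides merge with defaults
  cfg <- cohort_config(enzyme = list(sxk_mult = c(bg = 5)))
  expect_equal(cfg$enzyme$sxk_mult[["bg"]], 5)
  expect_equal(cfg$enzyme$sxk_mult[["ap"]], 0.25)
})

test_that("closed-form enzyme targets reproduce the pooled stoichiometry", {
  cfg <- cohort_config()
  tg <- enzlim:::enzyme_mean_targets(cfg)
  w_s <- cfg$n_sxk / (cfg$n_sxk + cfg$n_lxk)
  pooled <- w_s * tg["SXK", ] + (1 - w_s) * tg["LXK", ]
  c_pool <- pooled[["bg"]] + pooled[["cbh"]]
  expect_equal(c_pool, cfg$enzyme$c_total)
  expect_equal((pooled[["nag"]] + pooled[["lap"]]) / c_pool, 0.58)
  expect_equal(pooled[["ap"]] / c_pool, 1.51)
  # regional contrasts hold exactly on the targets
  expect_equal(tg["SXK", "bg"] / tg["LXK", "bg"], 3)
  expect_equal(tg["SXK", "ap"] / tg["LXK", "ap"], 0.25)
})

test_that("cohorts are deterministic, positive and correctly structured", {
  cfg <- test_config(seed = 7)
  s1 <- simulate_cohort(cfg)
  expect_identical(s1, simulate_cohort(cfg))
  expect_equal(nrow(s1), 30)
  expect_equal(sum(s1$region == "SXK"), 10)
  num <- dplyr::select(s1, -sample_id, -region)
  pos <- dplyr::select(num, -water_temp_c) # temperature may legally be <= 0
  expect_true(all(pos > 0))
  expect_true(all(is.finite(as.matrix(num))))
  expect_equal(s1$sed_n_to_p, s1$sed_tn / s1$sed_tp)
  expect_equal(s1$water_n_to_p, s1$water_tn / s1$water_tp)
  # a different seed gives a different cohort
  expect_false(identical(s1$bg, simulate_cohort(cfg, seed = 8)$bg))
})

test_that("regional enzyme contrasts are recovered at large n", {
  cfg <- cohort_config(seed = 3, n_sxk = 1500, n_lxk = 3000)
  s <- simulate_cohort(cfg)
  bg_ratio <- mean(s$bg[s$region == "SXK"]) / mean(s$bg[s$region == "LXK"])
  ap_ratio <- mean(s$ap[s$region == "SXK"]) / mean(s$ap[s$region == "LXK"])
  expect_equal(bg_ratio, 3, tolerance = 0.15)
  expect_equal(ap_ratio, 0.25, tolerance = 0.15)
  # sediment chemistry means hit their regional calibration
  expect_equal(mean(s$sed_tc[s$region == "SXK"]), 18.06, tolerance = 0.05)
  expect_equal(mean(s$sed_tc[s$region == "LXK"]), 5.43, tolerance = 0.05)
  expect_equal(mean(s$sed_tn[s$region == "SXK"]), 1.78, tolerance = 0.05)
  expect_equal(mean(s$sed_tp[s$region == "LXK"]), 0.44, tolerance = 0.05)
})

test_that("planted covariate effects are recovered by log-scale regression", {
  cfg <- cohort_config(seed = 13, n_sxk = 0, n_lxk = 4000)
  s <- simulate_cohort(cfg)
  # reconstruct the standardised latent drivers from the lognormal draws
  z_of <- function(v, mean_lxk, cv) {
    sigma <- sqrt(log(1 + cv^2))
    (log(v) - (log(mean_lxk) - sigma^2 / 2)) / sigma
  }
  d <- data.frame(
    lbg = log(s$bg),
    z_depth = z_of(s$depth_m, 5.0, 0.3),
    z_tds = z_of(s$water_tds, 150, 0.3),
    z_cond = z_of(s$water_conductivity, 240, 0.3),
    z_tc = z_of(s$sed_tc, 5.43, 0.3)
  )
  fit <- fit_ols(lbg ~ z_depth + z_tds + z_cond + z_tc, d)
  td <- tidy(fit)
  planted <- c(z_depth = -0.4, z_tds = 0.4, z_cond = 0.25, z_tc = 0.35)
  for (nm in names(planted)) {
    row <- td[td$term == nm, ]
    expect_lt(abs(row$estimate - planted[[nm]]), 2 * row$std_error + 0.02)
  }
})

test_that("null effect configuration decouples limitation from drivers", {
  # zero betas and neutral regional multipliers: enzymes carry no covariate
  # signal, so limitation must be uncorrelated with depth on average
  rs <- vapply(1:30, function(i) {
    cfg <- cohort_config(
      seed = 500 + i,
      enzyme = list(
        beta = c(depth = 0, tds = 0, cond = 0, tc = 0),
        sxk_mult = c(bg = 1, cbh = 1, nag = 1, lap = 1, ap = 1)
      )
    )
    s <- simulate_cohort(cfg)
    v <- suppressMessages(limitation_table(s))
    cor(v$length, s$depth_m)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.12)
})

test_that("phylum proportions concentrate on their means as Dirichlet tightens", {
  cfg <- test_config(seed = 9,
                     community = list(bacteria = list(concentration = 1e9),
                                      coupling = 0))
  s <- simulate_cohort(cfg)
  cm <- simulate_communities(s, cfg)
  pa <- phylum_abundance(cm$bacteria)
  proteo <- pa$rel_abund[pa$phylum == "Proteobacteria"]
  # only multinomial read noise remains
  expect_lt(max(abs(proteo - 0.3303)), 4 * sqrt(0.33 * 0.67 / 800) + 0.005)
})

test_that("zero coupling removes the community-limitation association", {
  rs <- vapply(1:12, function(i) {
    cfg <- test_config(seed = 700 + i, community = list(coupling = 0))
    s <- simulate_cohort(cfg)
    cm <- simulate_communities(s, cfg)
    v <- suppressMessages(limitation_table(s))
    bc <- distance_matrix(cm$bacteria)
    ids <- attr(bc, "Labels")
    vv <- v[match(ids, v$sample_id), ]
    ld <- dist(matrix(vv$length, dimnames = list(ids, NULL)))
    mantel_test(bc, ld, n_perm = 1, seed = 1)$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("default coupling produces the positive beta-diversity association", {
  cfg <- test_config(seed = 11)
  s <- simulate_cohort(cfg)
  cm <- simulate_communities(s, cfg)
  v <- suppressMessages(limitation_table(s))
  for (dom in c("bacteria", "fungi")) {
    bc <- distance_matrix(cm[[dom]])
    ids <- attr(bc, "Labels")
    vv <- v[match(ids, v$sample_id), ]
    ld <- dist(matrix(vv$length, dimnames = list(ids, NULL)))
    mt <- mantel_test(bc, ld, n_perm = 499, seed = 1)
    expect_gt(mt$r, 0)
    expect_lt(mt$p_value, 0.05)
  }
})

test_that("fixtures round-trip through files byte-identically", {
  cfg <- test_config(seed = 19)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  m1 <- write_fixture(cfg, out1)
  m2 <- write_fixture(cfg, out2)
  expect_equal(nrow(m1), 6) # samples, 2 OTU tables, 2 taxonomies, config
  expect_equal(nrow(readr::read_csv(file.path(out1, "samples.csv"),
                                    show_col_types = FALSE)), 30)
  for (f in basename(m1$file)) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))),
                     label = f)
  }
  # config round-trips through YAML
  cfg2 <- read_config(file.path(out1, "config.yaml"))
  expect_equal(cfg2$enzyme, cfg$enzyme, tolerance = 1e-12)
  expect_equal(cfg2$n_sxk, cfg$n_sxk)
  expect_equal(tibble::as_tibble(cfg2$chemistry), cfg$chemistry)
})
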