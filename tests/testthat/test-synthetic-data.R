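test_that("proteome generation is deterministic with plausible lengths", {
  cfg0 <- synthetic_config(n_proteins = 0L, n_null_sites = 0L,
                           n_true_substrates = 0L)
  expect_length(generate_proteome(cfg0), 0)

  cfg <- synthetic_config(n_proteins = 5L, seed = 1L)
  expect_identical(generate_proteome(cfg), generate_proteome(cfg))

  cfg2 <- synthetic_config(n_proteins = 100L, protein_length_mean = 400,
                           seed = 2L)
  ps <- generate_proteome(cfg2)
  expect_length(ps, 100)
  expect_true(all(nchar(ps) >= 11))
  expect_true(all(grepl("^[A-Z]+$", ps)))
  expect_lt(abs(mean(nchar(ps)) - 400) / 400, 0.2)
})

test_that("substrate planting is deterministic and respects eligibility", {
  cfg <- synthetic_config(n_proteins = 30L, n_null_sites = 50L,
                          n_true_substrates = 10L, seed = 4L)
  ps <- generate_proteome(cfg)
  t1 <- plant_substrates(ps, motif_spec(), cfg)
  t2 <- plant_substrates(ps, motif_spec(), cfg)
  expect_identical(t1$sites, t2$sites)
  expect_identical(t1$proteome, t2$proteome)
  expect_identical(sum(t1$sites$is_substrate), 10L)
  expect_true(all(t1$sites$position[t1$sites$is_substrate] >= 6))
  expect_true(all(t1$sites$residue %in% c("S", "T", "Y")))

  cfg0 <- synthetic_config(n_proteins = 30L, n_null_sites = 10L,
                           n_true_substrates = 0L, seed = 4L)
  t0 <- plant_substrates(ps, motif_spec(), cfg0)
  expect_identical(sum(t0$sites$is_substrate), 0L)

  # more substrates than proteins that can host one
  cfg_big <- synthetic_config(n_proteins = 30L, n_true_substrates = 31L)
  expect_error(plant_substrates(ps, motif_spec(), cfg_big), "insufficient")
})

test_that("simulation conserves sites, ids and obeys the design orientation", {
  cfg <- noise_free_config()
  truth <- plant_substrates(generate_proteome(cfg), motif_spec(), cfg)
  sim <- simulate_experiment(truth, config = cfg)
  # conservation: all truth ids emitted, none invented (no missingness here)
  expect_setequal(sim$sites$site_id, truth$sites$site_id)
  expect_identical(nrow(sim$sites), cfg$n_null_sites + cfg$n_true_substrates)

  # orientation algebra: planted -2 site gives H/L ~ 0.25 when treated-heavy
  # and ~ 4 in the label-swapped replicate (treated culture in light channel)
  planted <- truth$sites$site_id[truth$sites$is_substrate]
  i <- match(planted, sim$sites$site_id)
  expect_equal(sim$sites$ratio_R1[i], rep(0.25, length(i)), tolerance = 1e-12)
  expect_equal(sim$sites$ratio_R3[i], rep(4, length(i)), tolerance = 1e-12)
  # control replicate carries no effect
  expect_equal(sim$sites$ratio_C[i], rep(1, length(i)), tolerance = 1e-12)

  # determinism: identical config gives byte-identical tables
  sim2 <- simulate_experiment(truth, config = cfg)
  expect_identical(sim$sites, sim2$sites)
  expect_identical(sim$proteins, sim2$proteins)
})

test_that("missingness thins replicate measurements at the configured rate", {
  cfg <- synthetic_config(n_proteins = 100L, n_null_sites = 1500L,
                          n_true_substrates = 0L, missing_rate = 0.3,
                          seed = 6L)
  truth <- plant_substrates(generate_proteome(cfg), motif_spec(), cfg)
  sim <- simulate_experiment(truth, config = cfg)
  fmiss <- mean(is.na(sim$sites$ratio_R1))
  expect_lt(abs(fmiss - 0.3), 3 * sqrt(0.3 * 0.7 / 1500))
  # localization probabilities live in [0, 1] and straddle the 0.75 filter
  lp <- sim$sites$locprob_R1
  lp <- lp[!is.na(lp)]
  expect_true(all(lp >= 0 & lp <= 1))
  expect_gt(mean(lp >= 0.75), 0.5)
  expect_gt(mean(lp < 0.75), 0.05)
})

test_that("null-site log2 fold-change noise has the configured spread", {
  cfg <- synthetic_config(n_proteins = 100L, n_null_sites = 1000L,
                          n_true_substrates = 0L, noise_sd_log2 = 0.3,
                          missing_rate = 0,
                          frac_abundance_shifted_proteins = 0, seed = 9L)
  truth <- plant_substrates(generate_proteome(cfg), motif_spec(), cfg)
  sim <- simulate_experiment(truth, config = cfg)
  q <- quantify_replicate(sim$sites, NULL, sim$design[1, ])
  expect_lt(abs(stats::sd(q$log2fc) - 0.3) / 0.3, 0.15)
})

test_that("orientation round-trip leaves downstream values unchanged", {
  cfg <- noise_free_config()
  truth <- plant_substrates(generate_proteome(cfg), motif_spec(), cfg)
  sim <- simulate_experiment(truth, config = cfg)
  flip <- function(x) {
    for (cc in grep("^ratio_", names(x))) x[[cc]] <- 1 / x[[cc]]
    x
  }
  design_f <- sim$design
  design_f$orientation <- ifelse(sim$design$orientation == "heavy_treated",
                                 "light_treated", "heavy_treated")
  s1 <- kinase_screen(sim$sites, sim$proteins, sim$design)
  s2 <- kinase_screen(flip(sim$sites), flip(sim$proteins), design_f)
  expect_equal(s1$summary, s2$summary, tolerance = 1e-12)
  expect_identical(s1$tiers, s2$tiers)
})

test_that("phenotype series recover planted rates", {
  # noise-free: exact recovery
  s <- generate_phenotype_series(1, elongation_rate = 0.05,
                                 widening_rate = 0, noise_sd = 0,
                                 duration = 100, seed = 2L)
  r <- growth_rates(s)
  expect_equal(r$elongation, 0.05, tolerance = 1e-12)
  expect_equal(r$widening, 0, tolerance = 1e-12)
  # zero rates: constant volume
  s0 <- generate_phenotype_series(1, 0, 0, 0, duration = 60, seed = 3L)
  expect_equal(r0 <- growth_rates(s0)$volume_expansion, 0, tolerance = 1e-12)
  # noisy: mean recovered slope within 2 SE of truth
  sn <- generate_phenotype_series(50, elongation_rate = 0.04,
                                  widening_rate = 0.002, noise_sd = 0.05,
                                  duration = 120, seed = 4L)
  slopes <- vapply(split(sn, sn$cell_id),
                   function(d) growth_rates(d)$elongation, numeric(1))
  se <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.04), 2 * se)
  # determinism
  expect_identical(generate_phenotype_series(3, 0.05, 0, 0.1, 60, seed = 5L),
                   generate_phenotype_series(3, 0.05, 0, 0.1, 60, seed = 5L))
})
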