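make_summary_row <- function(site_id, n, mean_t, mean_c,
                             values = rep(NA_real_, 3)) {
  data.frame(site_id = site_id, n_treatment = n,
             mean_log2fc_treatment = mean_t,
             used_protein_normalized = NA,
             mean_log2fc_control = mean_c,
             value_R1 = values[1], value_R2 = values[2], value_R3 = values[3],
             stringsAsFactors = FALSE)
}

test_that("tier classification applies strict cutoffs and control exclusion", {
  th <- stringency_thresholds()
  s <- rbind(
    make_summary_row("a", 3L, mean(c(-2.1, -1.3, -1.5)), -0.2),
    make_summary_row("b", 1L, -1.2, NA),
    make_summary_row("c", 3L, -1.5, -1.4),
    make_summary_row("d", 3L, -1.0, NA),   # boundary: not more negative
    make_summary_row("e", 2L, -1.6, NA),
    make_summary_row("f", 0L, NA, 0.1))
  calls <- classify_tier(s, th)
  expect_identical(calls$tier,
                   c("highest", "lowest", "none", "none", "medium", "none"))
  expect_identical(calls$excluded_by_control,
                   c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
})

test_that("tier classifier matches a brute-force truth table", {
  th <- stringency_thresholds()
  oracle <- function(n, mt, mc) {
    dec <- !is.na(mt) && mt < -1
    cok <- is.na(mc) || !(mc < -1)
    if (!dec || !cok) return("none")
    if (n >= 3) "highest" else if (n >= 2) "medium"
    else if (n >= 1) "lowest" else "none"
  }
  set.seed(17)
  n <- sample(0:3, 2000, replace = TRUE)
  mt <- ifelse(n == 0, NA, round(runif(2000, -3, 1), 2))
  mc <- ifelse(runif(2000) < 0.3, NA, round(runif(2000, -3, 1), 2))
  s <- make_summary_row(sprintf("s%04d", 1:2000), n, mt, mc)
  got <- classify_tier(s, th)$tier
  want <- mapply(oracle, n, mt, mc)
  expect_identical(got, unname(want))
})

test_that("tiers are nested and shrink as the cutoff becomes more negative", {
  cfg <- synthetic_config(n_proteins = 60L, protein_length_mean = 200,
                          n_null_sites = 300L, n_true_substrates = 30L,
                          seed = 21L)
  truth <- plant_substrates(generate_proteome(cfg), motif_spec(), cfg)
  sim <- simulate_experiment(truth, config = cfg)
  scr <- kinase_screen(sim$sites, sim$proteins, sim$design)
  tier <- setNames(scr$tiers$tier, scr$tiers$site_id)
  hi <- names(tier)[tier == "highest"]
  med <- names(tier)[tier %in% c("medium", "highest")]
  low <- names(tier)[tier != "none"]
  expect_true(all(hi %in% med))
  expect_true(all(med %in% low))

  sets <- lapply(c(-1, -1.5, -2), function(cut) {
    th <- stringency_thresholds(decrease_cutoff_log2 = cut)
    calls <- classify_tier(scr$summary, th)
    list(low = calls$site_id[calls$tier != "none"],
         hi = calls$site_id[calls$tier == "highest"])
  })
  expect_true(all(sets[[2]]$low %in% sets[[1]]$low))
  expect_true(all(sets[[3]]$low %in% sets[[2]]$low))
  expect_true(all(sets[[2]]$hi %in% sets[[1]]$hi))
  expect_true(all(sets[[3]]$hi %in% sets[[2]]$hi))
})

test_that("ranking is by ascending mean with lexicographic tie-break", {
  s <- rbind(
    make_summary_row("b2", 3L, -2.0, NA),
    make_summary_row("a9", 3L, -3.1, NA),
    make_summary_row("b1", 3L, -2.0, NA),
    make_summary_row("c1", 3L, -1.1, NA),
    make_summary_row("z9", 3L, -0.5, NA))
  calls <- classify_tier(s, stringency_thresholds())
  r <- rank_sites(calls, s)
  expect_identical(r$site_id, c("a9", "b1", "b2", "c1"))
  expect_identical(r$rank, 1:4)
  # deterministic: ranking twice gives the same order
  expect_identical(rank_sites(calls, s), r)
})

test_that("strong subset uses an inclusive 4-fold boundary", {
  s <- rbind(
    make_summary_row("a", 3L, -2.0, NA),
    make_summary_row("b", 3L, -1.9, NA),
    make_summary_row("c", 2L, -5.0, NA))   # not highest tier
  calls <- classify_tier(s, stringency_thresholds())
  ss <- strong_subset(calls, s)
  expect_identical(ss$site_id, "a")
  none <- classify_tier(s[s$site_id == "b", ], stringency_thresholds())
  expect_identical(nrow(strong_subset(none, s)), 0L)
})

test_that("per-replicate decrease counts match a loop-based recount", {
  s1 <- make_summary_row("a", 2L, -1, NA, values = c(-1.5, -0.5, NA))
  s2 <- make_summary_row("b", 3L, -1.8, NA, values = c(-1.1, -1.2, -3.0))
  counts <- count_by_replicate_decrease(rbind(s1, s2))
  expect_identical(counts, c(at_least_1 = 2L, at_least_2 = 1L, all_3 = 1L))

  set.seed(31)
  n <- 400
  vals <- matrix(rnorm(3 * n, -0.5, 1), n, 3)
  vals[runif(3 * n) < 0.3] <- NA
  mc <- ifelse(runif(n) < 0.5, NA, rnorm(n, 0, 1))
  s <- make_summary_row(sprintf("s%03d", 1:n), rowSums(!is.na(vals)),
                        rowMeans(vals, na.rm = TRUE), mc)
  s$value_R1 <- vals[, 1]; s$value_R2 <- vals[, 2]; s$value_R3 <- vals[, 3]
  got <- count_by_replicate_decrease(s, -1, -1)
  # independent loop-based oracle
  want <- c(at_least_1 = 0L, at_least_2 = 0L, all_3 = 0L)
  for (i in seq_len(n)) {
    if (!is.na(mc[i]) && mc[i] < -1) next
    k <- sum(vals[i, ] < -1, na.rm = TRUE)
    if (k >= 1) want["at_least_1"] <- want["at_least_1"] + 1L
    if (k >= 2) want["at_least_2"] <- want["at_least_2"] + 1L
    if (k >= 3) want["all_3"] <- want["all_3"] + 1L
  }
  expect_identical(got, want)
})

test_that("percent formatting reproduces report-style strings", {
  expect_identical(format_percent(326, 8134)$display, "4%")
  expect_identical(format_percent(121, 8134)$display, "1.5%")
  expect_identical(format_percent(55, 8134)$display, "0.7%")
  expect_identical(format_percent(36, 55)$display, "65%")
  expect_identical(format_percent(0, 10)$display, "0%")
  expect_identical(format_percent(1, 2)$display, "50%")
  expect_equal(format_percent(326, 8134)$percent, 100 * 326 / 8134)
  expect_error(format_percent(1, 0), "positive")
  expect_error(format_percent(5, 4), "between")
})

test_that("threshold constructor rejects invalid settings", {
  expect_error(stringency_thresholds(decrease_cutoff_log2 = 0.5), "negative")
  expect_error(stringency_thresholds(min_replicates = c(lowest = 2, medium = 2,
                                                        highest = 3)),
               "increasing")
})
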