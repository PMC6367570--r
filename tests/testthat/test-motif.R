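test_that("window classification follows the consensus definition", {
  expect_identical(classify_window("HARAASAAAAA")$category, "full_consensus")
  expect_identical(classify_window("AAKAATAAAAA")$category, "basic_minus3_only")
  expect_identical(classify_window("AAAAASAAAAA")$category, "no_match")
  # padding at a constrained offset fails that constraint
  expect_identical(classify_window("_ARAASAAAAA")$category,
                   "basic_minus3_only")
  expect_identical(classify_window("____MSTAKQ_")$category, "no_match")
  expect_error(classify_window("ARAAS"), "too short")
  expect_error(classify_window("HARAASAAAA"), "odd")
})

test_that("motif grammar parses and rejects malformed strings", {
  spec <- parse_motif_spec("-5:H; -3:RHK; 0:ST")
  expect_identical(spec[["-5"]], "H")
  expect_setequal(spec[["-3"]], c("R", "H", "K"))
  expect_setequal(spec[["0"]], c("S", "T"))
  expect_error(parse_motif_spec("-5:H; -3:RHK"), "offsets")
  expect_error(parse_motif_spec("nonsense"), "malformed|offsets")
  expect_error(motif_spec(minus3 = character(0)), "non-empty")
})

test_that("classifier agrees with a regex oracle on random windows", {
  set.seed(7)
  alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "_")
  # skew toward H/R/K/S/T so every category is well represented
  w <- vapply(1:10000, function(i) {
    paste(sample(alphabet, 11, replace = TRUE,
                 prob = c(rep(1, 20), 2) *
                   ifelse(alphabet %in% c("H", "R", "K", "S", "T"), 4, 1)),
          collapse = "")
  }, character(1))
  got <- classify_window(w)$category
  full <- grepl("^H.[HRK]..[ST]", w)
  basic <- !full & grepl("^..[HRK]..[ST]", w)
  want <- ifelse(full, "full_consensus",
                 ifelse(basic, "basic_minus3_only", "no_match"))
  expect_identical(got, want)
  expect_gt(sum(full), 50)   # the oracle saw real matches, not a vacuous pass
  expect_gt(sum(basic), 50)
})

test_that("annotation counts categories and is order-invariant", {
  sites <- data.frame(
    site_id = c("a", "b", "c", "d"),
    sequence_window = c("HARAASAAAAA", "HARAATAAAAA", "AAKAATAAAAA", NA),
    stringsAsFactors = FALSE)
  expect_warning(ann <- annotate_sites(sites), "unclassified.*d")
  expect_identical(unname(ann$counts),
                   c(2L, 1L, 0L))
  perm <- sites[c(3, 1, 4, 2), ]
  expect_warning(ann2 <- annotate_sites(perm), "unclassified")
  expect_identical(ann2$counts, ann$counts)
})

test_that("every planted substrate classifies as full consensus", {
  cfg <- synthetic_config(n_proteins = 80L, n_null_sites = 200L,
                          n_true_substrates = 40L, seed = 13L)
  truth <- plant_substrates(generate_proteome(cfg), motif_spec(), cfg)
  sim <- simulate_experiment(truth, config = cfg)
  planted <- sim$sites[sim$sites$site_id %in%
                         truth$sites$site_id[truth$sites$is_substrate], ]
  calls <- classify_window(planted$sequence_window)
  expect_true(all(calls$category == "full_consensus"))
})

test_that("fold enrichment follows the cluster/genome frequency ratio", {
  universe <- sprintf("g%04d", 1:1000)
  tm <- term_map(list(T1 = universe[1:50], T2 = universe[1:10],
                      T0 = character(0)), universe)
  cluster <- c(universe[1:4], universe[900:905])
  enr <- enrich_terms(cluster, tm)
  expect_equal(enr$fold[enr$term_id == "T1"], (4 / 10) / (50 / 1000))  # 8.0
  expect_equal(enr$fold[enr$term_id == "T2"], (4 / 10) / (10 / 1000))
  expect_false("T0" %in% enr$term_id)  # K = 0 terms skipped
  # cluster == universe: every fold is 1
  enr_all <- enrich_terms(universe, tm)
  expect_true(all(enr_all$fold == 1))
  # k = 0 gives fold 0 and p = 1
  tm2 <- term_map(list(T3 = universe[999:1000]), universe)
  enr0 <- enrich_terms(universe[1:5], tm2)
  expect_identical(enr0$fold, 0)
  expect_identical(enr0$p, 1)
  expect_error(enrich_terms(character(0), tm), "non-empty")
  expect_error(enrich_terms("not_a_gene", tm), "missing from universe")
  # invariance to gene-id relabeling
  relabel <- setNames(sprintf("x%04d", 1:1000), universe)
  tmr <- term_map(list(T1 = relabel[universe[1:50]],
                       T2 = relabel[universe[1:10]]), relabel)
  enr_r <- enrich_terms(relabel[cluster], tmr)
  expect_equal(enr_r$fold, enr$fold)
  expect_equal(enr_r$p, enr$p)
})

test_that("hypergeometric p-value is exact and monotone in k", {
  # direct summation oracle over the mass function
  p_oracle <- function(k, K, n, N) {
    j <- k:min(n, K)
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
  }
  expect_identical(hypergeom_pvalue(0, 5, 3, 10), 1)
  expect_identical(hypergeom_pvalue(4, 4, 4, 4), 1)
  expect_equal(hypergeom_pvalue(4, 50, 10, 1000), p_oracle(4, 50, 10, 1000),
               tolerance = 1e-12)
  set.seed(23)
  for (i in 1:200) {
    N <- sample(2:60, 1)
    n <- sample(0:N, 1)
    K <- sample(0:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_pvalue(k, K, n, N), p_oracle(k, K, n, N),
                 tolerance = 1e-12)
  }
  # monotone non-increasing in k at fixed (K, n, N)
  p <- hypergeom_pvalue(0:10, 50, 10, 200)
  expect_true(all(diff(p) <= 1e-15))
  expect_error(hypergeom_pvalue(5, 2, 10, 100), "inconsistent")
  # Bonferroni correction is optional and off by default
  universe <- sprintf("g%03d", 1:100)
  tm <- term_map(list(A = universe[1:10], B = universe[1:20]), universe)
  raw <- enrich_terms(universe[1:5], tm)
  expect_identical(attr(raw, "adjust"), "none")
  expect_identical(raw$p_adjusted, raw$p)
  adj <- enrich_terms(universe[1:5], tm, adjust = "bonferroni")
  expect_equal(adj$p_adjusted, pmin(1, adj$p * 2))
})
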