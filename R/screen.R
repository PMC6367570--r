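#' Screen phosphosites for kinase substrates
#'
#' The main fitting function of the package. Runs the full inference chain
#' on a SILAC phosphoproteomics experiment: per-replicate ratio orientation
#' and protein normalization, localization filtering, cross-replicate
#' aggregation with the protein-normalized precedence rule, nested
#' stringency-tier classification with the wild-type control exclusion,
#' fold-decrease ranking, consensus-motif annotation, and replicate
#' correlation diagnostics.
#'
#' @param sites Phosphosite table (see [read_phosphosite_table()] or
#'   [simulate_experiment()]).
#' @param proteins Protein abundance table or `NULL`.
#' @param design Experiment design (see [read_design()]).
#' @param localization_threshold Localization-probability filter threshold
#'   (default 0.75, inclusive).
#' @param thresholds A [stringency_thresholds()] object.
#' @param motif A [motif_spec()] object.
#' @return An object of class `kinase_screen` with components `summary`
#'   (per-site summary), `tiers` (tier calls), `ranked` (ranked candidate
#'   table), `strong` (strong subset), `motif` (motif calls and counts for
#'   the ranked candidates), `strong_motif` (same for the strong subset),
#'   `correlations` (pairwise treatment-replicate Pearson r),
#'   `replicate_decrease_counts`, `counts` (dataset-level totals), and the
#'   parameters used. Methods: [print.kinase_screen()],
#'   [summary.kinase_screen()], [coef.kinase_screen()],
#'   [plot.kinase_screen()].
#' @export
kinase_screen <- function(sites, proteins = NULL, design,
                          localization_threshold = 0.75,
                          thresholds = stringency_thresholds(),
                          motif = motif_spec()) {
  design <- validate_design(design)
  treat <- design[design$role == "treatment", , drop = FALSE]
  ctrl <- design[design$role == "control", , drop = FALSE]

  tq <- lapply(seq_len(nrow(treat)), function(i) {
    quantify_replicate(sites, proteins, treat[i, ])
  })
  names(tq) <- treat$experiment_id
  cq <- if (nrow(ctrl)) quantify_replicate(sites, proteins, ctrl[1L, ])

  meta_cols <- intersect(c("site_id", "protein_id", "position", "residue",
                           "sequence_window"), names(sites))
  summ <- build_summary(tq, cq, localization_threshold,
                        site_meta = sites[meta_cols])
  calls <- classify_tier(summ, thresholds)
  ranked <- rank_sites(calls, summ)
  strong <- strong_subset(calls, summ, thresholds)
  motif_ann <- if (nrow(ranked)) annotate_sites(ranked, motif) else {
    list(calls = NULL,
         counts = c(full_consensus = 0L, basic_minus3_only = 0L,
                    no_match = 0L))
  }
  strong_ann <- if (nrow(strong)) annotate_sites(strong, motif) else {
    list(calls = NULL,
         counts = c(full_consensus = 0L, basic_minus3_only = 0L,
                    no_match = 0L))
  }

  tqf <- lapply(tq, filter_localization, localization_threshold)
  pairs <- if (length(tqf) >= 2L) utils::combn(names(tqf), 2L) else NULL
  correlations <- if (!is.null(pairs)) {
    data.frame(experiment_a = pairs[1L, ], experiment_b = pairs[2L, ],
               n_common = NA_integer_, pearson_r = NA_real_,
               stringsAsFactors = FALSE)
  } else {
    data.frame(experiment_a = character(0L), experiment_b = character(0L),
               n_common = integer(0L), pearson_r = numeric(0L))
  }
  if (!is.null(pairs)) {
    for (j in seq_len(ncol(pairs))) {
      rc <- replicate_correlation(tqf[[pairs[1L, j]]], tqf[[pairs[2L, j]]])
      correlations$n_common[j] <- rc$n_common
      correlations$pearson_r[j] <- rc$pearson_r
    }
  }

  ratio_cols <- paste0("ratio_", design$experiment_id)
  ratio_cols <- intersect(ratio_cols, names(sites))
  n_quantified <- if (length(ratio_cols)) {
    sum(rowSums(!is.na(as.matrix(sites[ratio_cols]))) > 0)
  } else 0L
  tier_n <- c(lowest = sum(calls$tier != "none"),
              medium = sum(calls$tier %in% c("medium", "highest")),
              highest = sum(calls$tier == "highest"))

  structure(list(
    summary = summ,
    tiers = calls,
    ranked = ranked,
    strong = strong,
    motif = motif_ann,
    strong_motif = strong_ann,
    correlations = correlations,
    replicate_decrease_counts = count_by_replicate_decrease(
      summ, thresholds$decrease_cutoff_log2, thresholds$control_cutoff_log2),
    counts = c(n_input_sites = nrow(sites),
               n_quantified = n_quantified,
               n_post_filter = nrow(summ),
               n_excluded_by_control = sum(calls$excluded_by_control)),
    tier_counts = tier_n,
    localization_threshold = localization_threshold,
    thresholds = thresholds,
    motif_spec = motif,
    design = design,
    call = match.call()
  ), class = "kinase_screen")
}

#' @export
print.kinase_screen <- function(x, ...) {
  cat("Kinase substrate screen\n")
  cat(sprintf("  %d input sites; %d quantified; %d passed localization filter (>= %.2f)\n",
              x$counts["n_input_sites"], x$counts["n_quantified"],
              x$counts["n_post_filter"], x$localization_threshold))
  nq <- max(1L, x$counts["n_quantified"])
  for (tier in c("lowest", "medium", "highest")) {
    fp <- format_percent(x$tier_counts[tier], nq)
    cat(sprintf("  %-7s stringency: %4d sites (%s of quantified)\n",
                tier, x$tier_counts[tier], fp$display))
  }
  cat(sprintf("  strong subset (mean log2FC <= %.1f in highest tier): %d sites\n",
              x$thresholds$strong_cutoff_log2, nrow(x$strong)))
  cat(sprintf("  control-excluded sites: %d\n",
              x$counts["n_excluded_by_control"]))
  mc <- x$motif$counts
  cat(sprintf("  motif (ranked candidates): %d full consensus, %d basic -3 only, %d no match\n",
              mc["full_consensus"], mc["basic_minus3_only"], mc["no_match"]))
  invisible(x)
}

#' Summarize a kinase screen
#'
#' @param object A [kinase_screen()] result.
#' @param ... Unused.
#' @return A `summary.kinase_screen` list with dataset counts, tier counts
#'   and formatted percentages, per-replicate decrease counts, motif
#'   category counts for the ranked and strong sets, and replicate
#'   correlations.
#' @export
summary.kinase_screen <- function(object, ...) {
  nq <- object$counts["n_quantified"]
  pct <- if (nq > 0) {
    vapply(object$replicate_decrease_counts,
           function(k) format_percent(k, nq)$display, character(1L))
  } else {
    stats::setNames(rep(NA_character_, 3L),
                    names(object$replicate_decrease_counts))
  }
  structure(list(counts = object$counts,
                 tier_counts = object$tier_counts,
                 replicate_decrease_counts = object$replicate_decrease_counts,
                 replicate_decrease_percent = pct,
                 motif_counts = object$motif$counts,
                 strong_motif_counts = object$strong_motif$counts,
                 n_strong = nrow(object$strong),
                 correlations = object$correlations),
            class = "summary.kinase_screen")
}

#' @export
print.summary.kinase_screen <- function(x, ...) {
  cat("Kinase substrate screen summary\n")
  cat(sprintf("  sites: %d input, %d quantified, %d post-filter\n",
              x$counts["n_input_sites"], x$counts["n_quantified"],
              x$counts["n_post_filter"]))
  cat("  tiers:", paste(sprintf("%s=%d", names(x$tier_counts), x$tier_counts),
                        collapse = ", "), "\n")
  rd <- x$replicate_decrease_counts
  cat(sprintf("  2-fold decreases: %d (%s) in >=1, %d (%s) in >=2, %d (%s) in 3 replicates\n",
              rd["at_least_1"], x$replicate_decrease_percent["at_least_1"],
              rd["at_least_2"], x$replicate_decrease_percent["at_least_2"],
              rd["all_3"], x$replicate_decrease_percent["all_3"]))
  cat(sprintf("  strong subset: %d sites; motif: %d full consensus, %d basic -3 only\n",
              x$n_strong, x$strong_motif_counts["full_consensus"],
              x$strong_motif_counts["basic_minus3_only"]))
  if (nrow(x$correlations)) {
    for (j in seq_len(nrow(x$correlations))) {
      cat(sprintf("  correlation %s vs %s: r = %.3f (n = %d)\n",
                  x$correlations$experiment_a[j], x$correlations$experiment_b[j],
                  x$correlations$pearson_r[j], x$correlations$n_common[j]))
    }
  }
  invisible(x)
}

#' Per-site mean log2 fold-changes of a screen
#'
#' @param object A [kinase_screen()] result.
#' @param ... Unused.
#' @return Named numeric vector of treatment mean log2 fold-changes.
#' @export
coef.kinase_screen <- function(object, ...) {
  stats::setNames(object$summary$mean_log2fc_treatment,
                  object$summary$site_id)
}

#' Replicate-agreement scatter plot for a screen
#'
#' Plots the retained per-replicate log2 fold-changes of two treatment
#' replicates against each other for sites quantified in both, annotated
#' with the Pearson correlation.
#'
#' @param x A [kinase_screen()] result.
#' @param pair Character vector of two treatment experiment ids; defaults
#'   to the first two.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.kinase_screen <- function(x, pair = NULL, ...) {
  vcols <- grep("^value_", names(x$summary), value = TRUE)
  if (length(vcols) < 2L) stop("need at least two treatment replicates to plot")
  if (is.null(pair)) pair <- sub("^value_", "", vcols[1:2])
  ca <- paste0("value_", pair[1L])
  cb <- paste0("value_", pair[2L])
  ok <- !is.na(x$summary[[ca]]) & !is.na(x$summary[[cb]])
  a <- x$summary[[ca]][ok]
  b <- x$summary[[cb]][ok]
  graphics::plot(a, b,
                 xlab = sprintf("log2 fold-change (%s)", pair[1L]),
                 ylab = sprintf("log2 fold-change (%s)", pair[2L]),
                 pch = 16, col = "#00000055", ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  graphics::abline(h = x$thresholds$decrease_cutoff_log2,
                   v = x$thresholds$decrease_cutoff_log2,
                   lty = 3, col = "firebrick")
  if (sum(ok) >= 2L) {
    graphics::legend("topleft", bty = "n",
                     legend = sprintf("r = %.3f (n = %d)",
                                      stats::cor(a, b), sum(ok)))
  }
  invisible(x)
}
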