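#' Apply the localization-probability filter to one replicate
#'
#' Only measurements whose phosphate placement is confidently localized
#' (probability greater than or equal to the threshold) are carried into
#' the cross-replicate summary. The filter is applied per replicate
#' measurement, so a site can pass in one replicate and fail in another.
#' Measurements without a localization probability are removed.
#'
#' @param quant A replicate quantification from [quantify_replicate()].
#' @param threshold Probability threshold in `[0, 1]`; the comparison is
#'   inclusive (`>= threshold` is kept). Default 0.75.
#' @return The filtered replicate quantification.
#' @export
filter_localization <- function(quant, threshold = 0.75) {
  stopifnot(threshold >= 0, threshold <= 1)
  keep <- !is.na(quant$locprob) & quant$locprob >= threshold
  out <- quant[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "experiment_id") <- attr(quant, "experiment_id")
  out
}

#' Aggregate one site's replicate values with protein-normalized precedence
#'
#' The cross-replicate mean for a site is computed from protein-normalized
#' values whenever any replicate provides one; non-normalized values for
#' the same site are then ignored, even if listed. Only when no replicate
#' has a protein-normalized value does the mean fall back to the
#' non-normalized values. The arithmetic mean of log2 fold-changes is used
#' (mean of logs, not log of mean) to damp outliers.
#'
#' @param values_normalized Protein-normalized log2 fold-changes across
#'   replicates (NAs ignored).
#' @param values_unnormalized Oriented, non-normalized log2 fold-changes
#'   across replicates (NAs ignored).
#' @return A list with `mean` (NA if both inputs are empty) and
#'   `used_protein_normalized` (logical flag, NA if no values).
#' @export
aggregate_site <- function(values_normalized, values_unnormalized) {
  vn <- values_normalized[!is.na(values_normalized)]
  vu <- values_unnormalized[!is.na(values_unnormalized)]
  if (length(vn)) {
    list(mean = mean(vn), used_protein_normalized = TRUE)
  } else if (length(vu)) {
    list(mean = mean(vu), used_protein_normalized = FALSE)
  } else {
    list(mean = NA_real_, used_protein_normalized = NA)
  }
}

# per-replicate retained value: normalized when present, else oriented raw
.replicate_value <- function(quant) {
  ifelse(!is.na(quant$log2fc_norm), quant$log2fc_norm, quant$log2fc)
}

#' Build the cross-replicate per-site summary
#'
#' Applies the localization filter to every replicate, then aggregates each
#' site across treatment replicates with the protein-normalized precedence
#' rule of [aggregate_site()]. The control experiment is aggregated by the
#' identical rule. Per-replicate values (normalized when available, raw
#' otherwise) are retained in `value_<experiment>` columns for
#' per-replicate counting and correlation diagnostics. No missing values
#' are imputed.
#'
#' @param treatment_quants List of treatment replicate quantifications.
#' @param control_quant Control quantification, or `NULL`.
#' @param localization_threshold Localization-probability threshold.
#' @param site_meta Optional `data.frame` with `site_id`, `protein_id`,
#'   `position`, `residue`, `sequence_window` to merge into the summary.
#' @return A `data.frame` with one row per site surviving the filter in at
#'   least one experiment: `site_id`, `n_treatment` (replicates quantified
#'   post-filter, 0-3), `mean_log2fc_treatment`, `used_protein_normalized`,
#'   `mean_log2fc_control`, and `value_<id>` columns.
#' @export
build_summary <- function(treatment_quants, control_quant = NULL,
                          localization_threshold = 0.75, site_meta = NULL) {
  tq <- lapply(treatment_quants, filter_localization, localization_threshold)
  cq <- if (!is.null(control_quant)) {
    filter_localization(control_quant, localization_threshold)
  }
  ids <- sort(unique(unlist(c(lapply(tq, function(q) q$site_id),
                              list(if (!is.null(cq)) cq$site_id)))))
  k <- length(tq)
  exp_ids <- vapply(tq, function(q) attr(q, "experiment_id"), character(1L))
  norm_mat <- matrix(NA_real_, length(ids), k)
  unnorm_mat <- matrix(NA_real_, length(ids), k)
  value_mat <- matrix(NA_real_, length(ids), k)
  for (j in seq_len(k)) {
    m <- match(tq[[j]]$site_id, ids)
    norm_mat[m, j] <- tq[[j]]$log2fc_norm
    unnorm_mat[m, j] <- tq[[j]]$log2fc
    value_mat[m, j] <- .replicate_value(tq[[j]])
  }
  n_treat <- rowSums(!is.na(unnorm_mat))
  has_norm <- rowSums(!is.na(norm_mat)) > 0
  mean_t <- ifelse(has_norm,
                   rowMeans(norm_mat, na.rm = TRUE),
                   rowMeans(unnorm_mat, na.rm = TRUE))
  mean_t[n_treat == 0] <- NA_real_
  used_norm <- ifelse(n_treat == 0, NA, has_norm)

  mean_c <- rep(NA_real_, length(ids))
  if (!is.null(cq) && nrow(cq)) {
    m <- match(cq$site_id, ids)
    agg <- mapply(function(vn, vu) aggregate_site(vn, vu)$mean,
                  cq$log2fc_norm, cq$log2fc)
    mean_c[m] <- agg
  }

  out <- data.frame(site_id = ids,
                    n_treatment = as.integer(n_treat),
                    mean_log2fc_treatment = mean_t,
                    used_protein_normalized = used_norm,
                    mean_log2fc_control = mean_c,
                    stringsAsFactors = FALSE)
  for (j in seq_len(k)) out[[paste0("value_", exp_ids[j])]] <- value_mat[, j]
  if (!is.null(site_meta)) {
    meta_cols <- intersect(c("site_id", "protein_id", "position", "residue",
                             "sequence_window"), names(site_meta))
    out <- merge(site_meta[meta_cols], out, by = "site_id", all.y = TRUE,
                 sort = TRUE)
  }
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two replicate experiments
#'
#' Computed on sites quantified in both replicates after localization
#' filtering, using each replicate's retained value (protein-normalized
#' when present, oriented raw otherwise). Inputs are expected to be
#' already filtered (see [filter_localization()]).
#'
#' @param quantA,quantB Replicate quantifications.
#' @return A list with `n_common` (sites quantified in both) and
#'   `pearson_r` (`NA` when fewer than 2 common sites).
#' @export
replicate_correlation <- function(quantA, quantB) {
  common <- intersect(quantA$site_id, quantB$site_id)
  n <- length(common)
  if (n < 2L) {
    return(list(n_common = n, pearson_r = NA_real_))
  }
  va <- .replicate_value(quantA)[match(common, quantA$site_id)]
  vb <- .replicate_value(quantB)[match(common, quantB$site_id)]
  list(n_common = n, pearson_r = stats::cor(va, vb))
}
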