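#' Stringency thresholds for tier classification
#'
#' Defaults follow the screening design: a site is called decreased when its
#' mean log2 fold-change after inhibition is more negative than -1.0 (i.e. a
#' greater-than-2-fold decrease, strict), it is excluded when the wild-type
#' control experiment shows a mean more negative than -1.0 (off-target
#' decrease), and the "strong" subset within the highest tier requires a
#' 4-fold or greater decrease (mean <= -2.0, inclusive). Tiers additionally
#' require quantification in at least 1 (lowest), 2 (medium), or all 3
#' (highest) treatment replicates.
#'
#' @param decrease_cutoff_log2 Treatment mean must be strictly more negative
#'   than this (default -1).
#' @param control_cutoff_log2 Control mean must NOT be more negative than
#'   this (default -1).
#' @param strong_cutoff_log2 Inclusive cutoff for the strong subset
#'   (default -2).
#' @param min_replicates Named integer vector with strictly increasing
#'   minimum replicate counts for `lowest`, `medium`, `highest`.
#' @return An object of class `stringency_thresholds`.
#' @export
stringency_thresholds <- function(decrease_cutoff_log2 = -1,
                                  control_cutoff_log2 = -1,
                                  strong_cutoff_log2 = -2,
                                  min_replicates = c(lowest = 1L, medium = 2L,
                                                     highest = 3L)) {
  if (decrease_cutoff_log2 >= 0 || control_cutoff_log2 >= 0 ||
      strong_cutoff_log2 >= 0) {
    stop("cutoffs must be negative (they encode fold-decreases)")
  }
  if (!all(c("lowest", "medium", "highest") %in% names(min_replicates))) {
    stop("min_replicates must name lowest, medium and highest")
  }
  mr <- as.integer(min_replicates[c("lowest", "medium", "highest")])
  if (any(diff(mr) <= 0L)) {
    stop("min_replicates must be strictly increasing across tiers")
  }
  structure(list(decrease_cutoff_log2 = decrease_cutoff_log2,
                 control_cutoff_log2 = control_cutoff_log2,
                 strong_cutoff_log2 = strong_cutoff_log2,
                 min_replicates = stats::setNames(mr, c("lowest", "medium",
                                                        "highest"))),
            class = "stringency_thresholds")
}

#' Classify sites into nested stringency tiers
#'
#' A site enters a tier when (i) its treatment mean log2 fold-change is
#' strictly more negative than the decrease cutoff, (ii) the control mean is
#' not strictly more negative than the control cutoff (an absent control
#' mean passes — exclusion requires affirmative evidence of an off-target
#' decrease), and (iii) it was quantified in at least the tier's minimum
#' number of treatment replicates. The reported tier is the highest level
#' attained, so highest implies membership of medium and lowest.
#'
#' @param summary Site summary from [build_summary()].
#' @param thresholds A [stringency_thresholds()] object.
#' @return A `data.frame` with `site_id`, `tier` (`"none"`, `"lowest"`,
#'   `"medium"`, `"highest"`), and `excluded_by_control` (TRUE when the
#'   decrease criterion was met but the control exclusion fired).
#' @export
classify_tier <- function(summary, thresholds = stringency_thresholds()) {
  stopifnot(inherits(thresholds, "stringency_thresholds"))
  n <- summary$n_treatment
  mt <- summary$mean_log2fc_treatment
  mc <- summary$mean_log2fc_control
  dec <- !is.na(mt) & mt < thresholds$decrease_cutoff_log2
  ctrl_ok <- is.na(mc) | !(mc < thresholds$control_cutoff_log2)
  mr <- thresholds$min_replicates
  tier <- rep("none", nrow(summary))
  eligible <- dec & ctrl_ok
  tier[eligible & n >= mr["lowest"]] <- "lowest"
  tier[eligible & n >= mr["medium"]] <- "medium"
  tier[eligible & n >= mr["highest"]] <- "highest"
  data.frame(site_id = summary$site_id,
             tier = tier,
             excluded_by_control = dec & !ctrl_ok & n >= mr["lowest"],
             stringsAsFactors = FALSE)
}

#' Rank candidate sites by fold-decrease
#'
#' Sites in any tier are ranked by ascending treatment mean log2
#' fold-change (most negative = rank 1), independent of motif match; ties
#' are broken by lexicographic site id.
#'
#' @param calls Tier calls from [classify_tier()].
#' @param summary Site summary from [build_summary()].
#' @return A ranked `data.frame` (`rank`, `site_id`, `tier`,
#'   `mean_log2fc_treatment`, plus any metadata columns present in the
#'   summary).
#' @export
rank_sites <- function(calls, summary) {
  keep <- calls$tier != "none"
  d <- merge(calls[keep, , drop = FALSE], summary, by = "site_id",
             sort = FALSE)
  o <- order(d$mean_log2fc_treatment, d$site_id)
  d <- d[o, , drop = FALSE]
  d$rank <- seq_len(nrow(d))
  rownames(d) <- NULL
  front <- c("rank", "site_id", "tier", "mean_log2fc_treatment")
  d[c(front, setdiff(names(d), front))]
}

#' Strong subset of the highest-stringency tier
#'
#' Members of the highest tier whose fold-decrease meets the strong cutoff
#' ("4-fold or greater" at the default): mean log2 fold-change less than or
#' equal to `strong_cutoff_log2` (inclusive boundary).
#'
#' @inheritParams rank_sites
#' @param thresholds A [stringency_thresholds()] object.
#' @return The ranked subset (same layout as [rank_sites()]).
#' @export
strong_subset <- function(calls, summary,
                          thresholds = stringency_thresholds()) {
  ranked <- rank_sites(calls, summary)
  out <- ranked[ranked$tier == "highest" &
                  ranked$mean_log2fc_treatment <= thresholds$strong_cutoff_log2,
                , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count sites by number of replicates showing a fold-decrease
#'
#' The per-replicate counting mode: a site counts toward "at least k" when
#' k or more of its individual retained replicate values (post-filter,
#' normalized when available) are strictly below the cutoff, subject to the
#' same control exclusion as the tiers. This is the framing behind counts
#' such as "decreased 2-fold or more in at least one experiment"; the
#' mean-based tier mode of [classify_tier()] is the other framing.
#'
#' @param summary Site summary from [build_summary()].
#' @param fold_cutoff_log2 Strict per-replicate cutoff (default -1).
#' @param control_cutoff_log2 Control-mean exclusion cutoff (default -1).
#' @return Named integer vector `c(at_least_1, at_least_2, all_3)`.
#' @export
count_by_replicate_decrease <- function(summary, fold_cutoff_log2 = -1,
                                        control_cutoff_log2 = -1) {
  vcols <- grep("^value_", names(summary), value = TRUE)
  vm <- as.matrix(summary[vcols])
  n_below <- rowSums(vm < fold_cutoff_log2, na.rm = TRUE)
  mc <- summary$mean_log2fc_control
  ctrl_ok <- is.na(mc) | !(mc < control_cutoff_log2)
  c(at_least_1 = sum(n_below >= 1 & ctrl_ok),
    at_least_2 = sum(n_below >= 2 & ctrl_ok),
    all_3 = sum(n_below >= 3 & ctrl_ok))
}

# round half away from zero at d decimal digits
.round_away <- function(x, d = 0) {
  sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d
}

#' Format a subset count as a percentage in report style
#'
#' The percentage is rounded (half away from zero) to the nearest integer
#' when it is at least 2, and to one decimal place otherwise; a trailing
#' ".0" is dropped. This reproduces report strings such as "4%", "1.5%",
#' "0.7%", and "65%".
#'
#' @param subset_count Numerator count.
#' @param total_count Denominator count; must be positive.
#' @return A list with `percent` (exact value, `100 * subset / total`) and
#'   `display` (formatted string with a percent sign).
#' @export
format_percent <- function(subset_count, total_count) {
  if (total_count <= 0) stop("total_count must be positive")
  if (subset_count < 0 || subset_count > total_count) {
    stop("subset_count must be between 0 and total_count")
  }
  p <- 100 * subset_count / total_count
  if (p >= 2) {
    display <- sprintf("%d%%", as.integer(.round_away(p, 0)))
  } else {
    v <- .round_away(p, 1)
    display <- if (v == as.integer(v)) {
      sprintf("%d%%", as.integer(v))
    } else {
      sprintf("%.1f%%", v)
    }
  }
  list(percent = p, display = display)
}
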