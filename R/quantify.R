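#' Orient a raw heavy/light ratio into a treated-over-control log2 fold-change
#'
#' SILAC ratios are reported as heavy/light. Which label carried the
#' inhibitor-treated culture varies by replicate (one replicate is
#' label-swapped to control for labeling artifacts), so the raw ratio must
#' be oriented before replicates can be compared: with the treated culture
#' in the heavy channel the oriented value is `log2(ratio)`, with the
#' treated culture in the light channel it is `-log2(ratio)`. Negative
#' oriented values always mean decreased phosphorylation (or abundance)
#' after kinase inhibition.
#'
#' @param ratio_hl Raw heavy/light ratio(s); must be positive (NA allowed).
#' @param orientation `"heavy_treated"` or `"light_treated"`.
#' @return Oriented log2 fold-change(s).
#' @examples
#' orient_log2fc(0.25, "heavy_treated")  # -2
#' orient_log2fc(0.25, "light_treated")  # +2
#' @export
orient_log2fc <- function(ratio_hl, orientation) {
  orientation <- match.arg(orientation, c("heavy_treated", "light_treated"))
  if (any(!is.na(ratio_hl) & ratio_hl <= 0)) {
    stop("heavy/light ratios must be positive")
  }
  if (orientation == "heavy_treated") log2(ratio_hl) else -log2(ratio_hl)
}

#' Normalize a phosphosite fold-change to protein abundance
#'
#' A change in phosphopeptide signal can reflect a change in phosphorylation
#' or merely a change in the amount of the protein. Subtracting the
#' protein-level log2 fold-change (division on the linear ratio scale)
#' removes the abundance component, leaving the phosphorylation-specific
#' change. Both inputs must be oriented with the same convention.
#'
#' @param site_log2fc Oriented site-level log2 fold-change(s).
#' @param protein_log2fc Oriented protein-level log2 fold-change(s).
#' @return `site_log2fc - protein_log2fc`.
#' @export
normalize_to_protein <- function(site_log2fc, protein_log2fc) {
  site_log2fc - protein_log2fc
}

#' Quantify one replicate experiment
#'
#' Converts the raw per-experiment ratios of a site table into oriented
#' log2 fold-changes, and — for sites whose protein was quantified in the
#' same experiment — protein-normalized log2 fold-changes. The protein
#' ratio is oriented with the same per-experiment rule before subtraction.
#'
#' @param sites Site table (see [read_phosphosite_table()]).
#' @param proteins Protein table, or `NULL` if protein abundance was not
#'   measured (no values are normalized then).
#' @param design_entry One design row (experiment id, role, orientation).
#' @return A `data.frame` with columns `site_id`, `log2fc` (oriented),
#'   `log2fc_norm` (protein-normalized, `NA` when the protein was not
#'   quantified), and `locprob`; only sites with a ratio in this experiment
#'   are included. The experiment id is attached as attribute
#'   `"experiment_id"`.
#' @export
quantify_replicate <- function(sites, proteins, design_entry) {
  id <- as.character(design_entry$experiment_id)
  orientation <- as.character(design_entry$orientation)
  rcol <- paste0("ratio_", id)
  pcol <- paste0("locprob_", id)
  if (!rcol %in% names(sites)) {
    stop("unknown experiment id '", id, "': column ", rcol,
         " not found in site table")
  }
  s <- sites[!is.na(sites[[rcol]]), , drop = FALSE]
  l2 <- orient_log2fc(s[[rcol]], orientation)
  prot_l2 <- rep(NA_real_, nrow(s))
  if (!is.null(proteins) && rcol %in% names(proteins)) {
    m <- match(s$protein_id, proteins$protein_id)
    prot_l2 <- orient_log2fc(proteins[[rcol]][m], orientation)
  }
  out <- data.frame(
    site_id = s$site_id,
    log2fc = l2,
    log2fc_norm = normalize_to_protein(l2, prot_l2),
    locprob = if (pcol %in% names(s)) s[[pcol]] else rep(NA_real_, nrow(s)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "experiment_id") <- id
  out
}
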