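#' Extract a phospho-centered sequence window
#'
#' Returns the amino-acid context around a phospho-acceptor residue as a
#' fixed-length string centered on the acceptor. Positions falling outside
#' the protein (at either terminus) are filled with the padding character,
#' so the acceptor always sits at the exact center.
#'
#' @param sequence Amino-acid sequence (single uppercase string).
#' @param position 1-based residue index of the phospho-acceptor.
#' @param half_width Number of residues on each side of the acceptor; must be
#'   at least 5 so the window covers the -5 position used by motif matching.
#'   Default 15 (31-residue windows, the width emitted by common site-table
#'   processing software).
#' @param pad Single padding character for positions beyond the termini.
#' @return A string of length `2 * half_width + 1` whose center character is
#'   `substr(sequence, position, position)`.
#' @examples
#' extract_sequence_window("MSTAKQ", 2, half_width = 5)
#' @export
extract_sequence_window <- function(sequence, position, half_width = 15,
                                    pad = "_") {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(pad) == 1L)
  if (half_width < 5) {
    stop("half_width must be >= 5 so windows cover the -5 position")
  }
  n <- nchar(sequence)
  if (is.na(position) || position < 1 || position > n) {
    stop("position ", position, " out of range for sequence of length ", n)
  }
  idx <- (position - half_width):(position + half_width)
  out <- rep(pad, length(idx))
  ok <- idx >= 1 & idx <= n
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  out[ok] <- chars[idx[ok]]
  paste(out, collapse = "")
}

#' Read a proteome from FASTA
#'
#' Sequence ids are the first whitespace-delimited token of each header;
#' sequences are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase amino-acid sequences.
#' @export
read_proteome_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1L), 1L)
  seqs <- toupper(as.character(aa))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate protein id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  stats::setNames(seqs, ids)
}

#' Write a proteome to FASTA
#'
#' @param proteome Named character vector of amino-acid sequences.
#' @param path Output path.
#' @export
write_proteome_fasta <- function(proteome, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteome), path)
  invisible(path)
}

#' Read or validate an experiment design table
#'
#' The design states, per SILAC experiment, its role (`treatment` or
#' `control`) and which label carried the inhibitor-treated culture
#' (`heavy_treated` or `light_treated`). A label-swapped replicate is simply
#' a treatment row with the opposite orientation.
#'
#' @param path Path to a TSV with columns `experiment_id`, `role`,
#'   `orientation`.
#' @return A validated design `data.frame`.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_design(df)
}

#' @rdname read_design
#' @param design A design `data.frame` to validate.
#' @export
validate_design <- function(design) {
  req <- c("experiment_id", "role", "orientation")
  miss <- setdiff(req, names(design))
  if (length(miss)) {
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(design$experiment_id)) {
    stop("duplicate experiment_id in design")
  }
  if (!all(design$role %in% c("treatment", "control"))) {
    stop("design role must be 'treatment' or 'control'")
  }
  if (!all(design$orientation %in% c("heavy_treated", "light_treated"))) {
    stop("design orientation must be 'heavy_treated' or 'light_treated'")
  }
  if (sum(design$role == "treatment") < 1L) {
    stop("design must contain at least one treatment replicate")
  }
  if (sum(design$role == "control") > 1L) {
    stop("design must contain at most one control experiment")
  }
  design
}

#' Write an experiment design table
#'
#' @param design Design `data.frame`.
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  utils::write.table(validate_design(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# shared validation for a standardized site table (native column names)
.validate_sites <- function(df, design, file_rows = NULL) {
  if (is.null(file_rows)) file_rows <- seq_len(nrow(df)) + 1L
  rowmsg <- function(i) paste(file_rows[i], collapse = ", ")

  df$position <- suppressWarnings(as.integer(df$position))
  bad <- which(is.na(df$position) | df$position < 1L)
  if (length(bad)) stop("invalid position in row(s) ", rowmsg(bad))

  bad <- which(!df$residue %in% c("S", "T", "Y"))
  if (length(bad)) stop("residue not one of S/T/Y in row(s) ", rowmsg(bad))

  w <- df$sequence_window
  has_w <- !is.na(w) & nzchar(w)
  bad <- which(has_w & nchar(w) %% 2L == 0L)
  if (length(bad)) stop("even-length sequence window in row(s) ", rowmsg(bad))
  ctr <- substr(w, (nchar(w) + 1L) %/% 2L, (nchar(w) + 1L) %/% 2L)
  bad <- which(has_w & ctr != df$residue)
  if (length(bad)) {
    stop("window center does not match residue in row(s) ", rowmsg(bad))
  }

  for (id in design$experiment_id) {
    rcol <- paste0("ratio_", id)
    r <- suppressWarnings(as.numeric(df[[rcol]]))
    bad <- which(!is.na(df[[rcol]]) & (is.na(r) | r <= 0))
    if (length(bad)) {
      stop("non-positive or non-numeric ratio for experiment '", id,
           "' in row(s) ", rowmsg(bad))
    }
    df[[rcol]] <- r
    pcol <- paste0("locprob_", id)
    p <- suppressWarnings(as.numeric(df[[pcol]]))
    bad <- which(!is.na(df[[pcol]]) & (is.na(p) | p < 0 | p > 1))
    if (length(bad)) {
      stop("localization probability outside [0, 1] for experiment '", id,
           "' in row(s) ", rowmsg(bad))
    }
    df[[pcol]] <- p
  }

  df$site_id <- paste(df$protein_id, df$position, sep = "_")
  if (anyDuplicated(df$site_id)) {
    stop("duplicate phosphosite(s): ",
         paste(unique(df$site_id[duplicated(df$site_id)]), collapse = ", "))
  }
  keep <- c("site_id", "protein_id", "position", "residue", "sequence_window",
            paste0("ratio_", design$experiment_id),
            paste0("locprob_", design$experiment_id))
  rownames(df) <- NULL
  df[keep]
}

#' Read a phosphosite table
#'
#' Two dialects are supported. The `native` dialect is a plain TSV with
#' columns `protein_id`, `position`, `residue`, `sequence_window`, and per
#' experiment `ratio_<id>` (raw heavy/light ratio) and `locprob_<id>`
#' (localization probability) columns. The `maxquant` dialect reads a
#' MaxQuant Phospho(STY)Sites export: `Protein`, `Position`, `Amino acid`,
#' `Sequence window`, per-experiment `Ratio H/L normalized <id>` columns
#' (the multiplicity-1 column `...___1` is used as a fallback), and
#' `Localization prob <id>` (falling back to the global
#' `Localization prob`). Rows flagged `Reverse` or `Potential contaminant`
#' are dropped.
#'
#' @param path Path to the table.
#' @param design Experiment design (see [read_design()]); its experiment ids
#'   select the ratio/localization columns.
#' @param dialect `"native"` or `"maxquant"`.
#' @return A `data.frame` with one row per (protein, position), a
#'   `site_id` column (`"<protein>_<position>"`), and standardized
#'   `ratio_<id>` / `locprob_<id>` columns.
#' @export
read_phosphosite_table <- function(path, design,
                                   dialect = c("native", "maxquant")) {
  dialect <- match.arg(dialect)
  design <- validate_design(design)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("", "NA", "NaN"))
  file_rows <- seq_len(nrow(df)) + 1L

  if (dialect == "native") {
    req <- c("protein_id", "position", "residue", "sequence_window",
             paste0("ratio_", design$experiment_id),
             paste0("locprob_", design$experiment_id))
    miss <- setdiff(req, names(df))
    if (length(miss)) {
      stop("phosphosite table is missing column(s): ",
           paste(miss, collapse = ", "))
    }
    return(.validate_sites(df, design, file_rows))
  }

  # MaxQuant dialect
  req <- c("Protein", "Position", "Amino acid", "Sequence window")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("MaxQuant site table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  drop <- rep(FALSE, nrow(df))
  for (flag in c("Reverse", "Potential contaminant")) {
    if (flag %in% names(df)) drop <- drop | (!is.na(df[[flag]]) & df[[flag]] == "+")
  }
  out <- data.frame(protein_id = df[["Protein"]],
                    position = df[["Position"]],
                    residue = df[["Amino acid"]],
                    sequence_window = df[["Sequence window"]],
                    stringsAsFactors = FALSE)
  for (id in design$experiment_id) {
    rcol <- paste0("Ratio H/L normalized ", id)
    if (!rcol %in% names(df)) rcol <- paste0("Ratio H/L normalized ", id, "___1")
    if (!rcol %in% names(df)) {
      stop("MaxQuant site table is missing ratio column for experiment '",
           id, "'")
    }
    pcol <- paste0("Localization prob ", id)
    if (!pcol %in% names(df)) pcol <- "Localization prob"
    if (!pcol %in% names(df)) {
      stop("MaxQuant site table is missing localization probability column")
    }
    out[[paste0("ratio_", id)]] <- df[[rcol]]
    out[[paste0("locprob_", id)]] <- df[[pcol]]
  }
  out <- out[!drop, , drop = FALSE]
  .validate_sites(out, design, file_rows[!drop])
}

#' Write a phosphosite table in the native dialect
#'
#' @param sites Site table as returned by [read_phosphosite_table()] or
#'   [simulate_experiment()].
#' @param path Output path.
#' @export
write_phosphosite_table <- function(sites, path) {
  out <- sites[setdiff(names(sites), "site_id")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a protein abundance table
#'
#' Native dialect: TSV with a `protein_id` column and one `ratio_<id>`
#' column (raw heavy/light abundance ratio) per experiment in the design.
#'
#' @inheritParams read_phosphosite_table
#' @return `data.frame` with `protein_id` and `ratio_<id>` columns.
#' @export
read_protein_table <- function(path, design) {
  design <- validate_design(design)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("", "NA", "NaN"))
  req <- c("protein_id", paste0("ratio_", design$experiment_id))
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("protein table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$protein_id)) {
    stop("duplicate protein id(s): ",
         paste(unique(df$protein_id[duplicated(df$protein_id)]),
               collapse = ", "))
  }
  for (id in design$experiment_id) {
    rcol <- paste0("ratio_", id)
    r <- suppressWarnings(as.numeric(df[[rcol]]))
    bad <- which(!is.na(df[[rcol]]) & (is.na(r) | r <= 0))
    if (length(bad)) {
      stop("non-positive or non-numeric protein ratio for experiment '", id,
           "' in row(s) ", paste(bad + 1L, collapse = ", "))
    }
    df[[rcol]] <- r
  }
  rownames(df) <- NULL
  df[req]
}

#' Write a protein abundance table in the native dialect
#'
#' @param proteins Protein table.
#' @param path Output path.
#' @export
write_protein_table <- function(proteins, path) {
  utils::write.table(proteins, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
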