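#' Configuration for the synthetic SILAC phosphoproteomics generator
#'
#' Describes the statistical structure of a simulated screening experiment:
#' a random proteome, a set of null phosphosites (no phosphorylation
#' change), a set of planted true substrates with a common log2 effect and
#' consensus-motif windows, log-normal ratio noise, per-replicate
#' missingness, a localization-probability distribution straddling the 0.75
#' filter, and protein-level abundance shifts that confound un-normalized
#' ratios.
#'
#' @param n_proteins Number of proteins in the synthetic proteome.
#' @param protein_length_mean Mean protein length in residues (Poisson,
#'   floored at 11 so every protein admits a centered window).
#' @param n_null_sites Number of phosphosites with true effect 0.
#' @param n_true_substrates Number of planted substrate sites (at most one
#'   per protein, so planted windows never overlap).
#' @param true_effect_log2 Planted log2 fold-change (negative = decreased
#'   phosphorylation after inhibition; default -2, a 4-fold decrease).
#' @param noise_sd_log2 SD of per-replicate site-level log2 ratio noise.
#' @param missing_rate Probability that a site is unquantified in a given
#'   replicate, independently per site and replicate.
#' @param locprob_alpha,locprob_beta Beta shape parameters of the
#'   localization-probability distribution on `[0, 1]`. Defaults (5, 1)
#'   put most sites above 0.75 with a tail below it.
#' @param frac_abundance_shifted_proteins Fraction of proteins given a
#'   protein-level log2 abundance change.
#' @param abundance_shift_log2 Signed log2 abundance change applied to the
#'   shifted proteins (positive = increased abundance after treatment).
#' @param protein_noise_sd_log2 SD of protein-level log2 ratio noise.
#'   Defaults to `noise_sd_log2 / 3`: protein ratios aggregate many
#'   peptides and are correspondingly less variable than single-site
#'   ratios.
#' @param protein_missing_rate Probability a protein is unquantified in a
#'   replicate.
#' @param seed Integer RNG seed; fixes all randomness of the generator
#'   (sub-streams are derived from it by fixed offsets).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 300L, protein_length_mean = 400,
                             n_null_sites = 1000L, n_true_substrates = 50L,
                             true_effect_log2 = -2,
                             noise_sd_log2 = 0.3, missing_rate = 0.1,
                             locprob_alpha = 5, locprob_beta = 1,
                             frac_abundance_shifted_proteins = 0.1,
                             abundance_shift_log2 = 1,
                             protein_noise_sd_log2 = noise_sd_log2 / 3,
                             protein_missing_rate = 0,
                             seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              protein_length_mean = protein_length_mean,
              n_null_sites = as.integer(n_null_sites),
              n_true_substrates = as.integer(n_true_substrates),
              true_effect_log2 = true_effect_log2,
              noise_sd_log2 = noise_sd_log2,
              missing_rate = missing_rate,
              locprob_alpha = locprob_alpha,
              locprob_beta = locprob_beta,
              frac_abundance_shifted_proteins = frac_abundance_shifted_proteins,
              abundance_shift_log2 = abundance_shift_log2,
              protein_noise_sd_log2 = protein_noise_sd_log2,
              protein_missing_rate = protein_missing_rate,
              seed = as.integer(seed))
  counts <- c(cfg$n_proteins, cfg$n_null_sites, cfg$n_true_substrates)
  if (any(is.na(counts)) || any(counts < 0L)) {
    stop("counts must be non-negative")
  }
  if (cfg$protein_length_mean <= 0) stop("protein_length_mean must be positive")
  if (is.na(cfg$missing_rate) || cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (cfg$protein_missing_rate < 0 || cfg$protein_missing_rate >= 1) {
    stop("protein_missing_rate must be in [0, 1)")
  }
  if (cfg$noise_sd_log2 < 0 || cfg$protein_noise_sd_log2 < 0) {
    stop("noise SDs must be non-negative")
  }
  if (cfg$locprob_alpha <= 0 || cfg$locprob_beta <= 0) {
    stop("locprob shape parameters must be positive")
  }
  if (cfg$frac_abundance_shifted_proteins < 0 ||
      cfg$frac_abundance_shifted_proteins > 1) {
    stop("frac_abundance_shifted_proteins must be in [0, 1]")
  }
  if (is.na(cfg$seed)) stop("seed must be an integer")
  structure(cfg, class = "synthetic_config")
}

.AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Generate a random proteome
#'
#' Sequences are uniform over the 20 amino acids (composition is irrelevant
#' to the downstream logic) with Poisson lengths floored at 11 residues.
#'
#' @param config A [synthetic_config()].
#' @return Named character vector of sequences (ids `P0001`, `P0002`, ...).
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  lens <- pmax(11L, stats::rpois(n, config$protein_length_mean))
  seqs <- vapply(lens, function(L) {
    paste(sample(.AMINO_ACIDS, L, replace = TRUE), collapse = "")
  }, character(1L))
  stats::setNames(seqs, sprintf("P%04d", seq_len(n)))
}

#' Plant consensus-motif substrates and choose null sites
#'
#' Chooses `n_true_substrates` acceptor positions (one per protein, at
#' least 6 residues from the N-terminus so the -5 position lies inside the
#' sequence) and rewrites the residues at offsets -5, -3 and 0 so every
#' planted window is a full match to the consensus motif. Null sites are
#' then drawn from the remaining S/T/Y positions of the (edited) proteome.
#' Protein-level abundance shifts are assigned to a random fraction of
#' proteins.
#'
#' @param proteome Named character vector from [generate_proteome()].
#' @param motif A [motif_spec()]; planted residues are drawn from its
#'   allowed sets.
#' @param config A [synthetic_config()].
#' @return An object of class `planted_truth`: list with `proteome` (the
#'   edited sequences), `sites` (`site_id`, `protein_id`, `position`,
#'   `residue`, `true_effect_log2`, `is_substrate`), `protein_shifts`
#'   (named log2 shift per protein, 0 when unshifted), `motif`, `config`.
#' @export
plant_substrates <- function(proteome, motif = motif_spec(), config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  ns <- config$n_true_substrates
  eligible <- names(proteome)[nchar(proteome) >= 6L]
  if (length(eligible) < ns) {
    stop("insufficient eligible positions: ", length(eligible),
         " proteins admit a planted window but ", ns, " substrates requested")
  }
  sub_prot <- if (ns > 0L) sample(eligible, ns) else character(0L)
  sub_pos <- vapply(sub_prot, function(p) {
    len <- nchar(proteome[[p]])
    if (len == 6L) 6L else sample(6:len, 1L)
  }, integer(1L))

  if (ns > 0L) {
    r5 <- sample(motif[["-5"]], ns, replace = TRUE)
    r3 <- sample(motif[["-3"]], ns, replace = TRUE)
    r0 <- sample(motif[["0"]], ns, replace = TRUE)
    for (i in seq_len(ns)) {
      s <- proteome[[sub_prot[i]]]
      substr(s, sub_pos[i] - 5L, sub_pos[i] - 5L) <- r5[i]
      substr(s, sub_pos[i] - 3L, sub_pos[i] - 3L) <- r3[i]
      substr(s, sub_pos[i], sub_pos[i]) <- r0[i]
      proteome[[sub_prot[i]]] <- s
    }
  }

  # null sites: S/T/Y positions of the edited proteome, excluding substrates
  sty <- lapply(proteome, function(s) {
    which(strsplit(s, "", fixed = TRUE)[[1L]] %in% c("S", "T", "Y"))
  })
  cand <- data.frame(protein_id = rep(names(proteome), lengths(sty)),
                     position = unlist(sty, use.names = FALSE),
                     stringsAsFactors = FALSE)
  if (nrow(cand)) {
    sub_ids <- paste(sub_prot, sub_pos, sep = "_")
    cand <- cand[!paste(cand$protein_id, cand$position, sep = "_") %in% sub_ids,
                 , drop = FALSE]
  }
  if (nrow(cand) < config$n_null_sites) {
    stop("insufficient S/T/Y positions for ", config$n_null_sites,
         " null sites")
  }
  pick <- if (config$n_null_sites > 0L) {
    sample(nrow(cand), config$n_null_sites)
  } else integer(0L)
  nulls <- cand[pick, , drop = FALSE]

  res_at <- function(prot, pos) {
    substr(proteome[prot], pos, pos)
  }
  sites <- data.frame(
    protein_id = c(sub_prot, nulls$protein_id),
    position = c(unname(sub_pos), nulls$position),
    stringsAsFactors = FALSE)
  sites$site_id <- paste(sites$protein_id, sites$position, sep = "_")
  sites$residue <- mapply(res_at, sites$protein_id, sites$position,
                          USE.NAMES = FALSE)
  sites$true_effect_log2 <- c(rep(config$true_effect_log2, ns),
                              rep(0, nrow(nulls)))
  sites$is_substrate <- c(rep(TRUE, ns), rep(FALSE, nrow(nulls)))
  o <- order(sites$site_id)
  sites <- sites[o, c("site_id", "protein_id", "position", "residue",
                      "true_effect_log2", "is_substrate")]
  rownames(sites) <- NULL

  shifts <- stats::setNames(rep(0, length(proteome)), names(proteome))
  n_shift <- round(config$frac_abundance_shifted_proteins * length(proteome))
  if (n_shift > 0L) {
    shifts[sample(names(proteome), n_shift)] <- config$abundance_shift_log2
  }

  structure(list(proteome = proteome, sites = sites,
                 protein_shifts = shifts, motif = motif, config = config),
            class = "planted_truth")
}

#' Default replicate design of the screening experiment
#'
#' Three treatment replicates — two with the inhibitor-treated culture in
#' the heavy channel and one label-swapped — plus one wild-type control
#' experiment (inhibitor analog applied to cells without the
#' analog-sensitive allele).
#'
#' @return A design `data.frame` (see [read_design()]).
#' @export
default_design <- function() {
  validate_design(data.frame(
    experiment_id = c("R1", "R2", "R3", "C"),
    role = c("treatment", "treatment", "treatment", "control"),
    orientation = c("heavy_treated", "heavy_treated", "light_treated",
                    "heavy_treated"),
    stringsAsFactors = FALSE))
}

#' Simulate SILAC site and protein tables from a planted truth
#'
#' For each experiment, every site's oriented log2 fold-change is its true
#' effect (treatment replicates only) plus the protein's abundance shift
#' plus Gaussian noise; the emitted raw heavy/light ratio is the oriented
#' value folded back through the experiment's label orientation, so the
#' label-swapped replicate carries reciprocal raw ratios. Sites are
#' independently missing per replicate, and localization probabilities are
#' Beta-distributed. Protein tables carry the abundance shifts plus
#' protein-level noise.
#'
#' @param truth A [plant_substrates()] result.
#' @param design Experiment design; default [default_design()].
#' @param config Generator configuration; defaults to the one stored in
#'   `truth`.
#' @return A list with `sites` (native-dialect site table including
#'   31-residue windows), `proteins` (native-dialect protein table),
#'   `design`, and `truth`.
#' @export
simulate_experiment <- function(truth, design = default_design(),
                                config = truth$config) {
  stopifnot(inherits(truth, "planted_truth"),
            inherits(config, "synthetic_config"))
  design <- validate_design(design)
  set.seed(config$seed + 2L)
  sites <- truth$sites
  nsite <- nrow(sites)
  prots <- names(truth$proteome)

  tab <- data.frame(site_id = sites$site_id,
                    protein_id = sites$protein_id,
                    position = sites$position,
                    residue = sites$residue,
                    sequence_window = vapply(seq_len(nsite), function(i) {
                      extract_sequence_window(truth$proteome[[sites$protein_id[i]]],
                                              sites$position[i])
                    }, character(1L)),
                    stringsAsFactors = FALSE)
  ptab <- data.frame(protein_id = prots, stringsAsFactors = FALSE)

  shift <- truth$protein_shifts[sites$protein_id]
  for (i in seq_len(nrow(design))) {
    id <- design$experiment_id[i]
    treated <- design$role[i] == "treatment"
    mu <- (if (treated) sites$true_effect_log2 else 0) + shift
    l2 <- mu + stats::rnorm(nsite, 0, config$noise_sd_log2)
    ratio <- if (design$orientation[i] == "heavy_treated") 2^l2 else 2^(-l2)
    miss <- stats::runif(nsite) < config$missing_rate
    ratio[miss] <- NA_real_
    locprob <- stats::rbeta(nsite, config$locprob_alpha, config$locprob_beta)
    locprob[miss] <- NA_real_
    tab[[paste0("ratio_", id)]] <- ratio
    tab[[paste0("locprob_", id)]] <- locprob

    pl2 <- truth$protein_shifts +
      stats::rnorm(length(prots), 0, config$protein_noise_sd_log2)
    pratio <- if (design$orientation[i] == "heavy_treated") 2^pl2 else 2^(-pl2)
    pmiss <- stats::runif(length(prots)) < config$protein_missing_rate
    pratio[pmiss] <- NA_real_
    ptab[[paste0("ratio_", id)]] <- unname(pratio)
  }
  rownames(tab) <- rownames(ptab) <- NULL
  list(sites = tab, proteins = ptab, design = design, truth = truth)
}

#' Write the planted truth as TSV
#'
#' @param truth A [plant_substrates()] result.
#' @param path Output path; columns `site_id`, `true_effect_log2`.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth$sites[c("site_id", "true_effect_log2")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate single-cell length/width time series
#'
#' Per-cell linear elongation and widening trends plus Gaussian measurement
#' noise, as fixtures for the growth-rate estimators. Baseline lengths and
#' widths vary between cells; times are sampled every `interval` minutes.
#'
#' @param n_cells Number of cells.
#' @param elongation_rate True length slope, micrometers per minute.
#' @param widening_rate True width slope, micrometers per minute.
#' @param noise_sd SD of measurement noise, micrometers.
#' @param duration Total imaging time, minutes.
#' @param seed Integer RNG seed.
#' @param interval Sampling interval, minutes (default 4).
#' @return `data.frame` with `cell_id`, `time`, `length`, `width`.
#' @export
generate_phenotype_series <- function(n_cells, elongation_rate,
                                      widening_rate, noise_sd, duration,
                                      seed = 1L, interval = 4) {
  stopifnot(is.finite(elongation_rate), is.finite(widening_rate),
            duration > 0, noise_sd >= 0, n_cells >= 0)
  set.seed(as.integer(seed))
  times <- seq(0, duration, by = interval)
  out <- lapply(seq_len(n_cells), function(i) {
    l0 <- 8 + stats::runif(1, -1, 1)
    w0 <- 3.8 + stats::runif(1, -0.2, 0.2)
    data.frame(cell_id = sprintf("cell%03d", i),
               time = times,
               length = l0 + elongation_rate * times +
                 stats::rnorm(length(times), 0, noise_sd),
               width = w0 + widening_rate * times +
                 stats::rnorm(length(times), 0, noise_sd),
               stringsAsFactors = FALSE)
  })
  if (!length(out)) {
    return(data.frame(cell_id = character(0L), time = numeric(0L),
                      length = numeric(0L), width = numeric(0L)))
  }
  do.call(rbind, out)
}
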