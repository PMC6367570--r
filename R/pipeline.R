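#' Read a run configuration from a flat YAML key/value file
#'
#' Recognized keys (all optional unless noted): `mode`
#' (`"analyze"` or `"simulate-and-analyze"`; required), `output_dir`
#' (required), `site_table`, `protein_table`, `proteome_fasta`,
#' `design_table`, `term_map`, `universe` (paths, required in analyze
#' mode except `protein_table`/`term_map`), `motif` (motif grammar string,
#' e.g. `"-5:H; -3:RHK; 0:ST"`), `localization_threshold`,
#' `decrease_cutoff_log2`, `control_cutoff_log2`, `strong_cutoff_log2`,
#' `seed`, plus any [synthetic_config()] field for simulate mode.
#'
#' @param path Path to the YAML file.
#' @return A named list suitable for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("run configuration must be a key/value mapping")
  cfg
}

.pipeline_defaults <- function(config) {
  defs <- list(mode = "analyze", localization_threshold = 0.75,
               decrease_cutoff_log2 = -1, control_cutoff_log2 = -1,
               strong_cutoff_log2 = -2, motif = "-5:H; -3:RHK; 0:ST",
               seed = 1L)
  utils::modifyList(defs, config)
}

#' Run the end-to-end screening pipeline
#'
#' Orchestrates quantify, filter, summarize, tier, rank, motif and
#' (optionally) enrichment, writing every result table plus a run report
#' and a stage log under `output_dir`. In `simulate-and-analyze` mode the
#' inputs are generated by the synthetic-data module (and written alongside
#' the outputs); in `analyze` mode they are read from the configured paths.
#' Given a fixed seed and inputs the run is deterministic, byte for byte.
#'
#' @param config Named list (see [read_run_config()]) or a path to a YAML
#'   configuration file.
#' @return Invisibly, the [kinase_screen()] object.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  cfg <- .pipeline_defaults(config)
  if (is.null(cfg$output_dir)) stop("config: output_dir is required")
  mode <- match.arg(cfg$mode, c("analyze", "simulate-and-analyze"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$output_dir, "run.log")
  log_lines <- character(0L)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  if (mode == "simulate-and-analyze") {
    sc_fields <- names(formals(synthetic_config))
    sc_args <- cfg[intersect(names(cfg), sc_fields)]
    sc_args$seed <- cfg$seed
    scfg <- do.call(synthetic_config, sc_args)
    motif <- parse_motif_spec(cfg$motif)
    truth <- plant_substrates(generate_proteome(scfg), motif, scfg)
    sim <- simulate_experiment(truth, config = scfg)
    sites <- sim$sites
    proteins <- sim$proteins
    design <- sim$design
    write_proteome_fasta(truth$proteome,
                         file.path(cfg$output_dir, "proteome.fasta"))
    write_truth(truth, file.path(cfg$output_dir, "truth.tsv"))
    write_phosphosite_table(sites, file.path(cfg$output_dir, "sites.tsv"))
    write_protein_table(proteins, file.path(cfg$output_dir, "proteins.tsv"))
    write_design(design, file.path(cfg$output_dir, "design.tsv"))
    say("simulate: %d proteins, %d sites (%d planted substrates), seed %d",
        scfg$n_proteins, nrow(sites), scfg$n_true_substrates, scfg$seed)
  } else {
    design <- read_design(cfg$design_table)
    sites <- read_phosphosite_table(cfg$site_table, design,
                                    dialect = cfg$dialect %||% "native")
    proteins <- if (!is.null(cfg$protein_table)) {
      read_protein_table(cfg$protein_table, design)
    }
    motif <- parse_motif_spec(cfg$motif)
    say("read: %d sites, %d proteins, %d experiments", nrow(sites),
        if (is.null(proteins)) 0L else nrow(proteins), nrow(design))
  }

  thresholds <- stringency_thresholds(
    decrease_cutoff_log2 = cfg$decrease_cutoff_log2,
    control_cutoff_log2 = cfg$control_cutoff_log2,
    strong_cutoff_log2 = cfg$strong_cutoff_log2)
  scr <- kinase_screen(sites, proteins, design,
                       localization_threshold = cfg$localization_threshold,
                       thresholds = thresholds, motif = motif)
  say("quantify: %d of %d sites quantified in >= 1 experiment",
      scr$counts["n_quantified"], scr$counts["n_input_sites"])
  say("filter: %d sites pass localization >= %.2f in >= 1 experiment",
      scr$counts["n_post_filter"], cfg$localization_threshold)
  say("tier: lowest %d, medium %d, highest %d (control-excluded %d)",
      scr$tier_counts["lowest"], scr$tier_counts["medium"],
      scr$tier_counts["highest"], scr$counts["n_excluded_by_control"])
  say("rank: %d candidate sites ranked, strong subset %d",
      nrow(scr$ranked), nrow(scr$strong))
  say("motif: %d full consensus, %d basic -3 only among ranked candidates",
      scr$motif$counts["full_consensus"],
      scr$motif$counts["basic_minus3_only"])

  if (!is.null(cfg$term_map) && !is.null(cfg$universe)) {
    universe <- readLines(cfg$universe)
    tmap <- read_term_map(cfg$term_map, universe)
    cluster <- unique(scr$ranked$protein_id)
    enr <- enrich_terms(cluster, tmap)
    utils::write.table(enr, file.path(cfg$output_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("enrichment: %d terms tested on a cluster of %d genes",
        nrow(enr), length(cluster))
  }

  write_report(scr, cfg$output_dir)
  say("report: written to %s", cfg$output_dir)
  writeLines(log_lines, log_path)
  invisible(scr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the result tables and run report of a screen
#'
#' Writes `summary.tsv` (per-site summary), one TSV per stringency tier
#' mirroring nested workbook tabs (`tier_lowest.tsv`, `tier_medium.tsv`,
#' `tier_highest.tsv`), `ranked_sites.tsv`, `strong_subset.tsv`,
#' `motif_calls.tsv`, a machine-readable `report.tsv` (key/value) and a
#' human-readable `report.txt`. Empty tiers yield files with a header and
#' zero rows; every percentage goes through [format_percent()]. Reports
#' contain no timestamps, so identical screens produce identical bytes.
#'
#' @param screen A [kinase_screen()] object.
#' @param output_dir Output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_report <- function(screen, output_dir) {
  stopifnot(inherits(screen, "kinase_screen"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, file) {
    utils::write.table(df, file.path(output_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  wt(screen$summary, "summary.tsv")
  for (tier in c("lowest", "medium", "highest")) {
    member <- switch(tier,
                     lowest = screen$ranked$tier != "none",
                     medium = screen$ranked$tier %in% c("medium", "highest"),
                     highest = screen$ranked$tier == "highest")
    wt(screen$ranked[member, , drop = FALSE], paste0("tier_", tier, ".tsv"))
  }
  wt(screen$ranked, "ranked_sites.tsv")
  wt(screen$strong, "strong_subset.tsv")
  if (!is.null(screen$motif$calls)) wt(screen$motif$calls, "motif_calls.tsv")

  nq <- screen$counts["n_quantified"]
  rd <- screen$replicate_decrease_counts
  kv <- rbind(
    data.frame(key = names(screen$counts), value = unname(screen$counts)),
    data.frame(key = paste0("tier_", names(screen$tier_counts)),
               value = unname(screen$tier_counts)),
    data.frame(key = paste0("decrease_", names(rd)), value = unname(rd)),
    data.frame(key = paste0("decrease_pct_", names(rd)),
               value = vapply(rd, function(k) {
                 if (nq > 0) format_percent(k, nq)$display else ""
               }, character(1L))),
    data.frame(key = paste0("motif_", names(screen$motif$counts)),
               value = unname(screen$motif$counts)),
    data.frame(key = paste0("strong_motif_", names(screen$strong_motif$counts)),
               value = unname(screen$strong_motif$counts)),
    data.frame(key = "n_strong", value = nrow(screen$strong))
  )
  if (nrow(screen$correlations)) {
    kv <- rbind(kv, data.frame(
      key = sprintf("pearson_r_%s_%s", screen$correlations$experiment_a,
                    screen$correlations$experiment_b),
      value = sprintf("%.6f", screen$correlations$pearson_r)))
  }
  wt(kv, "report.tsv")
  txt <- utils::capture.output({
    print(screen)
    print(summary(screen))
  })
  writeLines(txt, file.path(output_dir, "report.txt"))
  invisible(output_dir)
}
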