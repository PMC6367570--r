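#' NDR/LATS consensus motif specification
#'
#' Positional residue-class constraints relative to the phospho-acceptor at
#' offset 0. The default encodes the NDR/LATS consensus HxR/H/KxxS/T:
#' histidine at -5, a basic residue (H, R, or K) at -3, and a serine or
#' threonine acceptor at 0. Offsets -4, -2 and -1 are unconstrained.
#'
#' @param minus5 Allowed residues at offset -5.
#' @param minus3 Allowed residues at offset -3 ("basic amino acid": H, R, K).
#' @param acceptor Allowed phospho-acceptor residues at offset 0.
#' @return An object of class `motif_spec`: a list mapping offsets `-5`,
#'   `-3`, `0` to allowed residue sets.
#' @export
motif_spec <- function(minus5 = "H", minus3 = c("H", "R", "K"),
                       acceptor = c("S", "T")) {
  spec <- list(`-5` = minus5, `-3` = minus3, `0` = acceptor)
  for (off in names(spec)) {
    res <- spec[[off]]
    if (!length(res) || !all(res %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]])) {
      stop("allowed residues at offset ", off,
           " must be a non-empty subset of the 20 amino acids")
    }
  }
  structure(spec, class = "motif_spec")
}

#' Parse a motif specification from its text grammar
#'
#' Grammar: semicolon-separated `offset:RESIDUES` fields, e.g.
#' `"-5:H; -3:RHK; 0:ST"`. Offsets -5, -3 and 0 must all be present.
#'
#' @param text Specification string.
#' @return A [motif_spec()] object.
#' @export
parse_motif_spec <- function(text) {
  parts <- strsplit(text, ";", fixed = TRUE)[[1L]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, ":", fixed = TRUE)
  if (any(lengths(kv) != 2L)) {
    stop("malformed motif grammar; expected 'offset:RESIDUES' fields")
  }
  offs <- trimws(vapply(kv, `[[`, character(1L), 1L))
  res <- trimws(vapply(kv, `[[`, character(1L), 2L))
  names(res) <- offs
  need <- c("-5", "-3", "0")
  if (!all(need %in% offs)) {
    stop("motif grammar must constrain offsets -5, -3 and 0")
  }
  motif_spec(minus5 = strsplit(res[["-5"]], "")[[1L]],
             minus3 = strsplit(res[["-3"]], "")[[1L]],
             acceptor = strsplit(res[["0"]], "")[[1L]])
}

#' Classify sequence windows against the consensus motif
#'
#' Evaluates, per window, whether the -5 position is histidine (per the
#' spec), the -3 position is basic, and the acceptor is S/T, and assigns a
#' category: `full_consensus` (all three), `basic_minus3_only` (basic -3
#' and acceptor but no -5 histidine), or `no_match`. The terminal padding
#' character fails every residue constraint: a site too close to the
#' N-terminus cannot match positions outside the protein.
#'
#' @param window Centered sequence window string(s); odd length, long
#'   enough to cover offset -5.
#' @param spec A [motif_spec()] object.
#' @return A `data.frame` with logical columns `minus5_his`, `minus3_basic`,
#'   `acceptor_ok` and a `category` column.
#' @examples
#' classify_window("HARAASAAAAA")  # full_consensus
#' @export
classify_window <- function(window, spec = motif_spec()) {
  n <- nchar(window)
  if (any(n %% 2L == 0L)) stop("sequence windows must have odd length")
  center <- (n + 1L) %/% 2L
  if (any(center - 5L < 1L)) {
    stop("window too short to cover the -5 position")
  }
  at <- function(off) substr(window, center + off, center + off)
  m5 <- at(-5L) %in% spec[["-5"]]
  m3 <- at(-3L) %in% spec[["-3"]]
  acc <- at(0L) %in% spec[["0"]]
  category <- ifelse(m5 & m3 & acc, "full_consensus",
                     ifelse(m3 & acc & !m5, "basic_minus3_only", "no_match"))
  data.frame(minus5_his = m5, minus3_basic = m3, acceptor_ok = acc,
             category = category, stringsAsFactors = FALSE)
}

#' Annotate a set of sites with motif calls and category counts
#'
#' @param sites `data.frame` with `site_id` and `sequence_window` columns
#'   (e.g. a ranked tier table carrying summary metadata).
#' @param spec A [motif_spec()] object.
#' @return A list with `calls` (per-site motif calls; sites with a missing
#'   window get category `NA` and are reported via a warning) and `counts`
#'   (named counts over `full_consensus`, `basic_minus3_only`, `no_match`).
#' @export
annotate_sites <- function(sites, spec = motif_spec()) {
  w <- sites$sequence_window
  ok <- !is.na(w) & nzchar(w)
  calls <- data.frame(site_id = sites$site_id,
                      minus5_his = NA, minus3_basic = NA, acceptor_ok = NA,
                      category = NA_character_, stringsAsFactors = FALSE)
  if (any(ok)) {
    cw <- classify_window(w[ok], spec)
    calls[ok, c("minus5_his", "minus3_basic", "acceptor_ok", "category")] <- cw
  }
  if (any(!ok)) {
    warning("unclassified site(s) without a sequence window: ",
            paste(sites$site_id[!ok], collapse = ", "))
  }
  cats <- c("full_consensus", "basic_minus3_only", "no_match")
  counts <- stats::setNames(
    vapply(cats, function(cc) sum(calls$category == cc, na.rm = TRUE),
           integer(1L)),
    cats)
  list(calls = calls, counts = counts)
}

#' Read a flat term-to-gene annotation map
#'
#' @param path Two-column TSV (`term_id`, `gene_id`); the map is taken as
#'   already propagated (no ontology-graph inheritance is performed).
#' @param universe Character vector of gene ids forming the genome universe.
#' @return An object of class `term_map`: list with `terms` (term id ->
#'   gene id set) and `universe`.
#' @export
read_term_map <- function(path, universe) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("term_id", "gene_id") %in% names(df))) {
    stop("term map must have columns term_id and gene_id")
  }
  term_map(split(df$gene_id, df$term_id), universe)
}

#' @rdname read_term_map
#' @param terms Named list mapping term id to a character vector of gene ids.
#' @export
term_map <- function(terms, universe) {
  universe <- unique(as.character(universe))
  terms <- lapply(terms, function(g) unique(as.character(g)))
  bad <- unlist(lapply(terms, setdiff, universe))
  if (length(bad)) {
    stop("annotated gene(s) missing from universe: ",
         paste(unique(bad), collapse = ", "))
  }
  structure(list(terms = terms, universe = universe), class = "term_map")
}

#' Hypergeometric upper-tail probability for term enrichment
#'
#' Exact probability of observing `k` or more annotated genes in a cluster
#' of size `n` drawn without replacement from a universe of `N` genes of
#' which `K` are annotated: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k Annotated genes observed in the cluster.
#' @param K Annotated genes in the universe.
#' @param n Cluster size.
#' @param N Universe size.
#' @return Upper-tail probability in `[0, 1]`. Vectorized.
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0 | k > pmin(n, K) | n > N | K > N)) {
    stop("inconsistent counts: need 0 <= k <= min(n, K) and n, K <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term fold-enrichment with hypergeometric significance
#'
#' Fold-enrichment of a term is the ratio of its frequency within the gene
#' cluster to its frequency within the genome universe:
#' `(k / n) / (K / N)`. Significance is the exact hypergeometric upper tail.
#' Terms annotating no gene in the universe are skipped. Raw p-values are
#' reported; an optional Bonferroni correction across the tested terms can
#' be added (off by default, and flagged in the output).
#'
#' @param cluster Non-empty character vector of gene ids, a subset of the
#'   universe.
#' @param map A [term_map()] object.
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return `data.frame` with columns `term_id`, `k`, `n`, `K`, `N`, `fold`,
#'   `p`, and `p_adjusted` (equal to `p` when `adjust = "none"`), sorted by
#'   `p`; attribute `"adjust"` records the correction used.
#' @export
enrich_terms <- function(cluster, map, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(map, "term_map"))
  cluster <- unique(as.character(cluster))
  if (!length(cluster)) stop("cluster must be non-empty")
  if (!all(cluster %in% map$universe)) {
    stop("cluster gene(s) missing from universe: ",
         paste(setdiff(cluster, map$universe), collapse = ", "))
  }
  N <- length(map$universe)
  n <- length(cluster)
  Ks <- lengths(map$terms)
  keep <- Ks > 0
  terms <- names(map$terms)[keep]
  Ks <- Ks[keep]
  ks <- vapply(map$terms[keep],
               function(g) length(intersect(cluster, g)), integer(1L))
  fold <- (ks / n) / (Ks / N)
  p <- hypergeom_pvalue(ks, Ks, n, N)
  out <- data.frame(term_id = terms, k = ks, n = n, K = as.integer(Ks),
                    N = N, fold = fold, p = p,
                    p_adjusted = if (adjust == "bonferroni") {
                      stats::p.adjust(p, method = "bonferroni")
                    } else p,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "adjust") <- adjust
  out
}
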