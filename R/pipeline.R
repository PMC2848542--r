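# a length-1 unnamed character is taken as a file path; named character
# vectors are in-memory data (sample -> label, gene -> sequence)
.is_path <- function(x) is.character(x) && length(x) == 1 && is.null(names(x))

# High-level orchestration tying the stages into the standard workflow:
# expression -> gene scores -> reporter metabolites -> motif enrichment,
# plus cross-contrast comparison. Each runner accepts in-memory objects or
# file paths and records its parameters in a manifest for reproducible
# re-runs.

#' Run the reporter-metabolite stage
#'
#' Computes gene scores from probe expression (or ingests precomputed gene
#' scores) and scores every metabolite of the network.
#'
#' @param network a `MetabolicNetwork` or path to a network TSV.
#' @param expr probe x sample matrix or path to an expression TSV. Ignored
#'   when `gene_scores` is given.
#' @param groups named character vector (sample -> label) or path to a
#'   two-column TSV (`sample`, `group`).
#' @param contrast length-2 character vector `(label1, label2)`.
#' @param probe_map optional probe map data.frame or path.
#' @param gene_scores optional precomputed `GeneScore` table or path,
#'   bypassing the differential-expression step.
#' @param params a [reporter_params()].
#' @param method differential-expression method, see
#'   [differential_expression()].
#' @param out optional path for the score TSV.
#' @return the metabolite score table, with a `manifest` attribute
#'   recording parameters.
#' @export
run_reporter_analysis <- function(network, expr = NULL, groups = NULL,
                                  contrast = NULL, probe_map = NULL,
                                  gene_scores = NULL,
                                  params = reporter_params(),
                                  method = "moderated", out = NULL) {
  if (is.character(network)) network <- load_network(network, "tsv")
  if (is.character(probe_map)) probe_map <- read_probe_map(probe_map)
  if (is.null(gene_scores)) {
    if (is.character(expr)) expr <- read_expression(expr)
    if (.is_path(groups)) {
      g <- utils::read.delim(groups, colClasses = "character")
      groups <- stats::setNames(g$group, g$sample)
    }
    probes <- differential_expression(expr, groups, contrast, method = method,
                                      probe_map = probe_map)
    gene_scores <- summarize_probes(probes)
  } else if (is.character(gene_scores)) {
    gene_scores <- read_gene_scores(gene_scores)
  }
  scores <- score_metabolites(network, gene_scores, params = params)
  attr(scores, "manifest") <- list(
    seed = params$seed, alpha = params$alpha,
    n_background_samples = params$n_background_samples,
    exhaustive_limit = params$exhaustive_limit, method = method,
    contrast = contrast)
  if (!is.null(out)) write_reporter_tsv(scores, out)
  scores
}

#' Run the motif-enrichment stage
#'
#' Selects the up/down neighbor gene sets of the reporter metabolites and
#' tests them for motif enrichment against the network's remaining genes.
#'
#' @param scores metabolite score table from [run_reporter_analysis()].
#' @param network a `MetabolicNetwork` or network TSV path (supplies the
#'   background gene universe).
#' @param promoters named character vector or promoter FASTA path.
#' @param pfms list of PFMs or TRANSFAC file path.
#' @param alpha reporter threshold (default 0.05).
#' @param min_size minimum gene-set size (default 5).
#' @param threshold_frac scan threshold fraction (default 0.7).
#' @param q_cutoff significance threshold on q (default 0.05).
#' @param bg_order background Markov order (default 2).
#' @param out optional path for the enrichment TSV.
#' @return the enrichment table (possibly empty, with a warning, when no
#'   set reaches `min_size`).
#' @export
run_motif_enrichment <- function(scores, network, promoters, pfms,
                                 alpha = 0.05, min_size = 5,
                                 threshold_frac = 0.7, q_cutoff = 0.05,
                                 bg_order = 2, out = NULL) {
  if (is.character(network)) network <- load_network(network, "tsv")
  if (.is_path(promoters)) promoters <- read_promoters(promoters)
  if (is.character(pfms)) pfms <- parse_transfac(pfms)
  sets <- select_gene_sets(scores, alpha = alpha, min_size = min_size)
  if (!length(sets)) {
    warning("no reporter metabolite has ", min_size,
            " up- or down-regulated neighbor genes: empty enrichment")
    res <- .empty_enrichment()
  } else {
    all_genes <- sort(unique(unlist(network$gene_associations)))
    res <- enrich_motifs(sets, promoters, pfms,
                         background_gene_ids = all_genes,
                         bg_order = bg_order, threshold_frac = threshold_frac,
                         min_size = min_size, q_cutoff = q_cutoff)
  }
  if (!is.null(out))
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  res
}

#' Compare reporter sets across contrasts
#'
#' Thin wrapper over [call_reporters()] and [cluster_contrasts()]: extracts
#' each contrast's reporter metabolite set at `alpha` and clusters the
#' pairwise Jaccard distances.
#'
#' @param score_tables named list of metabolite score tables, one per
#'   contrast.
#' @param alpha reporter threshold (default 0.05).
#' @param linkage linkage method (default `"average"`).
#' @return as [cluster_contrasts()], plus `reporter_sets`.
#' @export
compare_contrasts <- function(score_tables, alpha = 0.05,
                              linkage = "average") {
  sets <- lapply(score_tables, function(s) call_reporters(s, alpha)$metabolite_id)
  res <- cluster_contrasts(sets, linkage = linkage)
  res$reporter_sets <- sets
  res
}
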