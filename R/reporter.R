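# Reporter metabolite scoring.
#
# Each metabolite is scored from its k neighbor enzymes: gene p-values are
# mapped to Z-scores through the inverse normal CDF, aggregated as
# sum(Z)/sqrt(k), and corrected against the null distribution of the same
# aggregate over random size-k enzyme sets drawn from the whole network
# (exhaustively enumerated when feasible, Monte-Carlo otherwise). The
# corrected Z maps back to a p-value through the normal CDF; metabolites at
# p <= alpha are called reporters.

#' Parameters for reporter scoring
#'
#' @param n_background_samples Monte-Carlo draws per neighborhood size k
#'   (default 10000).
#' @param alpha reporter call threshold on the corrected p-value (default
#'   0.05; the boundary is inclusive).
#' @param p_clamp p-values are clamped to `[p_clamp, 1 - p_clamp]` before
#'   the inverse-normal transform so Z stays finite (default 1e-15).
#' @param seed integer seed for the background sampling stream.
#' @param exhaustive_limit enumerate all k-subsets exactly whenever
#'   `choose(n, k)` does not exceed this (default 200000); set to 0 to force
#'   Monte-Carlo.
#' @return A list of class `reporter_params`.
#' @export
reporter_params <- function(n_background_samples = 10000, alpha = 0.05,
                            p_clamp = 1e-15, seed = 1L,
                            exhaustive_limit = 200000) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_background_samples < 1000)
    stop("n_background_samples must be at least 1000")
  if (p_clamp <= 0 || p_clamp >= 0.5) stop("p_clamp must lie in (0, 0.5)")
  structure(list(n_background_samples = as.integer(n_background_samples),
                 alpha = alpha, p_clamp = p_clamp, seed = as.integer(seed),
                 exhaustive_limit = exhaustive_limit),
            class = "reporter_params")
}

#' Inverse-normal transform of p-values
#'
#' Maps a p-value to `qnorm(1 - p)`: smaller p gives larger Z. Values
#' outside `[p_clamp, 1 - p_clamp]` are clamped with a warning so the
#' result stays finite (`p = 1` maps to a large negative Z, not `-Inf`).
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @param p_clamp clamping epsilon (default 1e-15).
#' @return numeric vector of Z-scores.
#' @export
p_to_z <- function(p, p_clamp = 1e-15) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  lo <- p < p_clamp
  hi <- p > 1 - p_clamp
  if (any(lo | hi))
    warning("p-value(s) clamped to [", p_clamp, ", ", 1 - p_clamp, "]")
  z <- stats::qnorm(p, lower.tail = FALSE)
  # evaluate the clamped tails at p_clamp itself so both ends are exact
  z[lo] <- stats::qnorm(p_clamp, lower.tail = FALSE)
  z[hi] <- stats::qnorm(p_clamp)
  z
}

#' Aggregate neighbor-enzyme Z-scores
#'
#' Returns `sum(z)/sqrt(k)`. The particular per-k normalization is
#' immaterial for the corrected score because the background mean and SD are
#' computed under the same aggregation, so any fixed scaling cancels.
#'
#' @param zs numeric vector of k Z-scores.
#' @return the aggregate Z, or `NA_real_` for an empty input (the caller
#'   excludes such metabolites).
#' @export
aggregate_z <- function(zs) {
  k <- length(zs)
  if (k == 0) return(NA_real_)
  sum(zs) / sqrt(k)
}

#' Background mean and SD of the size-k aggregate
#'
#' Null distribution of [aggregate_z()] over size-k enzyme sets drawn from
#' the network's scored enzymes. All `choose(n, k)` subsets are enumerated
#' exactly when that count is within `params$exhaustive_limit`; otherwise
#' `params$n_background_samples` Monte-Carlo sets are drawn, each without
#' replacement within the set. Monte-Carlo consumes the current RNG stream;
#' [score_metabolites()] seeds it once and requests sizes in ascending
#' k-order so runs are reproducible.
#'
#' @param enzyme_zs Z-scores of all scored enzyme units in the network.
#' @param k neighborhood size, `1 <= k <= length(enzyme_zs)`.
#' @param params a [reporter_params()] object.
#' @return named numeric `c(mu, sigma)` with attribute `"method"` set to
#'   `"exhaustive"` or `"monte-carlo"`. `sigma` is 0 when all subsets agree
#'   (degenerate background).
#' @export
background_stats <- function(enzyme_zs, k, params = reporter_params()) {
  n <- length(enzyme_zs)
  if (k < 1) stop("k must be at least 1")
  if (k > n) stop("k = ", k, " exceeds the number of scored enzymes (", n, ")")
  if (choose(n, k) <= params$exhaustive_limit) {
    agg <- utils::combn(enzyme_zs, k, FUN = sum) / sqrt(k)
    method <- "exhaustive"
  } else {
    b <- params$n_background_samples
    agg <- vapply(seq_len(b),
                  function(i) sum(enzyme_zs[sample.int(n, k)]), 0) / sqrt(k)
    method <- "monte-carlo"
  }
  mu <- mean(agg)
  # exhaustive enumeration IS the null distribution, so its SD is the
  # population SD; Monte-Carlo estimates it with the usual sample SD
  sigma <- if (length(agg) < 2) 0
           else if (method == "exhaustive") sqrt(mean((agg - mu)^2))
           else stats::sd(agg)
  structure(c(mu = mu, sigma = sigma), method = method)
}

#' Score all metabolites of a network
#'
#' For every metabolite with at least one scored neighbor enzyme: neighbor
#' enzyme units (minimum-p GPR collapse, deduplicated gene sets) give enzyme
#' p-values, the inverse-normal transform gives Z-scores, the aggregate is
#' corrected by the size-k background `(z - mu_k)/sigma_k`, and
#' `p = 1 - pnorm(z_corrected)`. Each enzyme's most significant gene also
#' contributes its direction to the metabolite's up/down neighbor gene
#' lists.
#'
#' @param net a `MetabolicNetwork`.
#' @param gene_scores `GeneScore` data.frame (`gene_id`, `p`, and optionally
#'   `logfc`, `direction`).
#' @param params a [reporter_params()] object.
#' @param dedup merge enzyme units with identical gene sets (default
#'   `TRUE`).
#' @return data.frame sorted by ascending p with columns `metabolite_id`,
#'   `name`, `k`, `z_raw`, `mu_k`, `sigma_k`, `z_corrected`, `p`, `n_up`,
#'   `n_down`, `up_genes`, `down_genes` (semicolon-separated lists).
#'   Metabolites without scored neighbors are omitted (their count is
#'   reported in a message).
#' @export
score_metabolites <- function(net, gene_scores, params = reporter_params(),
                              dedup = TRUE) {
  pvec <- .gene_p_vector(gene_scores)
  dir_vec <- if (is.data.frame(gene_scores) && "direction" %in% names(gene_scores))
    stats::setNames(gene_scores$direction, gene_scores$gene_id) else NULL

  # background pool: every distinct scored enzyme unit in the network
  pool_units <- network_enzymes(net, dedup = dedup)
  pool_p <- vapply(pool_units, function(u) as.numeric(score_enzyme(u, pvec)), 0)
  pool_p <- pool_p[!is.na(pool_p)]
  if (!length(pool_p)) stop("no enzyme unit of the network has a scored gene")
  pool_z <- suppressWarnings(p_to_z(pool_p, params$p_clamp))

  mets <- net$metabolites$id
  rows <- vector("list", length(mets))
  skipped <- 0L
  sigma_zero_warned <- FALSE
  for (i in seq_along(mets)) {
    units <- neighbor_enzymes(net, mets[i], dedup = dedup)
    ep <- lapply(units, score_enzyme, gene_scores = pvec)
    keep <- !vapply(ep, is.na, TRUE)
    if (!any(keep)) { skipped <- skipped + 1L; next }
    ep <- ep[keep]
    zs <- suppressWarnings(p_to_z(vapply(ep, as.numeric, 0), params$p_clamp))
    genes <- vapply(ep, attr, "", which = "gene")
    dirs <- if (is.null(dir_vec)) rep(NA_character_, length(genes))
            else unname(dir_vec[genes])
    up <- sort(unique(genes[!is.na(dirs) & dirs == "up"]))
    down <- sort(unique(genes[!is.na(dirs) & dirs == "down"]))
    rows[[i]] <- list(metabolite_id = mets[i], k = length(zs),
                      z_raw = aggregate_z(zs), up = up, down = down)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("no metabolite has a scored neighbor enzyme")
  if (skipped) message(skipped, " metabolite(s) without scored neighbor enzymes omitted")

  ks <- sort(unique(vapply(rows, function(r) r$k, 0L)))
  set.seed(params$seed)
  bg <- stats::setNames(vector("list", length(ks)), ks)
  for (k in ks) bg[[as.character(k)]] <- background_stats(pool_z, k, params)

  res <- do.call(rbind, lapply(rows, function(r) {
    b <- bg[[as.character(r$k)]]
    mu <- b[["mu"]]; sigma <- b[["sigma"]]
    if (sigma > 0) {
      zc <- (r$z_raw - mu) / sigma
    } else {
      if (!sigma_zero_warned) {
        warning("degenerate background (sigma_k = 0): corrected Z set to 0")
        sigma_zero_warned <<- TRUE
      }
      zc <- 0
    }
    data.frame(metabolite_id = r$metabolite_id, k = r$k, z_raw = r$z_raw,
               mu_k = mu, sigma_k = sigma, z_corrected = zc,
               p = stats::pnorm(zc, lower.tail = FALSE),
               n_up = length(r$up), n_down = length(r$down),
               up_genes = paste(r$up, collapse = ";"),
               down_genes = paste(r$down, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  res$name <- net$metabolites$name[match(res$metabolite_id, net$metabolites$id)]
  res <- res[order(res$p, res$metabolite_id), c(
    "metabolite_id", "name", "k", "z_raw", "mu_k", "sigma_k", "z_corrected",
    "p", "n_up", "n_down", "up_genes", "down_genes")]
  rownames(res) <- NULL
  res
}

#' Call reporter metabolites
#'
#' Subset of the score table with `p <= alpha` (inclusive boundary), input
#' order preserved.
#'
#' @param scores metabolite score table from [score_metabolites()].
#' @param alpha threshold (default 0.05).
#' @return the reporter subset of `scores`.
#' @export
call_reporters <- function(scores, alpha = 0.05) {
  if (!nrow(scores)) stop("empty score table")
  scores[scores$p <= alpha, , drop = FALSE]
}

#' Write / read a metabolite score table
#' @param scores score table.
#' @param path file path.
#' @return `path` (write) or the table (read).
#' @rdname reporter_io
#' @export
write_reporter_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname reporter_io
#' @export
read_reporter_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
}
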