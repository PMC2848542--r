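# Probe-level differential expression and probe-to-gene summarization.
# Expression values are assumed already normalized (e.g. RMA output on the
# log2 scale); this module starts from the probe x sample matrix.

#' Per-probe differential expression between two groups
#'
#' Computes a two-sided p-value and log2 fold-change (`mean(label1) -
#' mean(label2)`) per probe. `method = "moderated"` is the empirical-Bayes
#' moderated t-test: per-probe sample variances are shrunk toward a common
#' prior whose hyperparameters (prior df `d0`, prior variance `s0^2`) are
#' estimated by matching moments of the log sample variances (via
#' [limma::squeezeVar()]), and the reference distribution is t with
#' `d + d0` degrees of freedom. `method = "welch"` is the ordinary
#' unequal-variance t-test.
#'
#' @param expr numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param groups named character vector mapping sample id to group label.
#' @param contrast length-2 character vector `(label1, label2)`; positive
#'   log fold-changes mean higher in `label1`.
#' @param method `"moderated"` (default) or `"welch"`.
#' @param probe_map optional data.frame with columns `probe_id`, `gene_id`
#'   and optionally `rank_tier`; probes without a mapping are dropped with a
#'   warning. When `NULL`, `gene_id = probe_id` and every probe is tier 1.
#' @param d0 optional prior degrees of freedom overriding the estimate:
#'   `0` gives the ordinary per-probe t-test, `Inf` pools all probes onto
#'   the common prior variance. Mainly for calibration checks.
#' @return data.frame of probe scores: `probe_id`, `gene_id`, `rank_tier`,
#'   `p`, `logfc`.
#' @export
differential_expression <- function(expr, groups, contrast,
                                    method = c("moderated", "welch"),
                                    probe_map = NULL, d0 = NULL) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expr must have probe ids as rownames")
  if (is.null(colnames(expr))) stop("expr must have sample ids as colnames")
  if (!all(colnames(expr) %in% names(groups)))
    stop("every sample column needs a group label")
  if (length(contrast) != 2) stop("contrast must be (label1, label2)")
  g <- groups[colnames(expr)]
  i1 <- which(g == contrast[1])
  i2 <- which(g == contrast[2])
  if (length(i1) < 2 || length(i2) < 2)
    stop("each contrast group needs at least 2 samples (got ",
         length(i1), " and ", length(i2), ")")
  if (any(!is.finite(expr[, c(i1, i2)])))
    stop("expression matrix contains non-finite values")
  x1 <- expr[, i1, drop = FALSE]
  x2 <- expr[, i2, drop = FALSE]
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- .row_var(x1, m1); v2 <- .row_var(x2, m2)
  logfc <- m1 - m2

  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tt <- logfc / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
    zerov <- se2 == 0
    if (any(zerov)) {
      warning(sum(zerov), " zero-variance probe(s): p set to 1")
      p[zerov] <- 1
    }
  } else {
    df <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    if (all(s2 == 0)) {
      warning("all probes have zero pooled variance: p set to 1")
      p <- rep(1, length(s2))
    } else {
      if (is.null(d0)) {
        sq <- limma::squeezeVar(s2, df)
        var_post <- sq$var.post
        df_total <- df + sq$df.prior
      } else if (d0 == 0) {
        var_post <- s2
        df_total <- df
      } else if (is.infinite(d0)) {
        var_post <- rep(mean(s2), length(s2))
        df_total <- Inf
      } else {
        s0sq <- mean(s2)
        var_post <- (d0 * s0sq + df * s2) / (d0 + df)
        df_total <- df + d0
      }
      se <- sqrt(var_post * (1 / n1 + 1 / n2))
      tt <- logfc / se
      p <- 2 * stats::pt(abs(tt), df_total, lower.tail = FALSE)
      zerose <- se == 0
      if (any(zerose)) {
        warning(sum(zerose), " zero-variance probe(s): p set to 1")
        p[zerose] <- 1
      }
    }
  }
  p[logfc == 0] <- pmax(p[logfc == 0], 1, na.rm = TRUE)
  p[is.na(p)] <- 1
  out <- data.frame(probe_id = rownames(expr), gene_id = rownames(expr),
                    rank_tier = 1L, p = unname(p), logfc = unname(logfc),
                    stringsAsFactors = FALSE)
  if (!is.null(probe_map)) {
    if (!"rank_tier" %in% names(probe_map)) probe_map$rank_tier <- 1L
    idx <- match(out$probe_id, probe_map$probe_id)
    if (anyNA(idx)) {
      warning(sum(is.na(idx)), " probe(s) absent from probe_map dropped")
      out <- out[!is.na(idx), , drop = FALSE]
      idx <- idx[!is.na(idx)]
    }
    out$gene_id <- probe_map$gene_id[idx]
    out$rank_tier <- as.integer(probe_map$rank_tier[idx])
  }
  rownames(out) <- NULL
  out
}

.row_var <- function(x, m) {
  rowSums((x - m)^2) / (ncol(x) - 1)
}

#' Summarize probe scores to gene scores
#'
#' Per gene, probes are restricted to the minimal (best) `rank_tier`; a
#' single probe is copied through, several are combined by the median of
#' their p-values and of their log fold-changes. The direction is the sign
#' of the gene-level logfc; an exact zero breaks the tie deterministically
#' as `"down"` with a warning.
#'
#' @param scores probe-score data.frame from [differential_expression()].
#' @return data.frame of gene scores: `gene_id`, `p`, `logfc`, `direction`.
#'   Genes with no probes are simply absent.
#' @export
summarize_probes <- function(scores) {
  stopifnot(all(c("probe_id", "gene_id", "rank_tier", "p", "logfc") %in%
                  names(scores)))
  if (anyNA(scores$rank_tier)) stop("rank_tier missing for some probes")
  by_gene <- split(scores, scores$gene_id)
  p <- vapply(by_gene, function(s) {
    s <- s[s$rank_tier == min(s$rank_tier), , drop = FALSE]
    stats::median(s$p)
  }, 0)
  lfc <- vapply(by_gene, function(s) {
    s <- s[s$rank_tier == min(s$rank_tier), , drop = FALSE]
    stats::median(s$logfc)
  }, 0)
  if (any(lfc == 0))
    warning(sum(lfc == 0), " gene(s) with logfc exactly 0: direction set to 'down'")
  out <- data.frame(gene_id = names(by_gene), p = unname(p),
                    logfc = unname(lfc),
                    direction = ifelse(lfc > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# --- file interfaces -------------------------------------------------------

#' Read an expression matrix TSV
#'
#' First column `probe_id`, remaining header fields are sample ids.
#' @param path file path.
#' @return numeric matrix, probes x samples.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE)
  if (names(tab)[1] != "probe_id")
    stop("expression TSV must start with a 'probe_id' column")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$probe_id
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix TSV
#' @param expr probes x samples matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  tab <- data.frame(probe_id = rownames(expr), expr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe map TSV (probe_id, gene_id, optional rank_tier)
#' @param path file path.
#' @return data.frame with `probe_id`, `gene_id`, `rank_tier`.
#' @export
read_probe_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character")
  if (!all(c("probe_id", "gene_id") %in% names(tab)))
    stop("probe map needs columns probe_id, gene_id")
  tab$rank_tier <- if ("rank_tier" %in% names(tab))
    as.integer(tab$rank_tier) else 1L
  tab
}

#' Read precomputed gene scores (gene_id, p, logfc[, direction])
#'
#' Lets the pipeline ingest differential-expression results from any
#' external stack, bypassing [differential_expression()].
#' @param path file path.
#' @return `GeneScore` data.frame with `gene_id`, `p`, `logfc`, `direction`.
#' @export
read_gene_scores <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "")
  if (!all(c("gene_id", "p") %in% names(tab)))
    stop("gene score TSV needs columns gene_id, p")
  if (any(tab$p <= 0 | tab$p > 1)) stop("gene p-values must lie in (0, 1]")
  if (!"logfc" %in% names(tab)) tab$logfc <- NA_real_
  if (!"direction" %in% names(tab))
    tab$direction <- ifelse(!is.na(tab$logfc) & tab$logfc > 0, "up", "down")
  tab[, c("gene_id", "p", "logfc", "direction")]
}

#' Write gene scores to TSV
#' @param scores `GeneScore` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
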