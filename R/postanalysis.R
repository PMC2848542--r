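# Cross-contrast comparison of reporter sets (Jaccard distance, hierarchical
# clustering) and correlation of neighbor-gene centroid expression with
# phenotypes.

#' Jaccard distance between two sets
#'
#' `1 - |a intersect b| / |a union b|`: the fraction of non-overlapping
#' elements. Two empty sets have distance 0 by convention.
#'
#' @param a,b vectors treated as sets.
#' @return distance in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) {
    message("both sets empty: Jaccard distance 0 by convention")
    return(0)
  }
  1 - length(intersect(a, b)) / u
}

#' Hierarchical clustering of contrasts by reporter-set overlap
#'
#' Builds the pairwise Jaccard distance matrix over the contrasts' reporter
#' metabolite sets and clusters it agglomeratively (average linkage by
#' default).
#'
#' @param results named list: contrast id -> character vector of reporter
#'   metabolite ids. At least two contrasts; ids must be unique.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return list with `dist` (the distance matrix), `hclust` (the tree) and
#'   `newick` (the dendrogram serialized as a Newick string, branch lengths
#'   from the merge heights).
#' @export
cluster_contrasts <- function(results, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (length(results) < 2) stop("need at least two contrasts")
  if (is.null(names(results)) || anyDuplicated(names(results)))
    stop("duplicate or missing contrast ids")
  ids <- names(results)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- jaccard_distance(results[[i]], results[[j]])
  }
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(dist = d, hclust = hc, newick = newick)
}

#' Centroid expression profile of a metabolite's neighbor genes
#'
#' Per-sample mean of the metabolite's neighbor genes' expression after
#' per-gene standardization over all samples (mean 0, SD 1); `mode = "raw"`
#' skips the standardization.
#'
#' @param expr gene-level expression matrix (genes x samples).
#' @param net a `MetabolicNetwork`.
#' @param metabolite_id the metabolite.
#' @param mode `"zscore"` (default) or `"raw"`.
#' @return named numeric vector, one value per sample. Attribute
#'   `"n_genes_missing"` counts neighbor genes without expression rows.
#' @export
centroid_profile <- function(expr, net, metabolite_id,
                             mode = c("zscore", "raw")) {
  mode <- match.arg(mode)
  units <- neighbor_enzymes(net, metabolite_id)
  genes <- sort(unique(unlist(lapply(units, `[[`, "gene_ids"))))
  present <- intersect(genes, rownames(expr))
  missing <- length(genes) - length(present)
  if (!length(present))
    stop("no neighbor gene of ", metabolite_id, " has an expression row")
  x <- expr[present, , drop = FALSE]
  if (mode == "zscore") {
    mu <- rowMeans(x)
    sdv <- apply(x, 1, stats::sd)
    flat <- sdv == 0
    if (any(flat)) {
      warning(sum(flat), " constant gene(s) dropped from centroid of ",
              metabolite_id)
      x <- x[!flat, , drop = FALSE]; mu <- mu[!flat]; sdv <- sdv[!flat]
      if (!nrow(x)) stop("all neighbor genes constant for ", metabolite_id)
    }
    x <- (x - mu) / sdv
  }
  structure(colMeans(x), n_genes_missing = missing)
}

#' Correlate neighbor-gene centroid expression with a phenotype
#'
#' Pearson correlation between the metabolite's centroid profile and a
#' per-sample phenotype, within each group and for all samples pooled.
#' Two-sided p-values come from the usual t transform of r. Groups with
#' fewer than 3 paired observations, or with a constant phenotype or
#' centroid, are marked not computable (`NA`).
#'
#' @param expr gene-level expression matrix (genes x samples).
#' @param net a `MetabolicNetwork`.
#' @param metabolite_id the metabolite.
#' @param phenotype named numeric vector, sample -> value.
#' @param groups named character vector, sample -> group label.
#' @param mode centroid mode, see [centroid_profile()].
#' @return data.frame with columns `metabolite_id`, `group`, `n`, `r`, `p`
#'   (one row per group plus a `"pooled"` row).
#' @export
centroid_correlation <- function(expr, net, metabolite_id, phenotype, groups,
                                 mode = "zscore") {
  cen <- centroid_profile(expr, net, metabolite_id, mode = mode)
  samples <- intersect(names(cen), names(phenotype))
  if (!length(samples)) stop("no sample shared between expression and phenotype")
  cen <- cen[samples]
  ph <- phenotype[samples]
  grp <- groups[samples]
  levels_ <- c(sort(unique(grp)), "pooled")
  rows <- lapply(levels_, function(g) {
    idx <- if (g == "pooled") seq_along(samples) else which(grp == g)
    x <- cen[idx]; y <- ph[idx]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(metabolite_id = metabolite_id, group = g, n = n,
                        r = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
    }
    r <- stats::cor(x, y)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
    data.frame(metabolite_id = metabolite_id, group = g, n = n, r = r, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
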