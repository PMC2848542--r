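# Promoter motif enrichment: TRANSFAC-format position frequency matrices
# scanned as log-odds against an order-2 Markov background, per-sequence
# presence/absence calls at 70% of the matrix maximum, one-tailed Fisher
# enrichment of reporter gene sets vs the metabolic-gene background, and
# Storey q-values.

.dna_alphabet <- c("A", "C", "G", "T")

.dna_codes <- function(seq) {
  x <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], .dna_alphabet)
  x
}

.revcomp_codes <- function(x) rev(5L - x)

#' Reverse complement of a DNA string (N-aware)
#' @param seq character scalar over A,C,G,T,N.
#' @return reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", seq), "",
                     fixed = TRUE)[[1]]), collapse = "")
}

# --- promoter extraction ---------------------------------------------------

#' Extract promoter windows around transcription start sites
#'
#' Promoters span the -`upstream` .. +`downstream` window of the TSS,
#' strand-oriented: for a plus-strand gene the 0-based half-open genomic
#' interval `[tss - upstream, tss + downstream)`, for a minus-strand gene
#' the reverse complement of `[tss - downstream + 1, tss + upstream + 1)`.
#' Windows are truncated at chromosome ends with a warning. Soft-masked
#' (lowercase) bases become `N`.
#'
#' @param genome named character vector of chromosome sequences, a
#'   `Biostrings::BStringSet`/`DNAStringSet`, or the path to a FASTA file.
#' @param tss_table data.frame with columns `chrom`, `tss` (0-based
#'   coordinate of the transcription start base), `strand` (`"+"`/`"-"`),
#'   `gene_id`.
#' @param upstream,downstream window extents in bases (defaults 800 and
#'   200, i.e. the -800..+200 promoter).
#' @return named character vector of promoter sequences keyed by gene id
#'   (a `PromoterSet`).
#' @export
extract_promoters <- function(genome, tss_table, upstream = 800,
                              downstream = 200) {
  genome <- .as_masked_sequences(genome)
  need <- c("chrom", "tss", "strand", "gene_id")
  if (!all(need %in% names(tss_table)))
    stop("tss_table needs columns: ", paste(need, collapse = ", "))
  unknown <- setdiff(unique(tss_table$chrom), names(genome))
  if (length(unknown))
    stop("chromosome(s) absent from genome: ", paste(unknown, collapse = ", "),
         " (genes: ", paste(tss_table$gene_id[tss_table$chrom %in% unknown],
                            collapse = ", "), ")")
  out <- character(0)
  truncated <- character(0)
  for (i in seq_len(nrow(tss_table))) {
    chrom <- tss_table$chrom[i]
    tss <- tss_table$tss[i]
    len <- nchar(genome[[chrom]])
    if (tss < 0 || tss >= len) {
      warning("TSS of gene ", tss_table$gene_id[i],
              " outside chromosome ", chrom, ": skipped")
      next
    }
    if (tss_table$strand[i] == "+") {
      from0 <- tss - upstream; to0 <- tss + downstream  # [from0, to0)
    } else {
      from0 <- tss - downstream + 1; to0 <- tss + upstream + 1
    }
    cf <- max(from0, 0); ct <- min(to0, len)
    if (cf > from0 || ct < to0) truncated <- c(truncated, tss_table$gene_id[i])
    s <- substr(genome[[chrom]], cf + 1, ct)
    if (tss_table$strand[i] == "-") s <- reverse_complement(s)
    out[tss_table$gene_id[i]] <- s
  }
  if (length(truncated))
    warning("promoter(s) truncated at chromosome end: ",
            paste(truncated, collapse = ", "))
  out
}

# Normalizes genome/promoter input to a named character vector with
# soft-masked (lowercase) bases as N and everything outside A,C,G,T as N.
.as_masked_sequences <- function(x) {
  if (is.character(x) && length(x) == 1 && !is.null(x) && file.exists(x) &&
      is.null(names(x))) {
    x <- Biostrings::readBStringSet(x)
  }
  if (methods::is(x, "XStringSet")) {
    x <- stats::setNames(as.character(x), names(x))
  }
  if (!is.character(x) || is.null(names(x)))
    stop("expected a FASTA path, an XStringSet, or a named character vector")
  names(x) <- sub("\\s.*$", "", names(x))
  x <- chartr("acgtn", "NNNNN", x)
  gsub("[^ACGTN]", "N", x)
}

#' Read promoter sequences from FASTA
#'
#' Soft-masked lowercase bases are converted to `N`.
#' @param path FASTA path.
#' @return named character vector keyed by the first word of each header.
#' @export
read_promoters <- function(path) .as_masked_sequences(path)

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

# --- TRANSFAC matrices -----------------------------------------------------

#' Parse a TRANSFAC flat file of position frequency matrices
#'
#' Records are separated by `//`; `AC` gives the id, `ID`/`NA` the name,
#' the `P0`/`PO` header fixes the column order (remapped to A,C,G,T), and
#' numbered lines carry the per-position counts.
#'
#' @param path file path.
#' @return list of PFMs, each a list with `id`, `name`, and `counts`
#'   (4 x L numeric matrix, rows A,C,G,T).
#' @export
parse_transfac <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(grepl("^//", lines)))
  out <- list()
  for (rec in recs) {
    rec <- rec[!grepl("^//", rec)]
    rec <- rec[nzchar(trimws(rec))]
    if (!length(rec)) next
    ac <- sub("^AC\\s+", "", rec[grepl("^AC\\s", rec)][1])
    idl <- rec[grepl("^ID\\s", rec)]
    nal <- rec[grepl("^NA\\s", rec)]
    name <- if (length(nal)) sub("^NA\\s+", "", nal[1]) else
            if (length(idl)) sub("^ID\\s+", "", idl[1]) else ac
    if (is.na(ac)) ac <- name
    p0 <- rec[grepl("^P[0O]\\s", rec)]
    if (!length(p0))
      stop("TRANSFAC record '", ac, "' lacks a P0 header line")
    cols <- toupper(strsplit(trimws(sub("^P[0O]\\s+", "", p0[1])), "\\s+")[[1]])
    if (!setequal(cols, .dna_alphabet))
      stop("TRANSFAC record '", ac, "' has alphabet header ",
           paste(cols, collapse = " "), "; expected a permutation of A C G T")
    pos_lines <- rec[grepl("^[0-9]+\\s", rec)]
    if (!length(pos_lines))
      stop("TRANSFAC record '", ac, "' has no position lines")
    counts <- t(vapply(pos_lines, function(l) {
      f <- strsplit(trimws(l), "\\s+")[[1]]
      v <- suppressWarnings(as.numeric(f[2:5]))
      if (anyNA(v))
        stop("malformed position line in TRANSFAC record '", ac, "': ", l)
      v
    }, numeric(4)))
    colnames(counts) <- cols
    counts <- t(counts[, .dna_alphabet, drop = FALSE])  # 4 x L, rows ACGT
    dimnames(counts) <- list(.dna_alphabet, NULL)
    pfm <- list(id = ac, name = name, counts = counts)
    .validate_pfm(pfm)
    out[[length(out) + 1]] <- pfm
  }
  out
}

.validate_pfm <- function(pfm) {
  counts <- pfm$counts
  if (nrow(counts) != 4) stop("PFM '", pfm$id, "' must have 4 rows (A,C,G,T)")
  if (ncol(counts) < 4) stop("PFM '", pfm$id, "' shorter than 4 positions")
  if (any(counts < 0)) stop("PFM '", pfm$id, "' has negative counts")
  if (any(colSums(counts) == 0)) stop("PFM '", pfm$id, "' has an all-zero column")
  invisible(pfm)
}

#' Write PFMs in TRANSFAC flat format
#' @param pfms list of PFMs as returned by [parse_transfac()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transfac <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (pfm in pfms) {
    writeLines(c(paste("AC", pfm$id), paste("NA", pfm$name),
                 "P0      A      C      G      T"), con)
    counts <- pfm$counts
    cons <- .dna_alphabet[apply(counts, 2, which.max)]
    for (j in seq_len(ncol(counts))) {
      writeLines(sprintf("%02d %6g %6g %6g %6g %s", j, counts["A", j],
                         counts["C", j], counts["G", j], counts["T", j],
                         cons[j]), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

# --- Markov background -----------------------------------------------------

#' Train a Markov background model on promoter sequences
#'
#' Estimates `P(base | previous order bases)` with add-one pseudocounts;
#' windows containing `N` are skipped. Also records the overall base
#' composition (used as the stationary reference for log-odds score
#' bounds and for positions without a full context).
#'
#' @param sequences character vector of sequences over A,C,G,T,N.
#' @param order Markov order (default 2; 0 gives the base composition).
#' @return an object of class `markov_bg`.
#' @export
train_background <- function(sequences, order = 2) {
  stopifnot(order >= 0)
  codes <- lapply(sequences, .dna_codes)
  usable <- sum(vapply(codes, function(x) sum(!is.na(x)), 0L))
  if (usable < 10 * 4^(order + 1))
    stop("insufficient sequence (", usable, " usable bases) for order ",
         order, "; need at least ", 10 * 4^(order + 1),
         " - use a lower order")
  n_ctx <- 4L^order
  counts <- matrix(0, n_ctx, 4L)
  base_counts <- rep(0, 4L)
  for (x in codes) {
    base_counts <- base_counts + tabulate(x, 4L)
    n <- length(x)
    if (n <= order) next
    if (order == 0) {
      next
    }
    ctx <- rep(0L, n - order)
    ok <- rep(TRUE, n - order)
    for (j in seq_len(order)) {
      prev <- x[(order + 1 - j):(n - j)]
      ok <- ok & !is.na(prev)
      prev[is.na(prev)] <- 1L
      ctx <- ctx + (prev - 1L) * 4L^(j - 1L)
    }
    base <- x[(order + 1):n]
    use <- ok & !is.na(base)
    if (any(use))
      counts <- counts + matrix(tabulate(ctx[use] * 4L + base[use], n_ctx * 4L),
                                n_ctx, 4L, byrow = TRUE)
  }
  if (order == 0) counts <- matrix(base_counts, 1L, 4L)
  trans <- (counts + 1) / (rowSums(counts) + 4)
  base_freq <- (base_counts + 1) / (sum(base_counts) + 4)
  names(base_freq) <- .dna_alphabet
  colnames(trans) <- .dna_alphabet
  structure(list(order = as.integer(order), trans = trans,
                 logtrans = log(trans), base_freq = base_freq,
                 log_base = log(base_freq)),
            class = "markov_bg")
}

# Per-position background log-probability for a coded sequence; NA at N.
# Positions without a full non-N context fall back to the stationary
# base composition.
.bg_logprob <- function(x, bg) {
  n <- length(x)
  lp <- rep(NA_real_, n)
  known <- !is.na(x)
  lp[known] <- bg$log_base[x[known]]
  if (bg$order > 0 && n > bg$order) {
    ctx <- rep(0L, n - bg$order)
    ok <- rep(TRUE, n - bg$order)
    for (j in seq_len(bg$order)) {
      prev <- x[(bg$order + 1 - j):(n - j)]
      ok <- ok & !is.na(prev)
      prev[is.na(prev)] <- 1L
      ctx <- ctx + (prev - 1L) * 4L^(j - 1L)
    }
    pos <- (bg$order + 1):n
    base <- x[pos]
    use <- ok & !is.na(base)
    lp[pos[use]] <- bg$logtrans[cbind(ctx[use] + 1L, base[use])]
  }
  lp
}

# log frequency matrix of a PFM with 0.25 pseudocount per cell
.pfm_logf <- function(pfm) {
  f <- sweep(pfm$counts + 0.25, 2, colSums(pfm$counts) + 1, "/")
  log(f)
}

# score bounds against the background's stationary composition
.pfm_score_range <- function(pfm, bg) {
  lo <- .pfm_logf(pfm) - bg$log_base
  c(smin = sum(apply(lo, 2, min)), smax = sum(apply(lo, 2, max)))
}

.pfm_threshold <- function(range, threshold_frac) {
  smin <- range[["smin"]]; smax <- range[["smax"]]
  if (smax > 0) threshold_frac * smax
  else if (smax > smin) smin + threshold_frac * (smax - smin)
  else smax
}

# window scores of one coded strand: match part minus background part;
# windows overlapping N score -Inf
.window_scores <- function(x, lp, logf) {
  L <- ncol(logf)
  n <- length(x)
  nw <- n - L + 1
  if (nw < 1) return(numeric(0))
  s <- rep(0, nw)
  bad <- rep(FALSE, nw)
  for (j in seq_len(L)) {
    b <- x[j:(j + nw - 1)]
    na <- is.na(b)
    bad <- bad | na
    b[na] <- 1L
    s <- s + logf[cbind(b, j)]
  }
  lp0 <- lp
  lp0[is.na(lp0)] <- 0
  cs <- c(0, cumsum(lp0))
  s <- s - (cs[(L + 1):(n + 1)] - cs[1:nw])
  s[bad] <- -Inf
  s
}

#' Scan a sequence with a PFM against a Markov background
#'
#' Every window on both strands is scored as the sum over positions of
#' `log(f_j(base) / bg(base | context))`, with column frequencies `f` from
#' counts plus a 0.25 pseudocount per cell; windows containing `N` score
#' `-Inf`. A hit is called when the best score reaches `threshold_frac`
#' of the matrix's maximum achievable score against the background's
#' stationary composition (when that maximum is not positive, the fraction
#' is taken on the range-normalized score instead).
#'
#' @param seq sequence string over A,C,G,T,N.
#' @param pfm a PFM (list with `counts`).
#' @param bg a `markov_bg` from [train_background()].
#' @param threshold_frac hit threshold fraction (default 0.7).
#' @param both_strands scan the reverse complement too (default `TRUE`).
#' @return list with `hit` (logical), `best_score`, `n_hits`, `threshold`.
#'   A sequence shorter than the motif yields `hit = FALSE`.
#' @export
scan_sequence <- function(seq, pfm, bg, threshold_frac = 0.7,
                          both_strands = TRUE) {
  x <- .dna_codes(seq)
  logf <- .pfm_logf(pfm)
  if (length(x) < ncol(logf))
    return(list(hit = FALSE, best_score = -Inf, n_hits = 0L,
                threshold = NA_real_))
  rng <- .pfm_score_range(pfm, bg)
  thr <- .pfm_threshold(rng, threshold_frac)
  s <- .window_scores(x, .bg_logprob(x, bg), logf)
  if (both_strands) {
    xr <- .revcomp_codes(x)
    s <- c(s, .window_scores(xr, .bg_logprob(xr, bg), logf))
  }
  best <- if (length(s)) max(s) else -Inf
  list(hit = is.finite(best) && best >= thr,
       best_score = best,
       n_hits = sum(is.finite(s) & s >= thr),
       threshold = thr)
}

#' Scan many promoters with many PFMs
#'
#' Batch version of [scan_sequence()]: per-sequence background terms are
#' computed once and reused across matrices.
#'
#' @param promoters named character vector of sequences.
#' @param pfms list of PFMs.
#' @param bg a `markov_bg`.
#' @param threshold_frac hit threshold fraction (default 0.7).
#' @param threshold_mode `"matrix-max"` (default; threshold from each
#'   matrix's maximum achievable score) or `"observed-best"` (threshold
#'   from the best score observed for that matrix across all promoters).
#' @return logical matrix, promoters x motifs, `TRUE` where the promoter
#'   contains at least one hit.
#' @export
scan_promoters <- function(promoters, pfms, bg, threshold_frac = 0.7,
                           threshold_mode = c("matrix-max", "observed-best")) {
  threshold_mode <- match.arg(threshold_mode)
  ids <- vapply(pfms, function(p) p$id, "")
  codes <- lapply(promoters, .dna_codes)
  lps <- lapply(codes, .bg_logprob, bg = bg)
  codes_rc <- lapply(codes, .revcomp_codes)
  lps_rc <- lapply(codes_rc, .bg_logprob, bg = bg)
  best <- matrix(-Inf, length(promoters), length(pfms),
                 dimnames = list(names(promoters), ids))
  thr <- numeric(length(pfms))
  for (m in seq_along(pfms)) {
    logf <- .pfm_logf(pfms[[m]])
    thr[m] <- .pfm_threshold(.pfm_score_range(pfms[[m]], bg), threshold_frac)
    for (i in seq_along(codes)) {
      s <- c(.window_scores(codes[[i]], lps[[i]], logf),
             .window_scores(codes_rc[[i]], lps_rc[[i]], logf))
      if (length(s)) best[i, m] <- max(s)
    }
  }
  if (threshold_mode == "observed-best") {
    obs <- apply(best, 2, function(b) max(b[is.finite(b)], -Inf))
    thr <- threshold_frac * obs
  }
  sweep(best, 2, thr, ">=") & is.finite(best)
}

# --- gene sets and enrichment ----------------------------------------------

#' Select up/down neighbor gene sets of reporter metabolites
#'
#' For each reporter metabolite (score `p <= alpha`), the up-regulated and
#' down-regulated neighbor gene sets are emitted independently whenever
#' their size reaches `min_size` (boundary inclusive).
#'
#' @param scores metabolite score table from [score_metabolites()].
#' @param alpha reporter threshold (default 0.05).
#' @param min_size minimum set size (default 5).
#' @return named list of gene-id vectors; names are
#'   `"<metabolite_id>:up"` / `"<metabolite_id>:down"`.
#' @export
select_gene_sets <- function(scores, alpha = 0.05, min_size = 5) {
  rep_tab <- scores[scores$p <= alpha, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(rep_tab))) {
    up <- .split_genes(rep_tab$up_genes[i])
    down <- .split_genes(rep_tab$down_genes[i])
    if (length(up) >= min_size)
      out[[paste0(rep_tab$metabolite_id[i], ":up")]] <- up
    if (length(down) >= min_size)
      out[[paste0(rep_tab$metabolite_id[i], ":down")]] <- down
  }
  out
}

.split_genes <- function(s) {
  if (is.na(s) || !nzchar(s)) character(0)
  else strsplit(s, ";", fixed = TRUE)[[1]]
}

#' One-tailed Fisher (hypergeometric upper-tail) p-value
#'
#' Probability of `a` or more hit-positive members in the positive set
#' under the hypergeometric null of the 2x2 table `[a b; c d]`.
#'
#' @param a positives with a hit.
#' @param b positives without a hit.
#' @param c_ negatives with a hit.
#' @param d negatives without a hit.
#' @return the exact upper-tail p-value.
#' @export
fisher_onetail <- function(a, b, c_, d) {
  stats::phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
}

#' Storey q-values
#'
#' Estimates the null proportion `pi0` on the lambda grid 0.05..0.95 (step
#' 0.05) with cubic-smoothing-spline extrapolation to lambda = 1; with
#' fewer than 100 p-values the single-point estimate at lambda = 0.5 is
#' used instead. Then `q_i = pi0 * min_{p_j >= p_i} (n * p_j / rank_j)`,
#' monotone in p and capped at 1.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @param pi0 optional fixed null proportion overriding the estimate
#'   (e.g. `pi0 = 1` gives Benjamini-Hochberg-style values).
#' @return numeric vector of q-values, same order as `pvals`.
#' @export
storey_q <- function(pvals, pi0 = NULL) {
  n <- length(pvals)
  if (!n) return(numeric(0))
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  if (is.null(pi0)) pi0 <- estimate_pi0(pvals)
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * n * pvals[o] / rank(pvals, ties.method = "max")[o]
  q <- pmin(cummin(q), 1)
  q[ro]
}

#' Estimate the proportion of true nulls (pi0)
#' @param pvals p-values in (0, 1].
#' @param lambda tuning grid (default 0.05..0.95 by 0.05).
#' @return pi0 estimate in (0, 1].
#' @export
estimate_pi0 <- function(pvals, lambda = seq(0.05, 0.95, by = 0.05)) {
  n <- length(pvals)
  if (n < 100) {
    pi0 <- mean(pvals > 0.5) / 0.5
  } else {
    pi0_l <- vapply(lambda, function(l) mean(pvals > l) / (1 - l), 0)
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
  }
  min(max(pi0, 1 / n), 1)
}

#' Motif enrichment of gene sets against a metabolic-gene background
#'
#' For each (gene set, motif) pair, promoters are classified by
#' presence/absence of a motif hit and the 2x2 table of the positive set
#' versus the background (all supplied background genes not in the set) is
#' tested with the one-tailed Fisher test; q-values are computed per gene
#' set across motifs (or pooled over everything with `pooled_q = TRUE`).
#'
#' @param sets named list of gene-id vectors (e.g. from
#'   [select_gene_sets()]).
#' @param promoters named character vector of promoter sequences.
#' @param pfms list of PFMs.
#' @param background_gene_ids character vector of background genes
#'   (typically every gene of the metabolic network).
#' @param bg optional `markov_bg`; when `NULL`, an order-`bg_order` model
#'   is trained on the background genes' promoters.
#' @param bg_order background Markov order (default 2).
#' @param threshold_frac scan threshold fraction (default 0.7).
#' @param threshold_mode see [scan_promoters()].
#' @param min_size sets that retain fewer promoters are skipped with a
#'   warning (default 5).
#' @param q_cutoff significance flag threshold on q (default 0.05).
#' @param pooled_q compute q-values over all sets jointly (default FALSE).
#' @return data.frame with columns `gene_set_id`, `motif_id`, `motif_name`,
#'   `a`, `b`, `c`, `d`, `p`, `q`, `significant`.
#' @export
enrich_motifs <- function(sets, promoters, pfms, background_gene_ids,
                          bg = NULL, bg_order = 2, threshold_frac = 0.7,
                          threshold_mode = "matrix-max", min_size = 5,
                          q_cutoff = 0.05, pooled_q = FALSE) {
  if (!length(sets)) return(.empty_enrichment())
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be a uniquely named list")
  bg_genes <- intersect(background_gene_ids, names(promoters))
  if (is.null(bg)) {
    bg <- train_background(unname(promoters[bg_genes]), order = bg_order)
  }
  needed <- union(unlist(sets, use.names = FALSE), bg_genes)
  needed <- intersect(needed, names(promoters))
  hits <- scan_promoters(promoters[needed], pfms, bg,
                         threshold_frac = threshold_frac,
                         threshold_mode = threshold_mode)
  ids <- colnames(hits)
  nm <- vapply(pfms, function(p) p$name, "")
  rows <- list()
  for (set_id in names(sets)) {
    pos <- intersect(sets[[set_id]], needed)
    if (length(pos) < min_size) {
      warning("gene set '", set_id, "' has only ", length(pos),
              " promoters (< ", min_size, "): skipped")
      next
    }
    neg <- setdiff(bg_genes, sets[[set_id]])
    a <- colSums(hits[pos, , drop = FALSE])
    c_ <- colSums(hits[neg, , drop = FALSE])
    b <- length(pos) - a
    d <- length(neg) - c_
    p <- fisher_onetail(a, b, c_, d)
    rows[[set_id]] <- data.frame(
      gene_set_id = set_id, motif_id = ids, motif_name = nm,
      a = as.integer(a), b = as.integer(b), c = as.integer(c_),
      d = as.integer(d), p = unname(p), q = NA_real_,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(.empty_enrichment())
  out <- do.call(rbind, rows)
  if (pooled_q) {
    out$q <- storey_q(out$p)
  } else {
    for (set_id in unique(out$gene_set_id)) {
      i <- out$gene_set_id == set_id
      out$q[i] <- storey_q(out$p[i])
    }
  }
  out$significant <- out$q <= q_cutoff
  rownames(out) <- NULL
  out
}

.empty_enrichment <- function() {
  data.frame(gene_set_id = character(0), motif_id = character(0),
             motif_name = character(0), a = integer(0), b = integer(0),
             c = integer(0), d = integer(0), p = numeric(0), q = numeric(0),
             significant = logical(0), stringsAsFactors = FALSE)
}
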