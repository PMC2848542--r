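# Fully synthetic inputs with the statistical structure the pipeline
# assumes: a bipartite metabolite-reaction network with heavy-tailed
# metabolite connectivity and isozyme/complex gene groups, two-group probe
# expression with coordinated shifts planted around chosen metabolites,
# multi-probeset genes, and promoters from an order-2 Markov background with
# planted motif instances plus column-shuffled decoy matrices.

#' Simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: a small
#' metabolic network whose hubs mimic cofactor (ATP/NAD) connectivity, a
#' two-group microarray-like design, and promoters carrying one planted
#' regulator motif in the genes coordinately shifted around the planted
#' reporter metabolites.
#'
#' @param n_metabolites,n_reactions,n_genes network size (defaults 50, 120,
#'   150).
#' @param degree_power exponent of the truncated power law for metabolite
#'   connectivity weights (default 2.2).
#' @param mean_degree average metabolite degree after scaling the power-law
#'   weights (default 6; reactions then average 2-3 participants).
#' @param complex_rate,isozyme_rate probability that a gene-associated
#'   reaction carries an AND complex / OR isozyme group (defaults 0.15 each).
#' @param geneless_rate probability a reaction has no gene association
#'   (spontaneous/transport; default 0.08).
#' @param n_planted_reporters metabolites (degree >= 5) whose neighbor
#'   genes receive a coordinated shift (default 5).
#' @param effect_size planted mean shift in units of the gene baseline SD
#'   (default 1.5).
#' @param frac_neighbors_affected fraction of a planted metabolite's
#'   neighbor genes that shift (default 0.8).
#' @param n_samples_per_group samples per group (default 10).
#' @param baseline_mean,baseline_sd gene baseline law (defaults 8, 1,
#'   log2-intensity-like).
#' @param probe_sd per-probe noise SD (default 0.4).
#' @param probes_per_gene_prob probabilities of 1, 2 or 3 probes per gene
#'   (default `c(0.6, 0.3, 0.1)`).
#' @param promoter_length promoter length in bases (default 1000).
#' @param motif_plant_rate probability a target-set promoter receives a
#'   motif instance (default 0.9).
#' @param bg_order promoter background Markov order (default 2).
#' @param n_decoys column-shuffled decoy matrices emitted (default 10).
#' @param mask_frac fraction of promoter bases masked to N in runs
#'   (default 0.05).
#' @param seed integer seed; every generator derives its stream from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_metabolites = 50, n_reactions = 120, n_genes = 150,
                       degree_power = 2.2, mean_degree = 6,
                       complex_rate = 0.15, isozyme_rate = 0.15,
                       geneless_rate = 0.08, n_planted_reporters = 5,
                       effect_size = 1.5, frac_neighbors_affected = 0.8,
                       n_samples_per_group = 10, baseline_mean = 8,
                       baseline_sd = 1, probe_sd = 0.4,
                       probes_per_gene_prob = c(0.6, 0.3, 0.1),
                       promoter_length = 1000, motif_plant_rate = 0.9,
                       bg_order = 2, n_decoys = 10, mask_frac = 0.05,
                       seed = 42L) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_metabolites, cfg$n_reactions, cfg$n_genes,
              cfg$n_samples_per_group, cfg$promoter_length)
  if (any(counts <= 0)) stop("all counts must be positive")
  rates <- c(cfg$complex_rate, cfg$isozyme_rate, cfg$geneless_rate,
             cfg$frac_neighbors_affected, cfg$motif_plant_rate, cfg$mask_frac)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$n_reactions < cfg$n_metabolites / 2)
    stop("need n_reactions >= n_metabolites / 2")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic metabolic network with planted reporters
#'
#' Metabolite connectivity weights are drawn from a truncated power law and
#' scaled to the configured mean degree, so a few hub metabolites attach to
#' many reactions while most attach to few. Each gene-associated reaction
#' carries a single gene, an AND complex or an OR isozyme group per the
#' configured rates; a fraction of reactions stay gene-less. Planted
#' reporters are drawn among metabolites with at least 5 neighbor enzyme
#' units.
#'
#' @param cfg a [sim_config()].
#' @return list with `network` (a `MetabolicNetwork`) and `truth` (list with
#'   `planted`, the planted metabolite ids).
#' @export
gen_network <- function(cfg) {
  set.seed(cfg$seed)
  for (attempt in seq_len(100)) {
    net <- .gen_network_once(cfg)
    k_of <- vapply(net$metabolites$id,
                   function(m) length(neighbor_enzymes(net, m)), 0L)
    # planted reporters model localized programs: degree at least 5, but
    # not the dominant cofactor-style hubs, whose neighborhoods would span
    # much of the network and turn the planted signal into a global shift
    eligible <- net$metabolites$id[k_of >= 5 & k_of <= 15]
    if (length(eligible) < cfg$n_planted_reporters)
      eligible <- net$metabolites$id[k_of >= 5]
    if (length(eligible) >= cfg$n_planted_reporters) {
      planted <- if (cfg$n_planted_reporters > 0)
        sort(sample(eligible, cfg$n_planted_reporters)) else character(0)
      return(list(network = net, truth = list(planted = planted)))
    }
  }
  stop("could not realize a network with ", cfg$n_planted_reporters,
       " metabolites of degree >= 5 in 100 attempts; ",
       "increase connectivity or network size")
}

.gen_network_once <- function(cfg) {
  n_met <- cfg$n_metabolites
  n_rxn <- cfg$n_reactions
  mets <- sprintf("M%03d", seq_len(n_met))
  rxns <- sprintf("R%03d", seq_len(n_rxn))
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  # heavy-tailed connectivity weights, scaled to the target stub count
  dmax <- 50L
  w <- sample(dmax, n_met, replace = TRUE,
              prob = (seq_len(dmax))^(-cfg$degree_power))
  target_edges <- round(cfg$mean_degree * n_met)
  extra <- stats::rmultinom(1, max(target_edges - n_met, 0), prob = w)[, 1]
  deg <- 1L + extra
  stubs <- sample(rep(seq_len(n_met), deg))
  rxn_of <- sample.int(n_rxn, length(stubs), replace = TRUE)
  edges <- unique(data.frame(reaction_id = rxns[rxn_of],
                             metabolite_id = mets[stubs],
                             stringsAsFactors = FALSE))
  # every reaction needs at least one participant
  empty <- setdiff(rxns, edges$reaction_id)
  if (length(empty))
    edges <- rbind(edges, data.frame(
      reaction_id = empty,
      metabolite_id = mets[sample.int(n_met, length(empty), replace = TRUE)],
      stringsAsFactors = FALSE))
  edges$role <- sample(c("substrate", "product"), nrow(edges), replace = TRUE)
  # genes are drawn from a shuffled stack so each enzyme gene belongs to
  # (essentially) one reaction, as most metabolic genes do; the stack is
  # reshuffled only when exhausted
  stack <- sample(genes)
  take <- function(k) {
    if (k > length(stack)) stack <<- c(stack, sample(genes))
    out <- stack[seq_len(k)]
    stack <<- stack[-seq_len(k)]
    out
  }
  ga <- vector("list", n_rxn)
  gpr <- vector("list", n_rxn)
  for (i in seq_len(n_rxn)) {
    if (stats::runif(1) < cfg$geneless_rate) { ga[[i]] <- character(0); next }
    u <- stats::runif(1)
    size <- sample(2:3, 1)
    if (u < cfg$complex_rate) {
      gs <- take(size)
      gpr[[i]] <- list(op = "AND", args = as.list(gs))
    } else if (u < cfg$complex_rate + cfg$isozyme_rate) {
      gs <- take(size)
      gpr[[i]] <- list(op = "OR", args = as.list(gs))
    } else {
      gs <- take(1)
      gpr[[i]] <- gs
    }
    ga[[i]] <- gs
  }
  names(ga) <- rxns
  names(gpr) <- rxns
  metabolites <- data.frame(id = mets, name = mets, compartment = "",
                            stringsAsFactors = FALSE)
  present <- unique(edges$metabolite_id)
  metabolites <- metabolites[metabolites$id %in% present, , drop = FALSE]
  metabolic_network(metabolites, edges, ga,
                    gpr = gpr[!vapply(gpr, is.null, TRUE)])
}

#' Generate two-group probe expression with planted coordinated shifts
#'
#' Gene baselines are Normal(`baseline_mean`, `baseline_sd`); each probe
#' observation adds Normal(0, `probe_sd`) noise. For every planted
#' metabolite, a coherent sign is drawn and `frac_neighbors_affected` of
#' its neighbor genes are shifted by `sign * effect_size * baseline_sd` in
#' the first group; all other genes are null. Probes per gene follow the
#' configured law, all at rank tier 1.
#'
#' @param net a `MetabolicNetwork` from [gen_network()].
#' @param truth the truth list from [gen_network()].
#' @param cfg a [sim_config()].
#' @return list with `expr` (probe x sample matrix), `probe_map`, `groups`
#'   (named vector; labels `"case"`, `"control"`; the shift applies to
#'   case), `contrast`, and `truth` extended with per-metabolite `signs`
#'   and `affected_genes`.
#' @export
gen_expression <- function(net, truth, cfg) {
  set.seed(cfg$seed + 1L)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  shift <- stats::setNames(rep(0, cfg$n_genes), genes)
  signs <- stats::setNames(integer(0), character(0))
  affected <- list()
  for (m in truth$planted) {
    units <- neighbor_enzymes(net, m)
    nb <- sort(unique(unlist(lapply(units, `[[`, "gene_ids"))))
    sgn <- sample(c(-1L, 1L), 1)
    n_aff <- ceiling(cfg$frac_neighbors_affected * length(nb))
    aff <- sort(sample(nb, n_aff))
    fresh <- aff[shift[aff] == 0]  # genes shared with an earlier planted
    shift[fresh] <- sgn * cfg$effect_size * cfg$baseline_sd
    signs[m] <- sgn
    affected[[m]] <- aff
  }
  n <- cfg$n_samples_per_group
  samples <- sprintf("s%02d", seq_len(2 * n))
  groups <- stats::setNames(rep(c("case", "control"), each = n), samples)
  gene_mean <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  n_probes <- sample(seq_along(cfg$probes_per_gene_prob), cfg$n_genes,
                     replace = TRUE, prob = cfg$probes_per_gene_prob)
  probe_map <- data.frame(
    probe_id = unlist(lapply(seq_len(cfg$n_genes), function(i)
      sprintf("%s_at%d", genes[i], seq_len(n_probes[i])))),
    gene_id = rep(genes, n_probes),
    rank_tier = 1L, stringsAsFactors = FALSE)
  is_case <- groups[samples] == "case"
  mu <- outer(gene_mean[match(probe_map$gene_id, genes)], rep(1, 2 * n)) +
    outer(shift[probe_map$gene_id], as.numeric(is_case))
  expr <- mu + matrix(stats::rnorm(length(mu), 0, cfg$probe_sd), nrow(mu))
  dimnames(expr) <- list(probe_map$probe_id, samples)
  truth$signs <- signs
  truth$affected_genes <- affected
  list(expr = expr, probe_map = probe_map, groups = groups,
       contrast = c("case", "control"), truth = truth)
}

#' Gene-level expression by averaging probes
#' @param expr probe x sample matrix.
#' @param probe_map data.frame with `probe_id`, `gene_id`.
#' @return gene x sample matrix of per-gene probe means.
#' @export
gene_level_expression <- function(expr, probe_map) {
  g <- probe_map$gene_id[match(rownames(expr), probe_map$probe_id)]
  keep <- !is.na(g)
  m <- rowsum(expr[keep, , drop = FALSE], g[keep])
  m / as.vector(table(g[keep])[rownames(m)])
}

#' A synthetic transcription-factor position frequency matrix
#'
#' A 12-position matrix with a dominant consensus (17 of 20 counts per
#' position), informative enough for specific scanning.
#' @return a PFM list (`id`, `name`, `counts`).
#' @export
default_pfm <- function() {
  consensus <- c("T", "G", "A", "C", "G", "T", "C", "A", "G", "C", "A", "T")
  counts <- matrix(1, 4, length(consensus),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus)) counts[consensus[j], j] <- 17
  list(id = "M00001", name = "SYNTF_01", counts = counts)
}

# vectorized Markov sampling: n_seq sequences of length len, as codes
.sample_markov <- function(bg, n_seq, len) {
  out <- matrix(0L, n_seq, len)
  for (t in seq_len(len)) {
    if (t <= bg$order) {
      out[, t] <- sample.int(4, n_seq, replace = TRUE, prob = bg$base_freq)
    } else {
      ctx <- rep(0L, n_seq)
      for (j in seq_len(bg$order))
        ctx <- ctx + (out[, t - j] - 1L) * 4L^(j - 1L)
      pr <- bg$trans[ctx + 1L, , drop = FALSE]
      u <- stats::runif(n_seq)
      cp1 <- pr[, 1]; cp2 <- cp1 + pr[, 2]; cp3 <- cp2 + pr[, 3]
      out[, t] <- 1L + (u > cp1) + (u > cp2) + (u > cp3)
    }
  }
  out
}

.codes_to_seq <- function(x) {
  s <- c("A", "C", "G", "T", "N")[ifelse(is.na(x), 5L, x)]
  paste(s, collapse = "")
}

#' Generate synthetic promoters with planted motif instances
#'
#' Promoters are sampled from an order-`bg_order` Markov model trained on a
#' seeded random genome. Genes in `sets_with_motif` receive one
#' consensus-sampled instance of `pfm` at a uniform offset on a random
#' strand with probability `motif_plant_rate`. `n_decoys` column-shuffled
#' copies of the matrix are emitted (same information content, different
#' motif). A `mask_frac` fraction of bases is masked to `N` in short runs
#' that never overlap a planted instance. The promoters are also embedded
#' in a synthetic chromosome with a TSS table, so the coordinate-based
#' extraction path can be exercised end to end.
#'
#' @param genes character vector of gene ids needing promoters.
#' @param sets_with_motif gene ids whose promoters receive the motif.
#' @param pfm the true PFM (default [default_pfm()]).
#' @param cfg a [sim_config()].
#' @return list with `promoters` (named character), `genome` (named
#'   character, one chromosome), `tss` (data.frame `chrom`, `tss`,
#'   `strand`, `gene_id`), `pfms` (true matrix first, then decoys),
#'   `planted` (data.frame `gene_id`, `planted`, `offset`, `strand`), and
#'   `bg` (the generating `markov_bg`).
#' @export
gen_promoters <- function(genes, sets_with_motif, pfm = default_pfm(), cfg) {
  set.seed(cfg$seed + 2L)
  L <- ncol(pfm$counts)
  len <- cfg$promoter_length
  if (L >= len) stop("motif longer than promoter")
  # background trained on a seeded random genome with mild AT bias
  train_genome <- .codes_to_seq(sample.int(4, 60000, replace = TRUE,
                                           prob = c(0.3, 0.2, 0.2, 0.3)))
  bg <- train_background(train_genome, order = cfg$bg_order)
  codes <- .sample_markov(bg, length(genes), len)
  rownames(codes) <- genes
  freq <- sweep(pfm$counts, 2, colSums(pfm$counts), "/")
  planted <- data.frame(gene_id = genes, planted = FALSE, offset = NA_integer_,
                        strand = NA_character_, stringsAsFactors = FALSE)
  # per-position log-odds against the background's stationary composition:
  # instances are drawn from the matrix columns but kept only when they are
  # recognizable binding sites (score >= 75% of the matrix maximum), as a
  # planted site below the scanners' own 70% call threshold would not model
  # a functional site
  lo <- log(sweep(pfm$counts + 0.25, 2, colSums(pfm$counts) + 1, "/")) -
    log(bg$base_freq)
  smax <- sum(apply(lo, 2, max))
  consensus_codes <- apply(pfm$counts, 2, which.max)
  draw_instance <- function() {
    for (try in seq_len(50)) {
      inst <- vapply(seq_len(L), function(j)
        sample.int(4, 1, prob = freq[, j]), 0L)
      if (sum(lo[cbind(inst, seq_len(L))]) >= 0.75 * smax) return(inst)
    }
    consensus_codes
  }
  for (g in intersect(sets_with_motif, genes)) {
    if (stats::runif(1) > cfg$motif_plant_rate) next
    inst <- draw_instance()
    strand <- sample(c("+", "-"), 1)
    if (strand == "-") inst <- .revcomp_codes(inst)
    off <- sample.int(len - L + 1, 1)
    codes[g, off:(off + L - 1)] <- inst
    i <- match(g, planted$gene_id)
    planted$planted[i] <- TRUE
    planted$offset[i] <- off
    planted$strand[i] <- strand
  }
  # mask short runs to N, never touching a planted instance
  run_len <- 10L
  n_runs <- floor(cfg$mask_frac * len / run_len)
  for (i in seq_len(nrow(codes))) {
    keepout <- if (planted$planted[i])
      seq(planted$offset[i], planted$offset[i] + L - 1L) else integer(0)
    placed <- 0L
    for (tries in seq_len(200)) {
      if (placed >= n_runs) break
      st <- sample.int(len - run_len + 1L, 1)
      run <- st:(st + run_len - 1L)
      if (!length(intersect(run, keepout))) {
        codes[i, run] <- NA_integer_
        keepout <- c(keepout, run)
        placed <- placed + 1L
      }
    }
  }
  promoters <- stats::setNames(apply(codes, 1, .codes_to_seq), genes)
  # decoys: shuffled column order, never the identity permutation
  decoys <- lapply(seq_len(cfg$n_decoys), function(i) {
    repeat {
      perm <- sample(L)
      if (any(perm != seq_len(L))) break
    }
    list(id = sprintf("DECOY%02d", i), name = sprintf("DECOY_%02d", i),
         counts = pfm$counts[, perm, drop = FALSE])
  })
  # embed in one chromosome: spacer + oriented promoter segments
  spacer_len <- 50L
  strands <- sample(c("+", "-"), length(genes), replace = TRUE)
  segs <- character(2 * length(genes) + 1)
  segs[1] <- .codes_to_seq(sample.int(4, spacer_len, replace = TRUE))
  tss0 <- integer(length(genes))
  pos0 <- spacer_len  # 0-based start of next segment
  for (i in seq_along(genes)) {
    pseq <- promoters[[i]]
    seg <- if (strands[i] == "+") pseq else reverse_complement(pseq)
    segs[2 * i] <- seg
    tss0[i] <- if (strands[i] == "+") pos0 + 800L else pos0 + 199L
    pos0 <- pos0 + len
    segs[2 * i + 1] <- .codes_to_seq(sample.int(4, spacer_len, replace = TRUE))
    pos0 <- pos0 + spacer_len
  }
  genome <- stats::setNames(paste(segs, collapse = ""), "chrS")
  tss <- data.frame(chrom = "chrS", tss = tss0, strand = strands,
                    gene_id = genes, stringsAsFactors = FALSE)
  list(promoters = promoters, genome = genome, tss = tss,
       pfms = c(list(pfm), decoys), planted = planted, bg = bg)
}

#' Generate a phenotype linearly tied to a metabolite's centroid
#'
#' `phenotype = slope * centroid + Normal(0, noise_sd)` per sample, where
#' the centroid is the metabolite's standardized neighbor-gene mean.
#'
#' @param expr_genes gene-level expression matrix (genes x samples).
#' @param net a `MetabolicNetwork`.
#' @param metabolite_id the driving metabolite.
#' @param slope linear coefficient (default 1).
#' @param noise_sd Gaussian noise SD (default 0.5).
#' @param cfg a [sim_config()] (seed source).
#' @param groups named character vector, sample -> group label.
#' @return data.frame with columns `sample`, `value`, `group`.
#' @export
gen_phenotype <- function(expr_genes, net, metabolite_id, slope = 1,
                          noise_sd = 0.5, cfg, groups) {
  set.seed(cfg$seed + 3L)
  cen <- centroid_profile(expr_genes, net, metabolite_id)
  value <- slope * as.numeric(cen) + stats::rnorm(length(cen), 0, noise_sd)
  data.frame(sample = names(cen), value = value,
             group = unname(groups[names(cen)]), stringsAsFactors = FALSE)
}

#' Write a complete synthetic dataset to disk
#'
#' Generates network, expression, promoters and phenotype under one seed
#' and writes every format the pipeline reads: `network.tsv`,
#' `expression.tsv`, `probe_map.tsv`, `groups.tsv`, `promoters.fasta`,
#' `genome.fasta`, `tss.tsv`, `motifs.transfac`, `phenotype.tsv`, plus
#' `truth.json` for tests. The genes planted with the motif are the union
#' of the planted metabolites' affected genes (the coordinated shift and
#' the shared promoter motif emulate one upstream regulator).
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the generated objects and `files`, the
#'   named vector of written paths.
#' @export
simulate_dataset <- function(cfg = sim_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gn <- gen_network(cfg)
  ge <- gen_expression(gn$network, gn$truth, cfg)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  with_motif <- sort(unique(unlist(ge$truth$affected_genes)))
  gp <- gen_promoters(genes, with_motif, default_pfm(), cfg)
  expr_genes <- gene_level_expression(ge$expr, ge$probe_map)
  target <- if (length(gn$truth$planted)) gn$truth$planted[1] else
    gn$network$metabolites$id[1]
  ph <- gen_phenotype(expr_genes, gn$network, target, slope = 1,
                      noise_sd = 0.5, cfg = cfg, groups = ge$groups)
  files <- c(
    network = file.path(dir, "network.tsv"),
    expression = file.path(dir, "expression.tsv"),
    probe_map = file.path(dir, "probe_map.tsv"),
    groups = file.path(dir, "groups.tsv"),
    promoters = file.path(dir, "promoters.fasta"),
    genome = file.path(dir, "genome.fasta"),
    tss = file.path(dir, "tss.tsv"),
    motifs = file.path(dir, "motifs.transfac"),
    phenotype = file.path(dir, "phenotype.tsv"),
    truth = file.path(dir, "truth.json"))
  write_network_tsv(gn$network, files["network"])
  write_expression(ge$expr, files["expression"])
  utils::write.table(ge$probe_map, files["probe_map"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(ge$groups), group = unname(ge$groups)),
    files["groups"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(gp$promoters, files["promoters"])
  write_fasta(gp$genome, files["genome"])
  utils::write.table(gp$tss, files["tss"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_transfac(gp$pfms, files["motifs"])
  utils::write.table(ph, files["phenotype"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(seed = cfg$seed, planted = ge$truth$planted,
         signs = as.list(ge$truth$signs),
         affected_genes = ge$truth$affected_genes,
         motif_id = gp$pfms[[1]]$id,
         phenotype_metabolite = target),
    files["truth"], auto_unbox = TRUE, pretty = TRUE)
  invisible(list(network = gn$network, truth = ge$truth, expr = ge$expr,
                 probe_map = ge$probe_map, groups = ge$groups,
                 contrast = ge$contrast, promoters = gp, phenotype = ph,
                 files = files))
}
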