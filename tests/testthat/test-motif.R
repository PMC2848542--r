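test_that("TRANSFAC flat files parse, remap alphabets and round-trip", {
  f <- tempfile(fileext = ".transfac")
  writeLines(c(
    "AC M001", "NA TF_ONE", "P0      A      C      G      T",
    "01     10      0      0      2     A",
    "02      0     12      0      0     C",
    "03      0      0     12      0     G",
    "04      3      3      3      3     N",
    "05     12      0      0      0     A",
    "//",
    "AC M002", "NA TF_TWO", "P0      T      G      C      A",
    "01      9      1      1      1     T",
    "02      1      9      1      1     G",
    "03      1      1      9      1     C",
    "04      1      1      1      9     A",
    "//"), f)
  pfms <- parse_transfac(f)
  expect_length(pfms, 2)
  expect_equal(ncol(pfms[[1]]$counts), 5)
  expect_equal(unname(pfms[[1]]$counts["A", 1]), 10)
  # reordered alphabet header remapped to A,C,G,T rows
  expect_equal(unname(pfms[[2]]$counts[, 1]), c(1, 1, 1, 9))  # T-dominant
  expect_equal(pfm_consensus(pfms[[2]]), "TGCA")
  # empty file -> empty list
  empty <- tempfile(); writeLines(character(0), empty)
  expect_length(parse_transfac(empty), 0)
  # malformed position line names the record
  bad <- tempfile()
  writeLines(c("AC MBAD", "P0 A C G T", "01 x y z w N", "//"), bad)
  expect_error(parse_transfac(bad), "MBAD")
  # round trip
  out <- tempfile()
  write_transfac(pfms, out)
  again <- parse_transfac(out)
  expect_equal(again[[1]]$counts, pfms[[1]]$counts)
  expect_equal(again[[2]]$counts, pfms[[2]]$counts)
})

test_that("Markov background training matches known laws", {
  # poly-A: P(A | AA) -> 1 up to pseudocounts
  bgA <- train_background(strrep("A", 2000), order = 2)
  expect_gt(bgA$trans[1, "A"], 0.99)
  # i.i.d. uniform: all order-2 conditionals near 0.25
  set.seed(31)
  bgU <- train_background(random_dna(100000), order = 2)
  expect_true(all(abs(bgU$trans - 0.25) < 0.02))
  # order 0 equals the base composition
  set.seed(32)
  s <- random_dna(5000)
  bg0 <- train_background(s, order = 0)
  comp <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
  expect_equal(unname(bg0$trans[1, ]), as.numeric((comp + 1) / (sum(comp) + 4)),
               tolerance = 1e-12)
  expect_error(train_background("ACGT", order = 2), "lower order")
})

test_that("scanning finds a planted consensus and honors strand and masks", {
  set.seed(41)
  pfm <- default_pfm()
  bg <- uniform_bg()
  cons <- pfm_consensus(pfm)
  seq <- paste0(random_dna(40), cons, random_dna(40))
  res <- scan_sequence(seq, pfm, bg)
  expect_true(res$hit)
  # the consensus attains the matrix maximum against a uniform background
  expect_equal(res$best_score, pfm_smax(pfm, bg), tolerance = 1e-10)
  # reverse complement is found via the minus strand
  res_rc <- scan_sequence(reverse_complement(seq), pfm, bg)
  expect_true(res_rc$hit)
  expect_equal(res_rc$best_score, res$best_score, tolerance = 1e-12)
  # all-N sequence and too-short sequences never hit
  expect_false(scan_sequence(strrep("N", 100), pfm, bg)$hit)
  expect_false(scan_sequence("ACGT", pfm, bg)$hit)
})

test_that("hit calls are strand-symmetric for every generated matrix", {
  set.seed(43)
  cfg <- sim_config(seed = 43)
  gp <- gen_promoters(sprintf("g%04d", 1:8), sprintf("g%04d", 1:4),
                      default_pfm(), cfg)
  seqs <- gp$promoters[1:6]
  for (pfm in gp$pfms) {
    for (s in seqs) {
      a <- scan_sequence(s, pfm, gp$bg)
      b <- scan_sequence(reverse_complement(s), pfm, gp$bg)
      expect_identical(a$hit, b$hit)
      expect_equal(a$best_score, b$best_score, tolerance = 1e-12)
    }
  }
})

test_that("gene set selection keeps reporters with enough directional genes", {
  sc <- data.frame(
    metabolite_id = c("m1", "m2", "m3"),
    p = c(0.01, 0.04, 0.5),
    up_genes = c(paste(sprintf("u%d", 1:7), collapse = ";"),
                 paste(sprintf("v%d", 1:5), collapse = ";"),
                 paste(sprintf("w%d", 1:9), collapse = ";")),
    down_genes = c(paste(sprintf("d%d", 1:3), collapse = ";"),
                   paste(sprintf("e%d", 1:5), collapse = ";"),
                   ""))
  sets <- select_gene_sets(sc, alpha = 0.05, min_size = 5)
  # m1: only the up set (7 >= 5 > 3); m2: both at the inclusive boundary;
  # m3 is not a reporter and never emitted
  expect_setequal(names(sets), c("m1:up", "m2:up", "m2:down"))
  expect_length(sets[["m2:down"]], 5)
})

test_that("one-tailed Fisher p equals hypergeometric tail enumeration", {
  # closed form: all positives hit, no background hits
  expect_equal(fisher_onetail(5, 0, 0, 20), 1 / choose(25, 5),
               tolerance = 1e-12)
  # no positive hits: no evidence
  expect_equal(fisher_onetail(0, 5, 3, 17), 1)
  # brute-force tail sums on assorted tables, including balanced margins
  tail_oracle <- function(a, b, c_, d) {
    m <- a + c_; n <- b + d; k <- a + b
    xs <- max(0, k - n):min(k, m)
    probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
    sum(probs[xs >= a])
  }
  tables <- rbind(c(5, 5, 5, 5), c(3, 2, 1, 9), c(0, 4, 6, 2), c(7, 1, 2, 10),
                  c(2, 2, 8, 8), c(1, 0, 0, 1))
  for (i in seq_len(nrow(tables))) {
    tb <- tables[i, ]
    expect_equal(fisher_onetail(tb[1], tb[2], tb[3], tb[4]),
                 tail_oracle(tb[1], tb[2], tb[3], tb[4]), tolerance = 1e-12)
  }
  # monotone decreasing in a for fixed margins
  ps <- sapply(0:5, function(a) fisher_onetail(a, 5 - a, 5 - a, 15 + a))
  expect_true(all(diff(ps) < 0))
})

test_that("Storey q-values respect the rank formula and estimate pi0", {
  # single p with pi0 fixed at 1
  expect_equal(storey_q(0.04, pi0 = 1), 0.04)
  # identical p-values collapse to the same q
  expect_equal(storey_q(rep(0.01, 10), pi0 = 1), rep(0.01, 10))
  # pi0 = 1 reproduces Benjamini-Hochberg exactly
  set.seed(51)
  p <- runif(200)^1.5
  expect_equal(storey_q(p, pi0 = 1), p.adjust(p, "BH"), tolerance = 1e-12)
  # and in general q is never below pi0 * BH
  q <- storey_q(p)
  pi0 <- estimate_pi0(p)
  expect_true(all(q >= pi0 * p.adjust(p, "BH") - 1e-12))
  # uniform p-values: pi0 estimated near 1
  set.seed(52)
  pu <- runif(500)
  expect_gte(estimate_pi0(pu), 0.8)
  expect_lte(estimate_pi0(pu), 1)
  # monotone non-decreasing in p
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_length(storey_q(numeric(0)), 0)
})

test_that("promoter extraction does the strand-aware coordinate arithmetic", {
  set.seed(61)
  chrom <- random_dna(5000)
  genome <- c(chr1 = chrom)
  tss <- data.frame(chrom = "chr1", tss = 1000, strand = "+", gene_id = "gP")
  p <- extract_promoters(genome, tss)
  expect_equal(nchar(p[["gP"]]), 1000)
  expect_equal(p[["gP"]], substr(chrom, 201, 1200))
  # minus strand: reverse complement of the mirrored window
  tssm <- data.frame(chrom = "chr1", tss = 1000, strand = "-", gene_id = "gM")
  pm <- extract_promoters(genome, tssm)
  expect_equal(pm[["gM"]], reverse_complement(substr(chrom, 802, 1801)))
  # truncation at the chromosome start
  expect_warning(
    pt <- extract_promoters(genome, data.frame(chrom = "chr1", tss = 100,
                                               strand = "+", gene_id = "gT")),
    "truncated")
  expect_equal(nchar(pt[["gT"]]), 300)
  # soft-masked bases become N
  gsoft <- c(chr1 = paste0("AAAA", tolower("cgcg"), "TTTT"))
  ps <- extract_promoters(gsoft, data.frame(chrom = "chr1", tss = 8,
                                            strand = "+", gene_id = "gS"),
                          upstream = 6, downstream = 2)
  expect_equal(ps[["gS"]], "AANNNNTT")
  # unknown chromosome errors with the gene named
  expect_error(extract_promoters(genome, data.frame(
    chrom = "chrX", tss = 10, strand = "+", gene_id = "gZ")), "gZ")
  # TSS outside the chromosome is skipped with a warning
  expect_warning(
    p0 <- extract_promoters(genome, data.frame(chrom = "chr1", tss = 9999,
                                               strand = "+", gene_id = "gO")),
    "skipped")
  expect_length(p0, 0)
})

test_that("enrichment counts, q grouping and invariances behave", {
  set.seed(71)
  cfg <- sim_config(seed = 71, motif_plant_rate = 1)
  genes <- sprintf("g%04d", 1:60)
  pos <- genes[1:8]
  gp <- gen_promoters(genes, pos, default_pfm(), cfg)
  res <- enrich_motifs(list(set1 = pos), gp$promoters, gp$pfms,
                       background_gene_ids = genes, bg = gp$bg)
  expect_equal(nrow(res), length(gp$pfms))
  expect_true(all(res$a + res$b == 8))
  expect_true(all(res$c + res$d == 52))
  true_row <- res[res$motif_id == "M00001", ]
  expect_lt(true_row$p, 1e-4)
  expect_true(true_row$significant)
  # permuting gene order changes nothing
  res2 <- enrich_motifs(list(set1 = rev(pos)), gp$promoters, gp$pfms,
                        background_gene_ids = genes, bg = gp$bg)
  expect_equal(res2$p, res$p)
  # sets below min_size are skipped with a warning
  expect_warning(
    res3 <- enrich_motifs(list(tiny = genes[1:2]), gp$promoters, gp$pfms,
                          background_gene_ids = genes, bg = gp$bg),
    "skipped")
  expect_equal(nrow(res3), 0)
})
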