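# Shared fixtures, built in code.

# Two reactions around a shared metabolite plus a gene-less transport.
toy_network <- function() {
  metabolic_network(
    metabolites = data.frame(id = c("M", "A", "B"),
                             name = c("M", "A", "B"), compartment = ""),
    participants = data.frame(
      reaction_id = c("R1", "R1", "R2", "R2", "R3", "R3"),
      metabolite_id = c("A", "M", "M", "B", "B", "A"),
      role = c("substrate", "product", "substrate", "product",
               "substrate", "product")),
    gene_associations = list(R1 = c("g1", "g2"), R2 = "g3", R3 = character(0))
  )
}

toy_network_tsv <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "reaction_id\tmetabolite_id\trole\tgene_ids",
    "R1\tA\tsubstrate\tg1;g2",
    "R1\tM\tproduct\tg1;g2",
    "R2\tM\tsubstrate\tg3",
    "R2\tB\tproduct\tg3",
    "R3\tB\tsubstrate\t",
    "R3\tA\tproduct\t"), path)
  path
}

# exactly uniform order-0 background (equal counts + add-one keeps 0.25)
uniform_bg <- function() train_background(strrep("ACGT", 100), order = 0)

pfm_consensus <- function(pfm) {
  paste(c("A", "C", "G", "T")[apply(pfm$counts, 2, which.max)], collapse = "")
}

# maximum achievable log-odds score against a background's stationary
# composition, computed from first principles (0.25 pseudocount per cell)
pfm_smax <- function(pfm, bg) {
  f <- sweep(pfm$counts + 0.25, 2, colSums(pfm$counts) + 1, "/")
  sum(apply(log(f) - log(bg$base_freq), 2, max))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# gene scores where every gene has the same p (direction up)
flat_gene_scores <- function(genes, p = 0.5) {
  data.frame(gene_id = genes, p = p, logfc = 1, direction = "up",
             stringsAsFactors = FALSE)
}
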