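test_that("network TSV loads, queries and round-trips", {
  path <- toy_network_tsv()
  net <- load_network(path, "tsv")
  expect_s3_class(net, "MetabolicNetwork")
  # M sits between R1 and R2
  expect_setequal(
    net$participants$reaction_id[net$participants$metabolite_id == "M"],
    c("R1", "R2"))
  units <- neighbor_enzymes(net, "M")
  expect_length(units, 2)
  expect_equal(sort(vapply(units, function(u) paste(u$gene_ids, collapse = "+"),
                           "")), c("g1+g2", "g3"))
  # round trip preserves content
  out <- tempfile(fileext = ".tsv")
  write_network_tsv(net, out)
  net2 <- load_network(out, "tsv")
  expect_equal(net2$metabolites, net$metabolites)
  expect_equal(net2$participants, net$participants)
  expect_equal(lapply(net2$gene_associations, sort),
               lapply(net$gene_associations, sort))
})

test_that("compartment collapse merges suffix variants", {
  net <- metabolic_network(
    data.frame(id = c("atp_c", "atp_m", "glc_c")),
    data.frame(reaction_id = c("R1", "R2", "R1"),
               metabolite_id = c("atp_c", "atp_m", "glc_c"),
               role = c("substrate", "substrate", "product")),
    list(R1 = "g1", R2 = "g2"))
  merged <- collapse_compartments(net)
  expect_setequal(merged$metabolites$id, c("atp", "glc"))
  expect_setequal(
    merged$participants$reaction_id[merged$participants$metabolite_id == "atp"],
    c("R1", "R2"))
  expect_length(neighbor_enzymes(merged, "atp"), 2)
})

test_that("validation rejects malformed networks", {
  # unknown role token
  bad_role <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tmetabolite_id\trole\tgene_ids",
               "R1\tM\tcofactor\tg1"), bad_role)
  expect_error(load_network(bad_role, "tsv"), "unknown role")
  # dangling metabolite reference
  expect_error(metabolic_network(
    data.frame(id = "A"),
    data.frame(reaction_id = "R1", metabolite_id = c("A", "Z"),
               role = c("substrate", "product")),
    list(R1 = character(0))), "undeclared metabolite")
  # empty metabolite id on a data row
  blank <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tmetabolite_id\trole\tgene_ids",
               "R1\t\tsubstrate\tg1"), blank)
  expect_error(load_network(blank, "tsv"), "empty reaction or metabolite id")
  expect_error(load_network(tempfile(), "tsv"), "not found")
  expect_error(neighbor_enzymes(toy_network(), "nope"), "unknown metabolite")
})

test_that("neighbor enzymes deduplicate gene sets and skip gene-less reactions", {
  net <- metabolic_network(
    data.frame(id = c("M", "X")),
    data.frame(reaction_id = c("R1", "R2", "R3", "R4", "R1", "R2", "R3", "R4"),
               metabolite_id = c("M", "M", "M", "M", "X", "X", "X", "X"),
               role = rep(c("substrate", "product"), each = 4)),
    list(R1 = "g1", R2 = "g1", R3 = c("g2", "g3"), R4 = character(0)))
  units <- neighbor_enzymes(net, "M")
  expect_length(units, 2)  # {g1} deduped across R1/R2, R4 contributes nothing
  g1 <- units[[which(vapply(units, function(u) identical(u$gene_ids, "g1"), TRUE))]]
  expect_setequal(g1$source_reaction_ids, c("R1", "R2"))
  expect_length(neighbor_enzymes(net, "M", dedup = FALSE), 3)
  # a metabolite touched only by gene-less reactions has k = 0
  net2 <- metabolic_network(
    data.frame(id = "T"),
    data.frame(reaction_id = "R1", metabolite_id = "T", role = "substrate"),
    list(R1 = character(0)))
  expect_length(neighbor_enzymes(net2, "T"), 0)
})

test_that("enzyme scoring takes the minimum p over scored genes", {
  scores <- data.frame(gene_id = c("g1", "g2", "g3"), p = c(0.40, 0.01, 0.22))
  u <- list(gene_ids = c("g1", "g2", "g3"), source_reaction_ids = "R1")
  s <- score_enzyme(u, scores)
  expect_equal(as.numeric(s), 0.01)
  expect_equal(attr(s, "gene"), "g2")
  expect_equal(as.numeric(score_enzyme(list(gene_ids = "g1"), scores)), 0.4)
  # unscored genes are ignored; all-unscored yields the missing marker
  expect_equal(as.numeric(score_enzyme(list(gene_ids = c("gX", "g3")), scores)), 0.22)
  expect_true(is.na(score_enzyme(list(gene_ids = c("gX", "gY")), scores)))
  # never exceeds any input and is one of the inputs
  expect_true(as.numeric(s) %in% scores$p)
})

test_that("neighbor enzymes are symmetric in substrate/product roles", {
  set.seed(11)
  for (i in 1:5) {
    cfg <- sim_config(n_metabolites = 15, n_reactions = 30, n_genes = 30,
                      n_planted_reporters = 0, seed = 100 + i)
    net <- gen_network(cfg)$network
    flipped <- net
    flipped$participants$role <- ifelse(
      net$participants$role == "substrate", "product", "substrate")
    for (m in net$metabolites$id) {
      expect_identical(neighbor_enzymes(net, m), neighbor_enzymes(flipped, m))
    }
  }
})

test_that("k after dedup never exceeds the gene-associated neighbor count", {
  cfg <- sim_config(n_metabolites = 20, n_reactions = 40, n_genes = 25,
                    n_planted_reporters = 0, seed = 5)
  net <- gen_network(cfg)$network
  for (m in net$metabolites$id) {
    rxns <- unique(net$participants$reaction_id[
      net$participants$metabolite_id == m])
    n_assoc <- sum(vapply(rxns, function(r)
      length(net$gene_associations[[r]]) > 0, TRUE))
    expect_lte(length(neighbor_enzymes(net, m)), n_assoc)
  }
})

test_that("SBML readers handle fbc associations and legacy notes", {
  fbc <- tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1">
 <model id="toy">
  <listOfSpecies>
   <species id="glc_c" name="glucose" compartment="c"/>
   <species id="atp_c" name="ATP" compartment="c"/>
   <species id="g6p_c" name="G6P" compartment="c"/>
  </listOfSpecies>
  <fbc:listOfGeneProducts>
   <fbc:geneProduct fbc:id="gp1" fbc:label="HK1"/>
   <fbc:geneProduct fbc:id="gp2" fbc:label="HK2"/>
   <fbc:geneProduct fbc:id="gp3" fbc:label="GPI"/>
  </fbc:listOfGeneProducts>
  <listOfReactions>
   <reaction id="HEX1" reversible="false">
    <listOfReactants>
     <speciesReference species="glc_c" constant="true"/>
     <speciesReference species="atp_c" constant="true"/>
    </listOfReactants>
    <listOfProducts>
     <speciesReference species="g6p_c" constant="true"/>
    </listOfProducts>
    <fbc:geneProductAssociation>
     <fbc:or>
      <fbc:geneProductRef fbc:geneProduct="gp1"/>
      <fbc:geneProductRef fbc:geneProduct="gp2"/>
     </fbc:or>
    </fbc:geneProductAssociation>
   </reaction>
   <reaction id="PGI" reversible="true">
    <listOfReactants><speciesReference species="g6p_c"/></listOfReactants>
    <listOfProducts><speciesReference species="glc_c"/></listOfProducts>
    <fbc:geneProductAssociation>
     <fbc:geneProductRef fbc:geneProduct="gp3"/>
    </fbc:geneProductAssociation>
   </reaction>
  </listOfReactions>
 </model>
</sbml>', fbc)
  net <- load_network(fbc, "sbml")
  expect_setequal(net$gene_associations$HEX1, c("HK1", "HK2"))
  expect_equal(net$gene_associations$PGI, "GPI")
  expect_equal(net$gpr$HEX1$op, "OR")
  units <- neighbor_enzymes(net, "g6p_c")
  expect_length(units, 2)

  legacy <- tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">
 <model id="toy2">
  <listOfSpecies>
   <species id="A" compartment="c"/>
   <species id="B" compartment="c"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="R1">
    <notes><body xmlns="http://www.w3.org/1999/xhtml">
      <p>GENE_ASSOCIATION: (ga and gb) or gc</p>
    </body></notes>
    <listOfReactants><speciesReference species="A"/></listOfReactants>
    <listOfProducts><speciesReference species="B"/></listOfProducts>
   </reaction>
  </listOfReactions>
 </model>
</sbml>', legacy)
  net2 <- load_network(legacy, "sbml")
  expect_setequal(net2$gene_associations$R1, c("ga", "gb", "gc"))
  expect_equal(net2$gpr$R1$op, "OR")
  expect_equal(net2$gpr$R1$args[[1]]$op, "AND")
})
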