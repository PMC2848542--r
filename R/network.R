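# Metabolic network container: bipartite metabolite-reaction topology with
# gene-protein-reaction (GPR) associations. Only topology is kept; the
# reporter scoring never looks at stoichiometry or reversibility.

.roles <- c("substrate", "product")

#' Construct a metabolic network object
#'
#' Low-level constructor used by [load_network()] and the synthetic-data
#' generator. Most users should read networks from file instead.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`
#'   (compartment may be the empty string).
#' @param participants data.frame with columns `reaction_id`, `metabolite_id`,
#'   `role` (one of `"substrate"`, `"product"`). One row per
#'   reaction-metabolite incidence.
#' @param gene_associations named list, one entry per reaction id, each a
#'   character vector of gene ids (possibly empty for spontaneous or
#'   transport reactions).
#' @param gpr optional named list of nested AND/OR trees retained for
#'   provenance; never consulted by the scoring, which collapses every
#'   association by the minimum gene p-value.
#' @return An object of class `MetabolicNetwork`.
#' @export
metabolic_network <- function(metabolites, participants, gene_associations, gpr = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  participants <- as.data.frame(participants, stringsAsFactors = FALSE)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- ""
  net <- structure(
    list(
      metabolites = metabolites[, c("id", "name", "compartment")],
      participants = participants[, c("reaction_id", "metabolite_id", "role")],
      gene_associations = gene_associations,
      gpr = gpr
    ),
    class = "MetabolicNetwork"
  )
  validate_network(net)
  net
}

#' Validate a metabolic network
#'
#' Checks the structural invariants: unique metabolite and reaction ids,
#' every participant resolving to a declared metabolite, known role tokens,
#' and at least one participant per reaction.
#'
#' @param net a `MetabolicNetwork`.
#' @return `net`, invisibly. Errors describe all offenders found.
#' @export
validate_network <- function(net) {
  m <- net$metabolites
  p <- net$participants
  if (anyDuplicated(m$id))
    stop("duplicate metabolite ids: ", paste(unique(m$id[duplicated(m$id)]), collapse = ", "))
  if (any(is.na(m$id) | m$id == ""))
    stop("empty metabolite id in metabolite table")
  bad_role <- setdiff(unique(p$role), .roles)
  if (length(bad_role))
    stop("unknown role token(s): ", paste(bad_role, collapse = ", "),
         " (expected 'substrate' or 'product')")
  dangling <- setdiff(unique(p$metabolite_id), m$id)
  if (length(dangling))
    stop("participant references undeclared metabolite(s): ",
         paste(dangling, collapse = ", "))
  rxns <- reaction_ids(net)
  if (!length(rxns)) stop("network has no reactions")
  ga_extra <- setdiff(names(net$gene_associations), rxns)
  if (length(ga_extra))
    stop("gene associations for unknown reaction(s): ", paste(ga_extra, collapse = ", "))
  invisible(net)
}

#' Reaction ids of a network
#' @param net a `MetabolicNetwork`.
#' @return character vector of reaction ids, in order of first appearance.
#' @export
reaction_ids <- function(net) unique(net$participants$reaction_id)

#' @export
print.MetabolicNetwork <- function(x, ...) {
  n_ga <- sum(vapply(x$gene_associations, length, 1L) > 0)
  cat(sprintf(
    "MetabolicNetwork: %d metabolites, %d reactions (%d gene-associated), %d incidences\n",
    nrow(x$metabolites), length(reaction_ids(x)), n_ga, nrow(x$participants)))
  invisible(x)
}

#' Genes associated with a reaction (flattened)
#' @keywords internal
reaction_genes <- function(net, reaction_id) {
  g <- net$gene_associations[[reaction_id]]
  if (is.null(g)) character(0) else g
}

#' Load a metabolic network from file
#'
#' Reads either the tab-delimited reaction table (columns `reaction_id`,
#' `metabolite_id`, `role`, `gene_ids` with semicolon-separated, possibly
#' empty gene lists; header required) or SBML Level 2/3. For SBML, gene
#' associations are taken from `fbc:geneProductAssociation` elements or,
#' failing that, from legacy `GENE_ASSOCIATION:` notes; gene ids are used
#' verbatim and case-sensitively.
#'
#' @param path path to the network file.
#' @param format `"tsv"` or `"sbml"`.
#' @param collapse_compartments if `TRUE`, metabolites whose ids differ only
#'   by a compartment suffix (matched by `compartment_pattern`) are merged
#'   into a single node whose neighbor reactions are the union. Off by
#'   default.
#' @param compartment_pattern regular expression matching the compartment
#'   suffix at the end of a metabolite id (default `"_[a-z][0-9a-z]*$"`,
#'   e.g. `"atp_c"`, `"atp_m"`).
#' @return A `MetabolicNetwork`.
#' @export
load_network <- function(path, format = c("tsv", "sbml"),
                         collapse_compartments = FALSE,
                         compartment_pattern = "_[a-z][0-9a-z]*$") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  net <- switch(format,
    tsv = .load_network_tsv(path, compartment_pattern),
    sbml = .load_network_sbml(path)
  )
  if (collapse_compartments) net <- collapse_compartments(net, compartment_pattern)
  net
}

.load_network_tsv <- function(path, compartment_pattern) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           na.strings = NULL, fileEncoding = "UTF-8")
  need <- c("reaction_id", "metabolite_id", "role", "gene_ids")
  if (!all(need %in% names(tab)))
    stop("network TSV '", path, "' must have header columns: ",
         paste(need, collapse = ", "))
  if (!nrow(tab)) stop("network TSV '", path, "' has no data rows")
  blank <- which(tab$metabolite_id == "" | tab$reaction_id == "")
  if (length(blank))
    stop("network TSV '", path, "': empty reaction or metabolite id at data line(s) ",
         paste(blank, collapse = ", "))
  met_ids <- unique(tab$metabolite_id)
  comp <- rep("", length(met_ids))
  hit <- grepl(compartment_pattern, met_ids)
  comp[hit] <- sub("^_", "", regmatches(met_ids[hit],
                                        regexpr(compartment_pattern, met_ids[hit])))
  metabolites <- data.frame(id = met_ids, name = met_ids,
                            compartment = comp, stringsAsFactors = FALSE)
  participants <- tab[, c("reaction_id", "metabolite_id", "role")]
  ga <- lapply(split(tab$gene_ids, tab$reaction_id), function(gs) {
    genes <- unique(unlist(strsplit(gs[gs != ""], ";", fixed = TRUE)))
    genes[genes != ""]
  })
  rxns <- unique(tab$reaction_id)
  ga <- ga[rxns]
  names(ga) <- rxns
  ga[vapply(ga, is.null, TRUE)] <- list(character(0))
  metabolic_network(metabolites, participants, ga)
}

#' Write a metabolic network to the 4-column TSV format
#'
#' Inverse of `load_network(format = "tsv")`: a reload yields identical
#' metabolite, reaction and gene-association content.
#'
#' @param net a `MetabolicNetwork`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  p <- net$participants
  gene_str <- vapply(p$reaction_id, function(r)
    paste(reaction_genes(net, r), collapse = ";"), "")
  out <- data.frame(reaction_id = p$reaction_id, metabolite_id = p$metabolite_id,
                    role = p$role, gene_ids = gene_str, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# --- SBML ------------------------------------------------------------------

.xattr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) "" else v
}

.load_network_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML '", path, "': ",
                                           conditionMessage(e)))
  sp <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  if (!length(sp)) stop("SBML '", path, "' declares no species")
  metabolites <- data.frame(
    id = vapply(sp, .xattr, "", name = "id"),
    name = vapply(sp, function(s) {
      nm <- .xattr(s, "name"); if (nm == "") .xattr(s, "id") else nm
    }, ""),
    compartment = vapply(sp, .xattr, "", name = "compartment"),
    stringsAsFactors = FALSE
  )
  # fbc gene products: internal id -> label
  gps <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  gp_label <- vapply(gps, function(g) {
    lab <- .xattr(g, "label")
    if (lab == "") lab <- .xattr(g, "name")
    if (lab == "") lab <- .xattr(g, "id")
    lab
  }, "")
  names(gp_label) <- vapply(gps, .xattr, "", name = "id")

  rx <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  if (!length(rx)) stop("SBML '", path, "' declares no reactions")
  part_list <- vector("list", length(rx))
  ga <- vector("list", length(rx))
  gpr <- vector("list", length(rx))
  rids <- character(length(rx))
  for (i in seq_along(rx)) {
    r <- rx[[i]]
    rid <- .xattr(r, "id")
    rids[i] <- rid
    subs <- xml2::xml_find_all(
      r, ".//*[local-name()='listOfReactants']/*[local-name()='speciesReference']")
    prods <- xml2::xml_find_all(
      r, ".//*[local-name()='listOfProducts']/*[local-name()='speciesReference']")
    smet <- vapply(subs, .xattr, "", name = "species")
    pmet <- vapply(prods, .xattr, "", name = "species")
    part_list[[i]] <- data.frame(
      reaction_id = rid,
      metabolite_id = c(smet, pmet),
      role = c(rep("substrate", length(smet)), rep("product", length(pmet))),
      stringsAsFactors = FALSE
    )
    assoc <- xml2::xml_find_first(
      r, ".//*[local-name()='geneProductAssociation']")
    if (!inherits(assoc, "xml_missing")) {
      tree <- .fbc_tree(xml2::xml_children(assoc)[[1]], gp_label)
      gpr[[i]] <- tree
      ga[[i]] <- unique(.flatten_gpr(tree))
    } else {
      notes <- xml2::xml_find_first(r, ".//*[local-name()='notes']")
      txt <- if (inherits(notes, "xml_missing")) "" else xml2::xml_text(notes)
      m <- regmatches(txt, regexpr("GENE_ASSOCIATION:[^\n\r]*", txt))
      if (length(m)) {
        expr <- trimws(sub("^GENE_ASSOCIATION:", "", m[1]))
        if (nzchar(expr)) {
          tree <- .parse_gpr_string(expr)
          gpr[[i]] <- tree
          ga[[i]] <- unique(.flatten_gpr(tree))
        } else ga[[i]] <- character(0)
      } else ga[[i]] <- character(0)
    }
    if (is.null(ga[[i]])) ga[[i]] <- character(0)
  }
  names(ga) <- rids
  names(gpr) <- rids
  participants <- do.call(rbind, part_list)
  # species never referenced still belong to the model, but scoring ignores
  # them; keep only referenced ones consistent with the TSV representation
  metabolites <- metabolites[metabolites$id %in% participants$metabolite_id, ,
                             drop = FALSE]
  metabolic_network(metabolites, participants, ga,
                    gpr = gpr[!vapply(gpr, is.null, TRUE)])
}

.fbc_tree <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- .xattr(node, "geneProduct")
    lab <- gp_label[ref]
    if (is.na(lab) || lab == "") lab <- ref
    unname(lab)
  } else if (nm %in% c("and", "or")) {
    kids <- lapply(xml2::xml_children(node), .fbc_tree, gp_label = gp_label)
    c(list(op = toupper(nm)), list(args = kids))
  } else {
    stop("unsupported element in gene association: ", nm)
  }
}

# Recursive-descent parser for boolean GPR strings like
# "(g1 and g2) or g3"; case-insensitive and/or, parentheses allowed.
.parse_gpr_string <- function(expr) {
  toks <- regmatches(expr, gregexpr("\\(|\\)|[^()[:space:]]+", expr))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance(); args <- c(args, list(parse_and()))
    }
    if (length(args) == 1) args[[1]] else list(op = "OR", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance(); args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1) args[[1]] else list(op = "AND", args = args)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("malformed gene association: '", expr, "'")
    if (t == "(") {
      advance()
      sub <- parse_or()
      if (is.na(peek()) || advance() != ")")
        stop("unbalanced parentheses in gene association: '", expr, "'")
      sub
    } else advance()
  }
  out <- parse_or()
  if (pos <= length(toks))
    stop("trailing tokens in gene association: '", expr, "'")
  out
}

.flatten_gpr <- function(tree) {
  if (is.character(tree)) return(tree)
  unlist(lapply(tree$args, .flatten_gpr), use.names = FALSE)
}

# --- compartment collapse --------------------------------------------------

#' Merge compartment-specific metabolite nodes
#'
#' Metabolites whose ids differ only by a compartment suffix (e.g. `atp_c`,
#' `atp_m`) become one node whose neighbor reactions are the union of the
#' originals'.
#'
#' @param net a `MetabolicNetwork`.
#' @param compartment_pattern regex matching the suffix to strip.
#' @return A `MetabolicNetwork` with merged metabolites.
#' @export
collapse_compartments <- function(net, compartment_pattern = "_[a-z][0-9a-z]*$") {
  base <- sub(compartment_pattern, "", net$metabolites$id)
  map <- stats::setNames(base, net$metabolites$id)
  p <- net$participants
  p$metabolite_id <- unname(map[p$metabolite_id])
  p <- unique(p)
  mets <- data.frame(id = unique(base), stringsAsFactors = FALSE)
  mets$name <- mets$id
  mets$compartment <- ""
  metabolic_network(mets, p, net$gene_associations, gpr = net$gpr)
}

# --- neighbor enzymes ------------------------------------------------------

#' Neighbor enzymes of a metabolite
#'
#' Returns one enzyme unit per distinct gene set over all reactions touching
#' the metabolite as substrate or product (role plays no part). Reactions
#' without gene association contribute nothing. With `dedup = TRUE` (the
#' default) identical gene sets arising from several neighbor reactions are
#' merged, so one transcript signal is never counted twice; `dedup = FALSE`
#' restores per-reaction counting for sensitivity analysis.
#'
#' @param net a `MetabolicNetwork`.
#' @param metabolite_id metabolite to query.
#' @param dedup merge enzyme units with identical gene sets (default `TRUE`).
#' @return A list of enzyme units, each a list with elements `gene_ids`
#'   (sorted character vector) and `source_reaction_ids`. The list length is
#'   the metabolite's neighbor count `k`.
#' @export
neighbor_enzymes <- function(net, metabolite_id, dedup = TRUE) {
  if (!metabolite_id %in% net$metabolites$id)
    stop("unknown metabolite id: ", metabolite_id)
  rxns <- unique(net$participants$reaction_id[
    net$participants$metabolite_id == metabolite_id])
  .enzyme_units(net, rxns, dedup = dedup)
}

.enzyme_units <- function(net, rxns, dedup = TRUE) {
  units <- list()
  keys <- character(0)
  n <- 0L
  for (r in rxns) {
    genes <- reaction_genes(net, r)
    if (!length(genes)) next
    genes <- sort(unique(genes))
    key <- paste(genes, collapse = "\r")
    if (dedup && key %in% keys) {
      i <- match(key, keys)
      units[[i]]$source_reaction_ids <- union(units[[i]]$source_reaction_ids, r)
    } else {
      n <- n + 1L
      units[[n]] <- list(gene_ids = genes, source_reaction_ids = r)
      keys[n] <- key
    }
  }
  units
}

#' All scored enzyme units of a network
#'
#' The distinct gene sets over every gene-associated reaction; this is the
#' background population from which size-k enzyme sets are sampled during
#' reporter scoring.
#'
#' @param net a `MetabolicNetwork`.
#' @param dedup merge identical gene sets network-wide (default `TRUE`).
#' @return list of enzyme units as in [neighbor_enzymes()].
#' @export
network_enzymes <- function(net, dedup = TRUE) {
  .enzyme_units(net, reaction_ids(net), dedup = dedup)
}

#' Score an enzyme unit from gene-level p-values
#'
#' An enzyme (isozyme group or complex alike) takes the p-value of its most
#' significantly changed gene: the minimum p over the unit's scored genes.
#' Genes without a score are ignored; a unit none of whose genes is scored
#' yields `NA` (a missing marker, not an error) and is excluded from the
#' neighbor count by the caller.
#'
#' @param unit an enzyme unit (list with `gene_ids`).
#' @param gene_scores data.frame with columns `gene_id` and `p` (a
#'   `GeneScore` table), or a named numeric vector of p-values.
#' @return The minimum p-value, with attribute `"gene"` naming the gene that
#'   attains it; `NA_real_` if no gene of the unit is scored.
#' @export
score_enzyme <- function(unit, gene_scores) {
  p <- .gene_p_vector(gene_scores)
  ps <- p[unit$gene_ids]
  ok <- !is.na(ps)
  if (!any(ok)) return(NA_real_)
  ps <- ps[ok]
  i <- which.min(ps)
  structure(unname(ps[i]), gene = unit$gene_ids[ok][i])
}

.gene_p_vector <- function(gene_scores) {
  if (is.data.frame(gene_scores)) {
    stats::setNames(gene_scores$p, gene_scores$gene_id)
  } else if (is.numeric(gene_scores) && !is.null(names(gene_scores))) {
    gene_scores
  } else stop("gene_scores must be a GeneScore data.frame or a named numeric vector")
}
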