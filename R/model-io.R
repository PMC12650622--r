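#' Genome-scale metabolic model container
#'
#' A `pdmr_metabolic_model` holds metabolites (id, name, compartment),
#' reactions (id, stoichiometry as a named numeric vector over metabolite
#' ids, a boolean gene-protein-reaction rule, a subsystem label) and the
#' declared gene list.  Constructors validate that every reaction references
#' declared metabolites, every GPR parses and references declared genes, and
#' every reaction carries exactly one subsystem (`"unassigned"` if absent).
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions list of lists with `id`, `stoichiometry`, `gpr`,
#'   `subsystem`.
#' @param genes character vector of declared gene ids.
#' @param model_id model identifier.
#' @return object of class `pdmr_metabolic_model`.
#' @name pdmr_metabolic_model
#' @export
new_metabolic_model <- function(metabolites, reactions, genes,
                                model_id = "model") {
  assert_that(all(c("id", "name", "compartment") %in% names(metabolites)),
              "metabolites need id/name/compartment columns")
  met_ids <- metabolites$id
  for (r in reactions) {
    missing_m <- setdiff(names(r$stoichiometry), met_ids)
    assert_that(length(missing_m) == 0,
                "reaction '%s' references undeclared metabolite(s): %s",
                r$id, paste(missing_m, collapse = ", "))
    assert_that(length(r$stoichiometry) > 0,
                "reaction '%s' has empty stoichiometry", r$id)
    if (nzchar(r$gpr %||% "")) {
      rule_genes <- tryCatch(gpr_genes(parse_gpr(r$gpr)),
                             error = function(e) stop_pdmr(
                               "reaction '%s': unparseable GPR '%s' (%s)",
                               r$id, r$gpr, conditionMessage(e)))
      extra <- setdiff(rule_genes, genes)
      assert_that(length(extra) == 0,
                  "reaction '%s' GPR references undeclared gene(s): %s",
                  r$id, paste(extra, collapse = ", "))
    }
  }
  reactions <- lapply(reactions, function(r) {
    r$subsystem <- if (nzchar(r$subsystem %||% "")) r$subsystem else "unassigned"
    r$gpr <- r$gpr %||% ""
    r
  })
  orphan <- setdiff(met_ids, unique(unlist(
    lapply(reactions, function(r) names(r$stoichiometry)))))
  assert_that(length(orphan) == 0,
              "metabolite(s) with no reactions: %s",
              paste(orphan, collapse = ", "))
  structure(list(id = model_id, metabolites = metabolites,
                 reactions = reactions, genes = genes),
            class = "pdmr_metabolic_model")
}

#' @export
print.pdmr_metabolic_model <- function(x, ...) {
  cat(sprintf("pdmr_metabolic_model '%s': %d metabolites, %d reactions, %d genes\n",
              x$id, nrow(x$metabolites), length(x$reactions), length(x$genes)))
  invisible(x)
}

# ---- GPR boolean expressions -------------------------------------------------
# Grammar:  expr := term ('or' term)* ; term := factor ('and' factor)* ;
#           factor := GENE | '(' expr ')'
# Parsed form: a gene id string, or list(op = "and"|"or", args = list(...)).

tokenize_gpr <- function(rule) {
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", rule)[[1]]
  regmatches(rule, list(m))[[1]]
}

#' Parse a gene-protein-reaction rule
#'
#' @param rule boolean expression over gene ids using `and`, `or` and
#'   parentheses (case-insensitive keywords).
#' @return a gene id, or a nested list with elements `op` and `args`.
#' @export
parse_gpr <- function(rule) {
  toks <- tokenize_gpr(rule)
  assert_that(length(toks) > 0, "empty GPR rule")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take(); args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take(); args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- take()
    assert_that(!is.na(t), "GPR ended unexpectedly")
    if (t == "(") {
      e <- parse_expr()
      assert_that(identical(take(), ")"), "missing ')' in GPR")
      return(e)
    }
    assert_that(t != ")" && !(tolower(t) %in% c("and", "or")),
                "unexpected token '%s' in GPR", t)
    t
  }
  out <- parse_expr()
  assert_that(is.na(peek()), "trailing token '%s' in GPR", peek())
  out
}

# All gene ids appearing in a parsed rule.
gpr_genes <- function(node) {
  if (is.character(node)) return(node)
  unique(unlist(lapply(node$args, gpr_genes)))
}

#' Evaluate a GPR rule against differential-expression flags
#'
#' A reaction is considered DE-linked iff ANY gene in its rule is flagged
#' (OR-collapse linkage policy); the full AND/OR structure is nevertheless
#' parsed and can be evaluated strictly via `policy = "boolean"`.
#' Genes missing from `de_flags` are treated as not differentially
#' expressed.
#'
#' @param rule GPR rule string (or an already-parsed rule).
#' @param de_flags named logical vector, gene -> flagged.
#' @param policy `"any"` (default, OR-collapse) or `"boolean"` (respect
#'   AND/OR semantics).
#' @return logical scalar.
#' @export
evaluate_gpr <- function(rule, de_flags, policy = c("any", "boolean")) {
  policy <- match.arg(policy)
  if (is.character(rule) && length(rule) == 1L && !nzchar(rule)) return(FALSE)
  node <- if (is.character(rule) && length(rule) == 1L &&
                grepl("[()[:space:]]", rule)) parse_gpr(rule)
          else if (is.list(rule)) rule else parse_gpr(rule)
  flag <- function(g) isTRUE(unname(de_flags[g]))
  if (policy == "any") return(any(vapply(gpr_genes(node), flag, logical(1))))
  evl <- function(nd) {
    if (is.character(nd)) return(flag(nd))
    vals <- vapply(nd$args, evl, logical(1))
    if (nd$op == "and") all(vals) else any(vals)
  }
  evl(node)
}

# ---- JSON (community COBRA dialect) -----------------------------------------

#' Read a metabolic model from JSON or SBML
#'
#' JSON follows the community constraint-based-model dialect (`metabolites`,
#' `reactions` with a `metabolites` coefficient map and
#' `gene_reaction_rule`, `genes`).  SBML support covers Level 3 flux-balance
#' models whose GPRs are encoded either with `fbc:geneProductAssociation`
#' elements or `GENE_ASSOCIATION:` notes, with subsystems in `SUBSYSTEM:`
#' notes.
#'
#' @param path file path.
#' @param format `"json"`, `"sbml"`, or `"auto"` (by file extension).
#' @return a [pdmr_metabolic_model].
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml"
              else "json"
  if (format == "json") load_model_json(path) else load_model_sbml(path)
}

load_model_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(j$metabolites, function(m) data.frame(
    id = m$id, name = m$name %||% m$id,
    compartment = m$compartment %||% "", stringsAsFactors = FALSE)))
  reactions <- lapply(j$reactions, function(r) list(
    id = r$id,
    stoichiometry = unlist(r$metabolites),
    gpr = r$gene_reaction_rule %||% "",
    subsystem = r$subsystem %||% ""))
  genes <- vapply(j$genes, function(g) g$id, character(1))
  new_metabolic_model(mets, reactions, genes, model_id = j$id %||% "model")
}

#' Write a metabolic model
#'
#' @param model a [pdmr_metabolic_model].
#' @param path output path.
#' @param format `"json"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("json", "sbml")) {
  format <- match.arg(format)
  if (format == "json") write_model_json(model, path)
  else write_model_sbml(model, path)
  invisible(path)
}

write_model_json <- function(model, path) {
  j <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      list(id = model$metabolites$id[i], name = model$metabolites$name[i],
           compartment = model$metabolites$compartment[i])),
    reactions = lapply(model$reactions, function(r) list(
      id = r$id, name = r$id,
      metabolites = as.list(r$stoichiometry),
      gene_reaction_rule = r$gpr, subsystem = r$subsystem,
      lower_bound = -1000, upper_bound = 1000)),
    genes = lapply(model$genes, function(g) list(id = g, name = g)))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# ---- SBML L3 -----------------------------------------------------------------

write_model_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s">', esc(model$id)),
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>',
            unique(model$metabolites$compartment)),
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    sprintf(paste0('      <species id="%s" name="%s" compartment="%s" ',
                   'constant="false" hasOnlySubstanceUnits="false" ',
                   'boundaryCondition="false"/>'),
            esc(model$metabolites$id), esc(model$metabolites$name),
            esc(model$metabolites$compartment)),
    '    </listOfSpecies>',
    '    <fbc:listOfGeneProducts>',
    sprintf('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
            esc(model$genes), esc(model$genes)),
    '    </fbc:listOfGeneProducts>',
    '    <listOfReactions>')
  gpr_to_fbc <- function(node, indent) {
    pad <- strrep(" ", indent)
    if (is.character(node))
      return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="%s"/>', pad, node))
    tag <- if (node$op == "and") "fbc:and" else "fbc:or"
    c(sprintf("%s<%s>", pad, tag),
      unlist(lapply(node$args, gpr_to_fbc, indent = indent + 2)),
      sprintf("%s</%s>", pad, tag))
  }
  for (r in model$reactions) {
    s <- r$stoichiometry
    reac <- s[s < 0]; prod <- s[s > 0]
    lines <- c(lines,
      sprintf('      <reaction id="%s" reversible="false" fast="false">', esc(r$id)),
      '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
      sprintf('          <p>SUBSYSTEM: %s</p>', esc(r$subsystem)),
      '        </body></notes>')
    if (length(reac))
      lines <- c(lines, '        <listOfReactants>',
        sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                esc(names(reac)), -unname(reac)),
        '        </listOfReactants>')
    if (length(prod))
      lines <- c(lines, '        <listOfProducts>',
        sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                esc(names(prod)), unname(prod)),
        '        </listOfProducts>')
    if (nzchar(r$gpr))
      lines <- c(lines, '        <fbc:geneProductAssociation>',
                 gpr_to_fbc(parse_gpr(r$gpr), 10),
                 '        </fbc:geneProductAssociation>')
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(lines, path)
}

load_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  gp <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  genes <- xml2::xml_attr(gp, "fbc:id")
  if (length(genes) && all(is.na(genes))) genes <- xml2::xml_attr(gp, "id")
  genes <- genes[!is.na(genes)]
  fbc_to_gpr <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef")
      return(xml2::xml_attr(node, "geneProduct"))
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, fbc_to_gpr, character(1))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  reactions <- lapply(rx, function(r) {
    id <- xml2::xml_attr(r, "id")
    get_sto <- function(xp, sgn) {
      refs <- xml2::xml_find_all(r, xp, ns)
      stats::setNames(sgn * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      xml2::xml_attr(refs, "species"))
    }
    sto <- c(get_sto("./s:listOfReactants/s:speciesReference", -1),
             get_sto("./s:listOfProducts/s:speciesReference", 1))
    gpa <- xml2::xml_find_first(r, "./fbc:geneProductAssociation", ns)
    gpr <- ""
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      if (length(kids)) gpr <- fbc_to_gpr(kids[[1]])
    } else {
      notes <- xml2::xml_text(xml2::xml_find_first(r, "./s:notes", ns))
      ga <- regmatches(notes, regexpr("GENE_ASSOCIATION:[^\n<]*", notes))
      if (length(ga)) gpr <- trimws(sub("GENE_ASSOCIATION:", "", ga))
    }
    notes <- xml2::xml_text(xml2::xml_find_first(r, "./s:notes", ns))
    sub_m <- regmatches(notes, regexpr("SUBSYSTEM:[^\n<]*", notes))
    subsystem <- if (length(sub_m)) trimws(sub("SUBSYSTEM:", "", sub_m)) else ""
    list(id = id, stoichiometry = sto, gpr = gpr, subsystem = subsystem)
  })
  if (!length(genes))
    genes <- unique(unlist(lapply(reactions, function(r)
      if (nzchar(r$gpr)) gpr_genes(parse_gpr(r$gpr)))))
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  new_metabolic_model(mets, reactions, genes,
                      model_id = xml2::xml_attr(model_node, "id") %||% "model")
}
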