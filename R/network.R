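#' Genome-scale metabolic network container
#'
#' A `metabolic_network` holds an ordered metabolite table, an ordered
#' reaction table (bounds, gene-protein-reaction rules, subsystems), the
#' sparse stoichiometric matrix S (metabolites x reactions), and the gene
#' universe referenced by the GPR rules. Metabolite ids carry their
#' compartment as a bracket suffix (`"glc_D[c]"`, cytoplasm `c`,
#' mitochondria `m`, extracellular boundary `e`, shared medium `u`), the
#' convention used throughout the package.
#'
#' @param mets data.frame with columns `id`, `name`, `compartment`,
#'   `formula` (last two optional; `compartment` is derived from the id
#'   bracket suffix when absent).
#' @param rxns data.frame with columns `id`, `lower`, `upper`, `gpr`,
#'   `subsystem` (`gpr`/`subsystem` optional, default empty).
#' @param S stoichiometric matrix, metabolites x reactions; coerced to a
#'   sparse `Matrix::dgCMatrix` with dimnames from the id columns.
#' @param genes optional character vector; extended automatically with every
#'   gene referenced by a GPR rule.
#' @return object of class `metabolic_network`.
#' @export
metabolic_network <- function(mets, rxns, S, genes = character()) {
  mets <- as.data.frame(mets, stringsAsFactors = FALSE)
  rxns <- as.data.frame(rxns, stringsAsFactors = FALSE)
  if (is.null(mets$name)) mets$name <- mets$id
  if (is.null(mets$compartment)) mets$compartment <- met_compartment(mets$id)
  if (is.null(mets$formula)) mets$formula <- NA_character_
  if (is.null(rxns$gpr)) rxns$gpr <- ""
  rxns$gpr[is.na(rxns$gpr)] <- ""
  if (is.null(rxns$subsystem)) rxns$subsystem <- NA_character_
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite id: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  }
  if (anyDuplicated(rxns$id)) {
    stop("duplicate reaction id: ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  }
  if (any(!nzchar(mets$compartment))) {
    stop("metabolite with empty compartment tag: ",
         paste(mets$id[!nzchar(mets$compartment)], collapse = ", "))
  }
  if (any(rxns$lower > rxns$upper)) {
    stop("reaction with lower_bound > upper_bound: ",
         paste(rxns$id[rxns$lower > rxns$upper], collapse = ", "))
  }
  S <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  if (nrow(S) != nrow(mets) || ncol(S) != nrow(rxns)) {
    stop("stoichiometric matrix dimensions do not match id tables")
  }
  dimnames(S) <- list(mets$id, rxns$id)
  nz <- Matrix::colSums(S != 0)
  if (any(nz == 0)) {
    stop("reaction with empty stoichiometry: ",
         paste(rxns$id[nz == 0], collapse = ", "))
  }
  gpr_universe <- unique(unlist(lapply(rxns$gpr, gpr_genes), use.names = FALSE))
  genes <- sort(unique(c(genes, gpr_universe)))
  structure(list(mets = mets, rxns = rxns, S = S, genes = genes),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("metabolic_network: %d metabolites, %d reactions, %d genes\n",
              nrow(x$mets), nrow(x$rxns), length(x$genes)))
  cat("compartments:", paste(sort(unique(x$mets$compartment)), collapse = " "),
      "\n")
  invisible(x)
}

#' @rdname metabolic_network
#' @param network a `metabolic_network`.
#' @export
reaction_ids <- function(network) network$rxns$id

#' @rdname metabolic_network
#' @export
metabolite_ids <- function(network) network$mets$id

## compartment tag from a bracketed metabolite id, e.g. "glc_D[e]_astro" -> "e"
met_compartment <- function(ids) {
  out <- sub(".*\\[([^][]+)\\].*", "\\1", ids)
  out[!grepl("\\[", ids)] <- ""
  out
}

#' Identify exchange reactions
#'
#' An exchange reaction moves a single metabolite across the model boundary:
#' it has exactly one nonzero stoichiometric entry, of coefficient +-1, on a
#' metabolite whose compartment is a boundary/medium compartment.
#'
#' @param network a `metabolic_network`.
#' @param boundary compartment tags treated as boundary (default
#'   extracellular `"e"` and shared medium `"u"`).
#' @return named logical vector over reactions.
#' @export
is_exchange_reaction <- function(network, boundary = c("e", "u")) {
  S <- network$S
  nz <- Matrix::colSums(S != 0)
  out <- logical(ncol(S))
  cand <- which(nz == 1)
  if (length(cand)) {
    bmet <- network$mets$id[network$mets$compartment %in% boundary]
    for (j in cand) {
      i <- which(S[, j] != 0)
      out[j] <- abs(S[i, j]) == 1 && network$mets$id[i] %in% bmet
    }
  }
  names(out) <- network$rxns$id
  out
}

## ---------------------------------------------------------------------------
## GPR rules: tokenizer + recursive-descent parser for and/or/() expressions
## ---------------------------------------------------------------------------

gpr_tokens <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_parse <- function(rule) {
  toks <- gpr_tokens(rule)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_expr <- function() {
    node <- parse_term()
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      node <- list(op = "or", a = node, b = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      node <- list(op = "and", a = node, b = parse_factor())
    }
    node
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("unparsable GPR rule: ", rule)
    if (t == "(") {
      advance()
      node <- parse_expr()
      if (is.na(peek()) || peek() != ")") stop("unparsable GPR rule: ", rule)
      advance()
      return(node)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) {
      stop("unparsable GPR rule: ", rule)
    }
    advance()
    list(op = "gene", id = t)
  }
  node <- parse_expr()
  if (pos <= length(toks)) stop("unparsable GPR rule: ", rule)
  node
}

gpr_eval_node <- function(node, active) {
  switch(node$op,
         gene = node$id %in% active,
         and  = gpr_eval_node(node$a, active) && gpr_eval_node(node$b, active),
         or   = gpr_eval_node(node$a, active) || gpr_eval_node(node$b, active))
}

## deparse a parse tree back to the conventional textual form: "or" binds
## loosest, "and" tighter, parentheses only where precedence requires them
gpr_deparse <- function(node) {
  if (node$op == "gene") return(node$id)
  wrap <- function(child) {
    s <- gpr_deparse(child)
    if (node$op == "and" && child$op == "or") paste0("(", s, ")") else s
  }
  paste(wrap(node$a), node$op, wrap(node$b))
}

gpr_collect_genes <- function(node) {
  if (node$op == "gene") return(node$id)
  c(gpr_collect_genes(node$a), gpr_collect_genes(node$b))
}

#' Evaluate a gene-protein-reaction rule
#'
#' Boolean evaluation of a GPR expression (`and`/`or`/parentheses over gene
#' ids) against a set of active genes. An empty rule evaluates to `FALSE`
#' (no gene evidence supports the reaction), and genes absent from
#' `active_genes` count as inactive — the conservative reading when the
#' active set lists only measured genes.
#'
#' @param rule GPR expression string, possibly empty.
#' @param active_genes character vector of active gene ids.
#' @return logical scalar.
#' @export
#' @examples
#' evaluate_gpr("G1 and G2", "G1")            # FALSE
#' evaluate_gpr("(G1 and G2) or G3", "G3")    # TRUE
evaluate_gpr <- function(rule, active_genes) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(FALSE)
  gpr_eval_node(gpr_parse(rule), active_genes)
}

#' Genes referenced by a GPR rule
#' @param rule GPR expression string.
#' @return character vector (empty for an empty rule).
#' @export
gpr_genes <- function(rule) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(character())
  unique(gpr_collect_genes(gpr_parse(rule)))
}

#' Map core genes to core reactions
#'
#' Returns the reactions whose GPR rule evaluates `TRUE` under the given
#' core gene set. Reactions without a GPR are never mapped (no evidence).
#' The mapping is monotone: enlarging the core gene set never removes a
#' reaction from the result.
#'
#' @param network a `metabolic_network`.
#' @param core_genes character vector of core gene ids.
#' @return character vector of reaction ids.
#' @export
map_core_reactions <- function(network, core_genes) {
  hit <- vapply(network$rxns$gpr, evaluate_gpr, logical(1),
                active_genes = core_genes, USE.NAMES = FALSE)
  network$rxns$id[hit]
}

#' Extract a subnetwork by reaction ids
#'
#' Keeps the named reactions and every metabolite they touch, preserving
#' reaction order, bounds and GPRs.
#'
#' @param network a `metabolic_network`.
#' @param keep character vector of reaction ids to retain.
#' @return a `metabolic_network`.
#' @export
subnetwork <- function(network, keep) {
  missing <- setdiff(keep, network$rxns$id)
  if (length(missing)) {
    stop("unknown reaction id: ", paste(missing, collapse = ", "))
  }
  jj <- which(network$rxns$id %in% keep)
  S <- network$S[, jj, drop = FALSE]
  used <- Matrix::rowSums(S != 0) > 0
  metabolic_network(network$mets[used, , drop = FALSE],
                    network$rxns[jj, , drop = FALSE],
                    S[used, , drop = FALSE],
                    genes = network$genes)
}

## ---------------------------------------------------------------------------
## I/O: versioned JSON dialect and SBML Level 3 (+ flux bounds, GPRs)
## ---------------------------------------------------------------------------

#' Read or write a metabolic network
#'
#' `read_network()`/`write_network()` support two formats: a versioned JSON
#' dialect following the common genome-scale-model JSON layout (arrays of
#' metabolites, reactions with a stoichiometry map, genes), and SBML Level 3
#' with flux bounds and gene-association annotations. Reactions lacking
#' explicit bounds default to (-1000, 1000) when marked reversible and
#' (0, 1000) otherwise, the usual reconstruction convention in arbitrary
#' units. Round trips through either format are identity.
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; inferred from the file extension when
#'   omitted.
#' @return `read_network()` returns a `metabolic_network`; `write_network()`
#'   returns `path` invisibly.
#' @export
read_network <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else if (grepl("\\.json$", path, ignore.case = TRUE))
        "json" else stop("cannot infer network format from path: ", path)
  }
  if (!file.exists(path)) stop("network file does not exist: ", path)
  switch(format,
         json = read_network_json(path),
         sbml = read_network_sbml(path))
}

#' @rdname read_network
#' @param network a `metabolic_network` to serialize.
#' @export
write_network <- function(network, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  switch(format,
         json = write_network_json(network, path),
         sbml = write_network_sbml(network, path))
  invisible(path)
}

DEFAULT_BOUND <- 1000

read_network_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("malformed network JSON (missing 'metabolites' or 'reactions'): ",
         path)
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("malformed metabolite entry (missing id) in ", path)
    data.frame(id = m$id,
               name = m$name %||% m$id,
               compartment = m$compartment %||% met_compartment(m$id),
               formula = m$formula %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  n <- length(doc$reactions)
  ids <- character(n); lower <- upper <- numeric(n)
  gpr <- character(n); subsystem <- character(n)
  trip <- vector("list", n)
  met_index <- stats::setNames(seq_len(nrow(mets)), mets$id)
  for (j in seq_len(n)) {
    r <- doc$reactions[[j]]
    if (is.null(r$id)) stop("malformed reaction entry (missing id) in ", path)
    ids[j] <- r$id
    st <- r$stoichiometry %||% r$metabolites
    if (is.null(st) || !length(st)) {
      stop("reaction with empty stoichiometry: ", r$id)
    }
    bad <- setdiff(names(st), mets$id)
    if (length(bad)) {
      stop("reaction ", r$id, " references unknown metabolite: ",
           paste(bad, collapse = ", "))
    }
    rev <- isTRUE(r$reversible)
    lower[j] <- r$lower_bound %||% (if (rev) -DEFAULT_BOUND else 0)
    upper[j] <- r$upper_bound %||% DEFAULT_BOUND
    gpr[j] <- r$gpr %||% r$gene_reaction_rule %||% ""
    subsystem[j] <- r$subsystem %||% NA_character_
    trip[[j]] <- cbind(met_index[names(st)], j,
                       vapply(st, as.numeric, numeric(1)))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate reaction id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  trip <- do.call(rbind, trip)
  S <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                            dims = c(nrow(mets), n))
  genes <- vapply(doc$genes %||% list(), function(g)
    if (is.list(g)) g$id else g, character(1))
  metabolic_network(mets,
                    data.frame(id = ids, lower = lower, upper = upper,
                               gpr = gpr, subsystem = subsystem,
                               stringsAsFactors = FALSE),
                    S, genes = genes)
}

write_network_json <- function(network, path) {
  S <- network$S
  reactions <- lapply(seq_len(ncol(S)), function(j) {
    i <- which(S[, j] != 0)
    st <- as.list(S[i, j])
    names(st) <- network$mets$id[i]
    r <- network$rxns[j, ]
    out <- list(id = r$id, stoichiometry = st,
                lower_bound = r$lower, upper_bound = r$upper,
                gpr = r$gpr)
    if (!is.na(r$subsystem)) out$subsystem <- r$subsystem
    out
  })
  mets <- lapply(seq_len(nrow(network$mets)), function(i) {
    m <- network$mets[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    out
  })
  doc <- list(version = 1L,
              metabolites = mets,
              reactions = reactions,
              genes = as.list(network$genes))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## SBML SIds forbid brackets; escape every non-[A-Za-z0-9_] character as
## __<hex>__ so ids round-trip exactly.
sbml_escape <- function(x) {
  vapply(x, function(s) {
    chars <- strsplit(s, "")[[1]]
    paste(vapply(chars, function(ch) {
      if (grepl("^[A-Za-z0-9_]$", ch)) ch
      else sprintf("__%02x__", utf8ToInt(ch))
    }, character(1)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

sbml_unescape <- function(x) {
  vapply(x, function(s) {
    m <- gregexpr("__[0-9a-f]{2}__", s)[[1]]
    if (m[1] == -1) return(s)
    regmatches(s, gregexpr("__[0-9a-f]{2}__", s)) <- list(
      vapply(regmatches(s, gregexpr("__[0-9a-f]{2}__", s))[[1]], function(tok)
        intToUtf8(strtoi(substr(tok, 3, 4), 16L)), character(1)))
    s
  }, character(1), USE.NAMES = FALSE)
}

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

write_network_sbml <- function(network, path) {
  esc_m <- paste0("M_", sbml_escape(network$mets$id))
  esc_r <- paste0("R_", sbml_escape(network$rxns$id))
  esc_g <- paste0("G_", sbml_escape(network$genes))
  comps <- unique(network$mets$compartment)
  gpr_xml <- function(node) {
    if (node$op == "gene") {
      return(sprintf('<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                     sbml_escape(node$id)))
    }
    tag <- if (node$op == "and") "fbc:and" else "fbc:or"
    sprintf("<%s>%s%s</%s>", tag, gpr_xml(node$a), gpr_xml(node$b), tag)
  }
  buf <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_NS, FBC_NS),
    '<model id="model" fbc:strict="true">',
    "<listOfCompartments>",
    sprintf('<compartment id="%s" constant="true"/>', sbml_escape(comps)),
    "</listOfCompartments>",
    "<listOfSpecies>")
  buf <- c(buf, sprintf(
    '<species id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
    esc_m, xml_quote(network$mets$name),
    sbml_escape(network$mets$compartment)))
  buf <- c(buf, "</listOfSpecies>", "<listOfParameters>")
  bvals <- sort(unique(c(network$rxns$lower, network$rxns$upper)))
  bid <- function(v) sprintf("bnd_%s", sbml_escape(format(v, digits = 17)))
  buf <- c(buf, sprintf(
    '<parameter id="%s" value="%s" constant="true"/>',
    vapply(bvals, bid, character(1)), format(bvals, digits = 17)))
  buf <- c(buf, "</listOfParameters>", "<listOfReactions>")
  for (j in seq_len(nrow(network$rxns))) {
    r <- network$rxns[j, ]
    i <- which(network$S[, j] != 0)
    coef <- network$S[i, j]
    reac <- i[coef < 0]; prod <- i[coef > 0]
    buf <- c(buf, sprintf(
      '<reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      esc_r[j], tolower(r$lower < 0), bid(r$lower), bid(r$upper)))
    if (nzchar(r$gpr)) {
      buf <- c(buf, "<fbc:geneProductAssociation>",
               gpr_xml(gpr_parse(r$gpr)),
               "</fbc:geneProductAssociation>")
    }
    if (length(reac)) {
      buf <- c(buf, "<listOfReactants>", sprintf(
        '<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
        esc_m[reac], format(-coef[coef < 0], digits = 17)),
        "</listOfReactants>")
    }
    if (length(prod)) {
      buf <- c(buf, "<listOfProducts>", sprintf(
        '<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
        esc_m[prod], format(coef[coef > 0], digits = 17)),
        "</listOfProducts>")
    }
    buf <- c(buf, "</reaction>")
  }
  buf <- c(buf, "</listOfReactions>")
  if (length(esc_g)) {
    buf <- c(buf, "<fbc:listOfGeneProducts>", sprintf(
      '<fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
      esc_g, xml_quote(network$genes)),
      "</fbc:listOfGeneProducts>")
  }
  buf <- c(buf, "</model>", "</sbml>")
  writeLines(buf, path)
  invisible(path)
}

xml_quote <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

read_network_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML file ", path, ": ",
                                           conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model, "xml_missing")) stop("malformed SBML (no model): ", path)
  sp <- xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp)) stop("malformed SBML (no species): ", path)
  mids <- sbml_unescape(sub("^M_", "", xml2::xml_attr(sp, "id")))
  mets <- data.frame(
    id = mids,
    name = ifelse(is.na(xml2::xml_attr(sp, "name")), mids,
                  xml2::xml_attr(sp, "name")),
    compartment = sbml_unescape(xml2::xml_attr(sp, "compartment")),
    formula = NA_character_, stringsAsFactors = FALSE)
  pars <- xml2::xml_find_all(model, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx)) stop("malformed SBML (no reactions): ", path)
  met_index <- stats::setNames(seq_len(nrow(mets)), mets$id)
  n <- length(rx)
  ids <- character(n); lower <- upper <- numeric(n); gpr <- character(n)
  trip <- vector("list", n)
  gpr_from_xml <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      return(list(op = "gene",
                  id = sbml_unescape(sub("^G_", "",
                                         xml2::xml_attr(node, "geneProduct")))))
    }
    kids <- xml2::xml_children(node)
    node_list <- lapply(kids, gpr_from_xml)
    out <- node_list[[1]]
    for (k in seq_along(node_list)[-1]) {
      out <- list(op = nm, a = out, b = node_list[[k]])
    }
    out
  }
  for (j in seq_len(n)) {
    node <- rx[[j]]
    ids[j] <- sbml_unescape(sub("^R_", "", xml2::xml_attr(node, "id")))
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    lower[j] <- if (!is.na(lb_ref) && lb_ref %in% names(pval)) pval[[lb_ref]]
      else if (rev) -DEFAULT_BOUND else 0
    upper[j] <- if (!is.na(ub_ref) && ub_ref %in% names(pval)) pval[[ub_ref]]
      else DEFAULT_BOUND
    ga <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    gpr[j] <- if (inherits(ga, "xml_missing")) "" else
      gpr_deparse(gpr_from_xml(xml2::xml_child(ga)))
    reac <- xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference",
                               ns)
    prods <- xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference",
                                ns)
    sid <- c(sbml_unescape(sub("^M_", "", xml2::xml_attr(reac, "species"))),
             sbml_unescape(sub("^M_", "", xml2::xml_attr(prods, "species"))))
    sval <- c(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
              as.numeric(xml2::xml_attr(prods, "stoichiometry")))
    bad <- setdiff(sid, mets$id)
    if (length(bad)) {
      stop("reaction ", ids[j], " references unknown species: ",
           paste(bad, collapse = ", "))
    }
    if (!length(sid)) stop("reaction with empty stoichiometry: ", ids[j])
    trip[[j]] <- cbind(met_index[sid], j, sval)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate reaction id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  trip <- do.call(rbind, trip)
  S <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                            dims = c(nrow(mets), n))
  gp <- xml2::xml_find_all(model, ".//fbc:listOfGeneProducts/fbc:geneProduct",
                           ns)
  genes <- sbml_unescape(sub("^G_", "", xml2::xml_attr(gp, "id")))
  metabolic_network(mets,
                    data.frame(id = ids, lower = lower, upper = upper,
                               gpr = gpr, subsystem = NA_character_,
                               stringsAsFactors = FALSE),
                    S, genes = genes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
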