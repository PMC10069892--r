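SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"

#' Read an SBML model (Level 2/3, fbc or kinetic-law bounds)
#'
#' Parses species (compartment, boundary flag, `fbc:chemicalFormula` or a
#' `FORMULA:` note), reactions with stoichiometry, flux bounds from
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound` parameters or, as a fallback,
#' `LOWER_BOUND`/`UPPER_BOUND` kinetic-law parameters, and the active fbc
#' objective. Reactions lacking any bound default to (-1000, 1000) with a
#' warning; `reversible="false"` clamps the default lower bound to 0.
#'
#' EC numbers are harvested with the precedence: (1) MIRIAM/identifiers.org
#' `ec-code` CV terms in the reaction annotation; (2) regex
#' `\\b\\d+\\.\\d+\\.\\d+\\.(\\d+|-)\\b` over the reaction notes; (3) the
#' optional `ec_mapping` table. The first level with a hit wins and all hits
#' at that level are kept.
#'
#' @param path SBML file.
#' @param ec_mapping optional data.frame with columns `reaction` and `ec`.
#' @return a `metabolic_model`.
#' @export
read_sbml <- function(path, ec_mapping = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse failure in ", path, ": ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)  # work positionally; namespaces vary across emitters

  model_node <- xml2::xml_find_first(doc, ".//model")
  if (is.na(xml2::xml_name(model_node))) stop("no <model> element in ", path)
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id)) model_id <- "model"

  sp_nodes <- xml2::xml_find_all(model_node, ".//listOfSpecies/species")
  get_attr <- function(nodes, name, alt = NULL) {
    v <- xml2::xml_attr(nodes, name)
    if (!is.null(alt)) {
      v2 <- xml2::xml_attr(nodes, alt)
      v[is.na(v)] <- v2[is.na(v)]
    }
    v
  }
  formulas <- get_attr(sp_nodes, "chemicalFormula")
  notes_formula <- vapply(sp_nodes, function(n) {
    txt <- xml2::xml_text(xml2::xml_find_first(n, ".//notes"))
    m <- regmatches(txt, regexpr("FORMULA: *[A-Za-z0-9+-]+", txt))
    if (length(m)) sub("FORMULA: *", "", m) else NA_character_
  }, "")
  formulas[is.na(formulas)] <- notes_formula[is.na(formulas)]
  metabolites <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")),
                  xml2::xml_attr(sp_nodes, "id"),
                  xml2::xml_attr(sp_nodes, "name")),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    formula = formulas,
    is_boundary = !is.na(xml2::xml_attr(sp_nodes, "boundaryCondition")) &
      xml2::xml_attr(sp_nodes, "boundaryCondition") == "true",
    stringsAsFactors = FALSE)

  params <- xml2::xml_find_all(model_node, "./listOfParameters/parameter")
  param_val <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                               xml2::xml_attr(params, "id"))

  rxn_nodes <- xml2::xml_find_all(model_node, ".//listOfReactions/reaction")
  n <- length(rxn_nodes)
  ids <- xml2::xml_attr(rxn_nodes, "id")
  nms <- xml2::xml_attr(rxn_nodes, "name")
  nms[is.na(nms)] <- ids[is.na(nms)]
  lb <- ub <- rep(NA_real_, n)
  stoich <- vector("list", n)
  ecs <- vector("list", n)
  missing_bounds <- character(0)

  ec_regex <- "\\b[0-9]+\\.[0-9]+\\.[0-9]+\\.([0-9]+|-)"
  for (k in seq_len(n)) {
    node <- rxn_nodes[[k]]
    sref <- function(which) {
      refs <- xml2::xml_find_all(node, paste0("./", which, "/speciesReference"))
      if (!length(refs)) return(numeric(0))
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      stats::setNames(coef, xml2::xml_attr(refs, "species"))
    }
    reac <- sref("listOfReactants")
    prod <- sref("listOfProducts")
    st <- numeric(0)
    for (s in names(reac)) st[s] <- (if (s %in% names(st)) st[s] else 0) - reac[s]
    for (s in names(prod)) st[s] <- (if (s %in% names(st)) st[s] else 0) + prod[s]
    stoich[[k]] <- st

    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(param_val)) lb[k] <- param_val[lb_ref]
    if (!is.na(ub_ref) && ub_ref %in% names(param_val)) ub[k] <- param_val[ub_ref]
    if (is.na(lb[k]) || is.na(ub[k])) {
      kl <- xml2::xml_find_all(node,
        ".//kineticLaw//parameter | .//kineticLaw//localParameter")
      if (length(kl)) {
        kv <- stats::setNames(as.numeric(xml2::xml_attr(kl, "value")),
                              xml2::xml_attr(kl, "id"))
        if (is.na(lb[k]) && "LOWER_BOUND" %in% names(kv)) lb[k] <- kv["LOWER_BOUND"]
        if (is.na(ub[k]) && "UPPER_BOUND" %in% names(kv)) ub[k] <- kv["UPPER_BOUND"]
      }
    }
    rev_attr <- xml2::xml_attr(node, "reversible")
    if (is.na(lb[k]) || is.na(ub[k])) {
      missing_bounds <- c(missing_bounds, ids[k])
      if (is.na(lb[k])) {
        lb[k] <- if (!is.na(rev_attr) && rev_attr == "false") 0 else -1000
      }
      if (is.na(ub[k])) ub[k] <- 1000
    }

    # EC precedence: CV terms, then notes regex (user mapping handled below).
    # rdf-prefixed nodes survive xml_ns_strip; match by local name
    cv <- xml2::xml_find_all(node, ".//annotation//*[local-name()='li']")
    res <- xml2::xml_attr(cv, "resource")
    ec_cv <- res[!is.na(res) & grepl("ec-code", res)]
    if (length(ec_cv)) {
      ecs[[k]] <- unique(sub(".*ec-code[/:]", "", ec_cv))
    } else {
      notes <- xml2::xml_text(xml2::xml_find_first(node, ".//notes"))
      hits <- regmatches(notes, gregexpr(ec_regex, notes))[[1]]
      ecs[[k]] <- unique(hits)
    }
  }
  names(stoich) <- ids
  names(ecs) <- ids
  if (!is.null(ec_mapping)) {
    for (k in seq_len(n)) {
      if (!length(ecs[[k]])) {
        hit <- ec_mapping$ec[ec_mapping$reaction == ids[k]]
        if (length(hit)) ecs[[k]] <- unique(hit)
      }
    }
  }
  if (length(missing_bounds)) {
    warning("no flux bounds for ", length(missing_bounds),
            " reaction(s), defaulting to +/-1000: ",
            paste(utils::head(missing_bounds, 5), collapse = ", "),
            if (length(missing_bounds) > 5) ", ..." else "")
  }

  obj_nodes <- xml2::xml_find_all(model_node,
    ".//listOfObjectives/objective//fluxObjective")
  objective <- if (length(obj_nodes)) {
    stats::setNames(as.numeric(xml2::xml_attr(obj_nodes, "coefficient")),
                    xml2::xml_attr(obj_nodes, "reaction"))
  } else numeric(0)

  metabolic_model(id = model_id, metabolites = metabolites,
                  reactions = data.frame(id = ids, name = nms,
                                         lower_bound = lb, upper_bound = ub,
                                         stringsAsFactors = FALSE),
                  stoichiometry = stoich, objective = objective,
                  ec_numbers = ecs)
}

#' Write a model as SBML Level 3 + fbc version 2
#'
#' Used by the synthetic-model generator so that the SBML reader can be
#' exercised round-trip without any downloaded model. EC numbers are written
#' as identifiers.org `ec-code` CV terms, except where `ec_in_notes` lists
#' reaction ids whose ECs go into the notes body instead (exercising the
#' annotation-precedence fallback).
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @param ec_in_notes character vector of reaction ids.
#' @return invisibly, `path`.
#' @export
write_sbml <- function(model, path, ec_in_notes = character(0)) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) sprintf("%.17g", x)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
                   'fbc:required="false">'), SBML_CORE_NS, SBML_FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)),
    '    <listOfCompartments>')
  for (comp in unique(model$metabolites$compartment)) {
    out <- c(out, sprintf('      <compartment id="%s" constant="true"/>', comp))
  }
  out <- c(out, '    </listOfCompartments>', '    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    fml <- if (is.na(m$formula)) "" else
      sprintf(' fbc:chemicalFormula="%s"', m$formula)
    out <- c(out, sprintf(
      paste0('      <species id="%s" name="%s" compartment="%s" ',
             'hasOnlySubstanceUnits="false" boundaryCondition="%s" ',
             'constant="false"%s/>'),
      m$id, esc(m$name), m$compartment,
      if (m$is_boundary) "true" else "false", fml))
  }
  out <- c(out, '    </listOfSpecies>', '    <listOfParameters>')
  bounds <- sort(unique(c(model$reactions$lower_bound,
                          model$reactions$upper_bound)))
  bid <- function(v) paste0("b_", gsub("[^0-9A-Za-z]", "_", num(v)))
  for (v in bounds) {
    out <- c(out, sprintf(
      '      <parameter id="%s" value="%s" constant="true"/>', bid(v), num(v)))
  }
  out <- c(out, '    </listOfParameters>', '    <listOfReactions>')
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    st <- model$stoichiometry[[r$id]]
    ec <- model$ec_numbers[[r$id]]
    out <- c(out, sprintf(
      paste0('      <reaction id="%s" name="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      r$id, esc(r$name), if (r$lower_bound < 0) "true" else "false",
      bid(r$lower_bound), bid(r$upper_bound)))
    if (length(ec)) {
      if (r$id %in% ec_in_notes) {
        out <- c(out,
          '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
          sprintf('          <p>EC Number: %s</p>', paste(ec, collapse = " ")),
          '        </body></notes>')
      } else {
        out <- c(out,
          '        <annotation>',
          sprintf('          <rdf:RDF xmlns:rdf="%s" xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">', RDF_NS),
          sprintf('            <rdf:Description rdf:about="#%s">', r$id),
          '              <bqbiol:isVersionOf><rdf:Bag>',
          sprintf('                <rdf:li rdf:resource="https://identifiers.org/ec-code/%s"/>', ec),
          '              </rdf:Bag></bqbiol:isVersionOf>',
          '            </rdf:Description>',
          '          </rdf:RDF>',
          '        </annotation>')
      }
    }
    subs <- st[st < 0]
    prods <- st[st > 0]
    if (length(subs)) {
      out <- c(out, '        <listOfReactants>',
               sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       names(subs), num(abs(unname(subs)))),
               '        </listOfReactants>')
    }
    if (length(prods)) {
      out <- c(out, '        <listOfProducts>',
               sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       names(prods), num(unname(prods))),
               '        </listOfProducts>')
    }
    out <- c(out, '      </reaction>')
  }
  out <- c(out, '    </listOfReactions>')
  if (length(model$objective)) {
    out <- c(out,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      '        <fbc:listOfFluxObjectives>',
      sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="%s"/>',
              names(model$objective), num(unname(model$objective))),
      '        </fbc:listOfFluxObjectives>',
      '      </fbc:objective>',
      '    </fbc:listOfObjectives>')
  }
  out <- c(out, '  </model>', '</sbml>')
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
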