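#' Construct a compartmentalized stoichiometric metabolic model
#'
#' The central container of the package. Metabolites carry elemental formulas
#' (Hill notation) used for carbon accounting; reactions carry flux bounds in
#' mmol gDW^-1 h^-1, EC annotations, and exchange/transport flags. The sign
#' convention for exchange reactions is a single signed flux per boundary
#' metabolite: negative flux = import, positive = export.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `formula` (NA allowed), `is_boundary`.
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`.
#' @param stoichiometry named list: reaction id -> named numeric vector of
#'   signed coefficients over metabolite ids (negative = substrate).
#' @param objective named numeric vector: reaction id -> weight.
#' @param ec_numbers named list: reaction id -> character vector of EC strings.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, stoichiometry,
                            objective = numeric(0), ec_numbers = list()) {
  metabolites$formula <- as.character(metabolites$formula)
  if (is.null(metabolites$is_boundary)) metabolites$is_boundary <- FALSE
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(reactions$name)) reactions$name <- reactions$id
  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL
  m <- structure(list(id = id,
                      metabolites = metabolites,
                      reactions = reactions,
                      stoichiometry = stoichiometry,
                      objective = objective,
                      ec_numbers = ec_numbers),
                 class = "metabolic_model")
  m <- annotate_reaction_roles(m)
  validate_model(m)
  m
}

#' Validate structural invariants of a metabolic model
#'
#' Checks metabolite id uniqueness, formula parseability bookkeeping,
#' bound ordering, non-empty stoichiometries, resolvability of all
#' stoichiometry and objective keys, and the exchange-reaction contract
#' (exactly one non-boundary metabolite).
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors on violation.
#' @export
validate_model <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  if (anyDuplicated(met_ids)) stop("duplicate metabolite ids")
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids")
  if (!setequal(names(model$stoichiometry), rxn_ids)) {
    stop("stoichiometry entries must match reaction ids")
  }
  bad <- model$reactions$lower_bound > model$reactions$upper_bound
  if (any(bad)) stop("lower_bound > upper_bound for: ",
                     paste(rxn_ids[bad], collapse = ", "))
  for (r in rxn_ids) {
    st <- model$stoichiometry[[r]]
    if (length(st) == 0) stop("empty stoichiometry in reaction ", r)
    unknown <- setdiff(names(st), met_ids)
    if (length(unknown)) {
      stop("reaction ", r, " references unknown metabolites: ",
           paste(unknown, collapse = ", "))
    }
  }
  if (length(model$objective)) {
    unknown <- setdiff(names(model$objective), rxn_ids)
    if (length(unknown)) stop("objective references unknown reactions: ",
                              paste(unknown, collapse = ", "))
  }
  ex <- model$reactions$id[model$reactions$is_exchange]
  boundary <- met_ids[model$metabolites$is_boundary]
  for (r in ex) {
    touched <- setdiff(names(model$stoichiometry[[r]]), boundary)
    if (length(touched) != 1) {
      stop("exchange reaction ", r,
           " must touch exactly one non-boundary metabolite")
    }
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites),
      " in ", length(unique(x$metabolites$compartment)), " compartments\n",
      "  reactions:   ", nrow(x$reactions),
      " (", sum(x$reactions$is_exchange), " exchanges, ",
      sum(x$reactions$is_transport), " transporters)\n",
      "  objective:   ",
      if (length(x$objective)) paste(names(x$objective), collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(x)
}

# Strip the compartment tag from a metabolite id ("pga_h" -> "pga"), using the
# metabolite's own compartment so underscores inside base names survive.
met_base_name <- function(model, met_id) {
  i <- match(met_id, model$metabolites$id)
  comp <- model$metabolites$compartment[i]
  sub(paste0("_", comp, "$"), "", met_id)
}

# Flags exchanges (single non-boundary metabolite, nothing else non-boundary)
# and transporters (identical multiset of base names on both sides, needed to
# keep CO2 translocation out of production accounting).
annotate_reaction_roles <- function(model) {
  boundary <- model$metabolites$id[model$metabolites$is_boundary]
  is_ex <- logical(nrow(model$reactions))
  is_tr <- logical(nrow(model$reactions))
  for (k in seq_len(nrow(model$reactions))) {
    st <- model$stoichiometry[[model$reactions$id[k]]]
    internal <- setdiff(names(st), boundary)
    if (length(internal) == 1) {
      is_ex[k] <- TRUE
      next
    }
    subs <- names(st)[st < 0]
    prods <- names(st)[st > 0]
    if (length(subs) && length(prods)) {
      side_tab <- function(ids, coefs) {
        base <- vapply(ids, function(m) met_base_name(model, m), "")
        out <- tapply(abs(coefs), base, sum)
        out[order(names(out))]
      }
      lhs <- side_tab(subs, st[subs])
      rhs <- side_tab(prods, st[prods])
      is_tr[k] <- length(lhs) == length(rhs) &&
        all(names(lhs) == names(rhs)) &&
        all(abs(lhs - rhs) < 1e-9)
    }
  }
  model$reactions$is_exchange <- is_ex
  model$reactions$is_transport <- is_tr
  model
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix, metabolites (non-boundary) x reactions.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id[!model$metabolites$is_boundary]
  rxns <- model$reactions$id
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (r in rxns) {
    st <- model$stoichiometry[[r]]
    keep <- names(st) %in% mets
    S[names(st)[keep], r] <- st[keep]
  }
  S
}

#' Molar carbon fraction of the biomass reaction
#'
#' Mol carbon incorporated into biomass per unit flux of the biomass
#' reaction: the carbon in substrates (|coefficient| x carbon atoms) minus
#' the carbon returned in products, excluding the biomass pseudo-species
#' itself. Metabolites without a parseable formula are skipped and reported,
#' making the treatment of formula-less precursors auditable.
#'
#' @param model a `metabolic_model`.
#' @param biomass_reaction_id reaction id; defaults to the objective reaction.
#' @param biomass_species_id id of the biomass pseudo-species to exclude from
#'   the product side (default: any product whose base name is `"biomass"`).
#' @return list with `value` (mol C per unit biomass flux) and
#'   `skipped_metabolites`.
#' @export
biomass_carbon_fraction <- function(model, biomass_reaction_id = NULL,
                                    biomass_species_id = NULL) {
  if (is.null(biomass_reaction_id)) {
    if (!length(model$objective)) stop("no biomass reaction given or in objective")
    biomass_reaction_id <- names(model$objective)[1]
  }
  if (!biomass_reaction_id %in% model$reactions$id) {
    stop("biomass reaction not found: ", biomass_reaction_id)
  }
  st <- model$stoichiometry[[biomass_reaction_id]]
  if (is.null(biomass_species_id)) {
    prods <- names(st)[st > 0]
    biomass_species_id <- prods[vapply(prods, function(m)
      tolower(met_base_name(model, m)) == "biomass", TRUE)]
  }
  skipped <- character(0)
  value <- 0
  any_formula_substrate <- FALSE
  for (m in names(st)) {
    if (m %in% biomass_species_id && st[m] > 0) next
    i <- match(m, model$metabolites$id)
    nC <- element_count(model$metabolites$formula[i], "C")
    if (is.na(nC)) {
      skipped <- c(skipped, m)
      next
    }
    if (st[m] < 0) any_formula_substrate <- TRUE
    value <- value - st[m] * nC  # substrates (st<0) add, products subtract
  }
  if (!any_formula_substrate) {
    stop("carbon fraction undefined: no biomass substrate has a parseable formula")
  }
  list(value = unname(value), skipped_metabolites = skipped)
}

#' Elemental imbalance of every reaction for one element
#'
#' Sum of coefficient x atom count per reaction; `NA` where any participating
#' metabolite lacks a usable formula. Exchange reactions are inherently
#' unbalanced and reported as-is.
#'
#' @param model a `metabolic_model`.
#' @param element element symbol.
#' @return named numeric vector over reaction ids.
#' @export
element_balance <- function(model, element = "C") {
  counts <- vapply(model$metabolites$formula, element_count,
                   numeric(1), element = element)
  names(counts) <- model$metabolites$id
  vapply(model$reactions$id, function(r) {
    st <- model$stoichiometry[[r]]
    sum(st * counts[names(st)])
  }, numeric(1))
}
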