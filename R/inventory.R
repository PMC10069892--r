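#' Identify CO2 species in a model
#'
#' Recognition precedence: explicit `co2_ids`, then chemical formula exactly
#' `"CO2"`, then a case-insensitive id/name match (`co2` delimited by
#' underscores/non-word characters, or the name "carbon dioxide"). All
#' compartment instances are included.
#'
#' @param model a `metabolic_model`.
#' @param co2_ids optional explicit metabolite ids.
#' @return character vector of metabolite ids.
#' @export
find_co2_species <- function(model, co2_ids = NULL) {
  if (!is.null(co2_ids)) {
    unknown <- setdiff(co2_ids, model$metabolites$id)
    if (length(unknown)) stop("unknown CO2 species: ",
                              paste(unknown, collapse = ", "))
    return(co2_ids)
  }
  met <- model$metabolites
  by_formula <- !is.na(met$formula) & met$formula == "CO2"
  rx <- "(^|[_\\W])co2([_\\W]|$)"
  by_id <- grepl(rx, met$id, ignore.case = TRUE, perl = TRUE) |
    grepl(rx, met$name, ignore.case = TRUE, perl = TRUE) |
    grepl("carbon dioxide", met$name, ignore.case = TRUE)
  met$id[by_formula | by_id]
}

#' Build the per-reaction CO2 inventory of a model
#'
#' Computes, for every reaction, the net mol CO2 made per unit forward flux
#' (summed over all CO2 species) and classifies reactions with nonzero net
#' CO2 into forward producers and forward consumers. Transport reactions
#' (CO2 translocation between compartments) and exchange reactions (boundary
#' transport) are routed to `excluded` with a reason; so are reactions that
#' merely interconvert CO2 and bicarbonate when `ignore_bicarbonate = TRUE`.
#' Classification is per unit forward flux; direction-aware flux accounting
#' happens in the trait layer.
#'
#' @param model a `metabolic_model`.
#' @param co2_ids optional explicit CO2 metabolite ids.
#' @param ignore_bicarbonate reroute CO2/HCO3 interconversions to `excluded`.
#' @param exclude additional reaction ids to exclude (e.g. to reproduce the
#'   stricter biochemical definition that leaves out photosynthesis and
#'   photorespiration).
#' @return a `co2_inventory` object.
#' @export
build_inventory <- function(model, co2_ids = NULL, ignore_bicarbonate = FALSE,
                            exclude = character(0)) {
  co2 <- find_co2_species(model, co2_ids)
  if (!length(co2)) stop("model lacks CO2: no CO2 species found")
  hco3 <- model$metabolites$id[
    (!is.na(model$metabolites$formula) &
       model$metabolites$formula %in% c("HCO3", "CHO3")) |
      grepl("(^|[_\\W])hco3([_\\W]|$)", model$metabolites$id,
            ignore.case = TRUE, perl = TRUE)]

  net <- vapply(model$reactions$id, function(r) {
    st <- model$stoichiometry[[r]]
    sum(st[names(st) %in% co2])
  }, numeric(1))

  excluded <- character(0)
  tol <- 1e-9
  touches_co2 <- vapply(model$reactions$id, function(r)
    any(names(model$stoichiometry[[r]]) %in% co2), TRUE)
  for (k in seq_len(nrow(model$reactions))) {
    r <- model$reactions$id[k]
    if (!touches_co2[k]) next
    if (model$reactions$is_transport[k]) {
      excluded[r] <- "transport"
    } else if (model$reactions$is_exchange[k]) {
      excluded[r] <- "exchange"
    } else if (ignore_bicarbonate && length(hco3)) {
      st <- model$stoichiometry[[r]]
      d_hco3 <- sum(st[names(st) %in% hco3])
      if (abs(net[r] + d_hco3) <= tol) excluded[r] <- "bicarbonate-only"
    }
    if (r %in% exclude && is.na(excluded[r])) excluded[r] <- "user"
  }
  user_extra <- setdiff(exclude, names(excluded))
  for (r in intersect(user_extra, model$reactions$id)) excluded[r] <- "user"

  active <- names(net)[abs(net) > tol & !(names(net) %in% names(excluded))]
  structure(list(model_id = model$id,
                 co2_species = co2,
                 net_co2 = net,
                 producers_forward = active[net[active] > tol],
                 consumers_forward = active[net[active] < -tol],
                 excluded = excluded),
            class = "co2_inventory")
}

#' @export
print.co2_inventory <- function(x, ...) {
  cat("<co2_inventory> model ", x$model_id, "\n",
      "  CO2 species: ", paste(x$co2_species, collapse = ", "), "\n",
      "  producers (forward): ", length(x$producers_forward),
      " | consumers (forward): ", length(x$consumers_forward),
      " | excluded: ", length(x$excluded), "\n", sep = "")
  invisible(x)
}

#' EC numbers of the CO2-producing reactions of a model
#'
#' Union of EC annotations over the forward-producing reactions; reactions
#' without EC contribute nothing, partial ECs (trailing `-`) are kept as-is.
#'
#' @param model a `metabolic_model`.
#' @param inventory the [build_inventory()] result for that model.
#' @return character vector (a set) of EC strings.
#' @export
co2_ec_set <- function(model, inventory) {
  if (inventory$model_id != model$id) stop("inventory is for model ",
                                           inventory$model_id)
  sort(unique(unlist(model$ec_numbers[inventory$producers_forward])))
}

#' Compare CO2-producing EC sets across models
#'
#' Pairwise Jaccard index `|A n B| / |A u B|` (1 when both sets are empty)
#' plus, when a reference list is given, per-model coverage of that list.
#'
#' @param ec_sets named list: model id -> character vector of EC strings.
#' @param reference optional character vector (reference EC list).
#' @return an `ec_set_comparison` with `model_ids`, `jaccard` matrix and
#'   `coverage`.
#' @export
jaccard_compare <- function(ec_sets, reference = NULL) {
  if (length(ec_sets) < 2) stop("need at least 2 models to compare")
  ids <- names(ec_sets)
  n <- length(ids)
  J <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      a <- unique(ec_sets[[i]]); b <- unique(ec_sets[[j]])
      u <- union(a, b)
      J[i, j] <- J[j, i] <- if (length(u) == 0) 1 else
        length(intersect(a, b)) / length(u)
    }
  }
  coverage <- NULL
  if (!is.null(reference)) {
    reference <- unique(reference)
    if (!length(reference)) {
      warning("empty reference EC list; coverage omitted")
    } else {
      coverage <- vapply(ec_sets, function(a)
        length(intersect(unique(a), reference)) / length(reference), numeric(1))
    }
  }
  structure(list(model_ids = ids, jaccard = J, coverage = coverage),
            class = "ec_set_comparison")
}

#' Read a reference EC list (one EC per line, `#` comments)
#' @param path text file.
#' @return character vector of EC strings.
#' @export
read_ec_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
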