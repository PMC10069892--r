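#' RuBisCO oxygenation/carboxylation ratio constraint
#'
#' Physiological bounds on the ratio Vo/Vc. The defaults 0.31-0.55
#' correspond to the intracellular O2:CO2 partial-pressure ratio divided by
#' the average specificity of RuBisCO for CO2 over O2.
#'
#' @param carboxylation_reaction_id,oxygenation_reaction_id reaction ids.
#' @param ratio_min,ratio_max bounds on Vo/Vc.
#' @return a `rubisco_constraint` object.
#' @export
rubisco_constraint <- function(carboxylation_reaction_id,
                               oxygenation_reaction_id,
                               ratio_min = 0.31, ratio_max = 0.55) {
  stopifnot(ratio_min >= 0, ratio_min <= ratio_max)
  structure(list(carboxylation_reaction_id = carboxylation_reaction_id,
                 oxygenation_reaction_id = oxygenation_reaction_id,
                 ratio_min = ratio_min, ratio_max = ratio_max),
            class = "rubisco_constraint")
}

#' Emit the linear constraints for a RuBisCO ratio window
#'
#' Produces `vo - ratio_min vc >= 0` and `vo - ratio_max vc <= 0`. With
#' `vc = 0` both collapse and force `vo = 0`.
#'
#' @param model a `metabolic_model`.
#' @param rc a [rubisco_constraint()].
#' @return list of [linear_constraint()] objects.
#' @export
constrain_rubisco <- function(model, rc) {
  vc <- rc$carboxylation_reaction_id
  vo <- rc$oxygenation_reaction_id
  if (!vc %in% model$reactions$id) {
    stop("model lacks carboxylation reaction ", vc)
  }
  if (!vo %in% model$reactions$id) {
    stop("model lacks photorespiration: no oxygenation reaction ", vo)
  }
  list(linear_constraint(stats::setNames(c(1, -rc$ratio_min), c(vo, vc)), ">=", 0),
       linear_constraint(stats::setNames(c(1, -rc$ratio_max), c(vo, vc)), "<=", 0))
}

# Direction-aware per-reaction CO2 release/uptake at a flux distribution,
# over non-excluded reactions: release(r) = max(0, net_co2(r) * v_r).
co2_release_by_reaction <- function(flux, inv) {
  keep <- setdiff(names(inv$net_co2)[abs(inv$net_co2) > 1e-12],
                  names(inv$excluded))
  rate <- inv$net_co2[keep] * flux$flux[keep]
  rate[is.na(rate)] <- 0
  rate
}

#' Net CO2 assimilation of a flux distribution
#'
#' Sum of CO2-consuming minus CO2-producing fluxes over the non-excluded
#' reactions of the inventory, direction-aware (a reversible producer running
#' backward counts as consumption). Values with magnitude below `threshold`
#' (default 1e-9 mmol gDW^-1 h^-1, the solver feasibility reporting cutoff)
#' are reported as 0.
#'
#' @param flux a `flux_distribution`.
#' @param inv a `co2_inventory` from the same model.
#' @param threshold reporting threshold.
#' @return net assimilation A_net (mmol gDW^-1 h^-1).
#' @export
net_assimilation <- function(flux, inv, threshold = 1e-9) {
  if (flux$model_id != inv$model_id) {
    stop("flux distribution is for model ", flux$model_id,
         " but inventory for ", inv$model_id)
  }
  rate <- co2_release_by_reaction(flux, inv)
  a <- sum(pmax(0, -rate)) - sum(pmax(0, rate))
  if (abs(a) < threshold) 0 else a
}

# Growth respiration in the operational sense: sum of CO2-releasing fluxes.
growth_respiration <- function(flux, inv, threshold = 1e-9) {
  rg <- sum(pmax(0, co2_release_by_reaction(flux, inv)))
  if (rg < threshold) 0 else rg
}

co2_exchange_ids <- function(model, inv) {
  ex <- model$reactions$id[model$reactions$is_exchange]
  ex[vapply(ex, function(r)
    any(names(model$stoichiometry[[r]]) %in% inv$co2_species), TRUE)]
}

#' Compute the respiratory CO2 trait panel of a model
#'
#' Runs pFBA under the optional RuBisCO ratio constraint and derives, from
#' that single flux distribution: net CO2 assimilation `A_net`, the RuBisCO
#' fluxes `Vc` and `Vo`, estimated day respiration `Rd = Vc - 0.5 Vo -
#' A_net`, carbon use efficiency `CUE = 1 - (0.5 Vo + Rd)/Vc`, and growth
#' respiration `Rg` (sum of CO2-releasing fluxes). Maximum CO2 release
#' `Rnetmax` (CO2-export maximization) and maximum net CO2 fixation
#' `Anetmax` (import minus export) are assessed at optimal growth. `Rg` is
#' additionally scaled by growth rate times the biomass molar carbon
#' fraction, giving mol CO2 per mol biomass carbon.
#'
#' @param model a `metabolic_model` (must grow under FBA unless `mu = 0` is
#'   acceptable, in which case scaled values are flagged undefined).
#' @param inv a `co2_inventory` for the model.
#' @param rc optional [rubisco_constraint()]; dropped with a message when the
#'   model lacks the oxygenation reaction (non-plant models).
#' @param extra_constraints additional [linear_constraint()]s.
#' @param optimum_fraction fraction of the FBA optimum enforced in pFBA.
#' @param lexicographic use lexicographic pFBA (default TRUE so printed trait
#'   values are backend-stable).
#' @param threshold reporting threshold for near-zero values.
#' @return a `respiration_traits` object.
#' @export
compute_traits <- function(model, inv, rc = NULL, extra_constraints = list(),
                           optimum_fraction = 1, lexicographic = TRUE,
                           threshold = 1e-9) {
  cts <- extra_constraints
  have_rubisco <- FALSE
  if (!is.null(rc)) {
    ok <- rc$oxygenation_reaction_id %in% model$reactions$id &&
      rc$carboxylation_reaction_id %in% model$reactions$id
    if (ok) {
      cts <- c(cts, constrain_rubisco(model, rc))
      have_rubisco <- TRUE
    } else {
      message("model ", model$id, " lacks photorespiration; ",
              "RuBisCO ratio constraint not applied")
    }
  }
  sol <- pfba(model, cts, optimum_fraction = optimum_fraction,
              lexicographic = lexicographic)
  if (sol$status != "optimal") stop("pFBA not optimal: ", sol$status)

  mu <- unname(sum(model$objective * sol$flux[names(model$objective)]))
  Vc <- if (!is.null(rc) && rc$carboxylation_reaction_id %in% model$reactions$id)
    unname(sol$flux[rc$carboxylation_reaction_id]) else NA_real_
  Vo <- if (have_rubisco) unname(sol$flux[rc$oxygenation_reaction_id]) else
    if (!is.null(rc)) 0 else NA_real_
  A_net <- net_assimilation(sol, inv, threshold)
  Rg <- growth_respiration(sol, inv, threshold)
  Rd <- if (!is.na(Vc)) Vc - 0.5 * Vo - A_net else NA_real_
  CUE <- if (!is.na(Vc) && Vc > threshold) 1 - (0.5 * Vo + Rd) / Vc else NA_real_

  ex_ids <- co2_exchange_ids(model, inv)
  Rnetmax <- Anetmax <- NA_real_
  if (length(ex_ids)) {
    # export positive by sign convention; several CO2 boundaries sum up
    target <- stats::setNames(rep(1, length(ex_ids)), ex_ids)
    r1 <- maximize_flux(model, target, 1, cts)
    if (r1$status == "optimal") Rnetmax <- r1$objective_value
    r2 <- maximize_flux(model, -target, 1, cts)
    if (r2$status == "optimal") Anetmax <- r2$objective_value
  }

  cf <- tryCatch(biomass_carbon_fraction(model), error = function(e) NULL)
  growing <- mu > 1e-6  # separates numerically-zero growth from slow growth
  Rg_scaled <- if (growing && !is.null(cf) && cf$value > 0)
    Rg / (mu * cf$value) else NA_real_

  structure(list(model_id = model$id, A_net = A_net, Vc = Vc, Vo = Vo,
                 Rd = Rd, CUE = CUE, Rg = Rg,
                 Rnetmax = Rnetmax, Anetmax = Anetmax, mu = mu,
                 carbon_fraction = if (is.null(cf)) NA_real_ else cf$value,
                 Rg_scaled = Rg_scaled, growing = growing,
                 flux = sol),
            class = "respiration_traits")
}

#' @export
print.respiration_traits <- function(x, ...) {
  cat("<respiration_traits> model ", x$model_id, "\n", sep = "")
  v <- unlist(x[c("mu", "A_net", "Vc", "Vo", "Rd", "CUE", "Rg",
                  "Rnetmax", "Anetmax", "Rg_scaled")])
  print(round(v, 6))
  invisible(x)
}

#' Rank reactions by their CO2 release at a flux distribution
#'
#' Per-reaction CO2 release `max(0, net_co2(r) v_r)`, sorted descending with
#' ties broken by reaction id, with each reaction's share of total growth
#' respiration.
#'
#' @param flux a `flux_distribution`.
#' @param inv a `co2_inventory` from the same model.
#' @param model the `metabolic_model` (for EC annotations).
#' @return a `contribution_ranking` whose `entries` data.frame has columns
#'   `reaction`, `ec`, `co2_flux`, `share`; empty with a note when Rg = 0.
#' @export
rank_contributors <- function(flux, inv, model) {
  rate <- co2_release_by_reaction(flux, inv)
  rate <- rate[rate > 1e-12]  # pmax would drop names
  if (!length(rate)) {
    return(structure(list(entries = data.frame(reaction = character(0),
                                               ec = character(0),
                                               co2_flux = numeric(0),
                                               share = numeric(0)),
                          note = "no CO2 release at this flux distribution"),
                     class = "contribution_ranking"))
  }
  ord <- order(-rate, names(rate))
  rate <- rate[ord]
  entries <- data.frame(
    reaction = names(rate),
    ec = vapply(names(rate), function(r) {
      ec <- model$ec_numbers[[r]]
      if (is.null(ec) || !length(ec)) "" else paste(ec, collapse = ";")
    }, ""),
    co2_flux = unname(rate),
    share = unname(rate) / sum(rate),
    stringsAsFactors = FALSE)
  structure(list(entries = entries, note = NULL),
            class = "contribution_ranking")
}

#' @export
print.contribution_ranking <- function(x, ...) {
  if (!is.null(x$note)) cat("(", x$note, ")\n", sep = "")
  print(utils::head(x$entries, 10))
  invisible(x)
}

#' Day/night trait comparison with growth bounded by the day optimum
#'
#' Solves the day model first; the night model's growth is then bounded
#' above by the day-optimal value so the scaled traits are comparable. If
#' the night model cannot reach any growth under that cap the cap is simply
#' not binding (an upper bound); if the night model is infeasible with the
#' day-derived constraints it falls back to its own optimum with a warning.
#'
#' @param model_day,model_night day- and night-parameterized models sharing
#'   the biomass reaction id.
#' @param inv_day,inv_night matching inventories.
#' @param rc optional [rubisco_constraint()] applied to both.
#' @param ... passed to [compute_traits()].
#' @return list with elements `day` and `night` (both `respiration_traits`).
#' @export
compare_conditions <- function(model_day, model_night, inv_day, inv_night,
                               rc = NULL, ...) {
  if (!identical(names(model_day$objective), names(model_night$objective))) {
    stop("day and night models must share the biomass reaction id")
  }
  day <- compute_traits(model_day, inv_day, rc, ...)
  bio <- names(model_night$objective)[1]
  idx <- match(bio, model_night$reactions$id)
  model_night$reactions$upper_bound[idx] <-
    min(model_night$reactions$upper_bound[idx], day$mu)
  night <- tryCatch(
    compute_traits(model_night, inv_night, rc, ...),
    error = function(e) {
      warning("night model failed under day-optimal growth cap (",
              conditionMessage(e), "); falling back to night-optimal growth")
      compute_traits(model_night, inv_night, rc, ...)
    })
  list(day = day, night = night)
}
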