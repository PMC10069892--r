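ko_record <- function(ids, mu, Rg, Rg_scaled, fold_nominal, fold_scaled,
                      viable) {
  list(knockout_ids = ids, mu = mu, Rg = Rg, Rg_scaled = Rg_scaled,
       fold_nominal = fold_nominal, fold_scaled = fold_scaled,
       viable = viable)
}

#' Single/double reaction-knockout screen of CO2 traits
#'
#' For every knockout set (all singles, then all id-ordered pairs at
#' `depth = 2`), closes the reaction bounds, re-solves pFBA under the same
#' constraint regime as the wild type, and records growth, growth
#' respiration Rg (sum of CO2-releasing fluxes), scaled Rg (per mol biomass
#' carbon), and fold-changes against the wild-type record. Pairs in which
#' both reactions carry zero wild-type pFBA flux are pruned by default
#' (their joint knockout provably leaves the wild-type optimum feasible)
#' and counted in `skipped`. Records are deterministically ordered.
#'
#' @param model a `metabolic_model` that grows in FBA.
#' @param inv a `co2_inventory` for the model.
#' @param rc optional [rubisco_constraint()].
#' @param depth 1 or 2.
#' @param candidates reaction ids to knock out; defaults to all non-exchange
#'   reactions except the biomass (objective) reaction.
#' @param extra_constraints additional [linear_constraint()]s.
#' @param prune skip pairs with zero wild-type flux on both members.
#' @param viability_threshold a knockout is viable when its growth exceeds
#'   this fraction of wild-type growth (default 1e-6).
#' @param lexicographic use lexicographic pFBA for each knockout (slower;
#'   the default solver is already deterministic).
#' @return a `screen_report` with `wild_type`, `records` (data.frame) and
#'   `skipped`.
#' @export
run_screen <- function(model, inv, rc = NULL, depth = 1, candidates = NULL,
                       extra_constraints = list(), prune = TRUE,
                       viability_threshold = 1e-6, lexicographic = FALSE) {
  if (!depth %in% c(1, 2)) stop("unsupported depth: ", depth)
  cts <- extra_constraints
  if (!is.null(rc)) cts <- c(cts, constrain_rubisco(model, rc))

  cf <- biomass_carbon_fraction(model)$value
  wt_sol <- pfba(model, cts, lexicographic = lexicographic)
  if (wt_sol$status != "optimal") stop("wild-type model does not grow")
  wt_mu <- sum(model$objective * wt_sol$flux[names(model$objective)])
  if (wt_mu <= 0) stop("wild-type model does not grow")
  wt_rg <- growth_respiration(wt_sol, inv)
  wt <- ko_record(character(0), wt_mu, wt_rg, wt_rg / (wt_mu * cf), 1, 1, TRUE)

  if (is.null(candidates)) {
    candidates <- setdiff(
      model$reactions$id[!model$reactions$is_exchange],
      names(model$objective))
  }
  candidates <- sort(candidates)

  sets <- lapply(candidates, function(x) x)
  skipped <- 0L
  if (depth == 2 && length(candidates) >= 2) {
    zero_wt <- abs(wt_sol$flux[candidates]) < 1e-9
    for (i in seq_len(length(candidates) - 1)) {
      for (j in (i + 1):length(candidates)) {
        if (prune && zero_wt[i] && zero_wt[j]) {
          skipped <- skipped + 1L
        } else {
          sets[[length(sets) + 1]] <- c(candidates[i], candidates[j])
        }
      }
    }
  }

  rows <- vector("list", length(sets))
  for (k in seq_along(sets)) {
    ids <- sets[[k]]
    ko <- apply_knockout(model, ids)
    base <- fba(ko, cts)
    mu <- if (base$status == "optimal") base$objective_value else 0
    viable <- base$status == "optimal" && mu > viability_threshold * wt_mu
    if (viable) {
      sol <- pfba(ko, cts, lexicographic = lexicographic)
      rg <- growth_respiration(sol, inv)
      mu <- sum(model$objective * sol$flux[names(model$objective)])
      rg_s <- rg / (mu * cf)
      rows[[k]] <- data.frame(
        ko1 = ids[1], ko2 = if (length(ids) > 1) ids[2] else "",
        mu = mu, Rg = rg, Rg_scaled = rg_s,
        fold_nominal = if (wt_rg > 0) rg / wt_rg else NA_real_,
        fold_scaled = if (wt$Rg_scaled > 0) rg_s / wt$Rg_scaled else NA_real_,
        viable = TRUE, stringsAsFactors = FALSE)
    } else {
      rows[[k]] <- data.frame(
        ko1 = ids[1], ko2 = if (length(ids) > 1) ids[2] else "",
        mu = if (base$status == "optimal") mu else 0,
        Rg = NA_real_, Rg_scaled = NA_real_,
        fold_nominal = NA_real_, fold_scaled = NA_real_,
        viable = FALSE, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  structure(list(wild_type = wt, records = records, skipped = skipped,
                 model_id = model$id),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report> model ", x$model_id, ": ", nrow(x$records),
      " knockout sets (", sum(x$records$viable), " viable, ",
      x$skipped, " pairs pruned)\n",
      "  wild type: mu = ", format(x$wild_type$mu),
      ", scaled Rg = ", format(x$wild_type$Rg_scaled), "\n", sep = "")
  invisible(x)
}

#' Knockouts that reduce CO2 release per unit biomass carbon
#'
#' Filters a screen report to the viable records whose scaled growth
#' respiration dropped below the wild type (`fold_scaled < 1 - tolerance`).
#' An empty result is a legitimate outcome.
#'
#' @param report a `screen_report`.
#' @param tolerance strictness margin on the fold change.
#' @return data.frame subset of `report$records`.
#' @export
find_respiration_reducers <- function(report, tolerance = 1e-6) {
  rec <- report$records
  rec[rec$viable & !is.na(rec$fold_scaled) &
        rec$fold_scaled < 1 - tolerance, , drop = FALSE]
}

#' Minimize growth respiration per unit biomass carbon
#'
#' Minimizes the ratio (sum of CO2-producing fluxes, direction-aware) /
#' (carbon fraction x biomass flux) over the flux polytope via the
#' Charnes-Cooper transformation, and compares the achieved ratio with the
#' scaled Rg of the reference pFBA distribution. Also reports how many
#' reactions changed activity state (zero vs nonzero flux), quantifying the
#' flux rerouting required.
#'
#' @param model a `metabolic_model`.
#' @param inv a `co2_inventory`.
#' @param rc optional [rubisco_constraint()].
#' @param extra_constraints additional [linear_constraint()]s.
#' @param lexicographic use lexicographic pFBA for the reference solution.
#' @return list with `ratio_before`, `ratio_after`, `flux` (the minimizing
#'   `flux_distribution`), and `n_state_changes`.
#' @export
minimize_scaled_respiration <- function(model, inv, rc = NULL,
                                        extra_constraints = list(),
                                        lexicographic = TRUE) {
  cts <- extra_constraints
  if (!is.null(rc)) cts <- c(cts, constrain_rubisco(model, rc))
  cf <- biomass_carbon_fraction(model)$value
  if (!is.finite(cf) || cf <= 0) stop("carbon fraction undefined")

  ref <- pfba(model, cts, lexicographic = lexicographic)
  if (ref$status != "optimal") stop("reference pFBA failed: ", ref$status)
  mu <- sum(model$objective * ref$flux[names(model$objective)])
  ratio_before <- growth_respiration(ref, inv) / (mu * cf)

  # Direction-aware producing sum on the split halves: forward halves of
  # net>0 reactions plus |backward| halves of net<0 reactions produce CO2.
  keep <- setdiff(names(inv$net_co2)[abs(inv$net_co2) > 1e-12],
                  names(inv$excluded))
  net <- inv$net_co2[keep]
  lbs <- stats::setNames(model$reactions$lower_bound, model$reactions$id)
  ubs <- stats::setNames(model$reactions$upper_bound, model$reactions$id)
  revs <- lbs[keep] < 0 & ubs[keep] > 0
  fwd <- pmax(net, 0)
  fwd <- fwd[fwd > 0]
  rev <- -pmin(net[revs], 0)
  rev <- rev[rev > 0]
  numerator <- list(fwd = fwd, rev = if (length(rev)) rev else NULL)
  bio <- names(model$objective)[1]
  denominator <- stats::setNames(cf * model$objective[[bio]], bio)

  res <- minimize_linear_fractional(model, numerator, denominator, cts)
  ratio_after <- res$objective_value

  active_ref <- abs(ref$flux) > 1e-6
  active_new <- abs(res$flux) > 1e-6
  list(ratio_before = ratio_before, ratio_after = ratio_after, flux = res,
       n_state_changes = sum(active_ref != active_new))
}
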