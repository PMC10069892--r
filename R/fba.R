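#' Build a linear constraint over reaction fluxes
#'
#' @param coef named numeric vector over reaction ids.
#' @param dir one of `"<="`, `">="`, `"="`.
#' @param rhs right-hand side.
#' @return a `linear_constraint` object.
#' @export
linear_constraint <- function(coef, dir = c("<=", ">=", "="), rhs = 0) {
  dir <- match.arg(dir)
  stopifnot(is.numeric(coef), !is.null(names(coef)))
  structure(list(coef = coef, dir = dir, rhs = rhs),
            class = "linear_constraint")
}

# Stack extra constraints into <= and = rows over the reaction order of model.
constraint_rows <- function(model, extra_constraints) {
  rxns <- model$reactions$id
  A_ub <- matrix(0, 0, length(rxns)); b_ub <- numeric(0)
  A_eq <- matrix(0, 0, length(rxns)); b_eq <- numeric(0)
  for (ct in extra_constraints) {
    unknown <- setdiff(names(ct$coef), rxns)
    if (length(unknown)) stop("constraint references unknown reactions: ",
                              paste(unknown, collapse = ", "))
    row <- numeric(length(rxns)); names(row) <- rxns
    row[names(ct$coef)] <- ct$coef
    if (ct$dir == "<=") { A_ub <- rbind(A_ub, row); b_ub <- c(b_ub, ct$rhs) }
    else if (ct$dir == ">=") { A_ub <- rbind(A_ub, -row); b_ub <- c(b_ub, -ct$rhs) }
    else { A_eq <- rbind(A_eq, row); b_eq <- c(b_eq, ct$rhs) }
  }
  list(A_ub = A_ub, b_ub = b_ub, A_eq = A_eq, b_eq = b_eq)
}

new_flux_distribution <- function(model, flux, objective_value, status,
                                  tolerance = 1e-9) {
  structure(list(model_id = model$id, flux = flux,
                 objective_value = objective_value, status = status,
                 tolerance = tolerance),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("<flux_distribution> model ", x$model_id, ", status ", x$status,
      ", objective ", format(x$objective_value), "\n", sep = "")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes the model objective over the steady-state flux polytope
#' `{v : S v = 0, lb <= v <= ub}` intersected with `extra_constraints`.
#' Infeasibility and unboundedness are reported in `status`, never clipped.
#'
#' @param model a `metabolic_model` with a nonempty objective.
#' @param extra_constraints list of [linear_constraint()] objects.
#' @param objective optional named numeric overriding the model objective.
#' @return a `flux_distribution`.
#' @export
fba <- function(model, extra_constraints = list(), objective = NULL) {
  if (is.null(objective)) objective <- model$objective
  if (!length(objective)) stop("model has an empty objective")
  S <- stoich_matrix(model)
  rxns <- model$reactions$id
  obj <- numeric(length(rxns)); names(obj) <- rxns
  obj[names(objective)] <- objective
  ex <- constraint_rows(model, extra_constraints)
  res <- solve_lp(obj,
                  A_eq = rbind(S, ex$A_eq), b_eq = c(rep(0, nrow(S)), ex$b_eq),
                  A_ub = ex$A_ub, b_ub = ex$b_ub,
                  lb = model$reactions$lower_bound,
                  ub = model$reactions$upper_bound,
                  maximize = TRUE)
  flux <- stats::setNames(res$x, rxns)
  new_flux_distribution(model, flux, res$objective, res$status)
}

# Split reactions whose bounds straddle zero into forward/backward halves.
# Returns the split design shared by pfba and the fractional minimizer.
split_design <- function(model) {
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  rxns <- model$reactions$id
  rev <- lb < 0 & ub > 0
  n_split <- length(rxns) + sum(rev)
  fwd_col <- seq_along(rxns)
  rev_col <- integer(length(rxns))
  rev_col[rev] <- length(rxns) + seq_len(sum(rev))
  # sign[j]: +1 variable measures forward flux, -1 measures |backward| flux
  sgn <- ifelse(!rev & ub <= 0, -1, 1)
  lo <- hi <- numeric(n_split)
  for (j in seq_along(rxns)) {
    if (rev[j]) {
      lo[fwd_col[j]] <- 0; hi[fwd_col[j]] <- ub[j]
      lo[rev_col[j]] <- 0; hi[rev_col[j]] <- -lb[j]
    } else if (ub[j] <= 0) {      # strictly backward: variable is -v
      lo[fwd_col[j]] <- -ub[j]; hi[fwd_col[j]] <- -lb[j]
    } else {
      lo[fwd_col[j]] <- lb[j]; hi[fwd_col[j]] <- ub[j]
    }
  }
  list(rxns = rxns, rev = rev, fwd_col = fwd_col, rev_col = rev_col,
       sgn = sgn, lb = lo, ub = hi, n = n_split)
}

# Expand a row over net fluxes to the split columns (v = sgn*fwd - rev).
split_row <- function(design, coef_named) {
  row <- numeric(design$n)
  idx <- match(names(coef_named), design$rxns)
  for (k in seq_along(idx)) {
    j <- idx[k]
    row[design$fwd_col[j]] <- row[design$fwd_col[j]] +
      coef_named[k] * design$sgn[j]
    if (design$rev[j]) row[design$rev_col[j]] <- row[design$rev_col[j]] -
        coef_named[k]
  }
  row
}

split_matrix <- function(design, A) {
  out <- matrix(0, nrow(A), design$n)
  for (i in seq_len(nrow(A))) {
    coef <- A[i, ]
    nz <- which(coef != 0)
    if (length(nz)) {
      out[i, ] <- split_row(design, stats::setNames(coef[nz],
                                                    design$rxns[nz]))
    }
  }
  out
}

recombine_split <- function(design, y) {
  v <- design$sgn * y[design$fwd_col]
  v[design$rev] <- v[design$rev] - y[design$rev_col[design$rev]]
  stats::setNames(v, design$rxns)
}

#' Parsimonious flux balance analysis
#'
#' Fixes the objective at `optimum_fraction` times the FBA optimum, splits
#' every reversible reaction into two irreversible halves and minimizes the
#' sum of all half-fluxes (total absolute flux). With `lexicographic = TRUE`
#' the total-flux optimum is additionally pinned and each reaction's
#' absolute flux is minimized in reaction-id order, making the reported
#' distribution independent of pivoting order across LP backends.
#'
#' @param model a `metabolic_model`.
#' @param extra_constraints list of [linear_constraint()] objects.
#' @param optimum_fraction fraction of the FBA optimum to enforce, in (0, 1].
#' @param lexicographic pin individual fluxes after the total-flux solve.
#' @return a `flux_distribution`; attribute `total_flux` carries the minimal
#'   sum of absolute fluxes.
#' @export
pfba <- function(model, extra_constraints = list(), optimum_fraction = 1,
                 lexicographic = FALSE) {
  stopifnot(optimum_fraction > 0, optimum_fraction <= 1)
  base <- fba(model, extra_constraints)
  if (base$status != "optimal") return(base)

  design <- split_design(model)
  S <- stoich_matrix(model)
  Ss <- split_matrix(design, S)
  ex <- constraint_rows(model, extra_constraints)
  A_ub <- if (nrow(ex$A_ub)) split_matrix(design, ex$A_ub) else
    matrix(0, 0, design$n)
  b_ub <- ex$b_ub
  A_eq <- rbind(Ss, if (nrow(ex$A_eq)) split_matrix(design, ex$A_eq))
  b_eq <- c(rep(0, nrow(Ss)), ex$b_eq)

  obj_named <- model$objective
  obj_row <- split_row(design, obj_named)
  A_ub <- rbind(A_ub, -obj_row)
  b_ub <- c(b_ub, -optimum_fraction * base$objective_value)

  cost <- rep(1, design$n)
  res <- solve_lp(cost, A_eq = A_eq, b_eq = b_eq, A_ub = A_ub, b_ub = b_ub,
                  lb = design$lb, ub = design$ub)
  if (res$status != "optimal") {
    return(new_flux_distribution(model, stats::setNames(
      rep(NA_real_, length(design$rxns)), design$rxns), NA_real_, res$status))
  }
  total <- res$objective

  if (lexicographic) {
    A_ub <- rbind(A_ub, cost)
    b_ub <- c(b_ub, total + 1e-9)
    for (j in order(design$rxns)) {
      cj <- numeric(design$n)
      cj[design$fwd_col[j]] <- 1
      if (design$rev[j]) cj[design$rev_col[j]] <- 1
      r2 <- solve_lp(cj, A_eq = A_eq, b_eq = b_eq, A_ub = A_ub, b_ub = b_ub,
                     lb = design$lb, ub = design$ub)
      if (r2$status != "optimal") break
      A_ub <- rbind(A_ub, cj)
      b_ub <- c(b_ub, r2$objective + 1e-9)
      res <- r2
    }
  }

  flux <- recombine_split(design, res$x)
  flux[abs(flux) < 1e-8] <- 0  # feasibility-tolerance rounding (covers the
  # 1e-9 lexicographic pinning slack)
  out <- new_flux_distribution(model, flux,
                               sum(obj_named * flux[names(obj_named)]),
                               "optimal")
  attr(out, "total_flux") <- total
  out
}

#' Maximize a linear flux expression at (near-)optimal growth
#'
#' Maximizes `target' v` subject to steady state, bounds, extra constraints,
#' and the model objective held at `fixed_objective_fraction` times its FBA
#' optimum. Used for maximum CO2 release (export maximization) and maximum
#' net CO2 fixation (import minus export).
#'
#' @param model a `metabolic_model`.
#' @param target named numeric over reaction ids.
#' @param fixed_objective_fraction fraction of the FBA optimum to hold.
#' @param extra_constraints list of [linear_constraint()] objects.
#' @return a `flux_distribution` whose `objective_value` is the target value.
#' @export
maximize_flux <- function(model, target, fixed_objective_fraction = 1,
                          extra_constraints = list()) {
  base <- fba(model, extra_constraints)
  if (base$status != "optimal") return(base)
  cts <- c(extra_constraints,
           list(linear_constraint(model$objective, ">=",
                                  fixed_objective_fraction *
                                    base$objective_value)))
  fba(model, cts, objective = target)
}

#' Minimize a linear-fractional flux objective (Charnes-Cooper)
#'
#' Solves `min numerator' v / denominator' v` over the flux polytope via the
#' substitution `y = t v`, `t >= 0`, `denominator' y = 1`, which linearizes
#' the program exactly. Numerator and denominator may be given either as
#' named numeric vectors over net fluxes, or as `list(fwd = ..., rev = ...)`
#' of named vectors applying to the forward and |backward| half-fluxes of the
#' split system (needed for direction-aware CO2 production sums).
#'
#' @param model a `metabolic_model`.
#' @param numerator,denominator linear expressions (see Details).
#' @param extra_constraints list of [linear_constraint()] objects.
#' @return a `flux_distribution`; `objective_value` is the achieved ratio.
#' @export
minimize_linear_fractional <- function(model, numerator, denominator,
                                       extra_constraints = list()) {
  design <- split_design(model)
  expr_row <- function(e) {
    if (is.list(e)) {
      row <- numeric(design$n)
      if (!is.null(e$fwd)) {
        idx <- match(names(e$fwd), design$rxns)
        row[design$fwd_col[idx]] <- row[design$fwd_col[idx]] + e$fwd
      }
      if (!is.null(e$rev)) {
        idx <- match(names(e$rev), design$rxns)
        if (any(!design$rev[idx])) stop("rev part names a non-reversible reaction")
        row[design$rev_col[idx]] <- row[design$rev_col[idx]] + e$rev
      }
      row
    } else split_row(design, e)
  }
  num_row <- expr_row(numerator)
  den_row <- expr_row(denominator)

  S <- stoich_matrix(model)
  Ss <- split_matrix(design, S)
  ex <- constraint_rows(model, extra_constraints)

  # Columns: y (design$n) then t.
  nv <- design$n + 1
  pad <- function(row, t_coef = 0) c(row, t_coef)
  A_eq <- rbind(cbind(Ss, 0), pad(den_row))
  b_eq <- c(rep(0, nrow(Ss)), 1)
  A_ub <- matrix(0, 0, nv); b_ub <- numeric(0)
  if (nrow(ex$A_ub)) {
    Au <- split_matrix(design, ex$A_ub)
    A_ub <- rbind(A_ub, cbind(Au, -ex$b_ub))
    b_ub <- c(b_ub, rep(0, nrow(Au)))
  }
  if (nrow(ex$A_eq)) {
    Ae <- split_matrix(design, ex$A_eq)
    A_eq <- rbind(A_eq, cbind(Ae, -ex$b_eq))
    b_eq <- c(b_eq, rep(0, nrow(Ae)))
  }
  # Homogenized variable bounds: lb*t <= y <= ub*t.
  fin_up <- which(is.finite(design$ub))
  if (length(fin_up)) {
    rows <- matrix(0, length(fin_up), nv)
    rows[cbind(seq_along(fin_up), fin_up)] <- 1
    rows[, nv] <- -design$ub[fin_up]
    A_ub <- rbind(A_ub, rows)
    b_ub <- c(b_ub, rep(0, length(fin_up)))
  }
  nz_lo <- which(design$lb > 0)
  if (length(nz_lo)) {
    rows <- matrix(0, length(nz_lo), nv)
    rows[cbind(seq_along(nz_lo), nz_lo)] <- -1
    rows[, nv] <- design$lb[nz_lo]
    A_ub <- rbind(A_ub, rows)
    b_ub <- c(b_ub, rep(0, length(nz_lo)))
  }

  res <- solve_lp(c(num_row, 0), A_eq = A_eq, b_eq = b_eq,
                  A_ub = A_ub, b_ub = b_ub,
                  lb = rep(0, nv), ub = rep(Inf, nv))
  if (res$status != "optimal") {
    return(new_flux_distribution(model, stats::setNames(
      rep(NA_real_, length(design$rxns)), design$rxns), NA_real_, res$status))
  }
  t_star <- res$x[nv]
  if (t_star <= 1e-10) stop("degenerate fractional program: t* = 0 ",
                            "(unbounded growth direction)")
  v <- recombine_split(design, res$x[seq_len(design$n)] / t_star)
  out <- new_flux_distribution(model, v, res$objective, "optimal")
  attr(out, "t") <- t_star
  out
}

#' Knock out reactions by closing their flux bounds
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids ids to disable (bounds set to 0); the input model is
#'   not modified.
#' @return a new `metabolic_model`.
#' @export
apply_knockout <- function(model, reaction_ids) {
  unknown <- setdiff(reaction_ids, model$reactions$id)
  if (length(unknown)) stop("unknown reaction id(s): ",
                            paste(unknown, collapse = ", "))
  idx <- match(reaction_ids, model$reactions$id)
  model$reactions$lower_bound[idx] <- 0
  model$reactions$upper_bound[idx] <- 0
  model
}
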