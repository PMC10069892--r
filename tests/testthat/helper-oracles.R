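# Independent brute-force oracles. These never touch the package's simplex:
# linear algebra only, via base::qr. A vertex of {S v = 0, l <= v <= u} has
# at least n - rank(S) active bound constraints; enumerating every choice of
# fixed set and bound side visits every vertex of the (bounded) polytope.

enumerate_vertices <- function(model, extra_constraints = list()) {
  S <- stoich_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  # fold equality extra constraints into S; inequalities unsupported here
  for (ct in extra_constraints) {
    stopifnot(ct$dir == "=")
    row <- numeric(ncol(S)); names(row) <- colnames(S)
    row[names(ct$coef)] <- ct$coef
    S <- rbind(S, row)
    stopifnot(ct$rhs == 0)
  }
  n <- ncol(S)
  r <- qr(S)$rank
  nfix <- n - r
  verts <- list()
  if (nfix == 0) {
    sol <- qr.solve(S, rep(0, nrow(S)))
    if (all(sol >= lb - 1e-8 & sol <= ub + 1e-8)) verts[[1]] <- sol
  } else {
    for (fix_idx in utils::combn(n, nfix, simplify = FALSE)) {
      rest <- setdiff(seq_len(n), fix_idx)
      Sr <- S[, rest, drop = FALSE]
      if (qr(Sr)$rank < length(rest)) next  # non-unique; caught elsewhere
      sides <- expand.grid(rep(list(c(1, 2)), nfix))
      for (k in seq_len(nrow(sides))) {
        vfix <- ifelse(unlist(sides[k, ]) == 1, lb[fix_idx], ub[fix_idx])
        if (any(!is.finite(vfix))) next
        rhs <- -S[, fix_idx, drop = FALSE] %*% vfix
        vrest <- tryCatch(qr.solve(Sr, rhs), error = function(e) NULL)
        if (is.null(vrest)) next
        if (max(abs(S[, rest, drop = FALSE] %*% vrest - rhs)) > 1e-7) next
        v <- numeric(n)
        v[fix_idx] <- vfix
        v[rest] <- vrest
        if (all(v >= lb - 1e-7 & v <= ub + 1e-7)) {
          verts[[length(verts) + 1]] <- v
        }
      }
    }
  }
  if (!length(verts)) return(NULL)
  out <- do.call(rbind, verts)
  colnames(out) <- model$reactions$id
  out
}

# Brute-force FBA optimum: best objective value over all vertices.
oracle_fba_optimum <- function(model, extra_constraints = list()) {
  V <- enumerate_vertices(model, extra_constraints)
  if (is.null(V)) return(NA_real_)
  obj <- numeric(nrow(V))
  for (k in seq_len(nrow(V))) {
    obj[k] <- sum(model$objective * V[k, names(model$objective)])
  }
  max(obj)
}

# Linear-fractional minimum by bisection on lambda: the parametric program
# g(lambda) = min (num - lambda den)' v over the polytope is evaluated by
# vertex enumeration; the optimal ratio is the root of g.
oracle_min_ratio <- function(model, num, den, lo = 0, hi = 100,
                             tol = 1e-7) {
  V <- enumerate_vertices(model)
  stopifnot(!is.null(V))
  num_v <- den_v <- numeric(nrow(V))
  for (k in seq_len(nrow(V))) {
    num_v[k] <- sum(num * V[k, names(num)])
    den_v[k] <- sum(den * V[k, names(den)])
  }
  g <- function(lambda) min(num_v - lambda * den_v)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) < -1e-12) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

total_abs_flux <- function(flux) sum(abs(flux$flux))

carbon_of_exchange_mets <- function(model) {
  ex <- model$reactions$id[model$reactions$is_exchange]
  vapply(ex, function(r) {
    met <- names(model$stoichiometry[[r]])[1]
    i <- match(met, model$metabolites$id)
    nC <- element_count(model$metabolites$formula[i], "C")
    if (is.na(nC)) 0 else nC
  }, numeric(1))
}

# Net carbon crossing the boundary (positive = leaving), per unit time.
exchange_carbon_flux <- function(model, flux) {
  ex <- model$reactions$id[model$reactions$is_exchange]
  sum(carbon_of_exchange_mets(model) * flux$flux[ex])
}
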