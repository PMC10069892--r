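#' Solve a general linear program with the built-in simplex backend
#'
#' Minimizes (or maximizes) `obj' x` subject to equality constraints
#' `A_eq x = b_eq`, inequality constraints `A_ub x <= b_ub`, and variable
#' bounds `lb <= x <= ub`. The problem is canonicalized (finite lower bounds
#' shifted to zero, free variables split into positive and negative parts,
#' finite upper bounds and inequalities turned into slack rows) and handed to
#' a dense two-phase simplex with Bland's rule, which is deterministic and
#' cycling-safe.
#'
#' @param obj numeric objective vector (length n).
#' @param A_eq,b_eq equality constraints (matrix with n columns, may have 0 rows).
#' @param A_ub,b_ub inequality (`<=`) constraints.
#' @param lb,lbub numeric bounds; `-Inf`/`Inf` entries allowed.
#' @param ub upper bounds.
#' @param maximize if `TRUE` maximize instead of minimize.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iteration_limit"`), `x` (solution on the original variables) and
#'   `objective` (on the original sense).
#' @keywords internal
solve_lp <- function(obj, A_eq = NULL, b_eq = NULL, A_ub = NULL, b_ub = NULL,
                     lb = NULL, ub = NULL, maximize = FALSE) {
  n <- length(obj)
  if (is.null(lb)) lb <- rep(0, n)
  if (is.null(ub)) ub <- rep(Inf, n)
  if (is.null(A_eq)) { A_eq <- matrix(0, 0, n); b_eq <- numeric(0) }
  if (is.null(A_ub)) { A_ub <- matrix(0, 0, n); b_ub <- numeric(0) }
  A_eq <- matrix(A_eq, ncol = n)
  A_ub <- matrix(A_ub, ncol = n)
  stopifnot(length(lb) == n, length(ub) == n,
            nrow(A_eq) == length(b_eq), nrow(A_ub) == length(b_ub),
            all(lb <= ub))

  # Variable mapping: finite lb -> shift; lb = -Inf -> split x = xp - xn.
  free <- !is.finite(lb)
  n_pos <- n + sum(free)                 # columns before slacks
  map_pos <- seq_len(n)                  # column of the (shifted) positive part
  map_neg <- integer(n)                  # column of the negative part (0 = none)
  if (any(free)) map_neg[free] <- n + seq_len(sum(free))

  shift <- ifelse(is.finite(lb), lb, 0)

  expand <- function(A) {
    # rows of A on original vars -> rows on canonical columns
    if (nrow(A) == 0) return(matrix(0, 0, n_pos))
    out <- matrix(0, nrow(A), n_pos)
    out[, map_pos] <- A
    if (any(free)) out[, map_neg[free]] <- -A[, free, drop = FALSE]
    out
  }

  Aeq2 <- expand(A_eq)
  beq2 <- b_eq - as.vector(A_eq %*% shift)
  Aub2 <- expand(A_ub)
  bub2 <- b_ub - as.vector(A_ub %*% shift)

  # Finite upper bounds become inequality rows on the shifted variable.
  fin_ub <- which(is.finite(ub))
  if (length(fin_ub)) {
    rows <- matrix(0, length(fin_ub), n_pos)
    rhs <- numeric(length(fin_ub))
    for (k in seq_along(fin_ub)) {
      j <- fin_ub[k]
      rows[k, map_pos[j]] <- 1
      if (free[j]) rows[k, map_neg[j]] <- -1
      rhs[k] <- ub[j] - shift[j]
    }
    Aub2 <- rbind(Aub2, rows)
    bub2 <- c(bub2, rhs)
  }

  # Slack columns for inequalities.
  m_ub <- nrow(Aub2)
  ncol_tot <- n_pos + m_ub
  A <- matrix(0, nrow(Aeq2) + m_ub, ncol_tot)
  if (nrow(Aeq2)) A[seq_len(nrow(Aeq2)), seq_len(n_pos)] <- Aeq2
  if (m_ub) {
    A[nrow(Aeq2) + seq_len(m_ub), seq_len(n_pos)] <- Aub2
    A[cbind(nrow(Aeq2) + seq_len(m_ub), n_pos + seq_len(m_ub))] <- 1
  }
  b <- c(beq2, bub2)

  # Simplex wants b >= 0.
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }

  cc <- numeric(ncol_tot)
  sgn <- if (maximize) -1 else 1
  cc[map_pos] <- sgn * obj
  if (any(free)) cc[map_neg[free]] <- -sgn * obj[free]

  res <- .simplex_core(A, b, cc)
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "infeasible",
                   "2" = "unbounded", "3" = "iteration_limit")
  if (status != "optimal") {
    return(list(status = status, x = rep(NA_real_, n), objective = NA_real_))
  }
  xc <- as.numeric(res$x)
  x <- xc[map_pos] + shift
  if (any(free)) x[free] <- x[free] - xc[map_neg[free]]
  list(status = "optimal", x = x, objective = sum(obj * x))
}
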