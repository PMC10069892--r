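#' Growth-and-maintenance respiration coefficients
#'
#' @param gR growth respiration coefficient, mol CO2 per mol C.
#' @param mR maintenance respiration coefficient, mol CO2 per mol C per time.
#' @return a `growth_maintenance_params` object.
#' @export
growth_maintenance_params <- function(gR, mR) {
  stopifnot(gR >= 0, mR >= 0)
  structure(list(gR = gR, mR = mR), class = "growth_maintenance_params")
}

#' Growth-and-maintenance respiration rate
#'
#' The classical two-component model `R = R_G + R_M = gR dW/dt + mR W`, with
#' the growth and maintenance components reported separately.
#'
#' @param params a [growth_maintenance_params()].
#' @param dWdt growth rate, mol C per time.
#' @param W biomass, mol C (>= 0).
#' @return list with `R`, `RG`, `RM` (mol CO2 per time).
#' @export
respiration_eq1 <- function(params, dWdt, W) {
  stopifnot(all(W >= 0))
  RG <- params$gR * dWdt
  RM <- params$mR * W
  list(R = RG + RM, RG = RG, RM = RM)
}

#' General-paradigm respiration rate
#'
#' Respiration as the cost-weighted sum of process rates, `sum_r alpha_r
#' v_r`, with `alpha_r` the specific unit cost (mol CO2 per unit of process
#' rate) and `v_r` the rate of process r. Processes present in `costs` but
#' absent from `rates` contribute zero. Negative costs are permitted
#' (CO2-consuming processes) and flagged with a warning.
#'
#' @param costs named numeric: process id -> alpha_r.
#' @param rates named numeric: process id -> v_r; names must be a subset of
#'   `names(costs)`.
#' @return respiration rate R.
#' @export
respiration_general <- function(costs, rates) {
  stopifnot(!is.null(names(costs)))
  if (length(rates)) {
    unknown <- setdiff(names(rates), names(costs))
    if (length(unknown)) stop("rates without a unit cost: ",
                              paste(unknown, collapse = ", "))
  }
  if (any(costs < 0)) warning("negative unit cost(s): CO2-consuming process")
  if (!length(rates)) return(0)
  sum(costs[names(rates)] * rates)
}

#' Parameters of the nitrogen-carbon balanced-growth model
#'
#' Partitioning total nitrogen into protein nitrogen driving photosynthesis
#' and structurally bound nitrogen (`N = Np + gamma C`), with biomass
#' proportional to carbon (`W = k C`), yields a linear biomass ODE once the
#' growth yield `1/(1+gR)` and maintenance losses are accounted for.
#'
#' @param phiCN nitrogen-to-carbon conversion factor.
#' @param Np protein nitrogen pool.
#' @param gamma structural nitrogen per carbon.
#' @param k carbon-to-biomass proportionality (W = kC), > 0.
#' @param W0 initial biomass, mol C.
#' @return an `nc_growth_params` object.
#' @export
nc_growth_params <- function(phiCN, Np, gamma, k, W0) {
  if (any(c(phiCN, Np, gamma, W0) < 0) || k <= 0) {
    stop("parameters must be nonnegative and k > 0")
  }
  structure(list(phiCN = phiCN, Np = Np, gamma = gamma, k = k, W0 = W0),
            class = "nc_growth_params")
}

#' Simulate the nitrogen-carbon growth ODE
#'
#' Integrates `dW/dt = (phiCN Np k - phiCN gamma W - mR W) / (1 + gR)`,
#' i.e. the linear ODE `dW/dt = a - b W` with `a = phiCN Np k / (1 + gR)`
#' and `b = (phiCN gamma + mR) / (1 + gR)`, and reports the trajectory of
#' biomass, growth rate and the two-component respiration along it. A
#' classical fixed-step 4th-order Runge-Kutta scheme is used, with the step
#' halved until two successive refinements agree to 1e-10 relative; the
#' system is linear and stiffness-free, so nothing fancier is warranted,
#' but the closed form `W(t) = a/b + (W0 - a/b) exp(-b t)` (for b > 0) is
#' the validation oracle in the test suite.
#'
#' @param gm a [growth_maintenance_params()].
#' @param nc an [nc_growth_params()].
#' @param t_grid increasing time grid starting at 0.
#' @param time_unit label echoed in the output.
#' @return data.frame with columns `time`, `W`, `dWdt`, `R`, `RG`, `RM`;
#'   attributes `a`, `b`, `time_unit`.
#' @export
simulate_nc_growth <- function(gm, nc, t_grid, time_unit = "h") {
  stopifnot(length(t_grid) >= 2, t_grid[1] == 0, all(diff(t_grid) > 0))
  a <- nc$phiCN * nc$Np * nc$k / (1 + gm$gR)
  b <- (nc$phiCN * nc$gamma + gm$mR) / (1 + gm$gR)
  f <- function(W) a - b * W

  integrate_grid <- function(nsub) {
    W <- numeric(length(t_grid))
    W[1] <- nc$W0
    for (i in seq_len(length(t_grid) - 1)) {
      h <- (t_grid[i + 1] - t_grid[i]) / nsub
      w <- W[i]
      for (s in seq_len(nsub)) {
        k1 <- f(w)
        k2 <- f(w + h / 2 * k1)
        k3 <- f(w + h / 2 * k2)
        k4 <- f(w + h * k3)
        w <- w + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      W[i + 1] <- w
    }
    W
  }

  nsub <- 4
  W <- integrate_grid(nsub)
  repeat {
    nsub <- nsub * 2
    W2 <- integrate_grid(nsub)
    err <- max(abs(W2 - W) / pmax(abs(W2), 1e-12))
    W <- W2
    if (err < 1e-10 || nsub >= 1024) break
  }

  dWdt <- f(W)
  resp <- respiration_eq1(gm, dWdt, W)
  out <- data.frame(time = t_grid, W = W, dWdt = dWdt,
                    R = resp$R, RG = resp$RG, RM = resp$RM)
  attr(out, "a") <- a
  attr(out, "b") <- b
  attr(out, "time_unit") <- time_unit
  out
}

#' RuBisCO flux triple of the FvCB model
#'
#' @param Vc carboxylation rate; `Vo` oxygenation rate; `Rd` day respiration
#'   (all >= 0, mol CO2 per time or umol m^-2 s^-1 at leaf level).
#' @param Vo,Rd see above.
#' @return an `fvcb_fluxes` object.
#' @export
fvcb_fluxes <- function(Vc, Vo, Rd) {
  stopifnot(Vc >= 0, Vo >= 0, Rd >= 0)
  structure(list(Vc = Vc, Vo = Vo, Rd = Rd), class = "fvcb_fluxes")
}

#' Net CO2 assimilation of the FvCB model
#'
#' `A = Vc - 0.5 Vo - Rd`: gross carboxylation minus photorespiratory
#' release (half a CO2 per oxygenation) minus day respiration.
#'
#' @param f an [fvcb_fluxes()].
#' @return net assimilation A.
#' @export
fvcb_assimilation <- function(f) {
  f$Vc - 0.5 * f$Vo - f$Rd
}

#' Carbon use efficiency from FvCB fluxes
#'
#' `CUE = 1 - (0.5 Vo + Rd) / Vc`, the fraction of gross carboxylation
#' retained after photorespiratory and respiratory release; algebraically
#' equal to `A / Vc`. Undefined at `Vc = 0`.
#'
#' @param f an [fvcb_fluxes()].
#' @return CUE, a dimensionless value in (-Inf, 1].
#' @export
cue_from_fvcb <- function(f) {
  if (f$Vc <= 0) stop("CUE undefined: Vc = 0")
  1 - (0.5 * f$Vo + f$Rd) / f$Vc
}
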