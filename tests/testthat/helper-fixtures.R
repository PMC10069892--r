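# Micro stoichiometric fixtures, all small enough for exhaustive vertex
# enumeration. Formulas are carbon-consistent so carbon-conservation checks
# apply; cofactor pseudo-species carry no formula and are skipped in carbon
# accounting.

mk_mets <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r[[1]], name = r[[1]], compartment = r[[2]],
               formula = r[[3]], is_boundary = FALSE, stringsAsFactors = FALSE)
  }))
}

mk_model <- function(id, mets, rxns, objective, ecs = list()) {
  reactions <- do.call(rbind, lapply(rxns, function(r) {
    data.frame(id = r$id, name = r$id, lower_bound = r$lb,
               upper_bound = r$ub, stringsAsFactors = FALSE)
  }))
  stoich <- lapply(rxns, `[[`, "st")
  names(stoich) <- reactions$id
  metabolic_model(id = id, metabolites = mets, reactions = reactions,
                  stoichiometry = stoich, objective = objective,
                  ec_numbers = ecs)
}

rx <- function(id, st, lb = 0, ub = 1000) list(id = id, st = st, lb = lb, ub = ub)

# Linear chain: uptake -> conversion -> export. FBA optimum = 10.
fix_chain <- function(n_internal = 1) {
  mets <- mk_mets(list("A_c", "c", "C6H12O6"), list("B_c", "c", "C6H12O6"))
  rxns <- list(rx("EX_A", c(A_c = -1), lb = -10, ub = 0),
               rx("R1", c(A_c = -1, B_c = 1)),
               rx("EX_B", c(B_c = -1)))
  mk_model("chain", mets, rxns, c(EX_B = 1))
}

# Five-reaction linear chain with no redundancy (every knockout lethal).
fix_chain5 <- function() {
  mets <- mk_mets(list("A_c", "c", "C3H6O3"), list("B_c", "c", "C3H6O3"),
                  list("C_c", "c", "C3H6O3"), list("D_c", "c", "C3H6O3"))
  rxns <- list(rx("EX_A", c(A_c = -1), lb = -10, ub = 0),
               rx("R1", c(A_c = -1, B_c = 1)),
               rx("R2", c(B_c = -1, C_c = 1)),
               rx("R3", c(C_c = -1, D_c = 1)),
               rx("EX_D", c(D_c = -1)))
  mk_model("chain5", mets, rxns, c(EX_D = 1))
}

# Two routes with different yields; optimum uses the high-yield route only.
fix_branch <- function() {
  mets <- mk_mets(list("A_c", "c", "C2H4O2"), list("B_c", "c", "C2H4O2"))
  rxns <- list(rx("EX_A", c(A_c = -1), lb = -10, ub = 0),
               rx("GOOD", c(A_c = -1, B_c = 1)),
               rx("WASTE", c(A_c = -1, B_c = 0.5)),
               rx("EX_B", c(B_c = -1)))
  mk_model("branch", mets, rxns, c(EX_B = 1))
}

# Heterotroph (no RuBisCO): glucose-fed, ATP-limited growth with an obligate
# respiratory reaction. Optimum: pyr = 20, 2.5 r = 2 b, b + r = 20 =>
# b = 100/9.
fix_heterotroph <- function() {
  mets <- mk_mets(list("glc_c", "c", "C6H12O6"), list("pyr_c", "c", "C3H4O3"),
                  list("co2_c", "c", "CO2"), list("o2_c", "c", "O2"),
                  list("atp_c", "c", NA), list("biomass_c", "c", "C3H6O3"))
  rxns <- list(rx("EX_GLC", c(glc_c = -1), lb = -10, ub = 0),
               rx("GLYC", c(glc_c = -1, pyr_c = 2)),
               rx("RESP", c(pyr_c = -1, o2_c = -3, co2_c = 3, atp_c = 2.5)),
               rx("BIO", c(pyr_c = -1, atp_c = -2, biomass_c = 1)),
               rx("EX_BIO", c(biomass_c = -1)),
               rx("EX_CO2", c(co2_c = -1)),
               rx("EX_O2", c(o2_c = -1), lb = -1000, ub = 0))
  mk_model("heterotroph", mets, rxns, c(BIO = 1),
           ecs = list(RESP = "1.2.4.1"))
}

# Two conversion routes with different CO2 costs per unit product:
# R_CHEAP releases 2 CO2 per B, R_COSTLY releases 5 CO2 per 0.4 B
# (12.5 per B). Minimal CO2-per-biomass ratio uses R_CHEAP only.
fix_two_route <- function() {
  mets <- mk_mets(list("A_c", "c", "C7H14O7"), list("B_c", "c", "C5H10O5"),
                  list("co2_c", "c", "CO2"), list("biomass_c", "c", "C5H10O5"))
  rxns <- list(rx("EX_A", c(A_c = -1), lb = -10, ub = 0),
               rx("R_CHEAP", c(A_c = -1, B_c = 1, co2_c = 2), ub = 4),
               rx("R_COSTLY", c(A_c = -1, B_c = 0.4, co2_c = 5)),
               rx("BIO", c(B_c = -1, biomass_c = 1)),
               rx("EX_BIO", c(biomass_c = -1)),
               rx("EX_CO2", c(co2_c = -1)))
  mk_model("two_route", mets, rxns, c(BIO = 1))
}

# Carbonic anhydrase: CO2 hydration removes one CO2 per unit forward flux.
fix_carbonic_anhydrase <- function() {
  mets <- mk_mets(list("co2_c", "c", "CO2"), list("hco3_c", "c", "CHO3"),
                  list("h2o_c", "c", "H2O"), list("h_c", "c", "H"))
  rxns <- list(rx("EX_CO2", c(co2_c = -1), lb = -10),
               rx("CA", c(co2_c = -1, h2o_c = -1, hco3_c = 1, h_c = 1),
                  lb = -1000),
               rx("EX_HCO3", c(hco3_c = -1)),
               rx("EX_H2O", c(h2o_c = -1), lb = -1000),
               rx("EX_H", c(h_c = -1)))
  mk_model("ca_model", mets, rxns, c(EX_HCO3 = 1), ecs = list(CA = "4.2.1.1"))
}

# Pure CO2 translocation reaction (transport exclusion check).
fix_co2_translocation <- function() {
  mets <- rbind(mk_mets(list("co2_c", "c", "CO2")),
                mk_mets(list("co2_m", "m", "CO2")))
  rxns <- list(rx("EX_CO2", c(co2_c = -1), lb = -10),
               rx("T_CO2", c(co2_c = -1, co2_m = 1), lb = -1000),
               rx("SINK", c(co2_m = -1, co2_c = 1), lb = -1000))
  mk_model("translocation", mets, rxns, c(T_CO2 = 1))
}

toy_day <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_toyplant(toy_model_spec())
    cache
  }
})

toy_night <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_toyplant(toy_model_spec(night = TRUE))
    cache
  }
})
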