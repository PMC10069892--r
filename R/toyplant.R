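#' Specification of the toy photoautotroph model
#'
#' The generated model ("toyplant") is a miniature compartmentalized C3
#' photoautotroph: chloroplast (RuBisCO carboxylation/oxygenation, lumped
#' Calvin-Benson cycle, thylakoid light reactions with cyclic electron flow,
#' oxidative pentose-phosphate decarboxylation by 6-phosphogluconate
#' dehydrogenase, NADP-malic enzyme, starch mobilization, serine synthesis),
#' peroxisome (glycolate oxidase, aminotransferases, hydroxypyruvate
#' reductase fed by a malate/oxaloacetate redox shuttle), mitochondrion
#' (glycine decarboxylase closing photorespiration, pyruvate dehydrogenase,
#' TCA decarboxylations, oxidative phosphorylation plus alternative oxidase
#' and external NADH dehydrogenase), and cytosol (lower glycolysis,
#' ATP-consuming maintenance). Every internal reaction is elementally
#' balanced for C, H, O, N and P; water and protons close each reaction
#' automatically. Under the day parameterization the flux optimum is known
#' in closed form: 62 photons per unit of biomass flux.
#'
#' @param photon_bound maximum photon uptake, mmol gDW^-1 h^-1 (day model).
#' @param starch_bound maximum starch mobilization (night model).
#' @param include_futile_loop add a 2-reaction zero-net-stoichiometry loop.
#' @param night parameterize for night (photon uptake closed, starch open).
#' @param seed integer seed used by [generate_random_variant()] for bound
#'   jitter and sampled bypass reactions.
#' @return a `toy_model_spec` object.
#' @export
toy_model_spec <- function(photon_bound = 100, starch_bound = 1.2,
                           include_futile_loop = FALSE, night = FALSE,
                           seed = 1L) {
  stopifnot(photon_bound >= 0, starch_bound >= 0)
  structure(list(compartments = c(cytosol = "c", chloroplast = "h",
                                  mitochondrion = "m", peroxisome = "x"),
                 photon_bound = photon_bound, starch_bound = starch_bound,
                 include_futile_loop = include_futile_loop, night = night,
                 seed = as.integer(seed)),
            class = "toy_model_spec")
}

# Bookkeeping formulas: neutral forms chosen so every cofactor couple differs
# by a consistent moiety (ATP = ADP + HPO3, NAD(P)H = NAD(P) + H), which
# makes full elemental balancing possible without tracking charges.
toy_metabolites <- function() {
  m <- function(id, name, comp, formula) {
    data.frame(id = id, name = name, compartment = comp, formula = formula,
               is_boundary = FALSE, stringsAsFactors = FALSE)
  }
  rbind(
    # pooled small species (single pool, see vignette on toy simplifications)
    m("co2_c", "carbon dioxide", "c", "CO2"),
    m("o2_c", "oxygen", "c", "O2"),
    m("h2o_c", "water", "c", "H2O"),
    m("h_c", "proton", "c", "H"),
    m("pi_c", "orthophosphate", "c", "H3O4P"),
    m("nh3_c", "ammonia", "c", "H3N"),
    m("gap_c", "glyceraldehyde 3-phosphate", "c", "C3H7O6P"),
    m("pga_c", "3-phosphoglycerate", "c", "C3H7O7P"),
    m("pyr_c", "pyruvate", "c", "C3H4O3"),
    m("atp_c", "ATP", "c", "C10H16N5O13P3"),
    m("adp_c", "ADP", "c", "C10H15N5O10P2"),
    m("nad_c", "NAD", "c", "C21H27N7O14P2"),
    m("nadh_c", "NADH", "c", "C21H28N7O14P2"),
    # chloroplast
    m("photon_h", "photon", "h", NA),
    m("co2_h", "carbon dioxide", "h", "CO2"),
    m("rubp_h", "ribulose 1,5-bisphosphate", "h", "C5H12O11P2"),
    m("pga_h", "3-phosphoglycerate", "h", "C3H7O7P"),
    m("gap_h", "glyceraldehyde 3-phosphate", "h", "C3H7O6P"),
    m("g6p_h", "glucose 6-phosphate", "h", "C6H13O9P"),
    m("ru5p_h", "ribulose 5-phosphate", "h", "C5H11O8P"),
    m("p6g_h", "6-phosphogluconate", "h", "C6H13O10P"),
    m("starch_h", "starch (glucosyl unit)", "h", "C6H10O5"),
    m("pglyc_h", "2-phosphoglycolate", "h", "C2H5O6P"),
    m("glyclt_h", "glycolate", "h", "C2H4O3"),
    m("glyc_h", "glycerate", "h", "C3H6O4"),
    m("ser_h", "serine", "h", "C3H7NO3"),
    m("mal_h", "malate", "h", "C4H6O5"),
    m("pyr_h", "pyruvate", "h", "C3H4O3"),
    m("nh3_h", "ammonia", "h", "H3N"),
    m("atp_h", "ATP", "h", "C10H16N5O13P3"),
    m("adp_h", "ADP", "h", "C10H15N5O10P2"),
    m("nadp_h", "NADP", "h", "C21H28N7O17P3"),
    m("nadph_h", "NADPH", "h", "C21H29N7O17P3"),
    m("biomass_h", "biomass", "h", "C6H11NO4"),
    # mitochondrion
    m("co2_m", "carbon dioxide", "m", "CO2"),
    m("pyr_m", "pyruvate", "m", "C3H4O3"),
    m("ac_m", "acetyl unit", "m", "C2H4O2"),
    m("oaa_m", "oxaloacetate", "m", "C4H4O5"),
    m("cit_m", "citrate", "m", "C6H8O7"),
    m("akg_m", "2-oxoglutarate", "m", "C5H6O5"),
    m("succ_m", "succinate", "m", "C4H6O4"),
    m("mal_m", "malate", "m", "C4H6O5"),
    m("gly_m", "glycine", "m", "C2H5NO2"),
    m("ser_m", "serine", "m", "C3H7NO3"),
    m("nh3_m", "ammonia", "m", "H3N"),
    m("atp_m", "ATP", "m", "C10H16N5O13P3"),
    m("adp_m", "ADP", "m", "C10H15N5O10P2"),
    m("nad_m", "NAD", "m", "C21H27N7O14P2"),
    m("nadh_m", "NADH", "m", "C21H28N7O14P2"),
    m("nadp_m", "NADP", "m", "C21H28N7O17P3"),
    m("nadph_m", "NADPH", "m", "C21H29N7O17P3"),
    # peroxisome
    m("nh3_x", "ammonia", "x", "H3N"),
    m("glyclt_x", "glycolate", "x", "C2H4O3"),
    m("glx_x", "glyoxylate", "x", "C2H2O3"),
    m("gly_x", "glycine", "x", "C2H5NO2"),
    m("ser_x", "serine", "x", "C3H7NO3"),
    m("hpyr_x", "hydroxypyruvate", "x", "C3H4O4"),
    m("glyc_x", "glycerate", "x", "C3H6O4"),
    m("mal_x", "malate", "x", "C4H6O5"),
    m("oaa_x", "oxaloacetate", "x", "C4H4O5"),
    m("nad_x", "NAD", "x", "C21H27N7O14P2"),
    m("nadh_x", "NADH", "x", "C21H28N7O14P2"))
}

# Close H and O balance of a draft stoichiometry by adjoining water and
# protons from the pooled species; C, N and P must already balance by design.
balance_reaction <- function(st, counts, rxn_id) {
  net <- function(el) {
    tot <- 0
    for (s in names(st)) {
      cnt <- counts[[s]]
      if (is.null(cnt)) next  # species without formula (photon)
      v <- cnt[el]
      if (!is.na(v)) tot <- tot + st[s] * v
    }
    tot
  }
  for (el in c("C", "N", "P")) {
    if (abs(net(el)) > 1e-9) {
      stop("generator bug: ", el, " imbalance in ", rxn_id, ": ", net(el))
    }
  }
  dO <- net("O")
  if (abs(dO) > 1e-9) {
    st["h2o_c"] <- (if ("h2o_c" %in% names(st)) st[["h2o_c"]] else 0) - dO
  }
  dH <- net("H")
  if (abs(dH) > 1e-9) {
    st["h_c"] <- (if ("h_c" %in% names(st)) st[["h_c"]] else 0) - dH
  }
  st <- st[abs(st) > 1e-12]
  st
}

toy_reactions <- function(spec) {
  r <- list()
  add <- function(id, name, st, lb = 0, ub = 1000, ec = character(0),
                  balance = TRUE) {
    r[[length(r) + 1]] <<- list(id = id, name = name, st = st, lb = lb,
                                ub = ub, ec = ec, balance = balance)
  }
  # --- chloroplast ---
  add("LIGHT", "thylakoid light reactions (linear electron flow)",
      c(photon_h = -8, nadp_h = -2, adp_h = -2, pi_c = -2,
        nadph_h = 2, atp_h = 2, o2_c = 1))
  add("CEF", "cyclic electron flow (ATP only)",
      c(photon_h = -2, adp_h = -1, pi_c = -1, atp_h = 1))
  add("RBC_C", "RuBisCO carboxylase",
      c(rubp_h = -1, co2_h = -1, pga_h = 2), ec = "4.1.1.39")
  add("RBC_O", "RuBisCO oxygenase",
      c(rubp_h = -1, o2_c = -1, pga_h = 1, pglyc_h = 1), ec = "4.1.1.39")
  add("PGA_RED", "phosphoglycerate reduction (lumped PGK + GAPDH)",
      c(pga_h = -1, atp_h = -1, nadph_h = -1,
        gap_h = 1, adp_h = 1, pi_c = 1, nadp_h = 1))
  add("RUBP_REG", "RuBP regeneration (lumped C3->C5 + kinase)",
      c(gap_h = -5, atp_h = -3, rubp_h = 3, adp_h = 3, pi_c = 2))
  add("PRK", "phosphoribulokinase",
      c(ru5p_h = -1, atp_h = -1, rubp_h = 1, adp_h = 1), ec = "2.7.1.19")
  add("SERSYN", "serine synthesis (lumped phosphorylated pathway)",
      c(pga_h = -1, nh3_h = -1, ser_h = 1, pi_c = 1), ec = "2.6.1.52")
  add("G6PDH", "glucose-6-phosphate dehydrogenase",
      c(g6p_h = -1, nadp_h = -1, p6g_h = 1, nadph_h = 1), ec = "1.1.1.49")
  add("PGD", "6-phosphogluconate dehydrogenase (NADP, chloroplastic)",
      c(p6g_h = -1, nadp_h = -1, ru5p_h = 1, co2_h = 1, nadph_h = 1),
      ec = "1.1.1.44")
  add("PPP_NONOX", "non-oxidative pentose phosphate rearrangement",
      c(ru5p_h = -6, g6p_h = 5, pi_c = 1), lb = -1000)
  add("STARCH_DEG", "starch phosphorolysis",
      c(starch_h = -1, pi_c = -1, g6p_h = 1), ec = "2.4.1.1")
  add("GLYC_UP", "plastidic upper glycolysis (lumped PFK + aldolase + TPI)",
      c(g6p_h = -1, atp_h = -1, gap_h = 2, adp_h = 1))
  add("ME", "NADP-malic enzyme (chloroplastic)",
      c(mal_h = -1, nadp_h = -1, pyr_h = 1, co2_h = 1, nadph_h = 1),
      ec = "1.1.1.40")
  add("PGP_PHOS", "phosphoglycolate phosphatase",
      c(pglyc_h = -1, glyclt_h = 1, pi_c = 1), ec = "3.1.3.18")
  add("GLYK", "glycerate kinase",
      c(glyc_h = -1, atp_h = -1, pga_h = 1, adp_h = 1), ec = "2.7.1.31")
  add("BIOMASS", "biomass synthesis",
      c(gap_h = -1, ser_h = -1, atp_h = -2, nadph_h = -1,
        biomass_h = 1, adp_h = 2, pi_c = 3, nadp_h = 1))
  # --- peroxisome ---
  add("GOX", "glycolate oxidase (+ catalase)",
      c(glyclt_x = -1, o2_c = -0.5, glx_x = 1), ec = "1.1.3.15")
  add("GGAT", "glyoxylate amination (lumped GGAT + GS/GOGAT)",
      c(glx_x = -1, nh3_x = -1, nadh_x = -1, gly_x = 1, nad_x = 1),
      ec = "2.6.1.4")
  add("SGAT", "serine:glyoxylate aminotransferase",
      c(ser_x = -1, glx_x = -1, gly_x = 1, hpyr_x = 1), ec = "2.6.1.45")
  add("HPR", "hydroxypyruvate reductase",
      c(hpyr_x = -1, nadh_x = -1, glyc_x = 1, nad_x = 1), ec = "1.1.1.29")
  add("MDH_X", "peroxisomal malate dehydrogenase",
      c(mal_x = -1, nad_x = -1, oaa_x = 1, nadh_x = 1), ec = "1.1.1.37")
  # --- mitochondrion ---
  add("GDC", "glycine decarboxylase (+ SHMT)",
      c(gly_m = -2, nad_m = -1, ser_m = 1, co2_m = 1, nh3_m = 1, nadh_m = 1),
      ec = "1.4.4.2")
  add("PDH", "pyruvate dehydrogenase complex",
      c(pyr_m = -1, nad_m = -1, ac_m = 1, co2_m = 1, nadh_m = 1),
      ec = "1.2.4.1")
  add("CS", "citrate synthase (+ aconitase)",
      c(ac_m = -1, oaa_m = -1, cit_m = 1), ec = "2.3.3.1")
  add("IDH", "isocitrate dehydrogenase (NADP)",
      c(cit_m = -1, nadp_m = -1, akg_m = 1, co2_m = 1, nadph_m = 1),
      ec = "1.1.1.42")
  add("OGDH", "2-oxoglutarate dehydrogenase complex",
      c(akg_m = -1, nad_m = -1, succ_m = 1, co2_m = 1, nadh_m = 1),
      ec = "1.2.4.2")
  add("TCA_LOW", "lower TCA cycle (lumped SDH + fumarase + MDH)",
      c(succ_m = -1, nad_m = -2, oaa_m = 1, nadh_m = 2))
  add("MDH_M", "mitochondrial malate dehydrogenase",
      c(oaa_m = -1, nadh_m = -1, mal_m = 1, nad_m = 1), lb = -1000,
      ec = "1.1.1.37")
  add("NNT", "transhydrogenase (NADPH -> NADH)",
      c(nadph_m = -1, nad_m = -1, nadp_m = 1, nadh_m = 1), ec = "7.1.1.1")
  # P/O of 2.0 keeps dark respiration strictly less photon-efficient than
  # cyclic electron flow for ATP supply in the light, so the day optimum
  # cannot profit from a carbon burn-and-refix loop.
  add("OXPHOS", "oxidative phosphorylation (complex I route, P/O 2.0)",
      c(nadh_m = -1, o2_c = -0.5, adp_m = -2, pi_c = -2,
        nad_m = 1, atp_m = 2), ec = "7.1.1.2")
  add("AOX", "alternative oxidase (uncoupled)",
      c(nadh_m = -1, o2_c = -0.5, nad_m = 1), ec = "1.10.3.11")
  # P/O of 1.0 keeps the triose-phosphate shuttle + external dehydrogenase
  # round trip exactly cost-neutral against cyclic electron flow, so the day
  # optimum stays at the closed-form 62 photons per biomass (ties resolved
  # by pFBA toward zero shuttle flux).
  add("NDB", "external NADH dehydrogenase (cytosolic NADH, P/O 1.0)",
      c(nadh_c = -1, o2_c = -0.5, adp_m = -1, pi_c = -1,
        nad_c = 1, atp_m = 1), ec = "1.6.5.9")
  # --- cytosol ---
  add("GAPDH_C", "cytosolic GAPDH + PGK",
      c(gap_c = -1, nad_c = -1, adp_c = -1, pi_c = -1,
        pga_c = 1, nadh_c = 1, atp_c = 1), lb = -1000, ec = "1.2.1.12")
  add("PK", "pyruvate kinase (lumped enolase + PK)",
      c(pga_c = -1, adp_c = -1, pyr_c = 1, atp_c = 1), ec = "2.7.1.40")
  add("NGAM", "maintenance ATP hydrolysis",
      c(atp_c = -1, adp_c = 1, pi_c = 1))
  # --- transporters (reversible unless stated) ---
  tr <- function(id, from, to, name = NULL) {
    add(id, if (is.null(name)) paste0(from, " <-> ", to, " transport") else name,
        stats::setNames(c(-1, 1), c(from, to)), lb = -1000, balance = FALSE)
  }
  tr("T_CO2_HC", "co2_h", "co2_c", "chloroplast CO2 translocation")
  tr("T_CO2_MC", "co2_m", "co2_c", "mitochondrial CO2 translocation")
  tr("T_PGA_HC", "pga_h", "pga_c")
  tr("T_GAP_HC", "gap_h", "gap_c")
  tr("T_PYR_HC", "pyr_h", "pyr_c")
  tr("T_PYR_CM", "pyr_c", "pyr_m")
  tr("T_GLYCLT_HX", "glyclt_h", "glyclt_x")
  tr("T_GLY_XM", "gly_x", "gly_m")
  tr("T_SER_MX", "ser_m", "ser_x")
  tr("T_SER_HM", "ser_h", "ser_m")
  tr("T_GLYC_XH", "glyc_x", "glyc_h")
  tr("T_MAL_MH", "mal_m", "mal_h")
  tr("T_MAL_MX", "mal_m", "mal_x")
  tr("T_OAA_XM", "oaa_x", "oaa_m")
  tr("T_NH3_CH", "nh3_c", "nh3_h")
  tr("T_NH3_MX", "nh3_m", "nh3_x")
  tr("T_NH3_MC", "nh3_m", "nh3_c")  # photorespiratory ammonia recycling
  add("AAC_M", "mitochondrial ADP/ATP carrier",
      c(atp_m = -1, adp_c = -1, atp_c = 1, adp_m = 1), lb = -1000,
      balance = FALSE)
  add("AAC_H", "chloroplast ADP/ATP carrier",
      c(atp_c = -1, adp_h = -1, atp_h = 1, adp_c = 1), lb = -1000,
      balance = FALSE)
  # --- exchanges (negative flux = import, positive = export) ---
  exch <- function(id, met, lb, ub) {
    add(id, paste0(met, " exchange"), stats::setNames(-1, met), lb = lb,
        ub = ub, balance = FALSE)
  }
  exch("EX_CO2", "co2_c", -1000, 1000)
  exch("EX_O2", "o2_c", -1000, 1000)
  exch("EX_H2O", "h2o_c", -1000, 1000)
  exch("EX_H", "h_c", -1000, 1000)
  exch("EX_PI", "pi_c", -1000, 1000)
  exch("EX_NH3", "nh3_c", -1000, 1000)
  exch("EX_PHOTON", "photon_h",
       if (spec$night) 0 else -spec$photon_bound, 0)
  exch("EX_STARCH", "starch_h",
       if (spec$night) -spec$starch_bound else 0, 0)
  exch("EX_BIOMASS", "biomass_h", 0, 1000)
  if (spec$include_futile_loop) {
    add("FUTILE_A", "futile cycle half A", c(pyr_c = -1, pyr_m = 1),
        balance = FALSE)
    add("FUTILE_B", "futile cycle half B", c(pyr_m = -1, pyr_c = 1),
        balance = FALSE)
  }
  r
}

#' Generate the toy photoautotroph model with recorded ground truth
#'
#' See [toy_model_spec()] for the biology. The returned ground truth records
#' the hand-derived day FBA optimum (photon_bound / 62: per unit biomass the
#' designed pathway needs Vc = 6 carboxylations, 12 NADPH and 19 ATP, i.e.
#' 6 runs of the light reactions plus 7 turns of cyclic electron flow, 62
#' photons in total), the expected CO2 producer/consumer classification of
#' every CO2-touching reaction, the biomass carbon content (6 mol C per unit
#' biomass flux), and the expected dominant CO2 producers by daytime
#' (glycine decarboxylase, forced by the photorespiratory flux under the
#' oxygenation:carboxylation ratio constraint) and night (chloroplastic
#' 6-phosphogluconate dehydrogenase, the only dark NADPH source for the
#' chloroplast).
#'
#' @param spec a [toy_model_spec()].
#' @return list with elements `model` (a `metabolic_model`) and
#'   `ground_truth`.
#' @export
generate_toyplant <- function(spec = toy_model_spec()) {
  mets <- toy_metabolites()
  counts <- lapply(mets$formula, parse_formula)
  names(counts) <- mets$id

  drafts <- toy_reactions(spec)
  stoich <- list()
  rxn_rows <- list()
  ecs <- list()
  for (d in drafts) {
    st <- d$st
    if (d$balance) st <- balance_reaction(st, counts, d$id)
    stoich[[d$id]] <- st
    ecs[[d$id]] <- d$ec
    rxn_rows[[d$id]] <- data.frame(id = d$id, name = d$name,
                                   lower_bound = d$lb, upper_bound = d$ub,
                                   stringsAsFactors = FALSE)
  }
  reactions <- do.call(rbind, rxn_rows)
  rownames(reactions) <- NULL

  model <- metabolic_model(
    id = if (spec$night) "toyplant-v1-night" else "toyplant-v1",
    metabolites = mets, reactions = reactions, stoichiometry = stoich,
    objective = c(BIOMASS = 1), ec_numbers = ecs)

  producer_labels <- c(
    PGD = "producer", ME = "producer", GDC = "producer", PDH = "producer",
    IDH = "producer", OGDH = "producer",
    RBC_C = "consumer",
    T_CO2_HC = "excluded", T_CO2_MC = "excluded", EX_CO2 = "excluded")

  ground_truth <- list(
    optimal_growth = if (spec$night) NA_real_ else spec$photon_bound / 62,
    photons_per_biomass = 62,
    producer_labels = producer_labels,
    biomass_carbon = 6,
    dominant_day_producer = "GDC",
    dominant_night_producer = "PGD",
    rubisco = rubisco_constraint("RBC_C", "RBC_O"))

  list(model = model, ground_truth = ground_truth)
}

#' Randomized toy-model variant with labelled bypass reactions
#'
#' Adds `n_extra_reactions` carbon-balanced decarboxylating (or neutral)
#' bypass reactions `A -> B + k CO2` sampled among nitrogen- and
#' phosphorus-free carbon metabolites of the base model, water/proton
#' balanced like every internal reaction. Each added reaction carries a
#' ground-truth CO2 label derived from its sampled stoichiometry, so the
#' inventory classifier can be property-tested at scale. Sampling is fully
#' determined by `seed`.
#'
#' @param spec a [toy_model_spec()].
#' @param n_extra_reactions number of bypasses to add.
#' @param seed integer seed.
#' @return list with `model` and `ground_truth` (including `extra_labels`).
#' @export
generate_random_variant <- function(spec = toy_model_spec(),
                                    n_extra_reactions = 10, seed = spec$seed) {
  base <- generate_toyplant(spec)
  model <- base$model
  if (n_extra_reactions == 0) return(base)

  # nitrogen- and phosphorus-free carbon metabolites only, so a 1:1 bypass
  # plus CO2 release can always be closed with water and protons
  pool <- c("pyr_c", "pyr_h", "pyr_m", "ac_m", "oaa_m", "cit_m", "akg_m",
            "succ_m", "mal_m", "mal_h", "mal_x", "glyclt_h", "glyclt_x",
            "glx_x", "hpyr_x", "glyc_h", "glyc_x", "starch_h")
  counts <- lapply(model$metabolites$formula, parse_formula)
  names(counts) <- model$metabolites$id
  ncarbon <- vapply(pool, function(s) unname(counts[[s]]["C"]), numeric(1))
  comp_of <- stats::setNames(model$metabolites$compartment,
                             model$metabolites$id)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  labels <- character(0)
  for (i in seq_len(n_extra_reactions)) {
    repeat {
      ab <- sample(pool, 2)
      if (ncarbon[ab[1]] >= ncarbon[ab[2]]) break
    }
    a <- ab[1]; b <- ab[2]
    k <- ncarbon[a] - ncarbon[b]
    st <- stats::setNames(c(-1, 1), c(a, b))
    if (k > 0) {
      co2_id <- switch(comp_of[a], h = "co2_h", m = "co2_m", "co2_c")
      st[co2_id] <- k
    }
    st <- balance_reaction(st, counts, paste0("RND", i))
    rid <- sprintf("RND%02d", i)
    model$stoichiometry[[rid]] <- st
    model$reactions <- rbind(model$reactions,
                             data.frame(id = rid,
                                        name = sprintf("random bypass %d: %s -> %s", i, a, b),
                                        lower_bound = 0, upper_bound = 1000,
                                        is_exchange = FALSE,
                                        is_transport = FALSE,
                                        stringsAsFactors = FALSE))
    model$ec_numbers[[rid]] <- character(0)
    labels[rid] <- if (k > 0) "producer" else "zero"
  }
  model$id <- paste0(model$id, "-rnd", seed)
  model <- annotate_reaction_roles(model)
  validate_model(model)
  gt <- base$ground_truth
  gt$extra_labels <- labels
  list(model = model, ground_truth = gt)
}
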