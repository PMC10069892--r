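test_that("toy inventory reproduces the generator's ground-truth labels", {
  tp <- toy_day()
  inv <- build_inventory(tp$model)
  expect_setequal(inv$co2_species, c("co2_c", "co2_h", "co2_m"))
  labels <- tp$ground_truth$producer_labels
  expect_setequal(inv$producers_forward, names(labels)[labels == "producer"])
  expect_setequal(inv$consumers_forward, names(labels)[labels == "consumer"])
  expect_setequal(names(inv$excluded), names(labels)[labels == "excluded"])
  expect_equal(unname(inv$excluded[c("T_CO2_HC", "T_CO2_MC")]),
               c("transport", "transport"))
  expect_equal(unname(inv$excluded["EX_CO2"]), "exchange")
  # partition: producers, consumers and excluded are disjoint
  expect_length(intersect(inv$producers_forward, inv$consumers_forward), 0)
  expect_length(intersect(names(inv$excluded),
                          c(inv$producers_forward, inv$consumers_forward)), 0)
})

test_that("random variants keep the classification oracle exact", {
  for (seed in c(7, 23)) {
    v <- generate_random_variant(n_extra_reactions = 50, seed = seed)
    inv <- build_inventory(v$model)
    for (rid in names(v$ground_truth$extra_labels)) {
      lab <- v$ground_truth$extra_labels[[rid]]
      if (lab == "producer") {
        expect_true(rid %in% inv$producers_forward, label = rid)
      } else {
        expect_false(rid %in% c(inv$producers_forward, inv$consumers_forward),
                     label = rid)
      }
    }
  }
})

test_that("pure CO2 translocation is excluded as transport", {
  m <- fix_co2_translocation()
  inv <- build_inventory(m)
  expect_equal(unname(inv$excluded["T_CO2"]), "transport")
  expect_equal(unname(inv$excluded["SINK"]), "transport")
  expect_length(inv$producers_forward, 0)
})

test_that("carbonic anhydrase counts as a CO2 consumer unless bicarbonate is ignored", {
  m <- fix_carbonic_anhydrase()
  inv <- build_inventory(m)
  expect_true("CA" %in% inv$consumers_forward)
  inv2 <- build_inventory(m, ignore_bicarbonate = TRUE)
  expect_equal(unname(inv2$excluded["CA"]), "bicarbonate-only")
  expect_false("CA" %in% inv2$consumers_forward)
})

test_that("a model without CO2 errors out of the inventory", {
  expect_error(build_inventory(fix_chain()), "lacks CO2")
})

test_that("the CO2-producing EC set carries the expected plant decarboxylases", {
  tp <- toy_day()
  inv <- build_inventory(tp$model)
  ecs <- co2_ec_set(tp$model, inv)
  expect_true(all(c("1.4.4.2", "1.1.1.42", "1.1.1.44", "1.1.1.40") %in% ecs))
  # consumers contribute nothing: RuBisCO's EC must be absent
  expect_false("4.1.1.39" %in% ecs)
  # isozymes with the same EC appear once (set semantics)
  m <- fix_heterotroph()
  m$stoichiometry$RESP2 <- m$stoichiometry$RESP
  m$reactions <- rbind(m$reactions,
                       data.frame(id = "RESP2", name = "RESP2",
                                  lower_bound = 0, upper_bound = 1000,
                                  is_exchange = FALSE, is_transport = FALSE))
  m$ec_numbers$RESP2 <- "1.2.4.1"
  m <- validate_model(m)
  inv2 <- build_inventory(m)
  expect_equal(sum(co2_ec_set(m, inv2) == "1.2.4.1"), 1)
  # producers lacking EC annotations give an empty set
  m$ec_numbers$RESP <- character(0)
  m$ec_numbers$RESP2 <- character(0)
  expect_length(co2_ec_set(m, build_inventory(m)), 0)
})

test_that("Jaccard comparison behaves as a set similarity with coverage", {
  sets <- list(a = c("1.1.1.40", "1.1.1.42"),
               b = c("1.1.1.42"),
               c = c("9.9.9.9"),
               d = c("1.1.1.40", "1.1.1.42"))
  cmp <- jaccard_compare(sets, reference = c("1.1.1.40", "1.1.1.42",
                                             "1.1.1.44", "1.4.4.2"))
  J <- cmp$jaccard
  expect_equal(unname(J["a", "d"]), 1)        # identical sets
  expect_equal(unname(J["a", "c"]), 0)        # disjoint nonempty sets
  expect_equal(unname(J["a", "b"]), 0.5)      # 1 shared of 2 in the union
  expect_true(isSymmetric(J))
  expect_equal(unname(diag(J)), rep(1, 4))
  expect_equal(unname(cmp$coverage), c(0.5, 0.25, 0, 0.5))

  # permuting the model order permutes rows/columns consistently
  cmp2 <- jaccard_compare(sets[c("c", "a", "d", "b")])
  expect_equal(cmp2$jaccard[c("a", "b", "c", "d"), c("a", "b", "c", "d")],
               J)

  # both-empty sets compare as equal; empty reference warns
  expect_equal(unname(jaccard_compare(list(x = character(0),
                                           y = character(0)))$jaccard["x", "y"]),
               1)
  expect_warning(jaccard_compare(sets, reference = character(0)),
                 "empty reference")
  expect_error(jaccard_compare(sets["a"]), "at least 2")
})

test_that("adding a CO2-free reaction changes neither inventory nor Jaccard", {
  tp <- toy_day()
  m <- tp$model
  inv0 <- build_inventory(m)
  m$stoichiometry$DUMMY <- c(pga_c = -1, pga_h = 1)
  m$reactions <- rbind(m$reactions,
                       data.frame(id = "DUMMY", name = "extra shuttle",
                                  lower_bound = -1000, upper_bound = 1000,
                                  is_exchange = FALSE, is_transport = TRUE))
  m <- validate_model(m)
  inv1 <- build_inventory(m)
  expect_setequal(inv1$producers_forward, inv0$producers_forward)
  expect_setequal(inv1$consumers_forward, inv0$consumers_forward)
  e0 <- co2_ec_set(tp$model, inv0)
  e1 <- co2_ec_set(m, inv1)
  expect_setequal(e1, e0)
})

test_that("the shipped reference EC list reads and covers the toy producers", {
  path <- system.file("extdata", "co2_producing_ecs.txt",
                      package = "respitraits")
  ref <- read_ec_list(path)
  expect_gt(length(ref), 5)
  expect_true(all(grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.([0-9]+|-)$", ref)))
  tp <- toy_day()
  ecs <- co2_ec_set(tp$model, build_inventory(tp$model))
  cmp <- jaccard_compare(list(toy = ecs, ref_only = ref), reference = ref)
  expect_gt(cmp$coverage[["toy"]], 0.3)
})
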