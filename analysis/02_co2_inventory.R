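#!/usr/bin/env Rscript
# Classify CO2-producing and -consuming reactions in each model and compare
# the CO2-producing EC-number sets across models (Jaccard similarity and
# coverage of a reference list of plant decarboxylases).
# Outputs: results/inventory_<model>.tsv, results/jaccard.tsv,
#          results/ec_coverage.tsv

library(respitraits)
dir.create("results", showWarnings = FALSE)

models <- list(
  generate_toyplant(toy_model_spec())$model,
  generate_toyplant(toy_model_spec(night = TRUE))$model,
  generate_random_variant(n_extra_reactions = 20, seed = 7)$model)

ec_sets <- list()
for (m in models) {
  inv <- build_inventory(m)
  report <- data.frame(
    reaction = names(inv$net_co2),
    net_co2 = unname(inv$net_co2),
    class = ifelse(names(inv$net_co2) %in% inv$producers_forward, "producer",
            ifelse(names(inv$net_co2) %in% inv$consumers_forward, "consumer",
            ifelse(names(inv$net_co2) %in% names(inv$excluded),
                   paste0("excluded:",
                          inv$excluded[names(inv$net_co2)]), "none"))))
  report <- report[report$class != "none", ]
  write.table(report, sprintf("results/inventory_%s.tsv", m$id), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ec_sets[[m$id]] <- co2_ec_set(m, inv)
  message(sprintf("%s: %d producers, %d consumers, %d excluded; ECs: %s",
                  m$id, length(inv$producers_forward),
                  length(inv$consumers_forward), length(inv$excluded),
                  paste(ec_sets[[m$id]], collapse = " ")))
}

ref <- read_ec_list(system.file("extdata", "co2_producing_ecs.txt",
                                package = "respitraits"))
cmp <- jaccard_compare(ec_sets, reference = ref)
write.table(data.frame(model = rownames(cmp$jaccard), cmp$jaccard),
            "results/jaccard.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(model = names(cmp$coverage),
                       coverage = unname(cmp$coverage)),
            "results/ec_coverage.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("reference-list coverage: ",
        paste(sprintf("%s %.2f", names(cmp$coverage), cmp$coverage),
              collapse = ", "))
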