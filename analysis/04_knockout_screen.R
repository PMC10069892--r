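#!/usr/bin/env Rscript
# Single and double reaction-knockout screen of growth respiration on the
# day model, the search for knockouts that reduce CO2 release per unit of
# biomass carbon, and the direct linear-fractional minimization of that
# ratio (Charnes-Cooper).
# Outputs: results/screen_depth2.tsv, results/screen_summary.tsv

library(respitraits)
dir.create("results", showWarnings = FALSE)

day <- generate_toyplant(toy_model_spec())
inv <- build_inventory(day$model)
rc <- rubisco_constraint("RBC_C", "RBC_O", 0.31, 0.55)

t0 <- Sys.time()
screen <- run_screen(day$model, inv, rc, depth = 2)
message(sprintf("depth-2 screen: %d knockout sets (%d viable, %d pruned) in %.1f s",
                nrow(screen$records), sum(screen$records$viable),
                screen$skipped,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
write.table(screen$records, "results/screen_depth2.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

reducers <- find_respiration_reducers(screen)
message("knockouts reducing scaled Rg below wild type: ", nrow(reducers))

viable <- screen$records[screen$records$viable, ]
top <- viable[order(-viable$fold_scaled), ][1, ]
message(sprintf("largest scaled-Rg increase: {%s, %s} at %.2f-fold",
                top$ko1, top$ko2, top$fold_scaled))

msr <- minimize_scaled_respiration(day$model, inv, rc)
message(sprintf(paste0("ratio minimization: %.6f -> %.6f ",
                       "(%d reactions changed activity state)"),
                msr$ratio_before, msr$ratio_after, msr$n_state_changes))

summary <- data.frame(
  wild_type_mu = screen$wild_type$mu,
  wild_type_Rg_scaled = screen$wild_type$Rg_scaled,
  n_sets = nrow(screen$records),
  n_viable = sum(screen$records$viable),
  n_pruned = screen$skipped,
  n_reducers = nrow(reducers),
  max_fold_scaled = top$fold_scaled,
  ratio_before = msr$ratio_before,
  ratio_after = msr$ratio_after,
  n_state_changes = msr$n_state_changes)
write.table(summary, "results/screen_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
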