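#!/usr/bin/env Rscript
# Substrate-level trimming simulations: free ssRNA degradation, duplex
# overhang thresholds and endpoints, methylation and Mn2+ effects, and
# cold-RNA competition. Writes tables under results/.

suppressPackageStartupMessages(library(sdntrim))
SEED <- 1L
dir.create("results", showWarnings = FALSE)

g21 <- substr(strrep("ACGC", 6), 1, 21)  # 21-nt miR166-length guide

## Free ssRNA: product-size distributions per enzyme preset ----------------
message("== free ssRNA degradation ==")
rows <- list()
for (preset in c("WT", "2FA", "D283A", "dC")) {
  res <- simulate_ensemble(make_substrate(g21, mode = "SS"),
                           sdn_preset(preset), n = 4000,
                           seed = derive_seed(SEED, 1))
  tab <- as.data.frame(res$length_dist)
  names(tab) <- c("final_length", "molecules")
  tab$preset <- preset
  rows[[preset]] <- tab
  message(sprintf("  %-6s mean product %5.2f nt; floor fraction %.2f",
                  preset, mean(res$molecules$final_length),
                  mean(res$molecules$final_length == 4)))
}
write_tsv(do.call(rbind, rows), "results/ssRNA_product_sizes.tsv")

## Duplexes T0/T2/T4/T6: the 4-nt pocket-depth threshold -------------------
message("== miRNA/target duplex overhang series ==")
rows <- list()
for (o in c(0, 2, 4, 6)) {
  res <- simulate_ensemble(make_substrate(g21, o, "DUPLEX"),
                           sdn_preset("WT"), n = 4000,
                           seed = derive_seed(SEED, 2))
  final_o <- res$molecules$final_length - (21 - o)
  tab <- as.data.frame(table(final_o))
  names(tab) <- c("final_overhang", "molecules")
  tab$initial_overhang <- o
  rows[[as.character(o)]] <- tab
  message(sprintf("  T%d: trimmed %.2f of molecules; final overhangs {%s}",
                  o, mean(res$molecules$cuts > 0),
                  paste(sort(unique(final_o[res$molecules$cuts > 0])),
                        collapse = ", ")))
}
write_tsv(do.call(rbind, rows), "results/duplex_overhang_series.tsv")
message("  sub-pocket overhangs (T0/T2) are never engaged;")
message("  trimmed T4/T6 products end with 2-3 nt overhangs")

## Methylated duplexes: Mg2+ vs Mn2+ ---------------------------------------
message("== methylated duplex, Mg2+ vs Mn2+ ==")
rows <- list()
for (mn in c(FALSE, TRUE)) {
  for (o in c(2, 6)) {
    res <- simulate_ensemble(make_substrate(g21, o, "DUPLEX",
                                            methylated = TRUE),
                             sdn_preset("WT", mn_mode = mn),
                             n = 2000, max_rounds = 200,
                             seed = derive_seed(SEED, 3))
    rows[[paste(mn, o)]] <- data.frame(
      mn_mode = mn, initial_overhang = o,
      mean_final_length = mean(res$molecules$final_length),
      floor_fraction = mean(res$molecules$final_length == 4))
    message(sprintf("  %s T%d: mean final length %5.2f nt",
                    if (mn) "Mn2+" else "Mg2+", o,
                    mean(res$molecules$final_length)))
  }
}
write_tsv(do.call(rbind, rows), "results/methylated_duplex_mn.tsv")
message("  with Mn2+ an engaged methylated duplex is degraded to the ssRNA")
message("  floor regardless of the double-stranded region; T2 stays intact")

## Cold-RNA competition at 1:200:4000 --------------------------------------
message("== cold-RNA competition (labeled:enzyme:cold = 1:200:4000) ==")
rows <- list()
for (preset in c("WT", "2FA")) {
  cmp <- simulate_competition(make_substrate(g21, mode = "SS"),
                              n_labeled = 2000, n_cold = 8e6,
                              enz = sdn_preset(preset),
                              seed = derive_seed(SEED, 4))
  td <- as.data.frame(cmp$truncation_dist)
  names(td) <- c("truncation", "molecules")
  td$preset <- preset
  rows[[preset]] <- td
  message(sprintf("  %-4s modal truncation %s nt; near-floor fraction %.2f",
                  preset, names(cmp$truncation_dist)[
                    which.max(cmp$truncation_dist)],
                  mean(cmp$molecules$final_length <= 6)))
}
write_tsv(do.call(rbind, rows), "results/competition_truncation.tsv")
message("  the distributive mutant trims 1-2 nt; the processive enzyme")
message("  degrades labeled RNA to near-floor lengths despite competitor")

## Processivity estimation from cut counts ---------------------------------
message("== processivity recovery ==")
rows <- list()
for (p in c(0.2, 0.5, 0.9)) {
  res <- simulate_ensemble(make_substrate(strrep("AC", 150), mode = "SS"),
                           enzyme_params(p_proc = p, engage_factor = 1),
                           n = 10000, max_rounds = 1,
                           seed = derive_seed(SEED, 5))
  est <- estimate_processivity(
    res$molecules$cuts[res$molecules$engagements == 1])
  rows[[as.character(p)]] <- data.frame(p_true = p, p_hat = est$p_hat,
                                        se = est$se, n = est$n)
  message(sprintf("  p = %.1f -> p_hat = %.4f (se %.4f)", p, est$p_hat,
                  est$se))
}
write_tsv(do.call(rbind, rows), "results/processivity_recovery.tsv")
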