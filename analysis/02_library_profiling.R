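#!/usr/bin/env Rscript
# Synthetic AGO1-IP libraries under three enzyme conditions, profiled into
# truncation/tailing states: TR/FL ratios, condition comparisons against
# the catalytic-dead control, and the truncation-by-tailing matrix for
# miR166a-3p. Writes tables under results/.

suppressPackageStartupMessages(library(sdntrim))
SEED <- 1L
dir.create("results", showWarnings = FALSE)

refs <- read_references(system.file("extdata", "example_mirnas.fasta",
                                    package = "sdntrim"))
presets <- list(D283A = sdn_preset("D283A"), WT = sdn_preset("WT"),
                `2FA` = sdn_preset("2FA"))

message("== generating and profiling libraries (depth 50,000) ==")
profiles <- list()
for (i in seq_along(presets)) {
  cond <- names(presets)[i]
  lib <- generate_reads(refs, presets[[i]], tailing_params(),
                        depth = 50000L, seed = derive_seed(SEED, i),
                        n_molecules = 2000L)
  prof <- build_profile(lib$reads, refs)
  profiles[[cond]] <- prof
  tab <- tr_fl_table(prof)
  tab$condition <- cond
  write_tsv(tab, sprintf("results/tr_fl_%s.tsv", cond))
  message(sprintf("  %-6s assigned %d / %d reads; median TR/FL %.3f",
                  cond, prof$assigned, prof$total,
                  stats::median(tab$ratio, na.rm = TRUE)))
}

message("== condition comparisons (control: D283A) ==")
for (cond in c("WT", "2FA")) {
  cmp <- compare_conditions(profiles$D283A, profiles[[cond]])
  write_tsv(cmp, sprintf("results/compare_D283A_vs_%s.tsv", cond))
  message(sprintf("  %s: %d/%d miRNAs flagged as trimmed", cond,
                  sum(cmp$flagged), nrow(cmp)))
}

message("== truncation x tailing matrix, miR166a-3p ==")
rows <- list()
for (cond in names(profiles)) {
  mat <- truncation_tailing_matrix(profiles[[cond]], "miR166a-3p")
  long <- matrix_to_long(mat, "miR166a-3p")
  long$condition <- cond
  rows[[cond]] <- long
  top <- long[order(-long$proportion), ][1:3, ]
  message(sprintf("  %-6s top species (t,m,prop): %s", cond,
                  paste(sprintf("(%d,%d,%.2f)", top$t, top$m,
                                top$proportion), collapse = " ")))
}
write_tsv(do.call(rbind, rows), "results/matrix_miR166a-3p.tsv")
message("  under the active enzyme the mass moves off (t=0, m=0) into")
message("  truncations of 1-6 nt, with a U-tailing side population")
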