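# sdntrim

Tools for studying 3'→5' exonucleolytic trimming of small RNAs by DEDDh
nucleases of the SDN family (the pathway that initiates turnover of
AGO1-bound miRNAs in *Arabidopsis*), aimed at people analyzing small-RNA
3'-end metabolism: isomiR profiling of sRNA-seq libraries, mechanistic
simulation of trimming enzymology, and structural analysis of
nuclease-RNA complexes.

The package has three coordinated parts:

- **Profiler** — 5'-anchored classification of small-RNA reads against
  mature miRNA references into 3'-truncation/tailing states $(t, m)$:
  $t$ nucleotides truncated from the 3' end, $m$ non-templated (typically
  U) nucleotides appended. Per miRNA it computes the trimming-activity
  statistic
  $$\mathrm{TR}/\mathrm{FL} = \frac{\sum_{t\ge1}\mathrm{count}(t, m=0)}{\mathrm{count}(t=0, m=0)}$$
  (tailed species excluded by default, with an `include_tailed` switch),
  truncation-by-tailing proportion matrices, and flagged comparisons of an
  active enzyme against a catalytic-dead control.
- **Simulator** (the synthetic-data generator) — a stochastic rule model of
  DEDDh action: engagement requires ≥ 4 single-stranded 3' nucleotides
  (the catalytic-pocket depth), cutting is mononucleotide with one
  obligatory cut per engagement followed by geometric continuation with
  processivity $p$, floors at 4 nt (free ssRNA) and 2-nt overhangs
  (duplexes), a 2'-O-methylation engagement penalty, an Mn²⁺ mode, and an
  AGO-bound mode with capped 3'-end accessibility. It emits synthetic
  AGO1-IP-style sRNA-seq libraries with ground truth, and
  `estimate_processivity()` recovers $p$ from cut counts by closed-form
  maximum likelihood, $\hat p = 1 - n/\sum c_i$.
- **Structure & NMR stage** — PDB/mmCIF parsing with altloc and occupancy
  handling, Shrake–Rupley solvent-accessible surface area, buried interface
  areas $\mathrm{SASA}(A)+\mathrm{SASA}(B)-\mathrm{SASA}(A\cup B)$ in both
  the PISA-style (half) and full-buried conventions, protein–RNA contact
  maps, per-entity model statistics, and weighted-average chemical-shift
  perturbations $\Delta\delta_{avg} = \sqrt{\Delta\delta_H^2 +
  (0.2\,\Delta\delta_N)^2}$ with a strict 0.05 ppm threshold.

## Worked example

Trimming a miRNA/target duplex series (the T0/T2/T4/T6 overhang designs)
with the wild-type enzyme preset, then profiling a synthetic AGO1-IP
library:

```r
library(sdntrim)
g21 <- substr(strrep("ACGC", 6), 1, 21)          # 21-nt guide
for (o in c(0, 2, 4, 6)) {
  res <- simulate_ensemble(make_substrate(g21, o, "DUPLEX"),
                           sdn_preset("WT"), n = 4000, seed = 1)
  final_o <- res$molecules$final_length - (21 - o)
  cat(sprintf("T%d: trimmed %.2f of molecules; final overhangs {%s}\n",
              o, mean(res$molecules$cuts > 0),
              paste(sort(unique(final_o[res$molecules$cuts > 0])),
                    collapse = ", ")))
}
```

```
T0: trimmed 0.00 of molecules; final overhangs {}
T2: trimmed 0.00 of molecules; final overhangs {}
T4: trimmed 1.00 of molecules; final overhangs {2, 3}
T6: trimmed 1.00 of molecules; final overhangs {2, 3}
```

Overhangs shorter than the 4-nt pocket depth are never engaged; trimmed
duplexes end with 2–3-nt overhangs.

```r
refs <- read_references(system.file("extdata", "example_mirnas.fasta",
                                    package = "sdntrim"))
wt   <- generate_reads(refs, sdn_preset("WT"),    depth = 50000, seed = 2)
dead <- generate_reads(refs, sdn_preset("D283A"), depth = 50000, seed = 1)
pw <- build_profile(wt$reads, refs)
pd <- build_profile(dead$reads, refs)
median(tr_fl_table(pw)$ratio)   # wild type
median(tr_fl_table(pd)$ratio)   # catalytic-dead control
compare_conditions(pd, pw)$flagged
```

```
[1] 0.4672835
[1] 0
[1] TRUE TRUE TRUE TRUE TRUE
```

The active enzyme moves read mass off $(t=0, m=0)$ into 1–6-nt
truncations, raising TR/FL for every miRNA, while the catalytic-dead
control leaves all reads full length; the comparison flags all five
references as trimmed.

The numbered drivers under `analysis/` run the full set of analyses —
substrate-level simulations (`01`), library generation and profiling
(`02`), the structure report (`03`, on a bundled synthetic complex by
default, or any PDB/mmCIF file or fetchable PDB id), and the NMR CSP
report (`04`) — writing their tables under `results/`.

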