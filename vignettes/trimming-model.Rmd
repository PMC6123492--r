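---
title: "Modeling 3' trimming of small RNAs by a DEDDh exonuclease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling 3' trimming of small RNAs by a DEDDh exonuclease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdntrim)
```

## The system

Plant miRNAs are 2'-O-methylated at their 3' termini by HEN1 and loaded into
ARGONAUTE1 (AGO1), which anchors the 3' end in its PAZ domain. Their turnover
begins with 3'-to-5' trimming by SDN-family DEDDh exonucleases, followed by
uridylation of the trimmed, unmethylated species by nucleotidyl transferases
(HESO1/URT1). In deep-sequencing data this leaves a characteristic signature
on each miRNA: 3'-truncated isomiRs, U-tailed isomiRs, and combinations of
the two. `sdntrim` packages three computational pieces around this biology:

1. a **profiler** that classifies small-RNA reads against mature miRNA
   references into 3'-truncation/tailing states and computes the
   truncated-to-full-length (TR/FL) statistic and truncation-by-tailing
   matrices;
2. a **mechanistic simulator** of DEDDh trimming on free ssRNA,
   miRNA/target duplexes and AGO-bound miRNAs, which doubles as the
   synthetic-data generator for the profiler;
3. a **structure/CSP stage** that recomputes interface areas, protein-RNA
   contacts, ion occupancies and model statistics from coordinate files,
   and weighted-average chemical-shift perturbations from NMR titration
   tables.

## The profiler

### Classification model

Reads are assumed to share the mature miRNA 5' end (the enzymology being
modeled changes only 3' ends; 5' isomiRs are deliberately out of scope and
land in `UNASSIGNED`). For a read and a reference of length $L$, the longest
matched prefix $q$ determines the candidate state: truncation $t = L - q$
and non-templated tail equal to the remaining read suffix of length $m$. A
candidate is valid when $q \ge q_{\min}$, $t \le t_{\max}$ and
$m \le m_{\max}$; among references the winner maximizes $q$, then minimizes
$t$, then takes the lexicographically smallest id. The tie-break order is
fixed and tested.

The *maximal-prefix convention* matters when a tail nucleotide equals the
next templated base: a read equal to `ref[1:19] + "UU"` against a 20-nt
reference ending in U is scored as $(t = 0, m = 1)$, not $(t = 1, m = 2)$ —
ambiguous nucleotides are assigned to the reference, minimizing apparent
truncation. The convention is deterministic and is the reason round-trip
tests against the simulator use references without templated U near the 3'
end ("unambiguous tails").

Defaults are $q_{\min} = 12$, $t_{\max} = 8$, $m_{\max} = 8$: single-digit
truncation/tailing spans the biologically observed range for 21-22-nt
miRNAs, and a 12-nt anchor keeps random matches negligible at miRNA-set
sizes.

### Statistics

For one miRNA, `tr_fl_ratio()` returns $\mathrm{TR}/\mathrm{FL}$ with
$\mathrm{FL} = \mathrm{count}(t = 0, m = 0)$ and
$\mathrm{TR} = \sum_{t \ge 1} \mathrm{count}(t, m = 0)$. Whether
truncated-and-tailed reads should count as TR (and tailed full-length reads
as FL) is genuinely underdetermined by the source assays, so tailed species
are **excluded by default** and an `include_tailed` switch ignores tails in
both terms; both conventions are exercised in the tests. Division edge
cases are explicit: $\mathrm{FL} = 0$ with $\mathrm{TR} > 0$ returns a
flagged `Inf`, and $\mathrm{FL} = \mathrm{TR} = 0$ returns `NA`.

`truncation_tailing_matrix()` normalizes species counts over the
$(t, m)$ grid to proportions summing to one; species beyond the axis caps
accumulate into the cap bin and flag the matrix. `compare_conditions()`
contrasts two profiles (active enzyme vs catalytic-dead control), excludes
miRNAs with fewer than `min_fl` full-length counts in either condition
(default 10 — a minimum-evidence filter the source analyses leave
unstated), and flags a miRNA as trimmed when its ratio exceeds
`fold_threshold` (default 2) times the control ratio.

## The simulator

### Mechanistic rules

The simulator encodes the biochemical findings as a small stochastic rule
set per enzyme encounter:

- **Engagement** requires at least `k_engage = 4` single-stranded 3'
  nucleotides — the catalytic pocket is 4 nt deep, so shorter overhangs
  cannot reach the active site. Engagement succeeds with probability
  `engage_factor`, multiplied by `alpha_me` (default 0.1) for
  2'-O-methylated 3' ends; the first cut removes the methylated nucleotide.
- **Cutting** releases mononucleotides: one obligatory cut on engagement,
  then further cuts each with probability `p_proc` (processivity), until
  dissociation or a floor. This "1 + geometric" form is the simplest model
  separating binding from processivity, and it is identifiable from
  cut-count data (`estimate_processivity()` is its closed-form MLE,
  $\hat p = 1 - n/\sum c_i$, with standard error
  $\sqrt{\hat p (1-\hat p)^2 / n}$ from the Fisher information).
- **Floors**: free ssRNA is not degraded below `L_floor = 4` nt ("very
  small" products, set equal to the pocket depth); duplex overhangs stop at
  `f_duplex = 2` nt, so trimmed duplex products carry 2-3-nt overhangs —
  whether the endpoint is 2 or 3 deterministically is not resolvable from
  gel ladders, and here it is stochastic (dissociation at 3 vs one more cut
  to the floor at 2); AGO-bound guides can lose every accessible
  nucleotide.
- **Mn²⁺ mode** (`mn_mode`): initial engagement still requires a 4-nt
  overhang, but a nicked molecule may re-engage at any overhang and the
  floor becomes the ssRNA floor — reproducing full degradation of engaged
  methylated duplexes regardless of the double-stranded region while
  leaving T0/T2 substrates intact.
- `catalytic = FALSE` (the D283A-style preset) disables engagement
  entirely: the identity map on lengths, for all substrates and seeds.

Presets (`sdn_preset()`): WT (`p_proc = 0.9`, full engagement), 2FA
(distributive, `p_proc = 0.2`, `engage_factor = 0.3`), D283A (dead), dC
(RRM-deleted, `engage_factor = 0.05`). The numbers are model defaults
chosen to reproduce the qualitative orderings of the enzymatic assays
(processive vs distributive vs dead), not measured constants; all are
overridable.

### Competition and the encounter budget

`simulate_competition()` models the cold-RNA competition assay at the
1:200:4000 labeled:enzyme:cold molar ratio. Each enzyme encounter selects a
molecule uniformly from the union of the pools; since cold-molecule
outcomes cannot affect labeled molecules, the implementation draws
per-labeled-molecule encounter counts from the exact marginal (multinomial
with probability $n_{lab}/(n_{lab}+n_{cold})$), which is distributionally
identical to simulating the whole pool and keeps the full ratio tractable.

The assay's duration is not parameterized by rate constants, so the total
encounter budget is a free model constant. It is calibrated to the assay's
endpoint contrast: at 125 encounters per enzyme (mean ~6 per pool
molecule), the distributive preset's modal labeled truncation is 1-2 nt
while the processive preset drives most labeled molecules to near-floor
lengths. That calibration target is the observed endpoint itself; the
budget is not otherwise identifiable.

### The synthetic library generator

`generate_reads()` emulates sRNA-seq of AGO1-bound miRNAs after an in
vitro trimming reaction. Per miRNA, molecules are simulated in `AGO_BOUND`
mode with per-molecule 3' accessibility drawn from a geometric distribution
(mean 3 nt) capped at 6 nt — standing in for partial, target-RNA-mediated
displacement of the 3' end from the PAZ pocket, which caps trimming at "a
few nucleotides". The true accessibility distribution in an AGO1
immunoprecipitate is unknown; the capped geometric is a modeling choice,
chosen once. Post-trimming, U-only tails are appended with probability
`tau = 0.1` and geometric length (mean 1.5 nt), a phenomenological stand-in
for the HESO1/URT1 uridylation background — the trimming enzyme itself
does not tail. Reads are then multinomially sampled to the requested depth,
and the pre-sampling $(t, \text{tail})$ states are returned as ground
truth.

What the generator does **not** emulate: sequence-dependent cleavage rates,
time-course kinetics, 5' isomiRs or internal edits, sequencing errors,
adapter artifacts, mapping ambiguity against miRNA families, and
inter-library composition effects. Passing round-trip tests therefore
demonstrates correctness of the classification arithmetic and conventions,
not robustness to real-library noise sources.

```{r example, eval = FALSE}
refs <- read_references(system.file("extdata", "example_mirnas.fasta",
                                    package = "sdntrim"))
lib <- generate_reads(refs, sdn_preset("WT"), depth = 50000, seed = 1)
prof <- build_profile(lib$reads, refs)
tr_fl_table(prof)
```

## The structure stage

`load_structure()` parses PDB/mmCIF atom records (via bio3d), keeps the
highest-occupancy alternate-location conformer (ties by label order), types
residues by name dictionaries (standard amino acids -> protein; A/C/G/U and
common modified ribonucleotides -> RNA; ion and water lists; overridable),
and reads resolution/R-work/R-free from the header when present.

Solvent-accessible surface area uses the Shrake-Rupley construction: each
atom inflated by a 1.4 Å water probe and sampled with a deterministic
golden-spiral point set (960 points by default; doubling changes cluster
totals by <1%), against a published van-der-Waals radius table (Bondi;
`inst/extdata/vdw_radii.tsv`). Buried interface area is
$\mathrm{SASA}(A) + \mathrm{SASA}(B) - \mathrm{SASA}(A \cup B)$; because
published interface numbers are reported in two conventions differing
exactly twofold, both are exposed (`pisa` = half-buried, the default, and
`bsa` = full buried area), and reproduction checks accept the closer
convention. Waters are excluded from interface and contact calculations by
default.

Contacts are inter-entity heavy-atom pairs within 4.0 Å, flagged polar when
both atoms are N/O within 3.5 Å — deliberately a distance criterion, not a
full hydrogen-bond geometry model. Default domain ranges for the nuclease
are NTD 2-137, DEDDh 138-300, RRM 315-409, overridable per chain.

The bundled `write_demo_structure()` emits a small, fully synthetic
protein-RNA complex (fixed constant coordinates, labeled as such) so the
stage can be demonstrated and smoke-tested offline; reproducing deposited
quantities requires fetching the corresponding PDB entries at run time
(`fetch_pdb()`), which the desk-scale acceptance tests do.

## The NMR CSP stage

Weighted-average backbone amide perturbations are
$\Delta\delta_{avg} = \sqrt{\Delta\delta_H^2 + (0.2\,\Delta\delta_N)^2}$,
computed exactly as stated. The 0.05 ppm threshold is **strict** (greater
than): a residue sitting exactly on the boundary is unperturbed. A residue
observed in the reference but missing from the titrated spectrum is
`disappeared`; the input format (one table per spectrum, missing rows mean
unobserved) cannot express *when* in a titration series a peak vanished,
so "disappeared" refers to the endpoint spectrum supplied. A residue
present only in the titrated table is a consistency error rather than a
silent drop.

## Reproducibility and problem sizes

All stochastic stages are pure functions of (inputs, parameters, seed).
One global seed fans out to per-stage child seeds through a fixed integer
derivation (`derive_seed()`), so pipeline stages are independently
reproducible; `run_pipeline()` writes its full resolved configuration to
`manifest.json` beside the outputs, and identical configuration plus seed
yields byte-identical TSVs.

The shipped analyses and checks use ensemble sizes chosen to make the
Monte-Carlo error negligible relative to the effects examined: 2,000-5,000
molecules for substrate-level distributions, 2,000 labeled molecules
against the full 1:200:4000 cold-RNA ratio, 10,000 engagements for
processivity recovery (recovering $p \in \{0.2, 0.5, 0.9\}$ well within
±0.05), libraries of 50,000 reads over 2,000 molecules per miRNA, and
10,000 random read/reference pairs for the classifier-vs-oracle
equivalence check.

## Known limitations

- The simulator is phenomenological: no thermodynamics, no explicit time,
  no sequence preference; its constants (presets, floors, accessibility,
  tailing, encounter budget) are calibrated to qualitative assay endpoints
  and should not be read as measured rate constants.
- The profiler resolves multi-mapping only through its fixed tie-break; it
  does not model miRNA families beyond that, nor 5'/internal variation.
- SASA depends on the radius table and point density; interface values are
  algorithm-dependent at the few-percent level, which is why reproduction
  bands of ±10% (and the two interface conventions) are used.
- Entity typing is dictionary-based; exotic ligands fall into `other`
  unless overridden.
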