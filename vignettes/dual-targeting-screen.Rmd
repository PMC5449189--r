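---
title: "Screening for dual Sec/Tat-targeted membrane proteins"
author: "dualTat maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for dual Sec/Tat-targeted membrane proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(dualTat))
```

## The biological problem

Most polytopic membrane proteins of bacteria are threaded into the inner
membrane helix by helix, co-translationally, by the Sec translocon. A small
but conserved group of proteins cannot be finished that way: their final
transmembrane domain (TMD) is immediately followed by a large
extracytoplasmic domain that must fold — often around a metal cofactor — in
the cytoplasm before export. These proteins are assembled co-operatively:
Sec inserts the N-terminal helices, the polypeptide is then released, and
the twin-arginine translocation (Tat) pathway, which transports folded
proteins, handles the final TMD together with the folded domain. The
actinobacterial Rieske iron–sulfur protein is the archetype: three TMDs, a
twin-arginine (RR) motif in the cytoplasmic loop after TMD2, Sec-dependent
insertion of TMDs 1–2 and Tat-dependent insertion of TMD3.

Two physical features of the final TMD mark the hand-over point:

* **Weak hydrophobicity.** The apparent free energy of translocon-mediated
  insertion, ΔG_app, of the Tat-dependent helix is *positive* (insertion
  disfavoured), whereas the first helix is strongly negative.
* **Sec-avoidance charges.** A cluster of lysines/arginines sits in the
  ~20 residues C-terminal of the final helix; translocating them against
  the membrane potential is costly, so Sec aborts and releases the chain.

This package implements the corresponding genome-scale screen — RR-motif
detection combined with TMD counting and orientation filters — and the
quantitative feature rubric, as a reusable library plus command-line tool
operating on protein FASTA input.

## The screen

For each protein the pipeline computes:

1. **TM segments** (`scanSegments()`). Every window of 19–23 residues is
   scored with ΔG_app (below); non-overlapping windows are selected
   greedily by ascending ΔG_app and reported when at or below a threshold
   (default 0 kcal/mol).
2. **RR motifs** (`findRRMotifs()`). Every consecutive arginine pair; an
   optional consensus score (one point each for S/T, F, L, K at the
   S/T-R-R-x-F-L-K consensus positions) can be used as a stringency
   filter, but the screen defaults to plain RR detection: conservative
   substitutions retain partial Tat transport in vivo, so hard consensus
   filtering would discard real substrates. Adjacency to the final TMD
   (below) plays the discriminating role instead.
3. **Orientation** (`orientByCharge()` / `buildTopology()`). When an
   external prediction (TMHMM-style short format) is supplied it takes
   precedence, including its N-in probability. Otherwise a deterministic
   positive-inside score is used: with P_even / P_odd the K+R counts in
   even-/odd-parity loops (loop 0 = the N-terminal tail) and pseudocount
   c = 1,
   n_in = (P_even + c) / (P_even + P_odd + 2c).
   Histidine is not counted. This is a deliberately simple, testable
   surrogate for an HMM posterior; it is weaker than a real predictor
   (see *Limitations*).
4. **Classification** (`screenDual()`). A protein is a candidate when an
   RR motif has an **even** number of TMDs before it (≥ 2), **exactly
   one** after it, and an N-in score > 0.9 (class `N-in-even`); or an
   **odd** number (1/3/5/7) before it, exactly one after, and a score
   < 0.5 (class `N-out-odd`). Scores in (0.5, 0.9] stay unclassified
   (reason `orientation`) — the screen mirrors the original two-pass
   design rather than inventing a rule for the middle zone. The gap
   between the motif and the final helix start is bounded (default 30
   residues; the motif "directly precedes" the helix in all known
   families, gap 6 in the Rieske archetype).

Because the Tat-dependent helix has *positive* ΔG_app in every known
family, a plain threshold scan misses it. With `rescueWeakFinalTmd` on
(default), whenever a motif has zero helices after it the scanner is
re-queried for the best window after the motif regardless of threshold,
and screening is retried with that helix.

### Boundary noise and the motif-inside-helix rule

Terminal positions of a scored window receive near-zero positional weight,
so selected window boundaries carry roughly ±2 residues of noise — a
window can swallow the RR pair at its edge at essentially no ΔG cost. A
motif strictly interior to a helix span is skipped (it cannot be a
loop-resident signal), but a motif at or within 2 residues of a helix
N-terminus is treated as directly preceding that helix with gap 0. For the same reason
the orientation score counts residues in the outermost 2 positions of
each helix with the adjacent loop — a charge at a predicted helix
terminus is a flanking charge under the positive-inside rule, whichever
side of the noisy boundary it lands on. Without these tolerances,
classification would depend on which of several ΔG-degenerate windows
happened to win the scan.

## The ΔG_app model

The insertion free energy of a candidate helix of length L is

ΔG_app = Σᵢ ΔG(aaᵢ, zᵢ) + ΔG_len(L)

where zᵢ rescales position i to [−9, 9] (the half-width of the 19-residue
reference helix) and each residue contributes a Gaussian profile

ΔG(aa, z) = ΔG⁰(aa) · exp(−w(aa) · z²)

with the centre contribution ΔG⁰ and width w taken from the biological
hydrophobicity scale shipped as configuration data
(`inst/extdata/scales/biological_dg.yaml`). The aromatics W and Y carry an
additional double-Gaussian term peaking near |z| ≈ 6.3, their preference
for the interface region. The length correction is quadratic and is
anchored so that it is exactly zero at the reference length of 19
(the raw quadratic evaluates to ~0.002 there; anchoring removes that
residue so the invariant "no correction at the reference length" holds
identically). Values are reported to 3 decimals, matching the precision
at which such predictions are tabulated.

Numerical/decision details:

* **Profiles are pluggable.** `defaultScale("uniform")` weights every
  position 1 and drops the aromatic term; all hand-sum oracle tests run
  under this profile, so the test suite's arithmetic checks are
  independent of the positional parameterization.
* **Ties** in the window scan are broken by smaller start, then shorter
  length — determinism over elegance.
* **Unknown residues.** `X` is accepted and contributes a configurable
  value (default 0); spans containing it are flagged (`has_x`).
  Selenocysteine is read as cysteine; ambiguity codes (B/Z/J) are
  rejected — a genome screen must fail loudly rather than skip records.
* **Variants.** `variantDG()` reports the substituted span both over the
  fixed original window and after a local re-scan, because a substitution
  can shift where a scanner would place the helix and published variant
  tables do not always say which convention they used.
* The scale file is versioned; exact-match comparisons against published
  prediction tables are meaningful only relative to that file, and any
  re-transcription of the scale is a new version.

## The Sec-release rubric

For a classified candidate, `secReleaseReport()` computes:

* `final_tmd_dg` and `first_tmd_dg`, and their raw difference `dg_gap`
  (no flag threshold — published analyses report the comparison
  qualitatively, so we report the number);
* `cterm_basic_count`: K+R in the 20 residues after the final helix
  (window configurable; 20 covers the charge clusters observed across
  the known families), counted strictly after the helix end and truncated
  at the sequence end;
* `loop_len`: residues between the penultimate helix end and the first
  arginine — 43 in the Rieske archetype;
* flags: `weak_final_tmd` (ΔG_app > 0), `sec_avoidance` (≥ 2 basic
  residues in the window), `short_loop` (loop < 8 residues, the
  approximate minimum for Tat recognition of a membrane-tethered signal).
  `short_loop` is a flag only, never a filter: the minimum was measured
  for Tat recognition, not for the screen.
* `leucineWhatIf()` ranks the least hydrophobic residues of the final
  helix and reports the ΔG_app reduction from substituting each (and all)
  to leucine — the in-silico counterpart of the classic
  hydrophobicity-rescue experiment, where one or two leucines suffice to
  force Sec insertion of the normally released helix.

## The synthetic generator

`makeProtein()` builds proteins with known architecture so that every
stage is testable without downloads:

* helices are built by stochastic local search — random hydrophobic
  strings, single-residue swaps accepted when they move the measured
  ΔG_app toward its target, until within ±0.2 kcal/mol. Local search
  rather than analytic composition because the positional weights make
  exact composition scale-dependent;
* loops are drawn from a polar alphabet (S,T,N,Q,G,P,D,E) with K/R
  charges placed on the cytoplasmic side dictated by the ground-truth
  orientation; accidental RR pairs are broken during assembly;
* the RR motif is inserted with its consensus context (S-R-R-G-F-L-K) at
  a configurable distance before the final helix;
* everything is reproducible from one integer seed, recorded in the
  FASTA header.

Generator defaults are the study conditions and are not tuned per test:
helix length 21; Sec-helix target −2.0 kcal/mol; final-helix target +0.5
(the sign pattern shared by all known families); RR loop 43 residues and
motif-to-helix gap 6 (the Rieske archetype); four C-terminal basic
residues within the 20-residue window for family emulations (the count in
the extended Rieske fusion construct); **5 K/R per cytoplasmic loop**.
The last value deserves a note: with the pseudocounted charge-bias score,
clearing the 0.9 N-in threshold for a 3-helix protein requires at least
nine net inside charges, so a bias of 3 per loop — enough for a real HMM
predictor — would sit in the unclassified zone here. Five per loop (plus
the RR pair itself) clears the threshold across all architectures and is
within the range observed in cytoplasmic loops of polytopic proteins.

Family emulations that carry the C-terminal charge cluster are screened
through the imported-topology path (the generator's ground truth, packaged
as a TMHMM-style import) rather than the charge-bias surrogate: tail
charges legitimately depress a positive-inside score, and the original
screen likewise took orientation from an HMM's whole-protein probability,
not from raw loop counts.

What the generator does **not** emulate: realistic amino-acid background
frequencies, cofactor-binding sequence motifs, signal peptidase sites, or
helices with strongly amphipathic character. Passing on fixtures therefore
demonstrates the correctness of the screen's logic and arithmetic, not its
sensitivity/specificity on real proteomes.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated data:
scanner-vs-brute-force equivalence on 200 random sequences of up to 200
residues; orientation antisymmetry on 100 constructed topologies; screen
recall and false-positive rate on 105+ seeded fixtures across three
positive architectures and two negative controls; feature-flag concordance
on emulations of the four known dual-targeted families. These sizes give
exhaustive window-level coverage at desk scale; the screen itself is
linear in total sequence length and runs genome-sized FASTA input without
modification.

Reproducing the published per-accession ΔG_app tables additionally needs
the four reference UniProt sequences (Q9X807, P9WH23, Q9L0V6, Q1NSB0);
`fetchUniProt()` retrieves them when a network is available, and the
corresponding check in `test-acceptance.R` fails explicitly — rather than
silently passing — when they cannot be obtained. A coordinate-faithful
*synthetic* stand-in (`syntheticRieskeFixture()`) covers the coordinate
arithmetic (loop length 43, gap 6, four tail charges) but is never used to
assert published per-residue values.

## Known limitations

* The charge-bias orientation score is a stand-in for an HMM posterior.
  It is deterministic and testable, but weaker than TMHMM on real
  sequences; imported predictions should be preferred when available, and
  the screen thresholds apply to whichever score is present.
* The shipped scale file is a transcription of the published biological
  hydrophobicity model; agreement with the original prediction server to
  the third decimal is gated on that transcription and on unstated server
  defaults (length correction, scan mode). Sign and ordering relations
  (first helix most negative, final helix positive) are robust to these
  details; exact decimals may not be.
* TATFind-style downstream rules (h-region hydrophobicity, c-region
  charge) are not reimplemented; the adjacency-to-TMD requirement plays
  the equivalent role in this screen.
* Signal peptides vs. signal anchors are not discriminated; an N-terminal
  Sec signal peptide can be counted as a TMD, as it was in the original
  genome screen.

## A worked example

```{r example}
scale <- defaultScale()
fx <- syntheticRieskeFixture(scale)
df <- screenFasta(fx$record, scale,
                  imported = list(truthAsImported(fx$truth,
                                                  names(fx$record))))
t(df[, c("class", "n_before", "n_after", "rr_pos", "gap", "loop_len",
         "final_tmd_dg", "first_tmd_dg", "cterm_basic_count",
         "weak_final_tmd", "sec_avoidance", "short_loop")])
```

The stand-in is classified `N-in-even` — two Sec helices before the
motif, one Tat helix after it, 43-residue loop, weakly hydrophobic final
helix, charged tail — the signature this screen exists to find.
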