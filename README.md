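# tasitune

Design and efficacy tuning of plant synthetic trans-acting siRNA
(syn-tasiRNA) constructs.

## The problem

Syn-tasiRNAs are 21-nt artificial small RNAs expressed from an engineered
Arabidopsis *TAS1c* precursor. After miR173-guided cleavage of the
precursor transcript, DCL4 dices the downstream RNA into phased 21-nt
small RNAs, so a guide sequence placed exactly in one of the processing
slots 3'D2[+]–3'D5[+] is released verbatim and silences its target.
Classical RNAi tools maximize silencing; many applications (essential
genes, allelic series, dose-sensitive pathways) instead need a *chosen*
degree of silencing. Two orthogonal design modules provide that control:

1. **Precursor position** — accumulation and efficacy are highest at
   3'D2[+], next to the miR173 target site, and fall progressively toward
   3'D5[+]. Position 3'D1[+] retains the 3' half (11 nt) of the miR173
   target site and cannot carry a guide.
2. **3'-end complementarity** — consecutive mismatches engineered between
   the guide 3' end and the target-site 5' end tune activity: 0–1
   mismatches are tolerated, 2–3 diminish silencing, 4–5 abolish it.

`tasitune` implements the full design workflow for these constructs:

* **Guide design** (`design_guides()`): enumerates 21-nt windows, builds
  guides as reverse complements, applies designer heuristics (5' U,
  position-19 C, 30–60% GC, no long homopolymer, no BsaI site) and ranks
  candidates.
* **Off-target screening** (`scan_transcriptome()`, `score_site()`): a
  TargetFinder-style additive penalty — mismatch 1, G:U wobble 0.5,
  doubled at guide seed positions 2–13 — applied to every window of every
  transcript; a guide fails specificity if any unintended transcript has a
  site scoring ≤ 4.
* **Mismatch variant series** (`make_mismatch_series()`): variants with
  k = 1..5 consecutive 3'-terminal substitutions (guide base set equal to
  the opposing site base, which can neither pair nor wobble), each
  re-screened.
* **Precursor construction** (`assemble_precursor()`, `design_oligos()`,
  `golden_gate_assemble()`, `simulate_phasing()`): places guides into
  slots D2–D5 of a cloning-ready "B/c" backbone, emits the two annealing
  oligos with 5'-TTTA / 5'-CCGA overhangs (46 nt for D2/D3
  configurations), simulates BsaI digestion (GGTCTC, 1/5-nt cut offsets,
  4-nt 5' overhangs) and directional ligation, and verifies phased
  processing recovers each guide at its declared slot.
* **Efficacy tiers** (`efficacy_tier()`, `plan_settings()`,
  `efficacy_grid()`): the ordinal two-module model over the 4 × 6 grid of
  (position, 3'-end mismatches), and its inverse — which settings realize
  a requested tier.

Results come back as tibbles (or objects with `tidy()` / `glance()` /
`autoplot()` methods), so the package composes with the usual tidyverse
verbs. A thin command-line wrapper (`inst/exec/tasitune`) exposes the
subcommands `design`, `screen`, `variants`, `assemble`, `oligos`,
`phase`, `tier` and `fixtures`.

## Worked example

```r
library(tasitune)

# a synthetic transcriptome with a designable target transcript
anchor <- "UAUGGACGUAUCAUAGCACCC"
target <- c(TGT = paste0(reverse_complement(chartr("U", "T", anchor), "DNA"),
                         paste(sample(c("G", "C"), 400, TRUE), collapse = "")))
tx <- c(target, as.character(make_transcriptome(2, n_transcripts = 20)))

cand <- design_guides(target, tx, n = 3)
cand$guide[1]
#> [1] "UAUGGACGUAUCAUAGCACCC"      # 21 nt, passes all heuristics and the screen

ser <- make_mismatch_series(guide(cand$guide[1], cand$name[1]), cand$site[1])
tidy(ser)$three_prime_run
#> [1] 1 2 3 4 5                    # variant k has exactly k 3'-terminal mismatches

bb  <- make_backbone_fixture(3)
con <- assemble_precursor(bb, list(`2` = cand$guide[1]))
design_oligos(con)
#> <oligo pair> core 42 bp, oligos 46 nt
#>   top    5'-TTTA...-3'
#>   bottom 5'-CCGA...-3'

simulate_phasing(golden_gate_assemble(bb$sequence, design_oligos(con)),
                 cleavage_offset = bb$cleavage_offset)$sequence[2] == cand$guide[1]
#> [1] TRUE                         # the guide is released as phased sRNA #2

efficacy_tier(2, 0)$combined_label
#> [1] maximal                      # D2 + full complementarity = strongest design
plan_settings("maximal")[, c("position", "mismatches")]
#> position 2, mismatches 0 or 1
```

The packaged synthetic stand-in for the pENTR-AtTAS1c-D2-B/c entry vector
(`load_packaged_backbone()`) releases a 1461-bp stuffer cassette on
simulated BsaI digestion (`excised_stuffer_length()`).

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch against
seeded synthetic fixtures — fixture generation, guide design and
screening, the variant series, both single- and dual-guide assemblies
with oligo design, golden-gate simulation and phasing, packaged-vector
stuffer excision, and the efficacy grid — logging each stage to stderr
and writing the JSON report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
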