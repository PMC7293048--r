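---
title: "Designing and tuning syn-tasiRNA constructs with tasitune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and tuning syn-tasiRNA constructs with tasitune}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tasitune)
```

## The biological model

Synthetic trans-acting siRNAs (syn-tasiRNAs) are produced from an
engineered Arabidopsis *TAS1c* precursor. The trigger microRNA miR173,
loaded in AGO1, cleaves the precursor transcript inside its 21-nt target
site; the cleavage fragment is converted to double-stranded RNA and DCL4
then dices it into 21-nt small RNAs in a fixed register — the *phasing
register* — measured from the cleavage point. The first register slot,
3'D1[+], necessarily begins with the retained 3' half of the miR173
target site and therefore cannot encode a free-standing guide; slots
3'D2[+] through 3'D5[+] can. A 21-nt guide written into slot k of the
precursor DNA is released verbatim as the k-th phased small RNA.

Two properties of this system allow silencing strength to be *tuned*
rather than merely maximized, and they are the two modules this package
formalizes:

* **Position**: guide accumulation and silencing efficacy are highest at
  3'D2[+], immediately downstream of the trigger site, and decrease
  progressively through 3'D5[+].
* **3'-end complementarity**: consecutive mismatches between the guide 3'
  end and the target-site 5' end reduce activity stepwise — one terminal
  mismatch is tolerated, 2–3 consecutive mismatches significantly
  diminish silencing, and 4–5 abolish it.

## Coordinate and pairing conventions

All external coordinates are 0-based, half-open, on the plus (sense)
strand. Guide position 1 is the guide 5' end; under the antiparallel
duplex convention, guide position *i* faces target-site position
*L − i + 1*, so the guide 3' end pairs with the site 5' end. A position is
`WC` when the bases are Watson–Crick complements, `wobble` when guide G
faces site U or guide U faces site G, and `mismatch` otherwise. Slot k of
the precursor spans `[cleavage_offset + 21(k−1), cleavage_offset + 21k)`.

**Cleavage index.** AGO-guided slicing occurs between target-site
positions 10 and 11; the retained 3' half is therefore 11 nt and opens
slot D1. The literature states the biology without explicit indices; this
package fixes the standard slicing convention and exposes the resulting
`cleavage_offset` on every backbone object.

**Wobble and mismatch counting.** Whether a G:U pair counts as a mismatch
for the sensitivity tiers is not stated in the source system. The package
follows the convention of the established plant target-prediction tools:
a wobble is *not* a mismatch for tier purposes (it pairs, weakly), but it
*is* penalized (0.5, versus 1.0 for a mismatch) in off-target scoring.
The engineered mismatch variants sidestep the question entirely: setting
the guide base equal to the opposing site base guarantees a pair that can
neither Watson–Crick pair nor wobble, for all four bases.

## Sensitivity tiers

`classify_sensitivity()` implements two deterministic rule sets over the
3'-terminal mismatch run:

| rule set | 0–1 | 2–3 | 4–5 | ≥6 |
|---|---|---|---|---|
| `syntasi_3prime` (default) | unaffected | diminished | abolished | abolished |
| `site_5prime` (0–3 unaffected) | unaffected | unaffected | diminished | abolished |

The first encodes the syn-tasiRNA observations this package is built
around; the second is the classical miRNA target-site rule (1–3 / 4–5 /
>6 mismatches at the site 5' end) kept for comparison. Both are monotone
by construction.

## Off-target scoring

`score_site()` and `scan_transcriptome()` use a TargetFinder-style
additive penalty: mismatch 1.0, G:U wobble 0.5, each doubled at guide
seed positions 2–13 (the region where mismatches are most deleterious).
The constants live in `tasitune_config()` and are design decisions: the
source system names the tool but not its constants. Scanning is gapless
over every window of the transcript sense strand; single-base bulges are
deliberately not implemented (the `bulge` constant is reserved and
enabling `offtarget.bulges` raises an error) — gapless scanning is
deterministic, fast, and sufficient for the 21-nt guides this package
designs. Ambiguity codes (N) score as mismatches. The default specificity
cutoff — a guide fails if any unintended transcript has a site scoring
≤ 4.0 — is a documented assumption mirroring the customary reporting
bound of the cited tool; no numeric cutoff is stated in the source
system. Only the sense strand is scanned by default (small RNAs target
mRNA); `antisense = TRUE` adds the other strand.

## Guide design heuristics

The source system delegates guide design to a published webtool whose
exact rule set is not restated; `design_guides()` therefore implements
documented, individually switchable approximations: guide position 1 = U,
position 19 = C, GC content within 30–60%, no homopolymer of 5 or more,
and no BsaI recognition site in the guide or its complement (a hard
requirement of the cloning chemistry, not a heuristic). Candidates
satisfying the enabled rules are screened and ranked by fewest heuristic
violations, then the largest worst-case off-target margin (the minimum
penalty score observed on any unintended transcript — higher is safer),
then the 5'-most site. Variants that fail the off-target re-screen are
reported with `offtarget_pass = FALSE` rather than dropped: the check is
surfaced, not silently enforced.

## Cloning model

The BsaI record is hard-coded with a config override: recognition GGTCTC,
cut offsets 1/5, 4-nt 5' overhangs. A cloning-ready "B/c" vector carries
two *inverted, outward-cutting* sites (GAGACC … GGTCTC on the plus
strand) inside the stuffer, so digestion excises both recognition sites
with the stuffer and the ligation product is seamless — re-digestion
finds nothing. For site starts q (minus) and p (plus), the released
fragment is `p − q + 12` bp; the package defines "cassette length" as
this released fragment, including both 4-nt overhang regions (whether the
printed 1461-bp figure counts the recognition sites or only the released
fragment is ambiguous in the source; the released-fragment convention is
fixed here and reproduced by the packaged fixture).

The insert-span rule: the duplex core always covers slots D2–D3 at
minimum and extends in 21-nt steps to the most distal occupied slot;
unoccupied core slots carry endogenous precursor filler (configurable in
principle — the source does not state whether real constructs use
endogenous sequence or neutral spacer; endogenous is the default and the
only shipped behavior). This reproduces the printed 46-nt oligo length
for all D2/D3 configurations and generalizes to 67/88-nt oligos for D4/D5
— a generalization that could not be checked against the supplementary
oligo table, which is not available here. The top oligo is 5'-TTTA +
core; the bottom is 5'-CCGA + reverse-complemented core; annealing leaves
the two 4-nt 5' extensions that match the digested vector ends
orientation-specifically, making ligation directional.

U→T conversion at the RNA/DNA boundary is explicit (`as_dna()`) and
logged by `assemble_precursor()` unless `quiet = TRUE`.

## The efficacy lattice

The model is deliberately ordinal, not quantitative: the relative
accumulation data behind it exist only as figure bar graphs, so no
regression is fitted. `efficacy_tier()` crosses the 4-level position
scale with the 3-level complementarity class, with `abolished` absorbing
position (8 of the 24 grid cells), and names (full, D2) `maximal` — the
recommended setting for maximal silencing being a fully complementary
guide (0–1 terminal mismatches) at 3'D2[+]. The combined scale in
`tier_levels()` orders full-complementarity settings above all diminished
ones; whether position and mismatch effects combine this way
quantitatively is untested in the source system (explicitly flagged there
as a possibility, the "two-module mode"), so the lattice treats them as
independent ordinal factors and each result row carries a plain-language
`rationale` saying exactly which factor drove it. `plan_settings()` is
the exact inverse over the 24-cell grid.

## Synthetic fixtures: what they do and do not establish

No real sequences ship with the package: the supplementary vector and
oligo tables of the source system are not redistributable here, so every
fixture is generated, seeded and labelled synthetic.

* `make_transcriptome()` draws uniform-random transcripts and can implant
  the perfect site of a chosen guide at stated coordinates. Real
  transcriptomes have codon bias, repeats and paralog families; uniform
  sequence makes chance near-hits (score ≤ 4) vanishingly rare, so a green
  off-target test establishes scanner *correctness* (it equals the
  brute-force oracle), not real-world specificity rates.
* `make_backbone_fixture()` builds a plasmid with the published *layout*
  — miR173 site, phasing register, inverted BsaI pair, TTTA/CCGA
  chemistry, 1461-bp default cassette — around random filler. The packaged
  `pENTR_AtTAS1c_D2_Bc_synthetic.fasta` is one such vector; its digestion
  releasing 1461 bp checks the digestion *model* against the printed
  cassette size on a fixture constructed to that size, not the Addgene
  plasmid itself.
* All randomness flows through `withr::with_seed`; identical seeds give
  byte-identical fixtures. Rejection sampling keeps random segments free
  of accidental BsaI sites (and the maximal-insert junction check makes
  all 15 position subsets assemble seamlessly); a user guide that would
  create a junction site still fails loudly at assembly, by design.

## Numerical and degenerate-input choices

Scores are sums of 0.5 steps, so equality comparisons are exact. Ranking
ties break deterministically (stable sorts; 5'-most site last). Empty
design results warn rather than error; empty transcriptomes, duplicate
ids, out-of-range positions, k_max outside 1..20, position 1 requests,
guides containing BsaI sites, tandem or inward-pointing BsaI pairs, and
swapped-overhang ligations all raise classed errors
(`tasitune_*_error`). A trailing partial slot is dropped by
`simulate_phasing()` — DCL4 products are measured, whole 21-mers.

## Known limitations

* No thermodynamic duplex energies, target accessibility or
  translational-repression modeling; the pairing model is purely
  positional.
* No bulged (gapped) off-target alignments.
* No secondary-structure validation of the AtMIR173 hairpin in the
  co-expression cassette variant; the fixture only guarantees it is
  BsaI-free, mirroring the published 2-nt site mutations.
* GenBank I/O is not available in the installed stack; vectors and
  constructs read/write FASTA plus a plain-text feature table instead.
* The ordinal tier model predicts rank order, not knockdown percentages.
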