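---
title: "Methods: genome-wide bHLH family analysis with bhlhfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide bHLH family analysis with bhlhfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bhlhfam)
```

# The problem

Basic helix-loop-helix (bHLH) proteins are one of the largest
transcription-factor superfamilies in plants. The family is defined by a
~56-residue domain: an N-terminal *basic region* (~17 residues, DNA
contact), two amphipathic helices, and a loop that varies both in length
and in sequence. Genome-wide family studies follow a stereotyped workflow
— census the family, classify predicted DNA binding, cut subfamilies from
a neighbor-joining tree, reconstruct the duplication history with Ka/Ks
and a molecular clock, and profile gene structure and expression. bhlhfam
implements that workflow as composable, seedable R functions with a
synthetic-data generator for every stage, so each step can be validated
against planted ground truth without any external download.

# Domain model and scanning

## The consensus profile

The domain is modelled as a per-position *allowed-residue* profile
(`load_profile()`): 56 reference positions split into `basic` (1–17),
`helix1` (18–32), `loop` (33–38) and `helix2` (39–56), with 19 positions
flagged *conserved* — 5 in the basic region, 5 in helix 1, 1 in the loop
and 8 in helix 2. Published supplementary consensus tables are not
shipped with their papers, so the default profile is a **synthetic
stand-in** assembled from the residues the field's literature names
explicitly (His/Lys-9, Glu-13, Arg-14, Gln-15, Arg-16, Arg-17, Gln-22,
Leu-27, Leu-54, Val-31) plus canonical plant-alignment positions for the
remaining conserved slots. Everything downstream treats the profile as
data: a replacement TSV reproduces any other published consensus.

A *mismatch* is a residue outside the allowed set at a conserved position
(a gap counts as a mismatch). Non-conserved positions are free. This is
the only reading under which the classical "nine mismatches allowed" rule
is meaningful: the budget is checked against the 19-residue conserved
consensus, and `scan_proteome(max_mismatch = 9)` accepts a protein when
its best window has at most nine mismatches.

## Matching with a variable loop

`align_to_profile()` searches exhaustively over all start positions and
all loop lengths from `loop_min = 5` to `loop_max = 25` residues: the
basic region and both helices are matched at fixed length, the loop
stretches. Positions after the loop therefore keep their profile
numbering regardless of the actual loop — this is how "Leu-54" in a
compact numbering and "Leu-73" in a long-loop species name the same
helix-2 leucine. Loop residues are mapped onto the six reference loop
indices from the loop's 5′ end; extra residues of long loops carry no
profile coordinate. The single conserved loop position sits at the first
loop index so it is mapped for every admissible loop length.

Ties are broken by smallest mismatch count, then smallest start
coordinate, then smallest loop length — the scan is a pure function of
the sequence. Exhaustive search is deliberate: proteins are short, the
optimum is exact, and the tests can plant domains at known coordinates.
One domain is reported per protein (the family convention).

## Physicochemical properties

`protein_properties()` reports length, molecular weight (average isotopic
residue masses + one water), GRAVY (mean Kyte–Doolittle hydropathy), pI,
and Asp+Glu / Arg+Lys counts. The pI is the unique root of the strictly
decreasing Henderson–Hasselbalch net-charge function on pH 0–14, found by
bisection to |charge| < 10⁻⁴, with a Bjellqvist-style pKa set. All three
constant tables ship as TSVs and are replaceable. `X` residues are
excluded from GRAVY, pI and mass with a warning.

# DNA-binding classification

`classify_binding()` applies the residue rules in a fixed order:

1. **basic_count < 6 ⇒ NON_DNA_BINDING.** The count is of *basic residues*
   (R/K/H) at basic-region positions. The literal reading of "fewer than
   six residues in the basic region" contradicts a ~17-residue basic
   region, so the structural-literature reading (basic residues) is the
   default; `mode = "literal"` implements the literal count for
   comparison. This rule precedes all sequence-specific flags: an HLH
   protein is non-binding even with a perfect Glu-13.
2. **Glu-13 ∧ Arg-16 ⇒ E-box recognition**; within those,
   **His/Lys-9 ∧ Arg-17 ⇒ G_BOX**, else **E_BOX_NON_G**.
3. otherwise **NON_E_BOX_BINDER** (basic region present, no E-box
   specificity).

His counts as basic for the count but only His/Lys satisfies position-9
recognition — two separate predicates. A gap at a labelled position makes
its flag false. `dimer_tetramer_flags()` reports Leu-27/Leu-54
(dimerization) and the Arg-14 ∧ Gln-15 ∧ Gln-22 triple (MYC-type
tetramer readiness). The four categories partition every accepted hit.

# Phylogeny and subfamilies

Domain hits are already aligned in profile coordinates, so the profile
mapping doubles as the multiple alignment. Distances are p-distances with
pairwise gap deletion (Poisson correction −ln(1−p) is available via
`model = "poisson"`); the tree is neighbor joining with the standard
Q-criterion. Q-ties are broken by the lexicographically smallest pair of
representative leaf labels, making the topology independent of input
order. Negative branch lengths are reported as computed, with a warning,
never clamped. The final three nodes are joined by the three-point
formulas, giving the conventional trifurcating unrooted representation.

`bootstrap_support()` resamples alignment columns with replacement
(default 1000 replicates, seedable) and annotates each internal node with
the percentage of replicates containing its bipartition.
`extract_subfamilies()` cuts maximal clades whose support is **strictly
greater than** the threshold (default 50, honouring the ">50" convention:
support exactly 50 does not found a subfamily). Subfamily labels are
traversal-deterministic (`S1`, `S2`, ...), not matched to any published
1–24 numbering.

# Duplication, Ka/Ks and dating

*Tandem* duplicates are family members adjacent in the **full** gene
order of a chromosome — rank difference one, so a single intervening gene
of any kind breaks the call — whose global protein identity reaches
`identity_min` (default 0.4; published pipelines "checked manually", so
the threshold is exposed). *Segmental* duplicates are family pairs lying
in the two regions of one synteny block; containment uses the gene start
coordinate so straddlers resolve deterministically, and a pair already
called tandem is not re-flagged.

`ng86_kaks()` implements Nei–Gojobori (1986) from scratch:

* synonymous site fraction per codon from the universal code, averaged
  over the two sequences. Changes that create a stop codon are counted as
  nonsynonymous rather than excluded, so `s_sites + n_sites = 3 ×
  codons` holds exactly — this keeps the site decomposition a partition,
  and the hand-computed ten-codon example (s_sites = 28/3, Ks ≈ 0.1156)
  verifies under it;
* differences averaged over all minimal mutational pathways between the
  codons, pathways through stop codons excluded (NG86 convention), with
  equal weights; if every pathway passes through a stop, all pathways are
  used as a fallback rather than dropping the codon;
* Jukes–Cantor correction d = −3/4·ln(1 − 4p/3) applied to both
  proportions. A proportion ≥ 3/4 leaves the rate `NA` (saturated);
  the ratio is `NA` when Ks is zero or undefined.

The test suite carries a second, independently written brute-force NG86
oracle (explicit loops, recursive pathway enumeration) and requires
agreement to 10⁻¹⁰ on random codon pairs.

Dating uses T = Ks/(2λ). λ is essentially never printed in family
papers; the default 6.5 × 10⁻⁹ synonymous substitutions/site/year is the
grass-standard clock, consistent with the Mya values such papers report,
and every dated output records the λ used.

# Gene structure, promoters, expression

`infer_gene_structure()` chains exact matches of the CDS against genomic
DNA: longest match first, then an intron (minimum 4 bp), with
backtracking. Canonical GT..AG parses on either strand are exhausted
before any non-canonical parse is considered, and the minus strand is
handled by reverse complement with coordinates mapped back. Introns are
mapped onto the domain as (profile position, phase): an intron is
assigned to the codon it interrupts (phase 1/2) or the codon immediately
3′ of it (phase 0). Pattern typing compares the *position set* against a
catalog; phases are recorded but compared only when the catalog specifies
them, since published figures do not state whether phases distinguish
patterns. Only pattern IV (His-9, Val-31) is published verbatim, so the
shipped catalog contains just IV; `discover_patterns()` clusters
identical position sets and labels them by frequency rank for de novo
catalogs. A gene with no intron inside the domain is "intronless" even if
it has introns elsewhere; an intron landing on a loop residue without a
profile coordinate yields "novel".

Promoters are the 1500 bp 5′ of the gene start on the coding strand
(reverse-complemented for minus-strand genes, truncated at chromosome
edges). `scan_promoter()` matches IUPAC patterns on both strands,
overlaps allowed. The default dictionary ships only the two elements with
public literal definitions (TGACG-motif = `TGACG`, DRE core = `RCCGAC`);
ABRE, TCA-element and HSE matrices are database-internal and must be
user-supplied.

Expression support is deliberately thin: log₂(x + pseudocount) transforms
(pseudocount 1 by default) and 2^(−ΔΔCt) fold changes. Normalisation and
differential testing are out of scope.

# Synthetic data: what a green test establishes

Each generator emits standard formats plus a truth ledger and is
byte-deterministic under a fixed seed.

* `gen_proteome()` plants consensus-derived domains mutated at exactly
  *k* conserved positions (mutations to disallowed residues). Both
  plantings and decoys are verified by rejection sampling: a planting
  within the budget must be recovered at its exact window and mismatch
  count, a planting beyond the budget must have no window within the
  budget, and decoys must exceed it. The ledger is therefore exact by
  construction, which is what lets recovery tests demand 100%.
* `gen_codon_pairs()` evolves an ancestor along two branches by uniform
  single-nucleotide proposals accepted with probability 1 (synonymous) or
  ω (nonsynonymous), stop-creating changes rejected. Equal proposal rates
  mean the NG86 estimator's assumptions hold exactly; transition bias is
  deliberately absent. Proposal counts are sized so the pair's expected
  synonymous divergence is `expected_ks`; requests near JC saturation are
  refused.
* `gen_gene_models()` builds genes with GT..AG introns at requested
  (position, phase) coordinates, intron interiors free of internal AG,
  and re-runs the inference during generation, resampling flanks on the
  rare coincidental alternative parse — so "recovered exactly" is a
  statement about the algorithm, not about luck.
* `gen_duplication_layout()` plants adjacent tandem pairs, block-paired
  segmental pairs, lone family genes and filler genes across
  chromosomes; family proteins share the consensus domain with light
  mutations so identity filters pass.
* `gen_expression()` draws group-structured means with Gaussian noise and
  back-computes qPCR Ct values from planted fold changes.

None of the generators mimic real genome base composition, repeat
content, array noise structure, or the residue covariation of real
domains. A green recovery test establishes that the implementation
computes its stated function, not that the census of any particular
genome is reproduced — real-genome censuses additionally depend on the
annotation release and on the exact consensus table used.

# Numerical and design choices

* All internal coordinates are 1-based inclusive; 0-based half-open
  appears only at BED boundaries.
* GFF3 genes with several transcripts keep the longest-CDS transcript
  (one model per locus, deterministic).
* The NJ Q-tie tolerance is 10⁻¹² relative; branch lengths are written
  at full double precision.
* `expected_ks` above 1.5 is refused by the codon simulator (comfortably
  below the p = 3/4 JC pole, where the estimator is no longer usable).
* Selection classes: ratio < 1 purifying, > 1 positive, exactly 1
  neutral, `NA` undefined.
* The pipeline caches at whole-run granularity keyed by an md5 config
  hash: a changed configuration is never served from cache.

# Known limitations

* The scan is consensus matching, not an HMM; the acceptance budget
  weighs all conserved positions equally.
* NJ only — no ML/Bayesian inference; subfamily counts on real data are
  sensitive to the distance model, which published "default parameters"
  rarely pin down.
* Ka/Ks is NG86 only; published pair values computed with unnamed
  calculators may differ within method tolerance.
* Synteny blocks are inputs, not computed; no collinearity detection.
* Multi-domain proteins are not modelled (best hit only).
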