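---
title: "Mining full-length endogenous betaretroviruses: models and methods"
author: "proviscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining full-length endogenous betaretroviruses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proviscan)
```

# The problem

Endogenous retroviruses (ERVs) are proviruses fixed in a host germline: a
full-length element is the integrated DNA form
`5'LTR - PBS - gag - pro - pol - env - PPT - 3'LTR`, flanked by a short
target-site duplication (TSD) of host sequence created at integration.
Betaretroviruses (beta-ERVs) additionally carry a dUTPase domain inside
*pro*. proviscan re-implements, as a tested and reusable pipeline, the
desk-scale procedure used to discover and characterize such elements in
genome assemblies and transcriptome contigs:

1. **Translated homology search.** Reference Gag/Pol/Env proteins are
   aligned against all six reading frames of every scaffold with an exact
   affine-gap Smith-Waterman (BLOSUM62, gap existence 11 / extension 1) and
   hits are assessed with Karlin-Altschul statistics,
   $E = K m n e^{-\lambda S}$, at a cutoff of $10^{-10}$.
2. **Three-gene intersection.** Scaffolds hit by *gag*, *pol* and *env* in
   gene order on one strand within 15 kb become candidate loci.
3. **Delineation.** The locus is aligned against itself (match +1,
   mismatch -3, gap 5/2) to find the flanking LTR direct-repeat pair; the
   4-nt TSD and the polypurine tract (PPT) immediately 5' of the 3' LTR
   are then called.
4. **Annotation.** ORFs (>= 100 codons), the tRNA primer-binding site
   (PBS), enzymatic and structural motifs (protease DxG, RT DDD, integrase
   DDE, Gag MHR and CCHC zinc knuckles, the dUTPase blocks), and per-gene
   intact/defective/unknown states.
5. **Dating.** The two LTRs are identical at integration and diverge
   neutrally afterwards, so $T = (D/R)/2$ converts their p-distance $D$
   into an integration age given a host substitution rate $R$.
6. **Classification.** A rule set over the annotated features assigns each
   provirus to one of eight betaretroviral sub-groups.

Because the real assemblies and SRA transcriptomes are outside desk scale,
the package ships a first-class synthetic-genome module that plants decayed
proviruses with complete ground truth; every stage of the pipeline is
validated against that truth channel.

# The synthetic world

`make_background()` draws i.i.d. nucleotides at a target GC content
(default 0.42, mammalian-like) and can insert N-runs emulating the
non-sequenced regions (NSRs) of low-coverage assemblies.
`betaretro_template()` builds a provirus for one of the eight sub-groups
from the packaged reference panel; `build_provirus()` assembles it with two
exactly identical LTRs; `plant()` inserts it behind a duplicated 4-nt
target site and applies neutral decay.

**Decay model.** Each element independently accumulates
$\mathrm{Poisson}(R \cdot T)$ substitutions per site (uniform replacement,
Jukes-Cantor style — the simplest neutral model matching an uncorrected
p-distance estimator), plus indels at 5% of the substitution rate with
lengths uniform on 1-3 nt. No published indel model exists for
post-integration proviral decay, so the rate and length range were fixed
once at values that generate realistic frameshift/defective gene states
without destroying delineation; both are exposed (and flagged as a
stand-in) in `decay_params()`. Substitution positions are recorded before indels are
applied, so the truth channel stores every event in original element
coordinates. The expected LTR-pair divergence is $2RT$ (both LTRs mutate
independently); back-mutation bias at the divergences involved
($D \le 0.06$) is under 2% and far inside the clock noise.

**TSDs** are drawn uniformly from non-homopolymer 4-mers (homopolymers
would produce spurious flank matches in tests). **LTR termini** are the
canonical `TG ... CA` inverted dinucleotides of retroviral LTRs; the
delineation stage uses them (see below), so the generator plants them.

**What the generator does not emulate:** sequencing error, read-level
artifacts, nested or solo-LTR elements, segmental duplications, gene
conversion between LTRs, and host repeat families. A green recovery test
therefore establishes correctness of the pipeline's logic on clean neutral
decay, not robustness to assembly artifacts.

# The reference panel is synthetic

The original searches used extant betaretroviral proteins (MMTV, MPMV,
JSRV, SRV, SMR) and a mammalian lysine-tRNA library. Those sequences
cannot be redistributed or downloaded here, so the packaged panel
(`inst/extdata/*.synthetic.*`) consists of deterministic pseudo-proteins
that reproduce the *architecture* the method relies on:

- five Pol lineage clusters (HERVK, BAT_EARLY, MICROBAT_DIV, TYPE_B,
  TYPE_D) at roughly 65-75% pairwise identity — matching the 64-76% Pol
  similarity range reported for the genus — used as the
  phylogenetic-placement proxy;
- distinct beta and gamma Env families (the gamma family independent, as
  the gammaretroviral *env* of MPMV-like Type D elements is);
- motif blocks at fixed reference positions (MHR, two CCHC knuckles, the
  dUTPase blocks, DxG, the RT and IN catalytic acidic residues) that are
  never mutated when deriving variants;
- three lysine tRNA 3'-end 18-mers with Lys1_2 and Lys3 differing at five
  positions, so a PBS carrying two mutations still separates the two
  classes with the >= 2-match margin the caller requires, and never
  miscalls at zero mutations.

`generate_reference_panel()` regenerates the panel bit-identically; a test
asserts the packaged files equal the regeneration.

# Numerical and algorithmic choices

**Coordinates.** 1-based inclusive everywhere (the R, IRanges and GFF3
convention). Strand-aware conversion happens in the search module; minus
strand loci are processed on the reverse complement and reported back in
forward scaffold coordinates.

**Smith-Waterman.** Exact full dynamic programming, no word seeding: at
desk scale (tens of scaffolds) exactness is affordable and testable, and
the heuristic layer of BLAST is not this method's contribution. Gap of
length $k$ costs $11 + k$. Ties are broken deterministically: the maximal
cell with the smallest end coordinates wins and the traceback prefers
substitutions over gaps. X (and translated N) scores 0 against everything,
so NSRs neither attract nor repel alignments. $K = 0.041$ and
$\lambda = 0.267$ default to the published gapped BLOSUM62 11/1 constants
and are configurable; the shuffle-null test checks the statistic's
discrimination rather than the constants themselves. Additional hits per
frame are recovered by masking accepted spans to X and re-aligning.

**Low-complexity filter.** A sliding-window entropy mask (12 residues,
2.2 bits) stands in for SEG; on for searches, off for the repeat finder,
mirroring the original settings.

**LTR boundaries.** Self-alignment ends are fuzzy by a few nucleotides
(chance matches in the flanks, local-alignment trimming of decayed LTR
tails). Refinement proceeds in three steps: (i) ungapped outward extension
while columns match exactly; (ii) inner edges snap to the canonical
`CA`/`TG` termini within +/-3 nt, each LTR copy independently (an indel
near one copy's edge decouples the two); (iii) the outer corners are
chosen by a small joint search (+/-12 nt) scored by the TG/CA termini plus
an exact 4-nt TSD in the immediate flanks — integration evidence, the same
signal dedicated LTR annotators use — with an extra point when both
termini agree so that a chance flank 4-mer never outranks an intact
`TG...CA` pair. Finally, if the two copies' lengths still disagree by
more than 4 nt, the TSD-validated copy's length bounds the fuzzy edge,
accepted only when the reconciled segment keeps >= 50% cross-copy
identity. LTR-pair acceptance: identity >= 80% (matches over alignment
columns) and lengths within [250, 1500] nt, covering the observed
361-1265 nt range with margin.

**TSD.** Exact 4/4 match immediately outside both LTRs; no mismatch
tolerance (the reported TSDs are exact 4-mers). N in a flank gives
"masked", mirroring elements whose 5' LTRs sit in NSRs.

**PPT.** Longest window with purine fraction >= 0.85 ending within 5 nt of
the 3' LTR; ties prefer longer, then closer. Verified against an
exhaustive window oracle.

**Gene states.** A frameshift-aware protein-to-DNA dynamic program
(fastx-style: a residue consumes 3 nt; 2-nt or 4-nt consumptions model
frameshifts at a penalty of 20; internal stop codons pass at -6 but are
recorded) aligns each gene region to its reference protein, global in the
protein and local in the DNA. `intact` requires a full-length alignment
with zero frameshift and zero premature-stop events; in-frame (3n) indels
do not break intactness, matching how a shortened but uninterrupted gene
is still reported intact. Event positions are codon-resolution: when
neighbouring bases match, an indel cannot be placed more precisely than
the codon in which the irregular consumption occurs, so truth-recovery
tests assert positions within +/-3 nt.

**Motifs** are anchored by alignment, not free-floating regular
expressions: the gene translation is aligned to the reference, each
block's reference anchor is mapped through the alignment, and the
fixed-length pattern is checked in a +/-2 residue window. A motif is
present only when all of its blocks match; a failed reference alignment
yields "not assessable". The dUTPase signature uses five short conserved
blocks as a stand-in for a profile-HMM domain search (out of scope).

**ORFs.** ATG-to-stop spans of >= 100 codons (the cutoff chosen to limit
incidental non-coding ORFs), one per stop per frame; frames are never
stitched across frameshifts. Placement is classified against the provirus
map (`pre-gag`, `within-core-alt-frame`, `post-env`, `in-LTR`), and the
census deduplicates in-LTR ORFs across the two LTR copies.

**Dating.** $D$ is an uncorrected p-distance over a global alignment of
the two LTRs with gap and N columns excluded (the method statement says
"number of differences per site", not a model-corrected distance; it is
silent on gaps, so their exclusion is stated here). The division by 2
reflects independent post-integration mutation of both LTRs. Rates are
configuration constants, not estimates — Bayesian rate estimation is out
of scope — and the defaults (megabat $4.0\times10^{-10}$, microbat
$9.52\times10^{-10}$ subs/site/year) are back-calculated from published
divergence/age pairs. Ages are reported in Myr rounded half-up to one
decimal for report parity (R's `round()` is banker's rounding and would
print 36.2 where the published table prints 36.3); the raw value is kept.
A single LTR pair of length $L$ has clock noise
$\mathrm{sd}(T) \approx \sqrt{T/(2RL)}$ — several Myr for a 400-nt LTR —
which is why single-element ages are noisy even when the mean over many
elements converges (the round-trip test checks the mean over 200 plants to
5%).

**Classification.** Phylogenetic placement is proxied by the best Pol
alignment score against the packaged cluster references (maximum-likelihood
trees are out of scope, and group membership is ultimately anchored to
named representatives). The rules fire in order: a gammaretroviral *env*
dominates everything (group VIII, with a trace warning on conflicting
features); HERVK proxy + Lys1_2 gives I; the early bat cluster gives II;
the divergent microbat cluster + Lys3 gives III; LysAlt + Type B gives IV;
long LTR (>= 1000 nt) + Lys3 + Type B gives V; short LTR (<= 600 nt) +
Lys1_2 + beta *env* gives VI; short LTR + Lys3 + beta *env* gives VII.
When the two bat Pol clusters score within 2% of each other the proxy
cannot separate groups II and III; the classifier reports "II-or-III"
rather than guessing (tree topology with bootstrap support would be
needed). Every label carries its rule trace.

**Transcript merging** requires a perfect (100% identity) suffix/prefix
overlap of >= 100 nt, with optional end trims exposed as explicit
parameters (the published account trims 245 and 401 nt at the overlap
extremities without fully specifying the arithmetic, so no intent is
guessed); more than one qualifying overlap is an ambiguity error — the
recombination caveat. The generator's `make_transcripts()` requires the
fragment lengths and overlap to tile the source exactly, mirroring
5,433 + 5,830 - 3,152 = 8,111.

# A worked demonstration

```{r demo, eval = FALSE}
report <- run_pipeline(run_config(seed = 1))
summarize(report)$ages
#>                     name divergence age_myr group
#> 1 scaffold_01:2245-11558      0.006     6.9     V
#> 2 scaffold_02:3752-11555      0.011    13.5   VII
#> 3   scaffold_03:564-8489      0.007     8.8  VIII
```

Three proviruses (groups V, VII, VIII; true ages 10, 15 and 5 Myr under
the megabat rate) are planted, recovered, delineated, dated and
classified. The per-element clock noise discussed above explains the
spread of the age estimates around their truths.

# Known limitations

- The phylogenetic proxy is a similarity score, not a tree; deep or
  recombinant elements can be ambiguous (exposed as "II-or-III" or
  "unclassified", never guessed).
- Dating assumes no gene conversion between LTRs; conversion would bias
  ages downward and is reported only as a caveat.
- TSD calling is exact-match; a mutated TSD (or a truncated LTR) yields
  "none", as in the published census.
- The repeat finder reports architecture-level direct/inverted repeats and
  flags CTE-like ("TBE candidate") direct repeats downstream of *env*; it
  does not model RNA secondary structure.
- No nested/solo-LTR resolution, no Pfam/HMM search, no promoter or
  NLS/NES prediction (external trained tools in the original workflow).
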