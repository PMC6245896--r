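---
title: "Methods and design notes for anuramp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for anuramp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`anuramp` re-implements, at desk scale, a targeted amplicon-sequencing
strategy for the parallel discovery of anuran antimicrobial peptides
(AMPs). The biological premise is the tripartite architecture of anuran
AMP precursors: a highly conserved, secretion-targeting signal peptide;
a negatively charged (acidic) propeptide ending at a Lys-Arg (KR)
processing site; and a hypervariable, usually cationic mature peptide,
often carrying a C-terminal amidation signal (Gly optionally followed
by basic residues) and, in Ranidae, a C-terminal disulfide loop known
as the rana-box. Because the signal-peptide coding region is conserved
within a family while the mature region is not, a degenerate forward
primer anchored in the signal region, combined with a poly-dT reverse
primer annealing to the mRNA poly-A tail (a 3'-RACE layout), amplifies
the whole family of mature-peptide-coding transcripts in one reaction.

The package covers primer design from alignments, read simulation, read
processing and assembly, homology screening, precursor annotation, and
physicochemical characterization. Wet-lab steps (RNA extraction, PCR,
sequencing chemistry) and third-party tools the original workflow used
(cd-hit, HMMER, BLAST, CLC Genomics Workbench, Trinity, Muscle) are out
of scope; where their behaviour matters, a transparent in-package
equivalent is provided and tested against independent oracles.

# Primer design

Input is a gapped nucleotide alignment of signal-peptide (or, for
longer precursors, propeptide) coding regions, one per taxonomic
family; producing the alignment itself is the user's job (any MSA tool
works). Sequences may first be grouped with `cluster_by_identity()`, a
greedy longest-first clustering with a global-identity threshold
(default 0.8, as in the cd-hit step it replaces). Identity here is
matches / alignment columns under a Needleman-Wunsch alignment with
match +1, mismatch −1, gap −1; among optimal-score alignments the one
maximizing matches and then minimizing columns defines the value, so
the quantity is traceback-independent. cd-hit's internal definition
differs slightly; only the tool and threshold were specified upstream,
so the simplest reproducible definition is used.

`scan_windows()` slides a 20-column window (`window_len`, nt) across
the alignment and keeps gap-free windows with at most 3 polymorphic
columns (`max_polymorphic`). A column is polymorphic when at least two
distinct bases each exceed `minor_freq_floor` (default 0: any second
observed base counts; the floor exists to tolerate sequencing noise
when alignments come from assembled contigs). Each window's consensus
replaces polymorphic columns with the minimal IUPAC code covering the
observed bases; the primer's degeneracy is the product of per-position
expansion sizes. Note the published primer panel itself contains one
primer with four degenerate positions, so the limit of three is treated
as a configurable budget, not a hard law.

Window choice (`pick_primer_position()`) has two modes: `signal_any`
(fewest polymorphic columns, ties to leftmost) for short signal-peptide
regions where position barely affects amplicon size, and
`propeptide_3prime` (largest start coordinate within the degeneracy
budget) for long precursors where the primer must sit as close as
possible to the 3' end of the propeptide-coding region to keep the
amplicon sequenceable. `attach_tail()` prepends the fixed 5' tail used
for barcode attachment in a secondary outer amplification.

`predict_amplicons()` matches the gene-specific part IUPAC-aware and
ungapped against poly-A-tailed templates (best site = fewest
mismatches, ties leftmost, accepted within `max_mismatches`, default
2), and reports product length = distance from binding-site start to
the template 3' end plus both tail lengths, flagging products over
`platform_max` (default 450 nt, the read-length ceiling of the targeted
flow-based sequencer; the workflow this mirrors had to exclude a
Bombinatoridae library with ~573-nt products for exactly this reason).
Annealing thermodynamics are not modelled — specificity was controlled
experimentally by touch-down PCR in the original protocol, which is out
of scope.

# Read processing and assembly

Quality trimming implements the modified-Mott algorithm: each base gets
weight `limit − 10^(−Q/10)` (trimming limit default 0.05) and the
retained segment maximizes the running sum; the commercial workbench
used upstream documents this meaning for its "trimming limit", which
the tool itself never defines. Adapters are then clipped by semi-global
alignment (≤10% errors; a match in the 5' half removes everything
upstream, in the 3' half everything downstream), leading/trailing `N`
are removed, and reads shorter than `min_length` (default 100 nt) are
discarded. Demultiplexing assigns reads by 10-nt barcode prefix within
one mismatch, requiring pairwise barcode distances above twice the
tolerance.

Assembly is greedy overlap-layout-consensus. An overlap is an ungapped
placement of one contig at a non-negative offset along another (both
orientations): this subsumes the classic suffix-prefix dovetail and,
importantly, containment — amplicon reads share their 5' start, so
containment is the common case. Qualifying overlaps span at least
`min_overlap` (50 nt) at identity at least `min_overlap_identity`
(0.95); the pair with the most matching columns merges first, and
per-column base counts accumulate so the consensus is the column
majority with ties kept at the earlier-created contig's base. The
assembler is deliberately simple (no string graph, no
homopolymer-aware alignment): amplicon libraries are short and deep,
and every step is testable against construction. Contigs supported by
fewer than 3 reads are discarded (`min_support`), reads are re-mapped
semi-globally (unit-cost edit distance) to their best contig, and
contigs whose fraction of polymorphic columns (minor-allele frequency ≥
`polymorphism_floor` = 0.2) reaches `flag_rate` (0.02) are re-assembled
from their own reads at `stringent_identity` (0.99) to separate
collapsed variants. The stringency values quantify a qualitative
description in the source protocol and are defaults, not claims of
equivalence with the commercial assembler.

# Homology screening

Two screens stand in for the HMMER and BLAST gates of the original
pipeline, both gated at significance 0.05. The profile screen builds a
position-specific scoring model from a protein alignment (pseudocounted
column frequencies, log-odds base 2 against a uniform or supplied
background, columns with >50% gaps dropped) and scores each translated
peptide's best window; significance is empirical — the fraction of
residue-shuffled versions scoring at least as high — which reproduces
the gating behaviour without insert/delete states. The translated
search runs Smith-Waterman with affine gaps (BLOSUM62, gap open 11 /
extend 1, the BLAST defaults, since none were specified upstream) on
all six frames split at stop codons, and converts scores to E-values by
the Karlin-Altschul approximation `E = K·m·n·exp(−λS)` with `m` the
total translated query length across frames — using the whole search
space keeps the best-of-many selection calibrated, which a per-segment
`m` does not (verified by simulation in the test suite). The packaged
λ = 0.267, K = 0.041 are the published gapped constants for
BLOSUM62-11/1; `karlin_lambda()` can derive an ungapped λ for other
matrices. Numerical equivalence with HMMER/BLAST E-values is not
attainable and not claimed; only the 0.05 gate is reproduced.

# Precursor annotation

Annotation calls ORFs in all six frames (0-based half-open coordinates
on the forward strand; strand explicit). The precursor is the longest
ORF that yields a valid cleavage call — assembled contigs have
arbitrary orientation, and the reverse strand of a poly-A tail
translates to Phe runs that can fake long spurious ORFs, so the single
longest ORF is not reliable; among valid candidates, those with the
expected acidic propeptide take precedence over cationic-propeptide
calls regardless of length.

Cleavage follows the field's description — remove everything
N-terminal to the basic Lys-Arg site — operationalized as the *last*
KR whose downstream segment has non-negative net charge: anuran
precursors can contain internal KR pairs, and requiring a cationic
downstream segment prevents premature cleavage. Both choices are
configurable (`first_kr`, `accept_kk_rr`). The signal peptide defaults
to the N-terminal 22 residues, typical of anuran precursors, when no
external boundary is available. C-terminal amidation (strip a trailing
`G[KR]*` and flag the preceding residue amidated) is an explicit,
opt-in transformation and never silent, because reported sequence
tables are inconsistent about whether the signal is retained; the
function is idempotent on an already-amidated peptide. The rana-box
detector requires two Cys separated by 3–5 loop residues, both within
the C-terminal 10, with a basic residue in the loop.

Novelty tiers partition every peptide exactly once by best-hit identity
and query coverage: `known_identical` (100% identity, coverage ≥ 70%),
`identical_low_cover` (100% identity, coverage < 70%),
`similar_81_99`, `below_80`, and `novel_no_hit` (no hit below the
E-value gate). Identity is banded after rounding half away from zero.
The eight-class grouping reconstructs a manual classification as an
ordered, fully user-replaceable rule list over features (rana-box,
cysteine count, charge, mean hydrophobicity, length, and a Chou-Fasman
helix-propensity mean standing in for secondary-structure prediction);
class 8 is the explicit fallback. The shipped rules are a plausible
reconstruction, not canon.

# Physicochemical descriptors

Net charge uses the convention `(#K + #R) − (#D + #E) + 1` — basic and
acidic side chains plus the free N-terminal amine, with His, Cys and
the C-terminus neutral. No convention was stated where the reference
values were printed; this rule was recovered by solving against all 29
printed charges and is locked by tests (a pH-7 Henderson-Hasselbalch
estimate is available behind a flag). Mean hydrophobicity is the
arithmetic mean of per-residue values on the packaged consensus scale
(±10-normalized; Phe +10.0 most hydrophobic, Arg −10.0 least). The
exact numeric scale lives in a reference that is not reachable offline,
so the packaged values were recovered by solving the linear system the
29 printed (sequence, mean) pairs define — the system has full rank 20
with residuals below 5×10⁻⁴ and the solution rounds cleanly to one
decimal, so it is the unique one-decimal scale consistent with the
printed table. Kyte-Doolittle ships as an alternative. Molecular
weight sums average residue masses plus one water (18.015 Da), with
−0.985 Da for a C-terminal amide; both printed reference masses
reproduce to one decimal.

# Synthetic data

The generator states a world matching the described precursor biology:
per locus, a start codon plus a signal-peptide consensus (66 nt
encoding the canonical ranid signal MFTLKKSLLLLFFLGTINLSLC, so that the
22-residue signal default and the published primer sequences are
mutually consistent; the per-locus substitution rate defaults to 0.03)
— an acidic propeptide (composition from {D,E,A,S,L,Q}, acidic count
fixed by a charge target of −4) — `AAACGT`-encoded KR — a cationic
mature region (15–30 residues, charge target +3 via K/R placement,
rana-box probability 0.3, amidation probability 0.4) — stop — a 3' UTR
of 50–150 nt (hard bound < 200, as observed for these transcripts) —
and a 25-nt poly-A tail. Matures are redrawn if they contain an
internal KR or a spurious `G[KR]*` suffix, which would make exact
ground-truth recovery ill-posed rather than hard. Reads follow the
library layout (barcode, forward tail, insert through the poly-A,
reverse-complemented reverse tail) as amplicon *prefixes* with a
truncated-normal length model capped at 450 nt, per-base substitutions
(default 0.005), homopolymer-run ±1 length errors (default 0.005 per
run of length ≥ 2, a crude stand-in for flow-based error structure),
and a decreasing Phred profile. Everything is deterministic under the
spec seed.

What a green end-to-end test establishes: that trimming, assembly,
screening and annotation jointly recover ≥ 90% of manifest mature
peptides exactly under the stated error model. What it does not
establish: performance on real flowgram error structure (no flow-signal
simulation), chimeras, expression-level skew (the source protocol
itself warns its output is qualitative), or primer-template mismatch
dynamics under touch-down PCR.

# Numerical and degenerate-input choices

Degenerate codons translate to `X` unless every expansion agrees —
conservative, and harmless because only primers carry degenerate bases
and primers are never translated. Ties in `longest_orf` break by frame
order `+1,+2,+3,−1,−2,−3`, then leftmost in scanning direction.
Assembly merge ties prefer the longer overlap, then lower node indices;
consensus ties keep the earlier-created contig's base. The Smith-
Waterman traceback prefers diagonal, then gap-in-subject, then
gap-in-query. Empty inputs return empty results (not errors) wherever
that is a normal outcome: empty FASTQ gives an all-zero summary with a
warning; a contig without a KR site is flagged, not dropped silently.

# Known limitations

Clustering identity, gap parameters and Karlin-Altschul constants are
reasonable defaults, not fitted to the upstream tools; absolute E-values
differ from BLAST's. Read mapping is plain edit distance, so dense
homopolymer errors can depress coverage counts near run boundaries.
The greedy assembler can emit low-support truncation variants alongside
the main contig (they are collapsed by the support filter and the
on-target summary, but appear in the contig table). The eight-class
rules and the 22-residue signal default are reconstructions exposed as
configuration, and should be re-examined before use on non-anuran
families.
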