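---
title: "Mining bovine ultralong CDRH3 for knob domains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining bovine ultralong CDRH3 for knob domains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knobminer)
```

## The biological problem

Domesticated cattle assemble their heavy-chain repertoire from a small
set of gene segments — roughly 10 V, 10 D and 4 J — against 55 x 23 x 6
in humans (`theoreticalDiversity(55, 23, 6)` = 7,590 combinations).
They compensate with heavy somatic hypermutation (SHM) and with a unique
structural invention: the *ultralong* CDRH3, in which an extended
β-ribbon stalk presents a small, disulphide-stapled "knob" domain. The
knob core is encoded by one germline D segment (IGHD8-2) whose peptide
carries four cysteines and is rich in glycine, tyrosine and serine —
residues one nucleotide change away from a cysteine codon, so SHM keeps
minting new disulphide staples. Because antigen binding can reside
entirely in the knob, sequencing an antigen-enriched CDRH3 amplicon
library and excising the knobs yields affinity-matured, cysteine-rich
peptide binders of 3–6 kDa.

knobminer implements that discovery pipeline end to end, together with a
ground-truthed synthetic data generator that makes every stage testable
without sequencing data. This vignette records the models, the tunable
parameters, the numerical choices, and what the tests do and do not
demonstrate.

## The synthetic repertoire generator

The generator is first-class, tested code, not a fixture. It emulates:

* **Amplicon architecture.** Each read is
  `A-adaptor + 8-nt barcode + C + forward primer + CDRH3 + framework-4
  locus + trP1 adaptor`. The forward primer (degenerate,
  `GGACTCGGCCACMTAYTACTG`) translates to the framework-3 motif `DSATYY`;
  IUPAC positions are expanded uniformly at random per read, because a
  primer pool is a mixture of the concrete expansions. A structural
  consequence we model deliberately: the primer's final two bases form
  the first two bases of the first CDRH3 codon, so every CDRH3 begins
  with the conserved junction cysteine (codon `TG`T/`TG`C) and those two
  bases are primer-clamped — the generator never mutates them, exactly as
  a PCR primer overwrites its annealing site.
* **Germline segments.** The bundled `defaultGermlineSet()` is a
  synthetic stand-in (real bovine germline nucleotide sequences are not
  bundled): three short V tails, three regular D segments, a 29-residue
  knob core with exactly four cysteines in a Gly/Tyr/Ser-rich context,
  three J segments (one bearing a `VAYVYIW` descending-stalk motif), and
  a 15-nt duplication unit (`TTVHQ`) standing in for the duplicated
  V-gene tail that marks ultralong rearrangements. Real germlines can be
  substituted from annotated FASTA via `readGermlineSet()`.
* **Clone model.** A clone is ultralong with probability
  `ultralongFraction` (default 0.10, the frequency reported for naive
  bovine repertoires; antigen-selected pools can run lower). Ultralong
  clones are `V + 2x duplication unit + knob core + stalk-bearing J`
  (147 nt with the bundled segments); regular clones are `V + D + J`
  (42–54 nt). The >90 bp length threshold therefore separates the two
  classes with a wide margin, as it does in real data. Copy numbers are
  `1 + Geometric(p = 0.3)` (mean ≈ 3.3) — a modest right-skewed
  clone-size law; real campaigns' size distributions are not
  published, so the law is a modelling choice.
* **SHM model.** Independent per-site substitutions at `shmRate`
  (default 0.01/nt, a mid-range mutational load for a post-immunisation
  IgG repertoire). At Gly/Tyr/Ser codons, a substitution producing
  TGT/TGC receives weight `cysBias` (default 5) against 1 for the other
  targets — the single-nucleotide cysteine-conversion mechanism. Even
  cysteine parity then *emerges*: the core starts at four (even)
  cysteines, parity flips require an odd number of rare gain/loss events,
  and the no-event term dominates, so a 10,000-clone draw shows even
  counts far more often than odd (a property the suite asserts).
  Clones whose mutated CDRH3 gains a stop codon or an anchor motif are
  resampled: nonproductive rearrangements are not observed in IgG mRNA.
* **Planted truth.** Knob spans are planted from privileged knowledge:
  substitutions preserve coordinates, so the generator knows exactly
  where the core's cysteines sit. The span starts one residue before the
  first core cysteine and ends before the first aromatic-initial
  aromatic/aliphatic alternation after the last core cysteine, evaluated
  on the final mutated sequence. Annotation must *rediscover* the
  cysteine positions by alignment — that, not the shared boundary
  arithmetic, is what recovery tests exercise.
* **Error channel.** Substitutions at `subRate`; indels at `indelRate`,
  multiplied by 5 inside homopolymer runs (the characteristic
  flow-sequencing failure mode; the magnitude is our choice, stated
  here, as no instrument profile is bundled). Insertions duplicate the
  base; qualities are constant Q30 placeholders because no stage uses
  them.

What the generator does **not** emulate: PCR chimeras, amplification
bias beyond the clone-size law (the length-biased incorporation that
depletes long amplicons in real libraries is out of scope), paired-end
reads, and quality-value structure. Tests passing on this generator
show the pipeline's logic is correct under its stated assumptions; they
do not certify performance on real flow-sequencer error profiles.

## Read processing

Processing follows the classic chain: FASTQ→FASTA, demultiplexing on the
8-nt barcode found immediately after the adaptor (a barcode sheet is
rejected unless all mutual Hamming distances exceed `2 * maxMismatch`),
translation in all three frames, and extraction of the residues
*strictly between* `DSATYY` and `LLVTVSS`/`LLITVSS` — the two literal
downstream variants, not a broader pattern. Anchors are primer-encoded,
not somatic, so they are excluded from the CDRH3; coordinates are
0-based half-open throughout, with Kabat labels (H93–H102) reserved for
prose. A read qualifies in exactly one frame; multi-frame matches are
discarded with a reason code (truth is unknowable there, and the case is
vanishingly rare), as are reads with a stop or an `N` inside the
candidate span. Deduplication is exact at the nucleotide level within a
sample, sorted by copy number then sequence.

One bookkeeping subtlety: distinct clones can share a nucleotide
sequence (there are finitely many unmutated rearrangements), so
round-trip tests compare per-sample *unique* sequences and summed copy
numbers. A related consequence shows up in cohort composition: because
regular rearrangements collide far more often than hypermutated
ultralong ones, the ultralong share of *unique* sequences exceeds the
planted clone-level fraction (13–14% unique vs 10% of clones under the
default conditions).

The diversity helper implements the plain product `v x d x j`. For
cattle, 10 x 10 x 4 = 400, which is smaller than the "approximately
4,000" figure usually quoted for the bovine heavy-chain repertoire; the
discrepancy is documented rather than resolved — the helper computes
arithmetic, not immunogenetics.

## Ultralong classification

Length is the primary criterion and is strict: ultralong means
`length_nt > 90`. The duplicated V-tail hallmark is available as
corroborating evidence (two non-overlapping probe matches with at most
one mismatch, since SHM can hit the probe) but is off by default —
length alone already separates the classes. The probe sequence is a
required configuration value with a synthetic bundled default; we do not
invent the real V-gene tail. The threshold is measured on the
motif-bounded CDRH3 nucleotide span, the only span the pipeline defines.

Cysteine profiling reports count, 0-based positions, a spacing string
(`C-x3-C-x7-...`) and parity; the spacing string plus the first position
reconstructs the positions exactly (a round-trip the suite checks).

## Clonotyping

Percent identity comes from one optimal Needleman–Wunsch alignment with
match +1, mismatch 0, gap open −10, gap extend −1:
`identity = 100 * matches / alignment columns`. Columns are computed
arithmetically as `len(a) + len(b) − (matches + mismatches)`, which
equals the padded alignment length and avoids materialising alignment
strings. Gap columns therefore count against identity — length
differences between clonally related CDRH3 must penalise. Arguments are
ordered canonically before aligning, making the measure symmetric by
construction. Where co-optimal alignments exist they can in principle
carry different identities; the implementation reports the one alignment
the engine returns, and the oracle test accordingly asserts membership
in the exhaustively enumerated optimal set.

Clonotypes are single-linkage clusters — connected components of the
graph with edges at `identity >= 75%`. Components need no tie-breaking
and are independent of input order, which is why single linkage was
chosen over centroid methods. The threshold mode is a flag (`geq`
default, after the supplementary-table convention "≥75%"; the running
text's "greater than 75%" is available as `gt`). Summaries count
clusters of at least two members as clonotypes, with size-1 clusters as
singletons, since the reported clonotype count is presented alongside "a
remainder of singletons". Clustering can run on full CDRH3 (default) or
knob-only sequences (`knobOnly`).

Because the real 154-sequence antigen-enriched cohort is not deposited,
`simulateKnobCohort()` provides a synthetic stand-in with planted family
structure — 20 families holding about half of 154 sequences, the rest
unrelated singletons — and the suite requires the clustering stage to
recover the planted partition exactly. This validates the method, not
any particular deposited dataset.

## Knob boundaries and construct design

Germline cysteines are located by local alignment of the knob-core
peptide against the CDRH3 (same scoring as clonotyping), with an
alignment score below half the core's self-score rejected as "core not
found". Positions aligned to core cysteines are reported even when SHM
has replaced the residue (flagged `mutated`); a core cysteine aligned to
a gap is omitted with a warning.

The two boundary rules:

* **N-terminus** — the single residue immediately preceding the first
  germline cysteine (the first D-segment residue). A first cysteine at
  position 0 is an error: there is no preceding residue.
* **C-terminus** — scanning strictly after the *last* germline cysteine
  (to avoid matching intra-knob aromatics), find the first
  aromatic-initial run of ≥3 residues alternating between the aromatic
  class {F, W, Y} and the aliphatic class {A, V, L, I}; the knob ends
  after the last aliphatic residue before that run. Requiring the run to
  start aromatic disambiguates cases where an aliphatic knob residue
  abuts the stalk. His and Met belong to neither class; all of this is
  configurable because the residue classes are a convention, not data.
  With no such run the knob extends to the sequence end (empty
  descending stalk, warning emitted).

Construct design is string assembly with explicit bookkeeping: the
CDRH3–ScFc fusion is `leader + CDRH3 + template` (the bundled template
is a clearly-labelled synthetic stub carrying the TEV site and a 10x His
tract; the murine leader `MEWSWVFLFFLSVTTGVHS` is the default); the
Fab-knob graft is `acceptor[0:i] + ENLYFQG + knob + ENLYFQG +
acceptor[i:]`. TEV digestion cleaves after the Q of every `ENLYFQ`
followed by G or S — the standard recognition rule, stated explicitly
since only the enzyme is named in protocols. Fragments always
concatenate to the ORF; for a doubly flanked graft the released peptide
is `G/S remnant + knob + ENLYFQ`, and rather than assert which remnant
the "real" construct retains, the digest output records the remnant and
the retained motif explicitly.

## Mass prediction

Residue elemental compositions (CHNOS) are summed plus one water; each
disulphide removes two hydrogens (−2 x 1.00782503 Da). Constants are
pinned in the source — proton 1.00727646 Da, neutron 1.00866492 Da,
monoisotopic C/H/N/O/S masses, IUPAC representative isotope abundances —
because matching against vendor LC/MS software requires stating them.
By default all cysteines are assumed oxidised in pairs
(`floor(nCys / 2)` bonds), the fully bonded interpretation appropriate
for a folded knob; it is overridable. Charge states follow
`(M + z * mp) / z`.

Isotope envelopes are aggregated (by extra-neutron count, spacing one
neutron mass over z): each element's n-atom distribution is built by
binary-exponentiation convolution of its single-atom distribution, the
elements are convolved together, the result is normalised to maximum 1
and truncated below 1e-4 relative abundance, keeping the monoisotopic
peak first. The test oracle recomputes the same distribution by
closed-form multinomial enumeration (dbinom/dmultinom per element,
direct cross-element summation) and demands agreement within 1e-3.

## Binding analytics

**Single-cycle kinetics.** The 1:1 Langmuir model has a closed form on
each constant-concentration segment:
`R(t) = Req + (R0 − Req) exp(−(kon C + koff) t)` with
`Req = kon C Rmax / (kon C + koff)`; dissociation segments use C = 0,
and the segment-end response carries into the next segment — no
regeneration, which is the point of the protocol for a pH-fragile
antigen. The closed form is exact and fast; a numeric RK4 integration
cross-checks it in the tests only. The canonical schedule is seven
3-fold dilutions from 1 µM (so the lowest concentration is
1 µM / 3⁶ ≈ 1.37 nM), 230 s contact, 1,800 s final dissociation
(10,000 s is the preset appropriate for slowly dissociating fusion
proteins); there is no inter-injection gap by default, as gap handling
is instrument-specific. Simulated data are already
reference-subtracted; bulk shifts and mass-transport limitation are out
of model.

Fitting minimises least squares over (log10 kon, log10 koff, log10 Rmax)
with multi-start initialisation on a 3x3 grid spanning log10 kon in
[3, 7] and log10 koff in [−5, −1] plus a data-driven Rmax start; ties
break to the lower koff. Global (not per-injection) Rmax is fitted.
Fitted koff below 1e-5 s⁻¹ raises the `koff_below_limit` flag — the
practical floor for dissociation-rate determination on the instrument
class. Non-finite residuals yield a failure report, not an exception.
On noiseless simulations the fit recovers parameters to well under
0.1%; at 1 RU Gaussian noise the median relative KD error over 50
replicates stays under 10% and is unbiased.

**FRET dose-response.** One 4PL parameterisation,
`y = bottom + (top − bottom)/(1 + (x/mid)^(−hill))`, covers saturation
(hill > 0) and inhibition (hill < 0); the (bottom, top, hill) symmetry
is canonicalised so `top >= bottom`. The midpoint is fitted in log10
space (it must be positive); both Hill-sign starts are tried.
`hillInRange` records whether |hill| lies in [0.5, 2], the plausible
range for reversible mass-action binding. Background subtraction (the
mean of designated quenching wells) is a pre-processing option.

**Cheng–Prusoff.** `Ki = IC50 / (1 + [R]/KDapp)`. Competition assays run
with the labelled partner fixed at its apparent KD therefore report
`Ki = IC50 / 2`; with `[R] → 0`, `Ki → IC50`. Both limits are asserted.

## Pipeline and reporting

`runPipeline()` chains extract → classify → clonotype → knob-annotate →
design → mass, is deterministic given its seeds, and emits a manifest
holding the package version, an md5 hash of the semantic configuration
(output paths excluded), per-stage record counts (monotonically
non-increasing across the filtering stages, with every input read
accounted for either in the CDRH3 table or in a coded discard bin) and
output paths. Percentages are reported at one decimal and hit rates at
integer precision, matching the field's reporting conventions.

## Problem sizes and determinism

The suite runs the generator at 40–2,000 clones (10,000 for the parity
draw), clusters cohorts of up to 154 sequences, and fits 50 noisy
kinetics replicates at a reduced 0.2 Hz sampling rate — ample for rate
constants of 1e-3 s⁻¹ and chosen so the whole suite completes in a few
minutes on one core. All randomness flows through explicit integer
seeds; identical seeds give bit-identical tables and byte-identical
FASTQ.

## Known limitations

* The bundled germline set, ScFc template, Fab acceptor and duplication
  probe are synthetic stand-ins; conclusions about real bovine
  repertoires require substituting real sequences.
* Identity from one optimal alignment is well-defined but not unique
  under co-optimality; clustering at a threshold can, in contrived
  cases, depend on which optimal alignment an engine returns.
* The SCK model excludes mass transport; fitting data from
  transport-limited surfaces will bias kon downward, and the package
  deliberately offers no tc diagnostic.
* The knob C-terminal rule presumes a stalk with at least a three-residue
  aromatic/aliphatic alternation; unusual stalks fall back to
  knob-to-end with a warning rather than a guess.
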