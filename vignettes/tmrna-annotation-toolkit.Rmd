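---
title: "Reconciling and characterizing tmRNA, tRNA and smpB annotations"
author: "tmrnakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling and characterizing tmRNA, tRNA and smpB annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmrnakit)
```

# The problem

The trans-translation system — tmRNA (*ssrA*) plus SmpB (*smpB*) —
rescues ribosomes stalled on non-stop mRNAs. Annotating it across
bacterial genomes runs into a specific cluster of difficulties: the
primary tmRNA finders have very different false-positive profiles and
their commonest false positives are genuine tRNA genes; two-piece
tmRNAs obscure their termini; and in reduced endosymbiont genomes the
genes pseudogenize, frameshift, truncate, or overlap their neighbours,
producing biological curiosities such as a CDS that becomes a non-stop
mRNA whenever the RNA gene it overlaps is matured.

`tmrnakit` implements that annotation layer as composable,
deterministic operations over a single internal currency — the
`gene_calls` table, one row per genomic region of a call, 0-based
half-open coordinates on the forward strand. A single coordinate
convention with conversion only at the file boundary (GFF3 and the
predictor dialects are 1-based inclusive, BED is 0-based half-open)
eliminates off-by-one drift between modules.

# Reconciliation rules

## Merging raw calls

`merge_calls()` collapses the transitive closure of ≥ 1 bp overlap
into union intervals. Two conventions matter and are deliberate:

* the overlap threshold is a single shared base, matching the default
  of the standard interval tools this step emulates;
* merging is **strand-blind by default** (`strand_mode = "ignore"`),
  because raw hits from structure-based finders frequently disagree on
  strand while describing the same locus. Corroboration (below) is in
  contrast strand-*specific*, because agreement between two callers is
  only biologically meaningful on one strand.

Half-open coordinates make the boundary case unambiguous: intervals
`[10,20)` and `[20,30)` share no base and never merge.

## Valid versus questionable tRNAs

A tRNAscan-SE call is **valid** when all of the following hold:

1. Cove score strictly above `cove_min` (default 50 — the comparison is
   strict because the criterion is "above 50", and scores at the
   boundary are exactly the ambiguous ones);
2. not flagged Pseudo or Undetermined;
3. corroborated by a second caller: ≥ 1 bp same-strand overlap with a
   tRNA call from e.g. ARAGORN, with anticodon agreement required only
   when both callers report one. No overlap *fraction* is imposed: the
   minimal 1 bp criterion is documented and configurable rather than
   guessed.

Everything else from either caller is **questionable**. A
corroborating call absorbed by a valid gene is the same gene and is
dropped rather than double-counted; remaining identical intervals are
deduplicated, so valid ∪ questionable partitions the deduplicated
call set.

## tmRNA duplicate resolution

Two machine-checkable rejection rules are applied, in order:

* `overlaps_valid_trna` — the call overlaps a *valid* tRNA by ≥ 1 bp on
  either strand. "Better-called" is operationalized as validity;
  questionable tRNAs (mostly false positives themselves) never reject
  a tmRNA call.
* `missing_terminus` — fewer than two terminus-motif classes (5′ and
  3′) are found within the call's extent by the same mismatch-tolerant
  matcher used for refinement. This is the signature of a tmRNA
  pseudogene missing one gene end.

Surviving calls are accepted; a replicon with more than one accepted
call keeps all of them flagged `multi_allele`, since genuine second
and third alleles occur. Expert-judgment grounds for rejection (poor
conservation of alanyl-tRNA synthetase determinants, other tRNA-like
domain defects) are *not* folded in automatically: the determinant
check lives in the diagnostics module and its integration is left to
the analyst, because it is a judgment call in the source workflow too.

## Terminus refinement

`refine_termini()` scans the candidate ± `flank` (default 100 nt, in
reading sense) for the best occurrence of any 5′ motif and any 3′
motif under a Hamming (substitution-only) sliding window with at most
`max_mismatch` (default 2) mismatches. Termini are short (10–40 nt)
and highly conserved, so gapped alignment buys nothing and a
dependency-free exact matcher is easier to reason about and test.
Ties break by fewer mismatches, then by proximity to the original
boundary. A class with no acceptable match leaves its boundary
unchanged and is reported `unrefined`; a refinement that would invert
the region is discarded entirely.

## Profile threshold calibration

`calibrate_profile_threshold()` sets, per profile, `threshold =
factor × max(decoy scores)` with `factor = 1.4`. The phrase
"1.4-fold above" is read as multiplication (1.4 × max), not
max + 0.4 × max; the factor is a plain argument so the other reading
is one keystroke away. A profile with no decoy hits is a calibration
error, never a silent default — with `factor > 1` the construction
guarantees every decoy is strictly sub-threshold, which is the
property the test suite asserts over random score tables. Targets at
or above threshold are accepted; sub-threshold targets are retained
as fallbacks for genomes with no above-threshold hit.

# Sequential evaluation

`sequential_assign()` tests each merged raw hit against ordered
reference sets — conventionally final tmRNAs, valid tRNAs,
questionable tRNAs, Pfam-positive CDS segments — and assigns it to the
*first* set it overlaps by ≥ 1 bp (strand-blind, consistent with
merging). Every hit is assigned exactly once, so the report's
partition invariant `raw = Σ categories + unhit` holds structurally;
`evaluation_report()` re-checks it and refuses inconsistent counts.
The true-positive rate is `100 × n(first category) / raw`, rounded
half-up to one decimal to match conventional reporting precision, and
is undefined (`NA`), not zero, for an empty dataset. Which datasets
are evaluated against which reference sets is the caller's pairing:
nothing forces, say, archaeal hits onto bacterial references.
`subtract_hits()` supports the tiered evaluation of below-threshold
hit sets: whole-hit exclusion of anything touching an above-threshold
hit, no coordinate clipping.

# The CDS × RNA-gene overlap taxonomy

`classify_overlap()` assigns each overlapping (CDS, RNA) pair one
orientation — `same` iff strands agree — and one positional class:

* `cds_internal` — CDS within the RNA gene (identical extents included:
  a deterministic, documented tie-break);
* `cds_spanning` — CDS contains the RNA gene;
* otherwise the CDS extends beyond exactly one RNA boundary:
  `cds_upstream` past the RNA's 5′ boundary, `cds_downstream` past its
  3′ boundary.

Upstream/downstream are defined **relative to the RNA gene's strand**,
not genomic left/right and not the CDS strand. This choice makes the
non-stop mechanism legible in the class itself: maturation of the RNA
gene's 5′ end cleaves a co-oriented message 3′ of the upstream CDS,
which is exactly the smpB→ssrA configuration. It also makes every
class invariant under reverse-complementing the replicon, which the
suite asserts. The convention is an interpretation — the alternative
(genomic) reading is recoverable by flipping classes on minus-strand
RNAs — and is stated rather than hidden.

`flag_nonstop()` marks every same-orientation record as a non-stop
candidate and additionally marks same-orientation `cds_downstream`
records *suspicious*: a CDS "extending" past the RNA's 3′ end often
means its start codon was called too far upstream. Opposite-strand
records are never flagged. Each piece of a two-piece tmRNA is
classified independently (maturation cleaves at both pieces' ends)
and records carry the piece index. No filter excludes internal CDSs
for valid RNAs: a zero in that cell is an observation, not a rule.

# smpB neighborhoods

`build_windows()` takes the `2k + 1`-gene window (default `k = 5`,
the 11-gene window) centered on each gene of the center family, by
gene *rank*, not bp distance — "11-gene window" is a count. Circular
replicons wrap; linear edges truncate with a flag. Windows are
normalized to the center gene's strand (reversed and strand-flipped
when the center is on minus), so left/right mean upstream/downstream
of *smpB* and signatures are invariant under replicon reverse
complement. `frequent_families()` counts *presence* — once per window
regardless of copy number — with a strict `> min_count` cutoff
(default 200, appropriate to a ~2000-window dataset; a fraction mode
`min_frac` serves other sizes). `cluster_signature()` drops tokens
outside the frequent set (the center family is always kept), joining
the rest in window order as `family(strand)`; strands are retained by
default and gap information is dropped, both toggleable, since the
source figure does not pin either choice down. `rank_clusters()`
orders by count, then signature, so rankings are deterministic.

# Sequence diagnostics

## Acceptor-stem pairing

The default stem map for a one-piece tmRNA of length *L* ending in
`NCCA` (discriminator at *L* − 4) pairs 5′ position *i* (*i* = 0…6)
with *L* − 5 − *i*. This formula is this package's own formalization
of structural knowledge the literature assumes but never writes down
as coordinates; any sequence not fitting it (no terminal CCA, unusual
stems) must supply an explicit `stem_map()`. Pairs classify as
`canonical_GC` (exactly G:C — the closing pair of essentially all
tmRNAs and bacterial tRNA-Ala), `watson_crick` (A:U, U:A, C:G),
`wobble_GU`, or `non_pairing`; the classes are exhaustive and
exclusive, and substituting a base changes only classes of pairs
containing it. The alanylation-determinant check asks whether the
pair at stem index 2 is G:U in that order, by analogy to the
tRNA-Ala G3:U70 identity element; that positioning is an
interpretation and is documented as such.

## Tag reading frame by conservation

`find_tag_frame()` scans all three frame offsets and all window
positions on the reference row's ungapped coordinates, projecting
codon columns through the alignment; codons touching a gap score as
missing. A codon column scores the fraction of non-missing sequences
agreeing with the **modal** amino acid; a window scores the mean over
its codon columns; the maximizing (frame, window) wins, ties broken by
smaller frame then leftmost window (identical rows therefore return
frame 0, leftmost — a documented convention, not information).
Modal-residue agreement was chosen over entropy because it is robust
at the 3–10 sequence depths where this analysis is actually run.
Conservation is undefined below 3 sequences and is an error. Window
codon columns whose modal residue is a stop are annotated in the
result. Amino-acid *similarity* to known tag sequences — the other
half of the judgment in the source analysis — is deliberately not
scored; inventing a similarity model would fabricate precision.

## ORF integrity

`orf_integrity()` translates the candidate region in all three frames
and aligns each translation globally to the reference protein
(match +1, mismatch −1, linear gap −2, via `pairwiseAlignment`).
Identity scoring suffices because verdicts depend on coverage and
stops, not fine alignment quality. With per-reference-position match
profiles *M₀, M₁, M₂*:

* **intact** — one frame matches ≥ 90% of reference residues, no
  internal stop;
* **pseudogene_stops** — the covering frame contains stop codons
  within its aligned span (positions reported as codon indices);
* **frameshifted** — no single frame covers, but a prefix of one frame
  plus a suffix of another jointly reach 90%, with the breakpoint at
  the coverage-maximizing reference codon (a cumulative-sum scan over
  all ordered frame pairs);
* **truncated** — otherwise, reporting uncovered reference residues at
  each end. Degenerate inputs fall through to `truncated` with the
  full uncovered length rather than erroring.

The suite checks the breakpoint against planted single-nucleotide
deletions: localization within ±3 codons on 100 random fixtures.

## Region presence

`region_presence()` calls a named alignment region absent for a
sequence when its gap fraction over the region's columns reaches
`gap_threshold` (default 0.8 — a region is only called lost when it is
overwhelmingly gapped, protecting ragged alignments from
over-calling). It also reports residues beyond the last region column,
the C-terminal extensions relevant to SmpB tail variation. The
designated reference row must be ungapped over every region so column
ranges have a stable meaning.

# The synthetic-data generator

`simulate_genome()` plants **template** genes — a fixed tmRNA template
carrying distinct 15-nt 5′/3′ terminus motifs, a 12-codon tag ORF and
a terminal `NCCA` whose acceptor stem satisfies the default pairing
map, and a fixed tRNA consensus with a per-gene anticodon — on random
background, on random strands, with exact truth coordinates.
Template-based (not model-sampled) planting is deliberate: tests need
exact truth, not realism. `simulate_predictor_calls()` perturbs truth
with terminus jitter (Gaussian, default σ = 2 nt), a 5% miss rate,
uniformly placed false positives with depressed scores, and Cove-like
scores at 65 ± 10 — values chosen once as plausible for
high-quality finished genomes and good predictors. The zero-noise
configuration (all error-model knobs at zero, including score spread)
is the fixture for perfect-recovery invariants.
`make_ortholog_set()` derives orthologs from one ancestor with
synonymous-only substitution inside the planted ORF and free
substitution (default 30% per site) outside, optional short deletions
outside the ORF only; `make_overlap_scenarios()` plants one pair per
orientation × position cell plus the smpB→ssrA intrusion.

All generators run under `with_seed()`: identical spec + seed give
byte-identical outputs without disturbing the caller's RNG stream.

What the fixtures do **not** emulate: realistic base composition or
codon usage, phylogenetic correlation between orthologs, genomic
islands, predictor-specific error structure beyond
jitter/miss/false-positive, or two-piece tmRNA gene architecture in
the planted genomes (two-piece calls are exercised through the data
model and I/O instead). Passing tests therefore demonstrate
correctness of the rules and machinery, not field performance of the
upstream predictors.

# File formats and the CLI

GFF3 and BED6 go through `rtracklayer`; the tRNAscan-SE tabular,
ARAGORN batch and generic TSV dialects are parsed natively (strict by
default — evaluation results must not silently depend on dropped
rows; a lenient mode skips bad rows with warnings). Two-piece tmRNAs
serialize as two GFF3 features sharing a `Parent` (two BED rows
sharing a name); the generic-TSV two-region encoding (`id`/`part`
attribute keys) is this package's own, as no upstream convention
exists. BED6 by definition carries no gene type or attribute fields,
so only GFF3 round-trips calls with full fidelity; BED round-trips
regions, strands, scores, ids and two-piece grouping. Circular-origin
wrap-around is handled by storing origin-crossing features as
two-region calls internally.

The `tmtk` script is a thin dispatcher over exported functions: exit
0/2/1 for success/usage/data errors, YAML config with command-line
override, logs to stderr, data to files, and a `run_summary.json`
(version, config echo, input digests) per run for reproducibility.

# Problem sizes and numerical choices

The test and acceptance workloads are sized for a desk run: interval
oracles on 1000 random instances of ≤ 100 intervals; tag-frame
recovery on 100 ortholog sets (5 × ~360 nt, 30% divergence, 20-codon
window); frameshift localization on 100 fixtures (120-codon
references); calibration on 1000 random score tables; pipeline
fixtures of 20 kb with 11 planted genes. Floating-point ties in
window scores are broken with a 10⁻¹² tolerance toward the earlier
frame/window; all counts and coordinates are integer arithmetic.

# Known limitations

* Covariance-model, HMM and BLAST searching are out of scope: the
  toolkit consumes predictor output, it does not run predictors.
* The Pfam-positive CDS reference set is consumed as intervals, not
  derived from sequence.
* Manual-curation judgments (TLD quality, determinant-based
  rejection) are surfaced as diagnostics, not automated into the
  accept/reject path.
* Terminus matching is substitution-only; a terminus disrupted by an
  insertion within the motif will read as mismatches.
* BED6 output is lossy with respect to gene type and attributes, as
  the format has nowhere to put them.
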