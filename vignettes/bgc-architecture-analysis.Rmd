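---
title: "Module-architecture analysis of PKS and NRPS gene clusters"
author: "bgcarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module-architecture analysis of PKS and NRPS gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgcarch)
```

## The model

Modular polyketide synthases (type-I PKS) and nonribosomal peptide
synthetases (NRPS) are assembly lines: each module adds one building block to
the growing chain, so under the co-linearity rule the order and number of
modules determine the order and number of units in the product. A module is a
run of catalytic domains — for a reducing PKS module typically
KS/AT/[DH/ER/KR]/ACP, for an NRPS module C/A/T with optional E or MT — and
the whole enzyme is written compactly as modules separated by `-` with
domains separated by `/`. Acyltransferase specificity is a subscript
(`AT_m_` malonyl-CoA, `AT_mm_` methylmalonyl-CoA) and the amino acid
activated by an adenylation domain follows the A (`A_thr_`, `A_b-ala_`).
Iterative systems break the co-linearity logic: a type-II PKS is a discrete
KSα/KSβ/ACP triplet and a type-III PKS a standalone KS, both acting
iteratively.

`bgcarch` implements, over this notation, the complete in-silico workflow of
a comparative cluster study: parsing and normalization, cluster typing,
product-skeleton prediction, global module-architecture alignment for
ortholog and module-indel calls, cross-strain conserved-cluster inventories,
and threshold-based genomospecies delimitation. The shipped fixtures encode
the fifteen-cluster inventories of two marine *Micromonospora* strains
(TP-A0316 and TP-A0468) and the quinolidomicin (*qnm*) reference
architecture, so every stage of the analysis can be reproduced from plain
text.

```{r}
inv316 <- readClusterTable(bgcFixture("tp_a0316"))[[1]]
inv468 <- readClusterTable(bgcFixture("tp_a0468"))[[1]]
inv316
```

## Parsing conventions

The grammar is deliberately small; the conventions below resolve the
ambiguities that real tables contain.

* **Module boundaries.** A segment containing KS or C is an extension
  module; a CoA-ligase-led segment is a loading module. A release-only
  segment (`-Te`, `-TD`) is a continuation of the preceding piece, so
  `KS/AT_m_/ACP-Te` and `KS/AT_m_/ACP/Te` — two spellings used for the same
  module — normalize identically. A segment of only tailoring/carrier
  domains (DH, ER, KR, ACP, T, MT, E, AmT) following a module is likewise a
  continuation.
* **Standalone pieces.** A single-domain segment (a lone KS, C, A, T, ACP)
  and any KS/C-less multi-domain unit (`A/T`, `AT_mm_/DH/KR/ACP`) are
  *standalone*: trans-acting parts or split-module fragments that are not
  counted as assembly-line modules. The first piece of a cluster is promoted
  to the loading module when it is A/AT-bearing, which is how a chain-starting
  `A_gly_/T` or bare `A` gene is modeled.
* **Truncation.** A leading or trailing ellipsis marks an incompletely
  sequenced ORF and forces the cluster's `complete` flag to `FALSE`.
* **Unknown codes** parse to `X` with the raw text preserved — nothing is
  dropped.
* **Subscript dialects** `AT_m_`, `AT_m` and `ATm` all normalize to
  AT(malonyl); serialization always emits the balanced `_m_` form, and
  `parse ∘ serialize` is the identity.

Module counting includes the loading module: the large type-I cluster
*t1pks-2* of TP-A0316 counts 33 modules (L + 32 extension), matching its
reference, which counts L + 33:

```{r}
countModules(clusters(inv316)[["t1pks-2"]])
qnm <- clusters(readClusterTable(bgcFixture("qnm"))[[1]])[["qnm"]]
countModules(qnm)
```

## Product prediction

One unit per module, in gene order: the A-domain substrate (`x` when
unannotated), `y` for a module lacking an A domain, `pk` per KS-bearing
module, `st` for a CoA-ligase starter. Greek-prefix names (dipeptide,
hexaketide, ...) derive from the residue or ketide count, falling back to
`<n>-peptide`/`<n>-ketide` beyond deca. A thioesterase maps to a
thioesterase release, a terminal reductive domain to a reductive one.
Incomplete clusters are `unpredictable`; iterative type-II/III clusters get
their category (aromatic or type-III polyketide) with no unit string.

Clusters whose chemistry requires trans-acting pieces are flagged
`colinear = FALSE` and handled by a **trans-complementation rule**, a design
choice of this package: an annotated standalone A contributes its residue; an
unannotated A with a carrier (T/ACP) contributes `x`; a bare unannotated A
contributes `x` only when an unpaired standalone C exists to accept it
(paired in gene order); and pieces downstream of a release domain in the
same ORF contribute nothing (post-release fragments are not part of the
chain). For such clusters the emitted unit *order* is gene order and carries
no further guarantee — the curated orders printed for trans-AT/trans-A
clusters are expert judgments that no mechanical rule reproduces — so they
are compared as multisets, while fully colinear clusters reproduce their
printed unit strings exactly:

```{r}
predictionReport(inv316)[, c("cluster_id", "length_name", "units", "colinear")]
```

## Module-architecture alignment

`alignClusters()` runs a global (Needleman–Wunsch-style) dynamic program
over the two module sequences. The match score is `moduleSimilarity()`: a
Jaccard index over the modules' domain labels in which AT and A match at the
label level, with the contribution of a domain whose specificities disagree
on both sides multiplied by `specPenalty` (default 0.5; an unannotated side
never triggers the penalty). Loading modules align only to loading modules
(cross-role similarity 0). Each gap costs `gapPenalty` (default 0.4).

**Tie-breaking.** On exact score ties the traceback takes a reference gap
before a diagonal step (and a query gap last). Within a run of identical
tandem modules — ubiquitous in large PKSs — an indel position is only
defined up to the run, and this convention pins it to the *last* repeat,
which is how the domain-organization tables place the module absent from the
strain copies of the *qnm* reference:

```{r}
aln <- alignClusters(qnm, clusters(inv316)[["t1pks-2"]])
aln
head(renderAlignment(aln, qnm, clusters(inv316)[["t1pks-2"]]), 8)
```

A consequence is that mirrored alignments of swapped inputs agree on score
and gap counts but may place a tied gap on the mirrored position of an
identical-module run.

**Ortholog verdict.** `ortholog = TRUE` requires mean pair similarity ≥
`sMin` and coverage ≥ `cMin` on both sides. The defaults (`sMin = 0.93`,
`cMin = 0.8`) were calibrated on the packaged inventories: true ortholog
pairs — near-identical architectures up to one module indel and a few domain
differences — score above 0.95 mean similarity, whereas unrelated clusters
of the same class still reach ~0.85 because generic reducing-PKS modules
share most domain labels (the arisostatin-class and rifamycin-class clusters
of the two strains are the cautionary pair, at mean 0.79 with gaps). A
threshold at the conventional 0.6 of sequence-identity intuition would
declare most same-class cluster pairs orthologous; module-label sets are a
much coarser signal than sequence, so the bar must sit close to identity.

## Conserved-cluster inventories

`compareInventories()` restricts candidate pairs to equal content-based
types (hybrids compare only to hybrids), requires the ortholog verdict, and
matches greedily by similarity, one-to-one, breaking ties by inventory
order. Iterative (type-II/III) clusters have no modules to align and their
notation — a bare `KS`, or the KSα/KSβ/ACP triplet — is identical across
unrelated clusters, so architecture alone cannot support a conservation
call. For these, the package requires identical standalone-domain content
*plus* an agreeing, non-empty known-product annotation (carried as metadata
from external similarity searches; comparing an inventory against itself
matches trivially by cluster identity). This is an explicit design decision:
the sequence-level evidence that licenses such calls in a genome study is
out of scope here, and an annotation-free rule would conflate every aromatic
type-II system with every other.

```{r}
compareInventories(inv316, inv468)
```

`screenForOrtholog()` applies the same alignment against a panel of strain
inventories and reports the best-matching cluster with its verdict per
strain.

## Genomospecies thresholds

`pairwiseIdentity()` computes marker-gene identity from a global alignment
(via `Biostrings::pairwiseAlignment`) with terminal-gap columns excluded, so
unequal trim lengths do not count as differences; the result is a percent
rounded to one decimal. Verdict rules are inclusive at the boundary, as the
published correspondences state thresholds, not open intervals: gyrB
identity ≥ 98.5% (the identity corresponding to 70% DNA–DNA relatedness)
means same genomospecies; digital DNA–DNA hybridization ≥ 70% means same
species; 16S identity alone is always inconclusive (identical 16S sequences
occur across distinct genomospecies). dDDH values are *inputs* (a packaged
panel encodes the published genus survey); computing them is out of scope.
`panelVerdicts()` partitions strains into species groups as connected
components of the same-species graph, invariant to pair order.

```{r}
panel <- readDdhPanel(bgcFixture("fig6_ddh"))
head(panelVerdicts(panel)$groups, 3)
```

Panel values printed in the source only as bounds (">90", "~90", "<70") are
encoded as representative numbers on the correct side of the 70% cut-off and
flagged approximate in the fixture; the group structure is insensitive to
the exact representative within its side.

## Synthetic data

The generators make every stage testable with known ground truth and no
external data. `generateCluster()` emulates the architecture statistics of
the packaged tables: reducing-PKS modules KS/AT/[DH/ER/KR]/ACP with KR in
85%, DH in 50% and ER in 15% of modules and 35% methylmalonyl ATs; NRPS
modules C/A/T with 15% tailoring (E/MT) and 65% annotated substrates over
eleven residue codes; a CoA-ligase loading module, a terminal thioesterase,
and 1–4 ORFs. One seeded RNG stream drives each call, identical seed and
configuration give byte-identical serializations, and the caller's RNG state
is left untouched. `mutateCluster()` applies module deletions/insertions
(an insertion copies an adjacent module, mimicking tandem repeats), swaps of
optional domains, and specificity flips, returning an edit log whose replay
(`applyMutationLog()`) reproduces the mutant exactly.
`generateMarkerPair()` plants Binomial(length, divergence) substitutions and
returns the realized identity, which the alignment identity must equal
exactly.

What the generators do *not* emulate: split modules spanning ORF boundaries,
trans-AT systems, standalone trans-acting genes, docking-domain order
constraints, or any nucleotide-level signal. Passing the synthetic recovery
suites therefore demonstrates correctness of the algorithms on clean
assembly lines, not robustness to every annotation artifact of real
genomes.

## Numerical and testing choices

* Alignment scores are plain sums of similarities minus gap costs; ties are
  resolved exactly (score equality under `all.equal` tolerance), so results
  are deterministic.
* The test suite checks the dynamic program against a brute-force
  enumeration of all alignments for clusters of up to 6 modules, and module
  indel recovery over 200 seeded deletion trials (1–3 deletions on
  18–20-module lines, 95% exact-localization requirement with deleted
  positions canonicalized to the right end of their identical-module run,
  matching the tie-break convention). Round-tripping is checked over 1000
  generated architectures. These problem sizes keep the default suite under
  a minute while exercising every code path.
* The ortholog-screen recall check uses 20 synthetic strains, half seeded
  with a mutated copy (≤ 3 module deletions) of the qnm reference.

## Known limitations

* Module similarity ignores domain order within a module and repeated
  domains collapse to one label; this matches how the tables juxtapose
  modules but underweights unusual architectures.
* Conservation calls for iterative clusters lean on product annotations, as
  discussed above.
* The trans-complementation rule reproduces the curated unit multisets of
  the packaged tables but is a heuristic; genuinely novel trans-AT/trans-A
  chemistries may need manual interpretation.
* Species delimitation consumes precomputed dDDH/identity values; it does
  not compute genome-scale relatedness.
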