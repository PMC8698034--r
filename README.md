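# bgcarch

Comparative analysis of modular PKS and NRPS biosynthetic gene clusters
(BGCs) from their domain-organization notation.

Genome mining of actinomycetes routinely produces tables of secondary
metabolite gene clusters written in a compact assembly-line notation —
modules separated by `-`, catalytic domains by `/`, acyltransferase and
adenylation specificities as subscripts (`KS/AT_m_/DH/KR/ACP`,
`C/A_ser_/T`). For the people doing that mining, `bgcarch` turns the
notation into analyzable objects and implements the standard comparative
workflow on top of it:

* **Parsing/serialization** of the notation, with normalization rules for
  the spelling variants real tables contain (release-domain merging,
  subscript dialects, truncation ellipses, unknown codes).
* **Cluster typing** from content: modular type-I PKS, iterative type-II
  (KSα/KSβ/ACP) and type-III systems, NRPS, and hybrids.
* **Product-skeleton prediction** by the co-linearity rule: one unit per
  module in gene order — A-domain substrate, `x` (unannotated), `y` (no A
  domain), `pk` (ketide unit), `st` (starter) — with a trans-complementation
  rule for clusters that rely on standalone trans-acting domains.
* **Module-architecture alignment** (global dynamic programming with a
  specificity-aware Jaccard similarity) for ortholog verdicts and
  module-indel localization, e.g. a strain copy of a reference assembly
  line that lacks one module.
* **Inventory comparison and screening**: one-to-one conserved-cluster
  matching between strains, and presence/absence screening of a reference
  cluster across strain panels.
* **Genomospecies delimitation**: marker-gene identity (gyrB, 98.5%
  threshold), digital DNA–DNA hybridization verdicts (70% threshold), and
  species-group partitioning of relatedness panels.
* **Synthetic generators** of assembly lines, mutated ortholog copies with
  replayable edit logs, and marker-gene pairs with known identity.

The package ships plain-text fixtures encoding the 15-cluster inventories of
two marine *Micromonospora* strains (TP-A0316, the arisostatin producer, and
TP-A0468 = *M. okii*, the kosinostatin producer) and the quinolidomicin
(*qnm*) reference architecture, so the full analysis is reproducible offline.

## Worked example

```r
library(bgcarch)

inv316 <- readClusterTable(bgcFixture("tp_a0316"))[[1]]
inv468 <- readClusterTable(bgcFixture("tp_a0468"))[[1]]

## product prediction by co-linearity
predictProduct(clusters(inv316)[["nrps-5"]])
#> ProductPrediction nrps-5: peptide dipeptide (ser-pro) [release: thioesterase]

## the giant type-I assembly line and its reference
qnm <- clusters(readClusterTable(bgcFixture("qnm"))[[1]])[["qnm"]]
countModules(clusters(inv316)[["t1pks-2"]])
#> [1] 33
alignClusters(qnm, clusters(inv316)[["t1pks-2"]])
#> ModuleAlignment qnm vs t1pks-2: 33 pair(s), 1/0 gap(s), mean similarity 0.969,
#> coverage 0.97/1.00, ortholog
```

The alignment reports one reference-side gap at module 4: the strain's copy
of the quinolidomicin cluster is an ortholog that lacks that module, so its
product is predicted to be a congener with a shorter skeleton. Cross-strain
inventory comparison finds the conserved subset:

```r
compareInventories(inv316, inv468)
#> InventoryComparison: 4 conserved pair(s)
#>   t3pks-1 <-> t3pks-1  (similarity 1.000)
#>   pks/nrps-2 <-> pks/nrps-2  (similarity 1.000)
#>   pks/nrps-3 <-> pks/nrps-3  (similarity 1.000)
#>   t1pks-2 <-> t1pks-2  (similarity 0.967)
```

Only 4 of the 15 clusters per strain are conserved — consistent with the two
strains being distinct species, which the taxonomy module confirms from
marker thresholds:

```r
verdict(genomospeciesVerdict(94.9))   # gyrB identity, threshold 98.5
#> [1] "distinct_species"
verdict(ddhVerdict(51))               # digital DDH, threshold 70
#> [1] "distinct_species"
```

A thin command-line front end over the same functions is installed at
`system.file("scripts", "bgcarch-cli.R", package = "bgcarch")` with
subcommands `parse`, `predict`, `align`, `compare`, `screen`, `delimit` and
`simulate`.

See the vignette (`vignettes/bgc-architecture-analysis.Rmd`) for the models,
parameter defaults and their calibration, and known limitations.

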