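## Shared fixtures and independent oracles for the test suite.

inv_tp_a0316 <- function() readClusterTable(bgcFixture("tp_a0316"))[[1]]
inv_tp_a0468 <- function() readClusterTable(bgcFixture("tp_a0468"))[[1]]
qnm_cluster <- function()
  clusters(readClusterTable(bgcFixture("qnm"))[[1]])[["qnm"]]

## Brute-force global-alignment score by exhaustive enumeration of all
## monotone alignments (no DP tables); tractable for <= 6 modules a side.
brute_force_score <- function(ref, query, gapPenalty = 0.4,
                              specPenalty = 0.5) {
  rmods <- modules(ref)
  qmods <- modules(query)
  n <- length(rmods); m <- length(qmods)
  sim <- matrix(0, n, m)
  for (i in seq_len(n))
    for (j in seq_len(m))
      sim[i, j] <- moduleSimilarity(rmods[[i]], qmods[[j]],
                                    specPenalty = specPenalty)
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) best <- max(best, rec(i - 1L, j - 1L) + sim[i, j])
    if (i > 0L) best <- max(best, rec(i - 1L, j) - gapPenalty)
    if (j > 0L) best <- max(best, rec(i, j - 1L) - gapPenalty)
    best
  }
  rec(n, m)
}

## Canonicalize deleted-module positions: within a run of identical modules
## an indel position is defined only up to the run; the aligner reports the
## rightmost co-optimal slots.  `sers` are the serialized parent modules,
## `del` indices into that list.
canonical_deletions <- function(sers, del) {
  r <- rle(sers)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer()
  for (k in seq_along(starts)) {
    hit <- sum(del >= starts[k] & del <= ends[k])
    if (hit > 0L) out <- c(out, (ends[k] - hit + 1L):ends[k])
  }
  sort(out)
}

serialize_modules <- function(cluster)
  vapply(modules(cluster), bgcarch:::.serialize_module, character(1))

module_labels_of <- function(cluster)
  vapply(modules(cluster), function(m) m@indexLabel, character(1))
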