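## Cross-genome conserved-cluster matching and reference-based screening.

## Similarity route for clusters without assembly-line modules (iterative
## type-II/III systems).  Their notation — a bare KS, or the
## KSalpha/KSbeta/ACP triplet — is identical across unrelated clusters, so
## architecture alone cannot support a conservation call; content identity
## must be corroborated by an agreeing known-product annotation (or the
## trivial case of comparing a cluster with itself).
.content_match <- function(a, b) {
  la <- sort(domainLabels(a))
  lb <- sort(domainLabels(b))
  if (!identical(la, lb)) return(list(similarity = 0, ortholog = FALSE))
  annotated <- nzchar(a@annotation) && nzchar(b@annotation)
  ok <- (annotated && a@annotation == b@annotation) ||
    (a@clusterId == b@clusterId && a@annotation == b@annotation)
  list(similarity = 1, ortholog = ok)
}

.is_modular <- function(cl) countModules(cl) >= 1L

#' Conserved-cluster comparison of two inventories
#'
#' Candidate pairs are restricted to clusters of the same
#' \code{\link{classifyCluster}} type (hybrids compare only to hybrids).
#' Modular clusters are matched through \code{\link{alignClusters}}; clusters
#' without modules (iterative type-II/III) require identical domain content
#' plus an agreeing known-product annotation.  Matching is greedy best-first
#' by similarity and one-to-one; ties resolve by inventory order.
#'
#' @param a,b ClusterInventory objects.
#' @param params see \code{\link{alignmentParams}}.
#' @return an InventoryComparison.
#' @examples
#' inv1 <- readClusterTable(bgcFixture("tp_a0316"))[[1]]
#' inv2 <- readClusterTable(bgcFixture("tp_a0468"))[[1]]
#' compareInventories(inv1, inv2)  # 4 conserved pairs
#' @export
compareInventories <- function(a, b, params = alignmentParams()) {
  stopifnot(is(a, "ClusterInventory"), is(b, "ClusterInventory"),
            length(a@clusters) > 0L, length(b@clusters) > 0L)
  ta <- vapply(a@clusters, classifyCluster, character(1))
  tb <- vapply(b@clusters, classifyCluster, character(1))
  cand <- list()
  for (i in seq_along(a@clusters)) {
    for (j in seq_along(b@clusters)) {
      if (ta[i] != tb[j]) next
      ca <- a@clusters[[i]]; cb <- b@clusters[[j]]
      if (.is_modular(ca) && .is_modular(cb)) {
        aln <- alignClusters(ca, cb, params)
        if (!aln@ortholog) next
        cand[[length(cand) + 1L]] <- list(
          i = i, j = j, similarity = aln@meanSimilarity, alignment = aln)
      } else if (!.is_modular(ca) && !.is_modular(cb)) {
        cm <- .content_match(ca, cb)
        if (!cm$ortholog) next
        cand[[length(cand) + 1L]] <- list(
          i = i, j = j, similarity = cm$similarity, alignment = NULL)
      }
    }
  }
  matched <- list()
  usedA <- logical(length(a@clusters))
  usedB <- logical(length(b@clusters))
  if (length(cand)) {
    ord <- order(-vapply(cand, `[[`, numeric(1), "similarity"),
                 vapply(cand, `[[`, numeric(1), "i"),
                 vapply(cand, `[[`, numeric(1), "j"))
    for (k in ord) {
      p <- cand[[k]]
      if (usedA[p$i] || usedB[p$j]) next
      usedA[p$i] <- TRUE
      usedB[p$j] <- TRUE
      matched[[length(matched) + 1L]] <- list(
        refId = clusterId(a@clusters[[p$i]]),
        queryId = clusterId(b@clusters[[p$j]]),
        similarity = p$similarity, alignment = p$alignment)
    }
  }
  new("InventoryComparison", matchedPairs = matched,
      unmatchedA = vapply(a@clusters[!usedA], clusterId, character(1)),
      unmatchedB = vapply(b@clusters[!usedB], clusterId, character(1)))
}

#' @rdname accessors
#' @export
setMethod("matchedPairs", "InventoryComparison", function(x) x@matchedPairs)

setMethod("show", "InventoryComparison", function(object) {
  cat(sprintf("InventoryComparison: %d conserved pair(s)\n",
              length(object@matchedPairs)))
  for (p in object@matchedPairs)
    cat(sprintf("  %s <-> %s  (similarity %.3f)\n", p$refId, p$queryId,
                p$similarity))
  if (length(object@unmatchedA))
    cat("  unmatched A:", paste(object@unmatchedA, collapse = ", "), "\n")
  if (length(object@unmatchedB))
    cat("  unmatched B:", paste(object@unmatchedB, collapse = ", "), "\n")
})

#' Screen strain inventories for an ortholog of a reference cluster
#'
#' For each inventory, aligns the reference against every same-type modular
#' cluster and reports the best match and whether it passes the ortholog
#' thresholds.
#'
#' @param reference a GeneCluster with at least one module.
#' @param candidates list of ClusterInventory.
#' @param params see \code{\link{alignmentParams}}.
#' @return data.frame with one row per strain: strain_id, best_cluster,
#'   mean_similarity, coverage, present.
#' @export
screenForOrtholog <- function(reference, candidates,
                              params = alignmentParams()) {
  stopifnot(is(reference, "GeneCluster"), .is_modular(reference))
  rtype <- classifyCluster(reference)
  if (is(candidates, "ClusterInventory")) candidates <- list(candidates)
  rows <- lapply(candidates, function(inv) {
    best <- NULL
    for (cl in inv@clusters) {
      if (classifyCluster(cl) != rtype || !.is_modular(cl)) next
      aln <- alignClusters(reference, cl, params)
      better <- is.null(best) ||
        (aln@ortholog && !best@ortholog) ||
        (aln@ortholog == best@ortholog &&
           aln@meanSimilarity > best@meanSimilarity)
      if (better) best <- aln
    }
    if (is.null(best))
      data.frame(strain_id = inv@strainId, best_cluster = NA_character_,
                 mean_similarity = NA_real_, coverage = NA_real_,
                 present = FALSE, stringsAsFactors = FALSE)
    else
      data.frame(strain_id = inv@strainId, best_cluster = best@queryId,
                 mean_similarity = best@meanSimilarity,
                 coverage = best@coverage, present = best@ortholog,
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
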