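## Module-architecture alignment: similarity scoring, global dynamic
## programming over module sequences, rendering.

#' Default alignment and ortholog-verdict parameters
#'
#' \code{gapPenalty} is the per-gap cost of the global alignment;
#' \code{sMin} and \code{cMin} are the ortholog-verdict thresholds on mean
#' module similarity and on alignment coverage (both sides).
#' \code{specPenalty} scales a domain's match contribution when both sides
#' carry specificities that disagree (malonyl vs methylmalonyl, ser vs pro).
#'
#' The defaults separate near-identical ortholog architectures (mean module
#' similarity above ~0.96 on the packaged inventories) from unrelated
#' clusters of the same class, whose generic reducing-PKS modules still share
#' most domain labels (~0.85); see the methods vignette for the calibration.
#'
#' @param gapPenalty positive gap cost (default 0.4).
#' @param sMin ortholog threshold on mean similarity (default 0.93).
#' @param cMin ortholog threshold on coverage (default 0.8).
#' @param specPenalty disagreeing-specificity multiplier (default 0.5).
#' @return a named list.
#' @export
alignmentParams <- function(gapPenalty = 0.4, sMin = 0.93, cMin = 0.8,
                            specPenalty = 0.5) {
  stopifnot(gapPenalty > 0, sMin >= 0, sMin <= 1, cMin >= 0, cMin <= 1,
            specPenalty >= 0, specPenalty <= 1)
  list(gapPenalty = gapPenalty, sMin = sMin, cMin = cMin,
       specPenalty = specPenalty)
}

## unique labels + first specificity per label for one module
.mod_profile <- function(mod) {
  labs <- .mod_labels(mod)
  specs <- vapply(mod@domains, function(d) d@specificity, character(1))
  keep <- !duplicated(labs)
  list(labels = labs[keep], specs = specs[keep])
}

#' Similarity of two modules
#'
#' Jaccard index over the (unique) domain labels of the two modules.  AT and
#' A domains match at the label level; when both sides carry specificities
#' and they disagree, that domain's contribution to the intersection is
#' multiplied by \code{specPenalty} (default 0.5).  Cross-role pairs (loading
#' vs non-loading) score 0: the loading module is pinned to the loading
#' position.  Symmetric by construction.
#'
#' @param a,b Module objects.
#' @param specPenalty disagreeing-specificity multiplier.
#' @param roleAware logical; score loading-vs-extension pairs as 0.
#' @return a number in [0, 1].
#' @examples
#' m1 <- modules(parseOrfArchitecture("KS/AT_m_/DH/KR/ACP"))[[1]]
#' m2 <- modules(parseOrfArchitecture("KS/AT_m_/KR/ACP"))[[1]]
#' moduleSimilarity(m1, m2)  # 0.8
#' @export
moduleSimilarity <- function(a, b, specPenalty = 0.5, roleAware = TRUE) {
  stopifnot(is(a, "AssemblyModule"), is(b, "AssemblyModule"))
  if (roleAware && xor(a@role == "loading", b@role == "loading"))
    return(0)
  pa <- .mod_profile(a)
  pb <- .mod_profile(b)
  shared <- intersect(pa$labels, pb$labels)
  un <- union(pa$labels, pb$labels)
  if (!length(un)) return(0)
  contrib <- vapply(shared, function(l) {
    sa <- pa$specs[match(l, pa$labels)]
    sb <- pb$specs[match(l, pb$labels)]
    if (!is.na(sa) && !is.na(sb) && sa != sb) specPenalty else 1
  }, numeric(1))
  sum(contrib) / length(un)
}

## Modules entering an alignment: everything in gene order (loading,
## extension and standalone-role trans pieces alike; role-aware scoring keeps
## loading pinned to loading).
.alignable_modules <- function(cluster) modules(cluster)

#' Globally align the module sequences of two clusters
#'
#' Needleman-Wunsch-style dynamic programming over the two module sequences,
#' with \code{\link{moduleSimilarity}} as the match score and a constant gap
#' penalty.  On exact score ties the traceback takes a reference gap before
#' a diagonal step (and a query gap last), so an ambiguous gap sits at the
#' rightmost co-optimal reference position and the result is deterministic.
#' The ortholog verdict requires
#' mean similarity \eqn{\ge} \code{sMin} and coverage \eqn{\ge} \code{cMin}
#' on both sides.
#'
#' @param ref,query GeneCluster objects with at least one module each.
#' @param params see \code{\link{alignmentParams}}.
#' @return a ModuleAlignment.
#' @examples
#' a <- demoCluster("KS/AT_m_/KR/ACP-KS/AT_mm_/DH/KR/ACP-KS/AT_m_/ACP-Te")
#' alignClusters(a, a)
#' @export
alignClusters <- function(ref, query, params = alignmentParams()) {
  stopifnot(is(ref, "GeneCluster"), is(query, "GeneCluster"))
  if (countModules(ref) == 0L || countModules(query) == 0L)
    stop("cannot align a cluster with no modules", call. = FALSE)
  rmods <- .alignable_modules(ref)
  qmods <- .alignable_modules(query)
  n <- length(rmods); m <- length(qmods)
  sim <- matrix(0, n, m)
  for (i in seq_len(n))
    for (j in seq_len(m))
      sim[i, j] <- moduleSimilarity(rmods[[i]], qmods[[j]],
                                    specPenalty = params$specPenalty)
  gp <- params$gapPenalty
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- -(0:n) * gp
  S[1L, ] <- -(0:m) * gp
  for (i in seq_len(n))
    for (j in seq_len(m))
      S[i + 1L, j + 1L] <- max(S[i, j] + sim[i, j],
                               S[i, j + 1L] - gp,
                               S[i + 1L, j] - gp)
  ## traceback; on exact score ties a reference gap is taken before the
  ## diagonal (and a query gap last), which places an ambiguous gap at the
  ## rightmost co-optimal reference position: within a run of identical
  ## tandem modules the indel position is only defined up to the run, and
  ## the domain-organization tables pin it to the last repeat
  i <- n; j <- m
  steps <- list()
  repeat {
    if (i == 0L && j == 0L) break
    cur <- S[i + 1L, j + 1L]
    if (i > 0L && isTRUE(all.equal(cur, S[i, j + 1L] - gp))) {
      steps[[length(steps) + 1L]] <- c(i, NA)
      i <- i - 1L
    } else if (i > 0L && j > 0L &&
               isTRUE(all.equal(cur, S[i, j] + sim[i, j]))) {
      steps[[length(steps) + 1L]] <- c(i, j)
      i <- i - 1L; j <- j - 1L
    } else {
      steps[[length(steps) + 1L]] <- c(NA, j)
      j <- j - 1L
    }
  }
  steps <- rev(steps)
  rlab <- vapply(rmods, function(x) x@indexLabel, character(1))
  qlab <- vapply(qmods, function(x) x@indexLabel, character(1))
  pairs <- data.frame(
    refLabel = vapply(steps, function(s)
      if (is.na(s[1])) NA_character_ else rlab[s[1]], character(1)),
    queryLabel = vapply(steps, function(s)
      if (is.na(s[2])) NA_character_ else qlab[s[2]], character(1)),
    similarity = vapply(steps, function(s)
      if (anyNA(s)) NA_real_ else sim[s[1], s[2]], numeric(1)),
    stringsAsFactors = FALSE)
  matched <- !is.na(pairs$refLabel) & !is.na(pairs$queryLabel)
  meanSim <- if (any(matched)) mean(pairs$similarity[matched]) else 0
  covR <- sum(matched) / n
  covQ <- sum(matched) / m
  new("ModuleAlignment",
      refId = ref@clusterId, queryId = query@clusterId, pairs = pairs,
      refGaps = pairs$refLabel[!is.na(pairs$refLabel) & is.na(pairs$queryLabel)],
      queryGaps = pairs$queryLabel[is.na(pairs$refLabel) & !is.na(pairs$queryLabel)],
      meanSimilarity = meanSim, coverage = covR, queryCoverage = covQ,
      score = S[n + 1L, m + 1L],
      ortholog = meanSim >= params$sMin && covR >= params$cMin &&
        covQ >= params$cMin)
}

#' @rdname accessors
#' @export
setMethod("alignmentPairs", "ModuleAlignment", function(x) x@pairs)

#' @rdname accessors
#' @export
setMethod("isOrtholog", "ModuleAlignment", function(x) x@ortholog)

setMethod("show", "ModuleAlignment", function(object) {
  cat(sprintf(paste0("ModuleAlignment %s vs %s: %d pair(s), ",
                     "%d/%d gap(s), mean similarity %.3f, ",
                     "coverage %.2f/%.2f, %s\n"),
              object@refId, object@queryId,
              sum(stats::complete.cases(object@pairs[, 1:2])),
              length(object@refGaps), length(object@queryGaps),
              object@meanSimilarity, object@coverage, object@queryCoverage,
              if (object@ortholog) "ortholog" else "not ortholog"))
})

#' Render an alignment as a side-by-side table
#'
#' Three columns mimicking the domain-organization comparison tables of the
#' literature: reference module label, reference domain string, query domain
#' string ("-" at a gap).
#'
#' @param aln a ModuleAlignment.
#' @param ref,query the clusters that were aligned.
#' @param path optional TSV output file.
#' @return data.frame, invisibly when written.
#' @export
renderAlignment <- function(aln, ref, query, path = NULL) {
  rmods <- .alignable_modules(ref)
  qmods <- .alignable_modules(query)
  rlab <- vapply(rmods, function(x) x@indexLabel, character(1))
  qlab <- vapply(qmods, function(x) x@indexLabel, character(1))
  pr <- aln@pairs
  df <- data.frame(
    module = ifelse(is.na(pr$refLabel), "-", pr$refLabel),
    reference = ifelse(is.na(pr$refLabel), "-",
                       vapply(pr$refLabel, function(l)
                         if (is.na(l)) "-" else
                           .serialize_module(rmods[[match(l, rlab)]]),
                         character(1))),
    query = ifelse(is.na(pr$queryLabel), "-",
                   vapply(pr$queryLabel, function(l)
                     if (is.na(l)) "-" else
                       .serialize_module(qmods[[match(l, qlab)]]),
                     character(1))),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(df))
  }
  df
}
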