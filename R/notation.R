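## Parsing and serialization of the compact assembly-line notation:
## modules separated by "-", domains within a module by "/", AT/A
## specificities as subscripts ("AT_m_", "AT_mm_", "A_thr_"; the laxer
## dialects "AT_m" and "ATm" normalize identically), an ellipsis at either
## end marking a truncated ORF.

.ELLIPSIS_RE <- "(\\.\\.\\.|…)"

.spec_long <- c(m = "malonyl", mm = "methylmalonyl")
.spec_short <- c(malonyl = "m", methylmalonyl = "mm")

#' Construct a domain token
#'
#' @param label domain code (member of the closed enumeration; anything else
#'   becomes "X" with the raw text preserved).
#' @param specificity optional specificity ("malonyl"/"methylmalonyl" for AT,
#'   a lowercase residue code for A), NA when unannotated.
#' @param truncated logical, domain abuts an ellipsis marker.
#' @param raw raw source text (defaults to the label).
#' @return a DomainToken.
#' @export
domainToken <- function(label, specificity = NA_character_,
                        truncated = FALSE, raw = label) {
  if (!(label %in% DOMAIN_LABELS)) {
    raw <- label
    label <- "X"
  }
  new("DomainToken", label = label,
      specificity = as.character(specificity),
      truncated = truncated, raw = raw)
}

## Parse a single domain token such as "AT_mm_" or "A_b-ala_".
.parse_domain <- function(tok) {
  if (!nzchar(tok))
    stop("empty domain token in notation string", call. = FALSE)
  if (grepl("_$", tok) && !grepl("^[A-Za-z]+_[A-Za-z0-9-]+_$", tok) ||
      grepl("__", tok) || grepl("^_", tok))
    stop("unbalanced specificity subscript in token '", tok, "'",
         call. = FALSE)
  ## unicode Greek spellings of the type-II components
  if (tok %in% c("KSa", "KSα", "KSalpha")) return(domainToken("KSalpha", raw = tok))
  if (tok %in% c("KSb", "KSβ", "KSbeta")) return(domainToken("KSbeta", raw = tok))
  if (tok %in% DOMAIN_LABELS) return(domainToken(tok))
  m <- regmatches(tok, regexec("^AT_?(m{1,2})_?$", tok))[[1]]
  if (length(m) == 2L)
    return(domainToken("AT", specificity = .spec_long[[m[2]]], raw = tok))
  if (grepl("^AT_", tok))
    stop("unbalanced specificity subscript in token '", tok, "'",
         call. = FALSE)
  m <- regmatches(tok, regexec("^A_?([a-z][a-z0-9-]*)_?$", tok))[[1]]
  if (length(m) == 2L)
    return(domainToken("A", specificity = m[2], raw = tok))
  if (grepl("^A_", tok))
    stop("unbalanced specificity subscript in token '", tok, "'",
         call. = FALSE)
  domainToken(tok)  # unknown code -> X, raw preserved
}

.module <- function(domains, role, indexLabel = "") {
  new("AssemblyModule", domains = domains, role = role, indexLabel = indexLabel)
}

.mod_labels <- function(mod) vapply(mod@domains, function(d) d@label, character(1))

## Segment classification.  A segment is one "/"-joined run between "-"
## separators.  Returns a role string.
.classify_segment <- function(labels) {
  if (labels[1] == "CoL") return("loading")
  if (length(labels) == 1L) return("standalone")
  if (any(labels %in% c("KS", "C"))) return("extension")
  ## KS/C-less multi-domain units (A/T, AT_mm_/DH/KR/ACP, ...): trans-acting
  "standalone"
}

#' Parse a domain-organization string into an ORF architecture
#'
#' Grammar: segments separated by \code{-}, domains within a segment by
#' \code{/}; AT specificity as \code{_m_}/\code{_mm_} subscripts, A substrate
#' as a lowercase 3-letter (or hyphenated) code; \code{...} (or the ellipsis
#' character) at either end marks a truncated ORF.  Normalizations applied:
#' a trailing release-only segment (\code{-Te}, \code{-TD}) merges into the
#' preceding module, and a tailoring/carrier-only segment following a module
#' is merged likewise, so \code{"KS/AT_m_/ACP-Te"} and
#' \code{"KS/AT_m_/ACP/Te"} parse identically.  Unknown domain codes become
#' \code{X} with their raw text preserved, never dropped.
#'
#' @param text notation string, non-empty after whitespace stripping.
#' @param orfId ORF identifier, e.g. "1-1098".
#' @return an OrfArchitecture.
#' @examples
#' parseOrfArchitecture("C/A_ser_/T-C/A_pro_/T-Te", "12-31")
#' @export
parseOrfArchitecture <- function(text, orfId = "orf") {
  if (length(text) != 1L || is.na(text))
    stop("'text' must be a single notation string", call. = FALSE)
  s <- gsub("[[:space:]]+", "", text)
  if (!nzchar(s))
    stop("cannot parse an empty domain-organization string", call. = FALSE)
  left <- grepl(paste0("^", .ELLIPSIS_RE), s)
  right <- grepl(paste0(.ELLIPSIS_RE, "$"), s)
  s <- sub(paste0("^", .ELLIPSIS_RE), "", s)
  s <- sub(paste0(.ELLIPSIS_RE, "$"), "", s)
  if (grepl(.ELLIPSIS_RE, s))
    stop("ellipsis marker is only allowed at the ends of the string",
         call. = FALSE)
  if (!nzchar(s))
    stop("notation string contains no domains", call. = FALSE)
  segs <- strsplit(s, "-(?=[A-Z])", perl = TRUE)[[1]]
  ## the lookahead keeps hyphens inside substrate codes ("b-ala") intact:
  ## domain codes start uppercase, substrate codes are lowercase.
  segs <- segs[nzchar(segs)]
  mods <- list()
  for (seg in segs) {
    toks <- strsplit(seg, "/", fixed = TRUE)[[1]]
    if (any(!nzchar(toks)))
      stop("empty domain in segment '", seg, "'", call. = FALSE)
    doms <- lapply(toks, .parse_domain)
    labels <- vapply(doms, function(d) d@label, character(1))
    n <- length(mods)
    if (all(labels %in% RELEASE_LABELS) && n > 0L) {
      mods[[n]]@domains <- c(mods[[n]]@domains, doms)
      next
    }
    if (all(labels %in% TAILORING_LABELS) && n > 0L &&
        mods[[n]]@role != "standalone") {
      mods[[n]]@domains <- c(mods[[n]]@domains, doms)
      next
    }
    role <- .classify_segment(labels)
    mods[[length(mods) + 1L]] <- .module(doms, role)
  }
  if (left && length(mods))
    mods[[1]]@domains[[1]]@truncated <- TRUE
  if (right && length(mods)) {
    lastm <- length(mods)
    lastd <- length(mods[[lastm]]@domains)
    mods[[lastm]]@domains[[lastd]]@truncated <- TRUE
  }
  new("OrfArchitecture", orfId = orfId, modules = mods,
      leftTruncated = left, rightTruncated = right)
}

.serialize_domain <- function(d) {
  if (d@label == "X") return(d@raw)
  if (!is.na(d@specificity)) {
    suffix <- if (d@label == "AT") .spec_short[[d@specificity]] else d@specificity
    return(paste0(d@label, "_", suffix, "_"))
  }
  d@label
}

.serialize_module <- function(mod)
  paste(vapply(mod@domains, .serialize_domain, character(1)), collapse = "/")

#' Serialize an ORF architecture back to notation
#'
#' Inverse of \code{\link{parseOrfArchitecture}} up to normalization:
#' specificities are rendered as balanced subscripts (\code{AT_m_},
#' \code{A_thr_}) and merged release segments stay inside their module.
#' Round-trip identity holds: parsing the output reproduces the architecture.
#'
#' @param orf an OrfArchitecture.
#' @return a notation string.
#' @export
serializeOrfArchitecture <- function(orf) {
  stopifnot(is(orf, "OrfArchitecture"))
  body <- paste(vapply(orf@modules, .serialize_module, character(1)),
                collapse = "-")
  paste0(if (orf@leftTruncated) "..." else "", body,
         if (orf@rightTruncated) "..." else "")
}

#' Assemble a gene cluster from parsed ORFs
#'
#' Applies the cluster-level conventions: the first piece of the first ORF is
#' promoted to the loading module when it is an A/AT-bearing unit without
#' KS/C (a CoA-ligase-led segment is already loading), module index labels are
#' assigned cluster-wide ("L" for loading, ordinals for the rest), and the
#' completeness flag is forced FALSE if any ORF is truncated.
#'
#' @param clusterId cluster identifier.
#' @param orfList list of OrfArchitecture.
#' @param declaredType declared cluster type tag.
#' @param complete logical, cluster completely sequenced.
#' @param strainId strain identifier.
#' @param annotation known-product note ("" when orphan).
#' @return a GeneCluster.
#' @export
geneCluster <- function(clusterId, orfList, declaredType = "unknown",
                        complete = TRUE, strainId = "strain",
                        annotation = "") {
  if (length(orfList) && length(orfList[[1]]@modules)) {
    first <- orfList[[1]]@modules[[1]]
    labs <- .mod_labels(first)
    if (first@role == "standalone" && any(labs %in% c("A", "AT")) &&
        !orfList[[1]]@leftTruncated)
      orfList[[1]]@modules[[1]]@role <- "loading"
  }
  trunc <- any(vapply(orfList,
                      function(o) o@leftTruncated || o@rightTruncated,
                      logical(1)))
  cl <- new("GeneCluster", clusterId = clusterId,
            declaredType = declaredType, orfs = orfList,
            complete = complete && !trunc, strainId = strainId,
            annotation = annotation)
  .relabel_modules(cl)
}

## Assign index labels: "L" to loading modules, 1..n to the others
## (extension and standalone alike, in gene order), the numbering convention
## of published domain-organization tables.
.relabel_modules <- function(cl) {
  idx <- 0L
  for (i in seq_along(cl@orfs)) {
    for (j in seq_along(cl@orfs[[i]]@modules)) {
      m <- cl@orfs[[i]]@modules[[j]]
      if (m@role == "loading") {
        cl@orfs[[i]]@modules[[j]]@indexLabel <- "L"
      } else if (m@role == "extension") {
        idx <- idx + 1L
        cl@orfs[[i]]@modules[[j]]@indexLabel <- as.character(idx)
      } else {
        cl@orfs[[i]]@modules[[j]]@indexLabel <-
          paste0("s", i, ".", j)
      }
    }
  }
  cl
}

#' Quick single-architecture cluster for examples and tests
#'
#' Builds a one-ORF GeneCluster directly from a notation string.
#'
#' @param text notation string.
#' @param clusterId,orfId,declaredType,strainId,annotation passed through.
#' @return a GeneCluster.
#' @export
demoCluster <- function(text, clusterId = "demo", orfId = "orf-1",
                        declaredType = "unknown", strainId = "strain",
                        annotation = "") {
  geneCluster(clusterId, list(parseOrfArchitecture(text, orfId)),
              declaredType = declaredType, strainId = strainId,
              annotation = annotation)
}

## ---- accessors and show methods ----

#' @rdname accessors
#' @export
setMethod("clusterId", "GeneCluster", function(x) x@clusterId)

#' @rdname accessors
#' @export
setMethod("strainId", "GeneCluster", function(x) x@strainId)

#' @rdname accessors
#' @export
setMethod("strainId", "ClusterInventory", function(x) x@strainId)

#' @rdname accessors
#' @export
setMethod("clusters", "ClusterInventory", function(x) {
  names(x@clusters) <- vapply(x@clusters, clusterId, character(1))
  x@clusters
})

#' @rdname accessors
#' @export
setMethod("orfs", "GeneCluster", function(x) x@orfs)

#' @rdname accessors
#' @export
setMethod("modules", "OrfArchitecture", function(x) x@modules)

#' @rdname accessors
#' @export
setMethod("modules", "GeneCluster", function(x)
  do.call(c, c(lapply(x@orfs, function(o) o@modules), list(list()))))

#' @rdname accessors
#' @export
setMethod("domainLabels", "AssemblyModule", function(x) .mod_labels(x))

#' @rdname accessors
#' @export
setMethod("domainLabels", "GeneCluster", function(x)
  unlist(lapply(modules(x), .mod_labels), use.names = FALSE) %||% character())

#' @rdname accessors
#' @export
setMethod("isComplete", "GeneCluster", function(x) x@complete)

#' @rdname accessors
#' @export
setMethod("annotation", "GeneCluster", function(x) x@annotation)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn countModules loading plus extension modules across all ORFs.
#' @export
setMethod("countModules", "GeneCluster", function(x) {
  sum(vapply(x@orfs, function(o) countModules(o), integer(1)))
})

#' @describeIn countModules module count of a single ORF.
#' @export
setMethod("countModules", "OrfArchitecture", function(x) {
  sum(vapply(x@modules, function(m) m@role %in% c("loading", "extension"),
             logical(1)))
})

setMethod("show", "DomainToken", function(object) {
  cat("DomainToken:", .serialize_domain(object),
      if (object@truncated) "(truncated)" else "", "\n")
})

setMethod("show", "AssemblyModule", function(object) {
  cat(sprintf("Module [%s%s] %s\n", object@role,
              if (nzchar(object@indexLabel))
                paste0(" ", object@indexLabel) else "",
              .serialize_module(object)))
})

setMethod("show", "OrfArchitecture", function(object) {
  cat(sprintf("OrfArchitecture %s: %s\n", object@orfId,
              serializeOrfArchitecture(object)))
})

setMethod("show", "GeneCluster", function(object) {
  cat(sprintf("GeneCluster %s (%s) of %s: %d ORF(s), %d module(s)%s\n",
              object@clusterId, object@declaredType, object@strainId,
              length(object@orfs), countModules(object),
              if (object@complete) "" else " [incomplete]"))
  for (o in object@orfs)
    cat("  ", o@orfId, "  ", serializeOrfArchitecture(o), "\n", sep = "")
})

setMethod("show", "ClusterInventory", function(object) {
  cat(sprintf("ClusterInventory of %s: %d cluster(s)\n", object@strainId,
              length(object@clusters)))
  for (cl in object@clusters)
    cat(sprintf("  %-12s %-8s %2d modules%s\n", cl@clusterId,
                cl@declaredType, countModules(cl),
                if (cl@complete) "" else " [incomplete]"))
})
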