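#' @import methods
NULL

## Closed enumeration of catalytic-domain codes used in the notation.
## X is the catch-all for codes outside the enumeration; the raw text is kept.
DOMAIN_LABELS <- c(
  "KS", "AT", "DH", "ER", "KR", "ACP", "CoL", "Te", "TD", "E", "MT",
  "AmT", "C", "A", "T", "KSalpha", "KSbeta", "X"
)

## Domains that may carry a specificity subscript.
SPECIFIC_LABELS <- c("AT", "A")

## Chain-release domains; a trailing release-only segment merges into the
## preceding module so that "KS/AT_m_/ACP-Te" and "KS/AT_m_/ACP/Te" normalize
## identically.
RELEASE_LABELS <- c("Te", "TD")

## Tailoring and carrier domains: a segment made only of these, following a
## module, is a continuation of that module rather than a module of its own.
TAILORING_LABELS <- c("DH", "ER", "KR", "ACP", "T", "MT", "E", "AmT", "X")

MODULE_ROLES <- c("loading", "extension", "standalone")

CLUSTER_TYPES <- c("t1pks", "t2pks", "t3pks", "nrps", "pks_nrps", "unknown")

PRODUCT_CATEGORIES <- c(
  "polyketide", "peptide", "hybrid", "aromatic_polyketide",
  "type3_polyketide", "unpredictable"
)

RELEASE_MODES <- c("thioesterase", "reductive", "none_detected")

#' DomainToken: a single catalytic domain
#'
#' One domain of an assembly line, e.g. the \code{AT} of
#' \code{KS/AT_m_/KR/ACP}.  \code{specificity} holds \code{"malonyl"} or
#' \code{"methylmalonyl"} for AT domains and a lowercase residue code (e.g.
#' \code{"thr"}, \code{"b-ala"}, \code{"dhb"}) for A domains; it is \code{NA}
#' when unannotated and must be \code{NA} for every other label.  \code{raw}
#' preserves the source text for unknown (\code{X}) codes.
#'
#' @slot label character(1), one of the closed domain enumeration.
#' @slot specificity character(1) or NA.
#' @slot truncated logical(1), TRUE when the domain abuts an ellipsis marker.
#' @slot raw character(1), source token text.
#' @exportClass DomainToken
setClass("DomainToken", representation(
  label = "character",
  specificity = "character",
  truncated = "logical",
  raw = "character"
))

setValidity("DomainToken", function(object) {
  msg <- character()
  if (length(object@label) != 1L || !(object@label %in% DOMAIN_LABELS))
    msg <- c(msg, "label must be one of the domain enumeration")
  if (!is.na(object@specificity) && !(object@label %in% SPECIFIC_LABELS))
    msg <- c(msg, "specificity is only allowed on AT and A domains")
  if (length(msg)) msg else TRUE
})

#' AssemblyModule: an ordered run of domains
#'
#' Roles: \code{extension} (contains KS or C and elongates the chain),
#' \code{loading} (chain initiation: CoA-ligase led, or an A/AT-bearing unit
#' with no KS/C), \code{standalone} (trans-acting pieces not part of the
#' cis assembly line).  \code{indexLabel} is "L" for the loading module and a
#' 1-based ordinal (cluster-wide) otherwise.
#'
#' @slot domains list of DomainToken, order preserved as parsed.
#' @slot role character(1): loading, extension or standalone.
#' @slot indexLabel character(1).
#' @exportClass AssemblyModule
setClass("AssemblyModule", representation(
  domains = "list",
  role = "character",
  indexLabel = "character"
))

setValidity("AssemblyModule", function(object) {
  msg <- character()
  if (!all(vapply(object@domains, is, logical(1), "DomainToken")))
    msg <- c(msg, "domains must all be DomainToken objects")
  if (!(object@role %in% MODULE_ROLES))
    msg <- c(msg, "role must be loading, extension or standalone")
  labs <- vapply(object@domains, function(d) d@label, character(1))
  if (object@role == "extension" && !any(labs %in% c("KS", "C")))
    msg <- c(msg, "an extension module must contain a KS or C domain")
  if (object@role == "loading" && any(labs %in% c("KS", "C")) &&
      labs[1] != "CoL")
    msg <- c(msg, "a loading module contains no KS/C, or begins with CoL")
  if (length(msg)) msg else TRUE
})

#' OrfArchitecture: the parsed domain organization of one ORF
#'
#' All pieces of the ORF, including single-domain standalones, are held as
#' Module objects (role \code{standalone} for trans-acting pieces) so that
#' order along the gene is a single list.
#'
#' @slot orfId character(1), e.g. "1-1098".
#' @slot modules list of Module in gene order.
#' @slot leftTruncated,rightTruncated logical(1); TRUE iff the source string
#'   began/ended with an ellipsis marker ("..." or the single-char ellipsis).
#' @exportClass OrfArchitecture
setClass("OrfArchitecture", representation(
  orfId = "character",
  modules = "list",
  leftTruncated = "logical",
  rightTruncated = "logical"
))

setValidity("OrfArchitecture", function(object) {
  msg <- character()
  if (!all(vapply(object@modules, is, logical(1), "AssemblyModule")))
    msg <- c(msg, "modules must all be Module objects")
  if (length(object@orfId) != 1L || !nzchar(object@orfId))
    msg <- c(msg, "orfId must be a non-empty string")
  if (length(msg)) msg else TRUE
})

#' GeneCluster: a typed secondary-metabolite gene cluster
#'
#' @slot clusterId character(1), unique within an inventory.
#' @slot declaredType character(1): t1pks, t2pks, t3pks, nrps, pks_nrps or
#'   unknown, as declared in the source table (content-based typing is done by
#'   \code{\link{classifyCluster}}).
#' @slot orfs list of OrfArchitecture in cluster order.
#' @slot complete logical(1); FALSE when the cluster is not completely
#'   sequenced (any truncated ORF forces FALSE).
#' @slot strainId character(1).
#' @slot annotation character(1): known-product note carried as metadata (from
#'   similarity searches external to this package), "" when orphan.
#' @exportClass GeneCluster
setClass("GeneCluster", representation(
  clusterId = "character",
  declaredType = "character",
  orfs = "list",
  complete = "logical",
  strainId = "character",
  annotation = "character"
))

setValidity("GeneCluster", function(object) {
  msg <- character()
  if (!(object@declaredType %in% CLUSTER_TYPES))
    msg <- c(msg, "declaredType must be a known cluster type")
  if (!all(vapply(object@orfs, is, logical(1), "OrfArchitecture")))
    msg <- c(msg, "orfs must all be OrfArchitecture objects")
  trunc <- vapply(object@orfs, function(o) o@leftTruncated || o@rightTruncated,
                  logical(1))
  if (length(trunc) && any(trunc) && object@complete)
    msg <- c(msg, "a cluster with a truncated ORF cannot be complete")
  if (length(msg)) msg else TRUE
})

#' ClusterInventory: the secondary-metabolite cluster inventory of one strain
#'
#' @slot strainId character(1).
#' @slot clusters list of GeneCluster, all sharing strainId, unique ids.
#' @exportClass ClusterInventory
setClass("ClusterInventory", representation(
  strainId = "character",
  clusters = "list"
))

setValidity("ClusterInventory", function(object) {
  msg <- character()
  if (!all(vapply(object@clusters, is, logical(1), "GeneCluster")))
    msg <- c(msg, "clusters must all be GeneCluster objects")
  sid <- vapply(object@clusters, function(cl) cl@strainId, character(1))
  if (length(sid) && !all(sid == object@strainId))
    msg <- c(msg, "all clusters must share the inventory strainId")
  ids <- vapply(object@clusters, function(cl) cl@clusterId, character(1))
  if (anyDuplicated(ids))
    msg <- c(msg, "cluster ids must be unique within an inventory")
  if (length(msg)) msg else TRUE
})

#' ProductPrediction: co-linearity product skeleton
#'
#' @slot clusterId character(1).
#' @slot category character(1): polyketide, peptide, hybrid,
#'   aromatic_polyketide, type3_polyketide or unpredictable.
#' @slot units character vector of unit tokens: residue codes, "x"
#'   (unidentified residue), "y" (module lacks an A domain), "pk" (polyketide
#'   extender unit) or "st" (starter).
#' @slot lengthName character(1), e.g. "dipeptide", "hexaketide".
#' @slot colinear logical(1); FALSE when trans-acting standalone pieces make
#'   the cis unit order unreliable.
#' @slot release character(1): thioesterase, reductive or none_detected.
#' @exportClass ProductPrediction
setClass("ProductPrediction", representation(
  clusterId = "character",
  category = "character",
  units = "character",
  lengthName = "character",
  colinear = "logical",
  release = "character"
))

setValidity("ProductPrediction", function(object) {
  msg <- character()
  if (!(object@category %in% PRODUCT_CATEGORIES))
    msg <- c(msg, "unknown product category")
  if (!(object@release %in% RELEASE_MODES))
    msg <- c(msg, "unknown release mode")
  if (length(msg)) msg else TRUE
})

#' ModuleAlignment: global alignment of two module sequences
#'
#' @slot refId,queryId character(1), cluster ids.
#' @slot pairs data.frame with columns refLabel, queryLabel (NA for a gap on
#'   the opposite side), similarity (NA at gaps), in alignment order.
#' @slot refGaps,queryGaps character vectors of module index labels with no
#'   counterpart on the other side.
#' @slot meanSimilarity numeric(1) in [0,1], over non-gap pairs only.
#' @slot coverage numeric(1): fraction of reference modules aligned.
#' @slot queryCoverage numeric(1): same for the query.
#' @slot score numeric(1): the dynamic-programming score.
#' @slot ortholog logical(1): verdict at the thresholds used.
#' @exportClass ModuleAlignment
setClass("ModuleAlignment", representation(
  refId = "character",
  queryId = "character",
  pairs = "data.frame",
  refGaps = "character",
  queryGaps = "character",
  meanSimilarity = "numeric",
  coverage = "numeric",
  queryCoverage = "numeric",
  score = "numeric",
  ortholog = "logical"
))

#' InventoryComparison: one-to-one conserved-cluster matching
#'
#' @slot matchedPairs list; each element a list with elements refId, queryId
#'   and alignment (ModuleAlignment or NULL for content-matched non-modular
#'   clusters) plus similarity.
#' @slot unmatchedA,unmatchedB character vectors of cluster ids.
#' @exportClass InventoryComparison
setClass("InventoryComparison", representation(
  matchedPairs = "list",
  unmatchedA = "character",
  unmatchedB = "character"
))

#' TaxonVerdict: a threshold-rule species verdict
#'
#' @slot metric character(1): identity_16S, identity_gyrB or dDDH.
#' @slot value numeric(1), percent in [0,100].
#' @slot threshold numeric(1), percent.
#' @slot verdict character(1): same_species, distinct_species or inconclusive.
#' @exportClass TaxonVerdict
setClass("TaxonVerdict", representation(
  metric = "character",
  value = "numeric",
  threshold = "numeric",
  verdict = "character"
))

setValidity("TaxonVerdict", function(object) {
  msg <- character()
  if (!(object@metric %in% c("identity_16S", "identity_gyrB", "dDDH")))
    msg <- c(msg, "unknown metric")
  if (!(object@verdict %in% c("same_species", "distinct_species",
                              "inconclusive")))
    msg <- c(msg, "unknown verdict")
  if (object@value < 0 || object@value > 100)
    msg <- c(msg, "value must be a percent in [0,100]")
  if (length(msg)) msg else TRUE
})
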