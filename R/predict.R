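## Cluster typing and co-linearity product prediction.

#' Classify a gene cluster from its content
#'
#' Content-based typing, independent of the declared type tag:
#' \itemize{
#'   \item \code{t2pks}: no modules, and the standalone domains include the
#'     iterative type-II components KSalpha and KSbeta (chain length factor).
#'   \item \code{t3pks}: a single ORF holding a single standalone KS.
#'   \item \code{pks_nrps} (hybrid): both KS-bearing pieces and A/C-bearing
#'     pieces present.
#'   \item \code{t1pks}: KS/AT machinery only.
#'   \item \code{nrps}: C/A/T machinery only.
#' }
#' Anything matching no rule is \code{unknown}.
#'
#' @param cluster a GeneCluster.
#' @return a cluster type string.
#' @examples
#' classifyCluster(demoCluster("C/A_ser_/T-C/A_pro_/T-Te"))  # "nrps"
#' @export
classifyCluster <- function(cluster) {
  stopifnot(is(cluster, "GeneCluster"))
  mods <- modules(cluster)
  roles <- vapply(mods, function(m) m@role, character(1))
  labsets <- lapply(mods, .mod_labels)
  all_labels <- unlist(labsets, use.names = FALSE)
  countable <- roles %in% c("loading", "extension")

  if (!any(countable)) {
    if (all(c("KSalpha", "KSbeta") %in% all_labels)) return("t2pks")
    if (length(cluster@orfs) == 1L && length(mods) == 1L &&
        identical(all_labels, "KS")) return("t3pks")
  }
  has_pk <- any(vapply(seq_along(mods), function(i)
    countable[i] && any(labsets[[i]] %in% c("KS", "AT")), logical(1)))
  has_nrps <- any(vapply(seq_along(mods), function(i)
    any(labsets[[i]] %in% c("C", "A")), logical(1)))
  ## trans-acting KS pieces (e.g. a lone KS ORF inside a hybrid cluster)
  has_pk <- has_pk || ("KS" %in% all_labels && any(countable))
  if (has_pk && has_nrps) return("pks_nrps")
  if (has_pk) return("t1pks")
  if (has_nrps) return("nrps")
  "unknown"
}

.GREEK <- c("mono", "di", "tri", "tetra", "penta", "hexa", "hepta", "octa",
            "nona", "deca")

.length_name <- function(n, suffix) {
  if (n >= 1 && n <= length(.GREEK)) paste0(.GREEK[n], suffix)
  else paste0(n, "-", suffix)
}

## Unit contributed by one countable module (or loading piece); NA = none.
.module_unit <- function(labels, specs) {
  if ("KS" %in% labels) return("pk")
  if (labels[1] == "CoL") return("st")
  a <- which(labels == "A")
  if (length(a)) {
    s <- specs[a[1]]
    return(if (is.na(s)) "x" else s)
  }
  if (any(labels %in% c("C", "T", "ACP"))) return("y")
  NA_character_
}

#' Predict the product skeleton of a cluster by the co-linearity rule
#'
#' One unit per assembly-line module, in gene order: the A-domain substrate
#' (or \code{"x"} if unannotated) for NRPS modules, \code{"y"} for a module
#' lacking an A domain, \code{"pk"} per KS-bearing module, \code{"st"} for a
#' CoA-ligase starter.  Trans-acting standalone pieces contribute under the
#' trans-complementation rule (see the methods vignette): an annotated
#' standalone A contributes its residue; an A with a carrier contributes
#' \code{"x"}; a bare unannotated A contributes \code{"x"} only when an
#' unpaired standalone C exists; pieces after a release domain in the same
#' ORF contribute nothing.  Clusters with trans-acting pieces are flagged
#' \code{colinear = FALSE}: their unit order carries no guarantee beyond gene
#' order.  Incomplete clusters and clusters without countable units are
#' \code{unpredictable}; iterative type-II/III clusters get their category
#' with an empty unit list.
#'
#' @param cluster a GeneCluster.
#' @return a ProductPrediction.
#' @examples
#' predictProduct(demoCluster("C/A_ser_/T-C/A_pro_/T-Te"))  # ser-pro dipeptide
#' @export
predictProduct <- function(cluster) {
  stopifnot(is(cluster, "GeneCluster"))
  type <- classifyCluster(cluster)
  rel <- .release_mode(cluster)
  mk <- function(category, units = character(), lengthName = "",
                 colinear = TRUE)
    new("ProductPrediction", clusterId = cluster@clusterId,
        category = category, units = units, lengthName = lengthName,
        colinear = colinear, release = rel)

  if (type == "t2pks") return(mk("aromatic_polyketide"))
  if (type == "t3pks") return(mk("type3_polyketide"))
  if (!isComplete(cluster)) return(mk("unpredictable", colinear = FALSE))

  pieces <- .cluster_pieces(cluster)
  units <- .derive_units(pieces)
  if (!length(units$unit)) return(mk("unpredictable"))
  colinear <- !any(pieces$standalone)

  n_res <- sum(!(units$unit %in% c("pk", "st")))
  n_pk <- sum(units$unit == "pk")
  if (type == "nrps") {
    return(mk("peptide", units$unit, .length_name(n_res, "peptide"),
              colinear))
  }
  if (type == "t1pks") {
    return(mk("polyketide", units$unit, .length_name(n_pk, "ketide"),
              colinear))
  }
  if (type == "pks_nrps") {
    ln <- if (n_res <= 1L && n_pk >= 2L) {
      resid <- setdiff(units$unit, c("pk", "st"))
      paste0(.length_name(n_pk, "ketide"),
             if (length(resid)) paste0(" with ", resid[1]) else "")
    } else {
      paste0(.length_name(n_res, "peptide"), " with polyketide ",
             if (n_pk + sum(units$unit == "st") >= 2L) "moieties" else "moiety")
    }
    return(mk("hybrid", units$unit, ln, colinear))
  }
  mk("unpredictable")
}

.release_mode <- function(cluster) {
  labs <- unlist(lapply(modules(cluster), .mod_labels), use.names = FALSE)
  if ("Te" %in% labs) "thioesterase"
  else if ("TD" %in% labs) "reductive"
  else "none_detected"
}

## Flatten a cluster into an ordered piece table: one row per module with its
## labels, first-A specificity, standalone flag, and whether it follows a
## release domain within the same ORF.
.cluster_pieces <- function(cluster) {
  labels <- list(); specs <- list()
  role <- character(); post_release <- logical()
  for (o in cluster@orfs) {
    released <- FALSE
    for (m in o@modules) {
      labs <- .mod_labels(m)
      labels[[length(labels) + 1L]] <- labs
      specs[[length(specs) + 1L]] <-
        vapply(m@domains, function(d) d@specificity, character(1))
      role <- c(role, m@role)
      post_release <- c(post_release, released)
      if (any(labs %in% RELEASE_LABELS)) released <- TRUE
    }
  }
  list(labels = labels, specs = specs, role = role,
       standalone = role == "standalone", post_release = post_release)
}

## The unit-derivation walk, including the trans-complementation rule for
## standalone pieces of non-colinear clusters.
.derive_units <- function(p) {
  n <- length(p$role)
  unit <- rep(NA_character_, n)
  ## unpaired standalone C pool (indices), consumed by bare unannotated As
  free_c <- which(p$standalone &
                    vapply(p$labels, function(l) identical(l, "C"), logical(1)))
  for (i in seq_len(n)) {
    if (p$post_release[i] && p$standalone[i]) next
    labs <- p$labels[[i]]
    specs <- p$specs[[i]]
    if (p$role[i] %in% c("loading", "extension")) {
      unit[i] <- .module_unit(labs, specs)
      next
    }
    ## standalone pieces
    a <- which(labs == "A")
    if (!length(a)) next
    s <- specs[a[1]]
    has_carrier <- any(labs %in% c("T", "ACP"))
    if (!is.na(s)) {
      unit[i] <- s
    } else if (has_carrier) {
      unit[i] <- "x"
    } else if (length(free_c)) {
      unit[i] <- "x"
      free_c <- free_c[-1]
    }
  }
  keep <- !is.na(unit)
  list(unit = unit[keep], index = which(keep))
}

#' @rdname accessors
#' @export
setMethod("units", "ProductPrediction", function(x) x@units)

#' @rdname accessors
#' @export
setMethod("clusterId", "ProductPrediction", function(x) x@clusterId)

setMethod("show", "ProductPrediction", function(object) {
  cat(sprintf("ProductPrediction %s: %s%s%s [release: %s]%s\n",
              object@clusterId, object@category,
              if (nzchar(object@lengthName))
                paste0(" ", object@lengthName) else "",
              if (length(object@units))
                paste0(" (", paste(object@units, collapse = "-"), ")") else "",
              object@release,
              if (object@colinear) "" else " [non-colinear]"))
})

#' Prediction report over an inventory
#'
#' Applies \code{\link{predictProduct}} to every cluster and returns a table;
#' optionally writes TSV or JSON.
#'
#' @param inv a ClusterInventory.
#' @param path optional output file.
#' @param format "tsv" or "json" (used when \code{path} is given).
#' @return data.frame with columns cluster_id, category, length_name, units
#'   (hyphen-joined), colinear, release.
#' @export
predictionReport <- function(inv, path = NULL, format = c("tsv", "json")) {
  format <- match.arg(format)
  preds <- lapply(inv@clusters, predictProduct)
  df <- data.frame(
    cluster_id = vapply(preds, function(p) p@clusterId, character(1)),
    category = vapply(preds, function(p) p@category, character(1)),
    length_name = vapply(preds, function(p) p@lengthName, character(1)),
    units = vapply(preds, function(p) paste(p@units, collapse = "-"),
                   character(1)),
    colinear = vapply(preds, function(p) p@colinear, logical(1)),
    release = vapply(preds, function(p) p@release, character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    if (format == "tsv")
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    else jsonlite::write_json(df, path, auto_unbox = TRUE, pretty = TRUE)
  }
  df
}

#' Domain-level differences against a reference architecture
#'
#' Aligns the two clusters (see \code{\link{alignClusters}}) and reports, per
#' aligned module pair, the domains gained in the cluster relative to the
#' reference and the domains lost, e.g. the methyltransferase gained by a
#' tallysomycin-like hybrid module.
#'
#' @param cluster,reference GeneCluster objects.
#' @param ... passed to \code{\link{alignClusters}}.
#' @return data.frame with columns ref_module, query_module, gained, lost
#'   (comma-joined label lists), similarity; gap rows keep NA on the absent
#'   side.
#' @export
conservedAnnotationCheck <- function(cluster, reference, ...) {
  aln <- alignClusters(reference, cluster, ...)
  refmods <- .alignable_modules(reference)
  qmods <- .alignable_modules(cluster)
  reflab <- vapply(refmods, function(m) m@indexLabel, character(1))
  qlab <- vapply(qmods, function(m) m@indexLabel, character(1))
  pr <- aln@pairs
  gained <- lost <- character(nrow(pr))
  for (i in seq_len(nrow(pr))) {
    if (is.na(pr$refLabel[i]) || is.na(pr$queryLabel[i])) {
      gained[i] <- lost[i] <- NA_character_
      next
    }
    rl <- unique(.mod_labels(refmods[[match(pr$refLabel[i], reflab)]]))
    ql <- unique(.mod_labels(qmods[[match(pr$queryLabel[i], qlab)]]))
    gained[i] <- paste(setdiff(ql, rl), collapse = ",")
    lost[i] <- paste(setdiff(rl, ql), collapse = ",")
  }
  data.frame(ref_module = pr$refLabel, query_module = pr$queryLabel,
             gained = gained, lost = lost, similarity = pr$similarity,
             stringsAsFactors = FALSE)
}
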