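## Cluster-table file dialect: one row per ORF with columns
## strain_id, cluster_id, declared_type, complete_flag, orf_id, architecture,
## annotation.  TSV (UTF-8, header, "#" comments) or JSON (array of inventory
## objects with the same fields).

.TABLE_COLS <- c("strain_id", "cluster_id", "declared_type", "complete_flag",
                 "orf_id", "architecture", "annotation")

#' Read cluster-architecture tables
#'
#' Rows are grouped into clusters by (strain_id, cluster_id) preserving file
#' order; a "P" in \code{complete_flag} (the tables' "not completely
#' sequenced" mark) sets \code{complete = FALSE} for the whole cluster, as
#' does any truncated ORF.
#'
#' @param path file path.
#' @param dialect "tsv" or "json".
#' @return a list of ClusterInventory, one per strain, in file order.
#' @examples
#' inv <- readClusterTable(bgcFixture("tp_a0316"))[[1]]
#' length(clusters(inv))  # 15
#' @export
readClusterTable <- function(path, dialect = c("tsv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    rows <- .json_to_rows(path)
  } else {
    rows <- utils::read.delim(path, header = TRUE, sep = "\t",
                              quote = "", comment.char = "#",
                              colClasses = "character",
                              stringsAsFactors = FALSE)
  }
  missing <- setdiff(.TABLE_COLS, names(rows))
  if (length(missing))
    stop("cluster table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(rows) == 0L) return(list())
  key <- paste(rows$strain_id, rows$cluster_id, rows$orf_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stop(sprintf("duplicate (strain_id, cluster_id, orf_id) at row %d: %s/%s/%s",
                 dup, rows$strain_id[dup], rows$cluster_id[dup],
                 rows$orf_id[dup]), call. = FALSE)
  }
  out <- list()
  for (sid in unique(rows$strain_id)) {
    srows <- rows[rows$strain_id == sid, , drop = FALSE]
    cls <- list()
    for (cid in unique(srows$cluster_id)) {
      crows <- srows[srows$cluster_id == cid, , drop = FALSE]
      orfL <- lapply(seq_len(nrow(crows)), function(i) {
        tryCatch(
          parseOrfArchitecture(crows$architecture[i], crows$orf_id[i]),
          error = function(e)
            stop(sprintf("row for ORF %s of %s/%s: %s", crows$orf_id[i],
                         sid, cid, conditionMessage(e)), call. = FALSE))
      })
      complete <- !any(toupper(crows$complete_flag) == "P")
      annot <- crows$annotation[nzchar(crows$annotation)]
      cls[[length(cls) + 1L]] <- geneCluster(
        cid, orfL, declaredType = crows$declared_type[1],
        complete = complete, strainId = sid,
        annotation = if (length(annot)) annot[1] else "")
    }
    out[[length(out) + 1L]] <- new("ClusterInventory", strainId = sid,
                                   clusters = cls)
  }
  out
}

.json_to_rows <- function(path) {
  invs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  rows <- do.call(rbind, lapply(invs, function(inv) {
    do.call(rbind, lapply(inv$clusters, function(cl) {
      do.call(rbind, lapply(cl$orfs, function(o)
        data.frame(strain_id = inv$strain_id, cluster_id = cl$cluster_id,
                   declared_type = cl$declared_type,
                   complete_flag = if (isTRUE(cl$complete)) "" else "P",
                   orf_id = o$orf_id, architecture = o$architecture,
                   annotation = cl$annotation %||% "",
                   stringsAsFactors = FALSE)))
    }))
  }))
  if (is.null(rows))
    rows <- as.data.frame(stats::setNames(
      replicate(length(.TABLE_COLS), character(), simplify = FALSE),
      .TABLE_COLS), stringsAsFactors = FALSE)
  rows
}

.inventory_rows <- function(inv) {
  do.call(rbind, lapply(inv@clusters, function(cl) {
    do.call(rbind, lapply(cl@orfs, function(o)
      data.frame(strain_id = inv@strainId, cluster_id = cl@clusterId,
                 declared_type = cl@declaredType,
                 complete_flag = if (cl@complete) "" else "P",
                 orf_id = o@orfId,
                 architecture = serializeOrfArchitecture(o),
                 annotation = cl@annotation, stringsAsFactors = FALSE)))
  }))
}

#' Write cluster inventories to the table dialect
#'
#' @param inventories a ClusterInventory or list of them.
#' @param path output file.
#' @param dialect "tsv" or "json".
#' @return \code{path}, invisibly.
#' @export
writeClusterTable <- function(inventories, path, dialect = c("tsv", "json")) {
  dialect <- match.arg(dialect)
  if (is(inventories, "ClusterInventory")) inventories <- list(inventories)
  if (dialect == "tsv") {
    rows <- do.call(rbind, lapply(inventories, .inventory_rows))
    if (is.null(rows))
      rows <- as.data.frame(stats::setNames(
        replicate(length(.TABLE_COLS), character(), simplify = FALSE),
        .TABLE_COLS), stringsAsFactors = FALSE)
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    obj <- lapply(inventories, function(inv) list(
      strain_id = inv@strainId,
      clusters = lapply(inv@clusters, function(cl) list(
        cluster_id = cl@clusterId, declared_type = cl@declaredType,
        complete = cl@complete, annotation = cl@annotation,
        orfs = lapply(cl@orfs, function(o) list(
          orf_id = o@orfId,
          architecture = serializeOrfArchitecture(o)))))))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Packaged fixtures
#'
#' Paths of the plain-text data shipped with the package: \code{"tp_a0316"}
#' and \code{"tp_a0468"} (cluster inventories of the two Micromonospora
#' strains), \code{"qnm"} (the quinolidomicin reference architecture of
#' M. chalcea AK-AN57), and \code{"fig6_ddh"} (digital DNA-DNA hybridization
#' panel for the genus survey).
#'
#' @param name fixture name.
#' @return a file path.
#' @export
bgcFixture <- function(name = c("tp_a0316", "tp_a0468", "qnm", "fig6_ddh")) {
  name <- match.arg(name)
  fn <- c(tp_a0316 = "tp_a0316.tsv", tp_a0468 = "tp_a0468.tsv",
          qnm = "qnm_ak_an57.tsv", fig6_ddh = "fig6_ddh.tsv")[[name]]
  system.file("extdata", fn, package = "bgcarch", mustWork = TRUE)
}

#' Summarize a cluster inventory
#'
#' Per-strain summary used by the command-line "parse" stage: cluster count,
#' per-type counts from \code{\link{classifyCluster}}, and per-cluster module
#' counts.
#'
#' @param inv a ClusterInventory.
#' @return a list with elements \code{strain_id}, \code{n_clusters},
#'   \code{type_counts} (named integer vector) and \code{clusters}
#'   (data.frame: cluster_id, declared_type, classified_type, n_modules,
#'   complete).
#' @export
inventorySummary <- function(inv) {
  stopifnot(is(inv, "ClusterInventory"))
  types <- vapply(inv@clusters, classifyCluster, character(1))
  df <- data.frame(
    cluster_id = vapply(inv@clusters, clusterId, character(1)),
    declared_type = vapply(inv@clusters, function(cl) cl@declaredType,
                           character(1)),
    classified_type = types,
    n_modules = vapply(inv@clusters, countModules, integer(1)),
    complete = vapply(inv@clusters, isComplete, logical(1)),
    stringsAsFactors = FALSE)
  list(strain_id = inv@strainId, n_clusters = length(inv@clusters),
       type_counts = table(factor(types, levels = CLUSTER_TYPES)),
       clusters = df)
}
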