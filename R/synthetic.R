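## Seeded generators of synthetic assembly lines, mutated ortholog copies and
## marker-gene pairs with known ground truth.

## run code under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generator configuration
#'
#' Defaults emulate the architecture statistics of the packaged inventories:
#' reducing-PKS modules are KS/AT/[DH/ER/KR]/ACP with beta-processing domains
#' drawn per-module (KR common, DH frequent, ER occasional), roughly a third
#' of AT domains methylmalonyl-specific; NRPS modules are C/A/T with
#' occasional epimerization or methylation, and about two thirds of A domains
#' carry an annotated substrate.
#'
#' @param seed integer RNG seed.
#' @param nModules module count, or a length-2 range to sample from.
#' @param pDH,pER,pKR per-module probabilities of the reducing domains.
#' @param pAtMm probability an AT is methylmalonyl-specific.
#' @param substrateAlphabet residue codes for A-domain substrates.
#' @param pSubstrateAnnotated probability an A domain carries a substrate.
#' @param pTailoring per-module probability of an E/MT tailoring domain
#'   (NRPS).
#' @param mutationRates named numeric: p_module_del, p_module_ins,
#'   p_domain_swap, p_spec_flip, each in [0, 1].
#' @return a named list.
#' @export
generatorConfig <- function(seed = 1L, nModules = c(5L, 15L),
                            pDH = 0.5, pER = 0.15, pKR = 0.85,
                            pAtMm = 0.35,
                            substrateAlphabet = c("ala", "asn", "cys", "gly",
                                                  "glu", "ile", "phe", "pro",
                                                  "ser", "thr", "val"),
                            pSubstrateAnnotated = 0.65,
                            pTailoring = 0.15,
                            mutationRates = c(p_module_del = 0.1,
                                              p_module_ins = 0.05,
                                              p_domain_swap = 0.05,
                                              p_spec_flip = 0.05)) {
  probs <- c(pDH, pER, pKR, pAtMm, pSubstrateAnnotated, pTailoring,
             mutationRates)
  stopifnot(is.numeric(seed), length(seed) == 1L,
            all(probs >= 0), all(probs <= 1),
            all(nModules >= 1), length(nModules) %in% 1:2,
            all(c("p_module_del", "p_module_ins", "p_domain_swap",
                  "p_spec_flip") %in% names(mutationRates)))
  list(seed = as.integer(seed), nModules = as.integer(nModules),
       pDH = pDH, pER = pER, pKR = pKR, pAtMm = pAtMm,
       substrateAlphabet = substrateAlphabet,
       pSubstrateAnnotated = pSubstrateAnnotated, pTailoring = pTailoring,
       mutationRates = mutationRates)
}

.gen_pks_module <- function(config) {
  spec <- if (stats::runif(1) < config$pAtMm) "methylmalonyl" else "malonyl"
  doms <- list(domainToken("KS"), domainToken("AT", spec))
  if (stats::runif(1) < config$pDH) doms <- c(doms, domainToken("DH"))
  if (stats::runif(1) < config$pER) doms <- c(doms, domainToken("ER"))
  if (stats::runif(1) < config$pKR) doms <- c(doms, domainToken("KR"))
  c(doms, domainToken("ACP"))
}

.gen_nrps_module <- function(config) {
  spec <- if (stats::runif(1) < config$pSubstrateAnnotated)
    sample(config$substrateAlphabet, 1) else NA_character_
  doms <- list(domainToken("C"), domainToken("A", spec))
  if (stats::runif(1) < config$pTailoring)
    doms <- c(doms, domainToken(sample(c("E", "MT"), 1)))
  c(doms, domainToken("T"))
}

#' Generate a synthetic assembly-line cluster
#'
#' Deterministic per (config, kind): identical seed and configuration give a
#' byte-identical serialization.  PKS modules always contain KS and ACP,
#' NRPS modules always contain C and T; the cluster gets a CoA-ligase loading
#' module and a terminal thioesterase, and modules are distributed over 1-4
#' ORFs.
#'
#' @param config see \code{\link{generatorConfig}}.
#' @param kind "t1pks" or "nrps".
#' @param clusterId,strainId identifiers.
#' @return a GeneCluster.
#' @examples
#' cl <- generateCluster(generatorConfig(seed = 1, nModules = 5), "nrps")
#' countModules(cl)  # 6: loading plus five extension modules
#' @export
generateCluster <- function(config = generatorConfig(),
                            kind = c("t1pks", "nrps"),
                            clusterId = paste0("syn-", kind),
                            strainId = "synthetic") {
  kind <- match.arg(kind)
  .with_seed(config$seed, {
    n <- if (length(config$nModules) == 2L)
      sample(seq(config$nModules[1], config$nModules[2]), 1)
    else config$nModules
    gen <- if (kind == "t1pks") .gen_pks_module else .gen_nrps_module
    mods <- c(
      list(.module(list(domainToken("CoL"),
                        domainToken(if (kind == "t1pks") "ACP" else "T")),
                   "loading")),
      lapply(seq_len(n), function(i) .module(gen(config), "extension")))
    mods[[length(mods)]]@domains <-
      c(mods[[length(mods)]]@domains, domainToken("Te"))
    ## split into ORFs at random boundaries
    n_orfs <- sample(1:min(4L, length(mods)), 1)
    cuts <- sort(sample(seq_len(length(mods) - 1L),
                        n_orfs - 1L, replace = FALSE))
    bounds <- c(0L, cuts, length(mods))
    orfL <- lapply(seq_len(n_orfs), function(k) {
      new("OrfArchitecture", orfId = paste0("syn-", k),
          modules = mods[(bounds[k] + 1L):bounds[k + 1L]],
          leftTruncated = FALSE, rightTruncated = FALSE)
    })
    geneCluster(clusterId, orfL, declaredType = kind, strainId = strainId)
  })
}

#' Generate a synthetic strain inventory
#'
#' \code{nClusters} random clusters of mixed kinds under one seed; used for
#' screening panels.
#'
#' @param config see \code{\link{generatorConfig}}; per-cluster seeds are
#'   derived from \code{config$seed}.
#' @param nClusters number of clusters.
#' @param strainId identifier.
#' @return a ClusterInventory.
#' @export
generateInventory <- function(config = generatorConfig(), nClusters = 3L,
                              strainId = "synthetic") {
  kinds <- .with_seed(config$seed,
                      sample(c("t1pks", "nrps"), nClusters, replace = TRUE))
  cls <- lapply(seq_len(nClusters), function(i) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * i
    generateCluster(cfg, kinds[i],
                    clusterId = paste0(kinds[i], "-", i),
                    strainId = strainId)
  })
  new("ClusterInventory", strainId = strainId, clusters = cls)
}

## ---- mutation ----

.flat_modules <- function(cluster) modules(cluster)

.rebuild_single_orf <- function(cluster, mods, clusterId = cluster@clusterId) {
  orf <- new("OrfArchitecture", orfId = "mut-1", modules = mods,
             leftTruncated = FALSE, rightTruncated = FALSE)
  geneCluster(clusterId, list(orf), declaredType = cluster@declaredType,
              strainId = cluster@strainId, annotation = cluster@annotation)
}

#' Apply a mutation log to a cluster
#'
#' Replays a log produced by \code{\link{mutateCluster}}.  The log is
#' sufficient: replaying it on the parent reproduces the mutant exactly.
#' Operations are applied in log order; positions refer to the module list
#' (loading included) of the evolving cluster.
#'
#' @param parent a GeneCluster.
#' @param log data.frame with columns op ("del", "ins", "swap", "flip"),
#'   pos, and detail (serialized module for "ins", domain position and
#'   replacement for "swap"/"flip").
#' @param clusterId id for the product.
#' @return a GeneCluster (single synthetic ORF).
#' @export
applyMutationLog <- function(parent, log, clusterId = paste0(parent@clusterId,
                                                             "-mut")) {
  mods <- .flat_modules(parent)
  for (k in seq_len(nrow(log))) {
    op <- log$op[k]; pos <- log$pos[k]; detail <- log$detail[k]
    if (op == "del") {
      mods <- mods[-pos]
    } else if (op == "ins") {
      seg <- parseOrfArchitecture(detail)@modules[[1]]
      seg@role <- "extension"
      mods <- append(mods, list(seg), after = pos)
    } else if (op == "swap") {
      parts <- strsplit(detail, ":", fixed = TRUE)[[1]]
      di <- as.integer(parts[1])
      mods[[pos]]@domains[[di]] <- .parse_domain(parts[2])
    } else if (op == "flip") {
      parts <- strsplit(detail, ":", fixed = TRUE)[[1]]
      di <- as.integer(parts[1])
      mods[[pos]]@domains[[di]]@specificity <- parts[2]
    } else stop("unknown mutation op '", op, "'", call. = FALSE)
  }
  .rebuild_single_orf(parent, mods, clusterId)
}

.empty_log <- function()
  data.frame(op = character(), pos = integer(), detail = character(),
             stringsAsFactors = FALSE)

#' Mutate a cluster with seeded module indels, domain swaps, specificity flips
#'
#' Models the relationship between orthologous clusters in different strains:
#' whole-module deletions and insertions (an insertion copies an adjacent
#' module, mimicking tandem near-identical modules), swaps of optional
#' beta-processing/tailoring domains, and AT/A specificity flips.  The exact
#' edit log is returned for ground-truth evaluation; a deletion that would
#' leave no module is skipped and logged as op "skip".
#'
#' @param parent a GeneCluster with at least 2 modules.
#' @param config see \code{\link{generatorConfig}} (uses seed and
#'   mutationRates).
#' @param clusterId id for the mutant.
#' @return list with elements \code{cluster} (the mutant) and \code{log}
#'   (data.frame; "del" positions refer to the parent module list, later ops
#'   to the evolving list, matching \code{\link{applyMutationLog}} replay
#'   order).
#' @export
mutateCluster <- function(parent, config = generatorConfig(),
                          clusterId = paste0(parent@clusterId, "-mut")) {
  stopifnot(is(parent, "GeneCluster"))
  mods <- .flat_modules(parent)
  stopifnot(length(mods) >= 2L)
  r <- config$mutationRates
  .with_seed(config$seed, {
    log <- .empty_log()
    ## deletions: drawn against parent extension positions, applied
    ## high-to-low so logged positions stay valid at replay
    delable <- which(vapply(mods, function(m) m@role == "extension",
                            logical(1)))
    del <- delable[stats::runif(length(delable)) < r[["p_module_del"]]]
    if (length(del) >= length(delable)) {
      keep_one <- sample(seq_along(del), 1)
      log <- rbind(log, data.frame(op = "skip", pos = del[keep_one],
                                   detail = "deletion skipped",
                                   stringsAsFactors = FALSE))
      del <- del[-keep_one]
    }
    for (p in sort(del, decreasing = TRUE))
      log <- rbind(log, data.frame(op = "del", pos = p, detail = "",
                                   stringsAsFactors = FALSE))
    work <- if (length(del)) mods[-del] else mods
    ## insertions: copy of the left neighbour
    n_ins <- stats::rbinom(1, length(work), r[["p_module_ins"]])
    for (k in seq_len(n_ins)) {
      at <- sample(seq_along(work), 1)
      tmpl <- work[[at]]
      if (tmpl@role != "extension") next
      log <- rbind(log, data.frame(op = "ins", pos = at,
                                   detail = .serialize_module(tmpl),
                                   stringsAsFactors = FALSE))
      work <- append(work, list(tmpl), after = at)
    }
    ## domain swaps: replace an optional domain with another optional code
    optional <- c("DH", "ER", "KR", "MT", "E")
    for (i in seq_along(work)) {
      if (stats::runif(1) >= r[["p_domain_swap"]]) next
      labs <- vapply(work[[i]]@domains, function(d) d@label, character(1))
      cand <- which(labs %in% optional)
      if (!length(cand)) next
      di <- if (length(cand) == 1L) cand else sample(cand, 1)
      repl <- sample(setdiff(optional, labs[di]), 1)
      log <- rbind(log, data.frame(op = "swap", pos = i,
                                   detail = paste0(di, ":", repl),
                                   stringsAsFactors = FALSE))
      work[[i]]@domains[[di]] <- domainToken(repl)
    }
    ## specificity flips on AT (m <-> mm) and A (resample substrate)
    for (i in seq_along(work)) {
      if (stats::runif(1) >= r[["p_spec_flip"]]) next
      labs <- vapply(work[[i]]@domains, function(d) d@label, character(1))
      specs <- vapply(work[[i]]@domains, function(d) d@specificity,
                      character(1))
      cand <- which(labs %in% SPECIFIC_LABELS & !is.na(specs))
      if (!length(cand)) next
      di <- if (length(cand) == 1L) cand else sample(cand, 1)
      newspec <- if (labs[di] == "AT") {
        if (specs[di] == "malonyl") "methylmalonyl" else "malonyl"
      } else {
        sample(setdiff(config$substrateAlphabet, specs[di]), 1)
      }
      log <- rbind(log, data.frame(op = "flip", pos = i,
                                   detail = paste0(di, ":", newspec),
                                   stringsAsFactors = FALSE))
      work[[i]]@domains[[di]]@specificity <- newspec
    }
    apply_log <- log[log$op != "skip", , drop = FALSE]
    list(cluster = applyMutationLog(parent, apply_log, clusterId), log = log)
  })
}

#' Delete specific modules from a cluster
#'
#' Convenience wrapper used by the indel-recovery evaluations: removes the
#' extension modules with the given index labels and returns the mutant plus
#' the replayable log.
#'
#' @param parent a GeneCluster.
#' @param indexLabels character vector of extension-module labels to delete.
#' @param clusterId id for the mutant.
#' @return a GeneCluster.
#' @export
deleteModules <- function(parent, indexLabels,
                          clusterId = paste0(parent@clusterId, "-del")) {
  mods <- .flat_modules(parent)
  labs <- vapply(mods, function(m) m@indexLabel, character(1))
  pos <- match(as.character(indexLabels), labs)
  if (anyNA(pos))
    stop("no module with index label ",
         paste(indexLabels[is.na(pos)], collapse = ", "), call. = FALSE)
  log <- do.call(rbind, lapply(sort(pos, decreasing = TRUE), function(p)
    data.frame(op = "del", pos = p, detail = "", stringsAsFactors = FALSE)))
  applyMutationLog(parent, log, clusterId)
}

#' Generate a marker-gene pair with known identity
#'
#' A random nucleotide sequence and a copy with Binomial(length, divergence)
#' substitutions at seeded positions.  The realized identity (percent, one
#' decimal) is returned alongside; \code{\link{pairwiseIdentity}} of the pair
#' equals it exactly.
#'
#' @param length sequence length (>= 1).
#' @param divergence substitution probability per site in [0, 1].
#' @param seed RNG seed.
#' @return list with elements \code{a}, \code{b} (character sequences) and
#'   \code{identity} (percent).
#' @export
generateMarkerPair <- function(length = 1000L, divergence = 0.02, seed = 1L) {
  stopifnot(length >= 1, divergence >= 0, divergence <= 1)
  .with_seed(seed, {
    a <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    nsub <- stats::rbinom(1, length, divergence)
    b <- a
    if (nsub > 0) {
      pos <- sample.int(length, nsub)
      for (p in pos)
        b[p] <- sample(setdiff(c("A", "C", "G", "T"), a[p]), 1)
    }
    list(a = paste(a, collapse = ""), b = paste(b, collapse = ""),
         identity = round(100 * (length - nsub) / length, 1))
  })
}
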