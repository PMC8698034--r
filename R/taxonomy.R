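## Marker-gene identity and threshold-rule genomospecies delimitation.
##
## Threshold rules: a gyrB sequence identity of 98.5% corresponds to the 70%
## DNA-DNA relatedness species boundary, and digital DNA-DNA hybridization
## (dDDH) uses the classical 70% species cut-off.  Both thresholds are
## inclusive at the boundary.  16S identity alone is treated as insufficient
## for delimitation and always yields an inconclusive verdict.

.taxon_verdict <- function(metric, value, threshold, verdict)
  new("TaxonVerdict", metric = metric, value = value, threshold = threshold,
      verdict = verdict)

#' Pairwise nucleotide identity of two marker-gene sequences
#'
#' Ends-free global alignment (terminal gaps free, so marker genes of unequal
#' trim lengths are compared over their overlap); identity = matches /
#' aligned columns excluding terminal gaps, as a percent rounded to one
#' decimal.
#'
#' @param seqA,seqB character strings or DNAString, alphabet ACGTN-.
#' @return percent identity in [0, 100].
#' @examples
#' pairwiseIdentity("ACGTACGT", "ACGTACGT")  # 100
#' @export
pairwiseIdentity <- function(seqA, seqB) {
  seqA <- .as_dna(seqA, "seqA")
  seqB <- .as_dna(seqB, "seqB")
  aln <- Biostrings::pairwiseAlignment(
    seqA, seqB, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 8, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ## drop terminal-gap columns (unequal trim lengths are not mismatches)
  gap <- pa == "-" | ps == "-"
  keep <- seq_along(pa) >= match(FALSE, gap) &
    seq_along(pa) <= length(gap) + 1L - match(FALSE, rev(gap))
  pa <- pa[keep]; ps <- ps[keep]
  if (!length(pa))
    stop("sequences share no aligned overlap", call. = FALSE)
  round(100 * sum(pa == ps & pa != "-") / length(pa), 1)
}

.as_dna <- function(x, what) {
  if (is(x, "DNAString")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L || !nzchar(x))
    stop(sprintf("'%s' must be a single non-empty nucleotide sequence", what),
         call. = FALSE)
  x <- toupper(gsub("[[:space:]]", "", x))
  bad <- gsub("[ACGTN-]", "", x)
  if (nzchar(bad))
    stop(sprintf("'%s' contains non-nucleotide symbols: %s", what,
                 paste(unique(strsplit(bad, "")[[1]]), collapse = "")),
         call. = FALSE)
  Biostrings::DNAString(x)
}

#' Read marker-gene sequences from FASTA
#'
#' @param path FASTA file.
#' @return a named character vector of sequences.
#' @export
readMarkerFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

.check_percent <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 100)
    stop("value must be a percent in [0, 100]", call. = FALSE)
  as.numeric(value)
}

#' Genomospecies verdict from gyrB identity
#'
#' Same species iff identity >= threshold (default 98.5, the gyrB identity
#' corresponding to 70% DNA-DNA relatedness); boundary inclusive.
#'
#' @param identity gyrB percent identity in [0, 100].
#' @param threshold percent, default 98.5.
#' @return a TaxonVerdict.
#' @examples
#' verdict(genomospeciesVerdict(94.9))  # "distinct_species"
#' @export
genomospeciesVerdict <- function(identity, threshold = 98.5) {
  identity <- .check_percent(identity)
  .taxon_verdict("identity_gyrB", identity, threshold,
                 if (identity >= threshold) "same_species"
                 else "distinct_species")
}

#' Species verdict from digital DNA-DNA hybridization
#'
#' Same species iff dDDH >= threshold (default 70, the classical cut-off);
#' boundary inclusive.
#'
#' @param ddh dDDH percent in [0, 100].
#' @param threshold percent, default 70.
#' @return a TaxonVerdict.
#' @examples
#' verdict(ddhVerdict(51))  # "distinct_species"
#' @export
ddhVerdict <- function(ddh, threshold = 70) {
  ddh <- .check_percent(ddh)
  .taxon_verdict("dDDH", ddh, threshold,
                 if (ddh >= threshold) "same_species" else "distinct_species")
}

#' 16S identity verdict (always inconclusive)
#'
#' 16S rRNA identity alone cannot delimit species in this genus (identical
#' 16S sequences occur across distinct genomospecies), so the verdict is
#' always inconclusive; the value is carried for reporting.
#'
#' @param identity percent in [0, 100].
#' @return a TaxonVerdict.
#' @export
identity16SVerdict <- function(identity) {
  identity <- .check_percent(identity)
  .taxon_verdict("identity_16S", identity, NA_real_, "inconclusive")
}

#' @rdname accessors
#' @export
setMethod("verdict", "TaxonVerdict", function(x) x@verdict)

setMethod("show", "TaxonVerdict", function(object) {
  cat(sprintf("TaxonVerdict [%s] %.1f%% (threshold %s) -> %s\n",
              object@metric, object@value,
              if (is.na(object@threshold)) "-"
              else sprintf("%.1f%%", object@threshold), object@verdict))
})

#' Read a pairwise-relatedness panel
#'
#' TSV with columns strain_a, strain_b, metric (identity_16S, identity_gyrB
#' or dDDH) and value (percent); "#" comment lines allowed.
#'
#' @param path TSV file (e.g. \code{bgcFixture("fig6_ddh")}).
#' @return a data.frame.
#' @export
readDdhPanel <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("strain_a", "strain_b", "metric", "value")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("panel is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$value <- as.numeric(df$value)
  df
}

#' Verdicts and species groups over a relatedness panel
#'
#' Applies the per-metric verdict rules to every pair, then partitions the
#' strains into species groups as the connected components of the
#' same-species graph.  The partition is invariant to pair order.
#'
#' @param pairs data.frame with columns strain_a, strain_b, metric, value.
#' @param gyrbThreshold,ddhThreshold percent thresholds.
#' @return list with \code{verdicts} (data.frame: strain_a, strain_b, metric,
#'   value, verdict) and \code{groups} (list of character vectors of strain
#'   ids, each sorted; singletons included).
#' @examples
#' panel <- readDdhPanel(bgcFixture("fig6_ddh"))
#' groups <- panelVerdicts(panel)$groups
#' @export
panelVerdicts <- function(pairs, gyrbThreshold = 98.5, ddhThreshold = 70) {
  stopifnot(is.data.frame(pairs))
  v <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    v[i] <- switch(pairs$metric[i],
      dDDH = verdict(ddhVerdict(pairs$value[i], ddhThreshold)),
      identity_gyrB = verdict(genomospeciesVerdict(pairs$value[i],
                                                   gyrbThreshold)),
      identity_16S = verdict(identity16SVerdict(pairs$value[i])),
      stop("unknown metric '", pairs$metric[i], "'", call. = FALSE))
  }
  strains <- sort(unique(c(pairs$strain_a, pairs$strain_b)))
  ## union-find over the same-species edges
  parent <- stats::setNames(seq_along(strains), strains)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in which(v == "same_species")) {
    ra <- find(match(pairs$strain_a[i], strains))
    rb <- find(match(pairs$strain_b[i], strains))
    if (ra != rb) parent[rb] <- ra
  }
  comp <- vapply(seq_along(strains), find, numeric(1))
  groups <- unname(lapply(split(strains, comp), sort))
  groups <- groups[order(vapply(groups, `[`, character(1), 1))]
  out <- pairs[, c("strain_a", "strain_b", "metric", "value")]
  out$verdict <- v
  list(verdicts = out, groups = groups)
}
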