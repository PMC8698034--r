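test_that("pairwise identity matches a count-based oracle", {
  pair0 <- generateMarkerPair(1000L, 0, seed = 3)
  expect_equal(pair0$identity, 100)
  expect_equal(pairwiseIdentity(pair0$a, pair0$b), 100)

  ## 10 substitutions in 1000 nt -> 99.0
  p <- generateMarkerPair(1000L, 0, seed = 4)
  b <- strsplit(p$b, "")[[1]]
  set.seed(5)
  pos <- sample.int(1000L, 10L)
  for (i in pos) b[i] <- setdiff(c("A", "C", "G", "T"), b[i])[1]
  expect_equal(pairwiseIdentity(p$a, paste(b, collapse = "")), 99.0)

  ## generator-realized identity equals the alignment identity exactly
  for (seed in c(7, 8, 9)) {
    mp <- generateMarkerPair(1000L, 0.051, seed = seed)
    expect_equal(pairwiseIdentity(mp$a, mp$b), mp$identity)
  }

  ## symmetry, and 100 iff identical
  mp <- generateMarkerPair(800L, 0.02, seed = 11)
  expect_equal(pairwiseIdentity(mp$a, mp$b), pairwiseIdentity(mp$b, mp$a))
  expect_lt(pairwiseIdentity(mp$a, mp$b), 100)

  ## unrelated random sequences sit near the 25% background
  r1 <- generateMarkerPair(1000L, 0, seed = 21)$a
  r2 <- generateMarkerPair(1000L, 0, seed = 22)$a
  bg <- pairwiseIdentity(r1, r2)
  expect_gt(bg, 15); expect_lt(bg, 40)

  ## terminal trimming: a truncated copy still scores 100
  expect_equal(pairwiseIdentity(mp$a, substr(mp$a, 51, 800)), 100)

  expect_error(pairwiseIdentity("", "ACGT"), "non-empty")
  expect_error(pairwiseIdentity("ACGT", "ACXT"), "non-nucleotide")
})

test_that("threshold verdicts reproduce the qualitative species calls", {
  expect_equal(verdict(genomospeciesVerdict(94.9)), "distinct_species")
  expect_equal(verdict(genomospeciesVerdict(98.5)), "same_species")
  expect_equal(verdict(genomospeciesVerdict(100)), "same_species")
  expect_equal(verdict(ddhVerdict(51)), "distinct_species")
  expect_equal(verdict(ddhVerdict(94)), "same_species")
  expect_equal(verdict(ddhVerdict(70)), "same_species")
  expect_equal(verdict(identity16SVerdict(100)), "inconclusive")
  expect_error(ddhVerdict(101), "percent")
  expect_error(genomospeciesVerdict(-1), "percent")

  ## monotone: raising a value never flips same -> distinct
  grid <- seq(0, 100, by = 0.5)
  gv <- vapply(grid, function(v) verdict(genomospeciesVerdict(v)),
               character(1))
  dv <- vapply(grid, function(v) verdict(ddhVerdict(v)), character(1))
  expect_false(is.unsorted(gv == "same_species"))
  expect_false(is.unsorted(dv == "same_species"))
})

test_that("the genus panel partitions into the published species groups", {
  panel <- readDdhPanel(bgcFixture("fig6_ddh"))
  res <- panelVerdicts(panel)
  groups <- res$groups
  find_group <- function(strain)
    groups[[which(vapply(groups, function(g) strain %in% g, logical(1)))]]

  aur <- find_group("M. aurantiaca ATCC 27029")
  expect_setequal(aur, c("M. aurantiaca ATCC 27029", "Micromonospora sp. L5",
                         "Micromonospora sp. RV43",
                         "Micromonospora sp. WMMB235",
                         "Micromonospora sp. CNZ297",
                         "Micromonospora sp. CNZ296",
                         "M. globosa NRRL B-2673"))
  expect_setequal(find_group("M. chalcea DSM 43026"),
                  c("M. chalcea DSM 43026", "Micromonospora sp. M42",
                    "Micromonospora sp. DSW705"))
  expect_setequal(find_group("Micromonospora sp. NRRL B-16802"),
                  c("Micromonospora sp. NRRL B-16802",
                    "M. profundi DSM 45981"))
  expect_setequal(find_group("Micromonospora sp. CNZ322"),
                  c("Micromonospora sp. CNZ322",
                    "M. saelicesensis DSM 44871"))
  ## independent genomospecies stay singletons
  for (s in c("Micromonospora sp. B006", "Micromonospora sp. WMMA2032",
              "Micromonospora sp. TSRI0369", "Micromonospora sp. TP-A0468",
              "Micromonospora sp. NRRL B-2672"))
    expect_length(find_group(s), 1L)
  ## the oryzae/haikouensis complex groups together
  expect_setequal(find_group("Micromonospora sp. TP-A0316"),
                  c("Micromonospora sp. TP-A0316", "M. haikouensis JXNU-1",
                    "M. haikouensis DSM 45626", "Micromonospora sp. Rc5"))

  ## partition is invariant to pair order
  res2 <- panelVerdicts(panel[rev(seq_len(nrow(panel))), ])
  expect_equal(res2$groups, groups)

  ## boundary and degenerate panels
  one <- data.frame(strain_a = "a", strain_b = "b", metric = "dDDH",
                    value = 69.9, stringsAsFactors = FALSE)
  expect_length(panelVerdicts(one)$groups, 2L)
  low <- data.frame(strain_a = c("a", "b"), strain_b = c("b", "c"),
                    metric = "dDDH", value = c(12, 65),
                    stringsAsFactors = FALSE)
  expect_length(panelVerdicts(low)$groups, 3L)
})

test_that("marker FASTA round-trips through the reader", {
  tmp <- tempfile(fileext = ".fasta")
  mp <- generateMarkerPair(120L, 0.05, seed = 13)
  writeLines(c(">gyrB_a", mp$a, ">gyrB_b", mp$b), tmp)
  seqs <- readMarkerFasta(tmp)
  expect_equal(names(seqs), c("gyrB_a", "gyrB_b"))
  expect_equal(pairwiseIdentity(seqs["gyrB_a"], seqs["gyrB_b"]), mp$identity)
})
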