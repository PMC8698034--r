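test_that("module and domain parsing follows the notation grammar", {
  orf <- parseOrfArchitecture("C/A_ser_/T-C/A_pro_/T-Te", "12-31")
  expect_length(modules(orf), 2L)
  expect_equal(vapply(modules(orf), function(m) m@role, character(1)),
               c("extension", "extension"))
  expect_equal(domainLabels(modules(orf)[[1]]), c("C", "A", "T"))
  ## the release segment merges into the last module
  expect_equal(domainLabels(modules(orf)[[2]]), c("C", "A", "T", "Te"))
  expect_equal(modules(orf)[[2]]@domains[[2]]@specificity, "pro")

  load <- parseOrfArchitecture("CoL/ACP", "qnmA1")
  expect_length(modules(load), 1L)
  expect_equal(modules(load)[[1]]@role, "loading")

  merged <- parseOrfArchitecture("KS/AT_m_/ACP-Te", "1-1098")
  expect_length(modules(merged), 1L)
  expect_equal(domainLabels(modules(merged)[[1]]), c("KS", "AT", "ACP", "Te"))
  ## the two table spellings normalize identically
  expect_equal(serializeOrfArchitecture(merged),
               serializeOrfArchitecture(
                 parseOrfArchitecture("KS/AT_m_/ACP/Te", "x")))

  trunc <- parseOrfArchitecture("...KR", "16-1")
  expect_true(trunc@leftTruncated)
  expect_false(trunc@rightTruncated)
  expect_length(modules(trunc), 1L)
  expect_equal(modules(trunc)[[1]]@role, "standalone")

  expect_error(parseOrfArchitecture("", "bad"), "empty")
  expect_error(parseOrfArchitecture("KS/AT_", "bad"), "AT_")
  expect_error(parseOrfArchitecture("C/A_", "bad"), "A_")
})

test_that("specificity subscript dialects normalize to one form", {
  for (txt in c("AT_m_", "ATm", "AT_m")) {
    d <- modules(parseOrfArchitecture(paste0("KS/", txt, "/ACP")))[[1]]@domains[[2]]
    expect_equal(d@label, "AT")
    expect_equal(d@specificity, "malonyl")
  }
  d <- modules(parseOrfArchitecture("KS/AT_mm_/ACP"))[[1]]@domains[[2]]
  expect_equal(d@specificity, "methylmalonyl")
  d <- modules(parseOrfArchitecture("C/A_b-ala_/T"))[[1]]@domains[[2]]
  expect_equal(d@specificity, "b-ala")
  ## unknown codes become X with raw text preserved, never dropped
  m <- modules(parseOrfArchitecture("KS/FOO/ACP"))[[1]]
  expect_equal(domainLabels(m), c("KS", "X", "ACP"))
  expect_equal(m@domains[[2]]@raw, "FOO")
  expect_match(serializeOrfArchitecture(parseOrfArchitecture("KS/FOO/ACP")),
               "FOO", fixed = TRUE)
})

test_that("serialization round-trips and conserves every domain", {
  cases <- c("C/A_gly_/T", "KS/AT_mm_/DH/ER/KR/ACP",
             "CoL/KR/ACP-KS/AT_m_/DH/KR/ACP-KS/AT_mm_/DH/ER/KR/ACP",
             "A/T-KS/DH", "...KR", "KS/AT...", "A_glu_/T-TD",
             "C/A_ser_/T-C/T-Te-A/T")
  for (txt in cases) {
    orf <- parseOrfArchitecture(txt, "t")
    s <- serializeOrfArchitecture(orf)
    orf2 <- parseOrfArchitecture(s, "t")
    expect_equal(serializeOrfArchitecture(orf2), s, info = txt)
    ## domain conservation: every token of the input appears exactly once
    n_out <- sum(vapply(modules(orf), function(m) length(m@domains),
                        integer(1)))
    toks <- strsplit(gsub("(\\.\\.\\.|-)", "/", txt), "/+")[[1]]
    expect_equal(n_out, sum(nzchar(toks)), info = txt)
  }
})

test_that("generated architectures round-trip through parse/serialize", {
  n_orfs <- 0L
  seed <- 0L
  while (n_orfs < 1000L) {
    seed <- seed + 1L
    kind <- if (seed %% 2L) "t1pks" else "nrps"
    cl <- generateCluster(generatorConfig(seed = seed, nModules = c(2L, 8L)),
                          kind)
    for (orf in orfs(cl)) {
      s <- serializeOrfArchitecture(orf)
      expect_identical(
        serializeOrfArchitecture(parseOrfArchitecture(s, orf@orfId)), s)
      n_orfs <- n_orfs + 1L
    }
  }
  expect_gte(n_orfs, 1000L)
})

test_that("cluster tables read and write in both dialects", {
  invs <- readClusterTable(bgcFixture("tp_a0316"))
  expect_length(invs, 1L)
  inv <- invs[[1]]
  expect_equal(strainId(inv), "TP-A0316")
  expect_length(clusters(inv), 15L)
  ## the incompletely sequenced clusters carry complete = FALSE
  expect_false(isComplete(clusters(inv)[["t1pks-4"]]))
  expect_false(isComplete(clusters(inv)[["nrps-4"]]))
  expect_true(isComplete(clusters(inv)[["t1pks-2"]]))

  ## TSV round trip
  tmp <- tempfile(fileext = ".tsv")
  writeClusterTable(inv, tmp, dialect = "tsv")
  inv2 <- readClusterTable(tmp, dialect = "tsv")[[1]]
  expect_equal(vapply(clusters(inv2), countModules, integer(1)),
               vapply(clusters(inv), countModules, integer(1)))
  ## JSON round trip
  tmpj <- tempfile(fileext = ".json")
  writeClusterTable(inv, tmpj, dialect = "json")
  inv3 <- readClusterTable(tmpj, dialect = "json")[[1]]
  expect_equal(vapply(clusters(inv3), countModules, integer(1)),
               vapply(clusters(inv), countModules, integer(1)))
  expect_false(isComplete(clusters(inv3)[["t1pks-4"]]))

  ## header-only file -> empty inventory list
  empty <- tempfile(fileext = ".tsv")
  writeLines(paste(c("strain_id", "cluster_id", "declared_type",
                     "complete_flag", "orf_id", "architecture",
                     "annotation"), collapse = "\t"), empty)
  expect_length(readClusterTable(empty), 0L)

  ## schema and duplicate validation
  bad <- tempfile(fileext = ".tsv")
  writeLines("strain_id\tcluster_id", bad)
  expect_error(readClusterTable(bad), "missing column")
  dup <- tempfile(fileext = ".tsv")
  writeLines(c(paste(c("strain_id", "cluster_id", "declared_type",
                       "complete_flag", "orf_id", "architecture",
                       "annotation"), collapse = "\t"),
               "s\tc1\tnrps\t\to1\tC/A/T\t",
               "s\tc1\tnrps\t\to1\tC/A/T\t"), dup)
  expect_error(readClusterTable(dup), "duplicate")
})

test_that("module counting includes loading, excludes standalones", {
  inv <- inv_tp_a0316()
  expect_equal(countModules(clusters(inv)[["t1pks-2"]]), 33L)
  expect_equal(countModules(clusters(inv)[["nrps-5"]]), 2L)
  expect_equal(countModules(demoCluster("CoL/ACP")), 1L)
  expect_equal(countModules(qnm_cluster()), 34L)
  ## per-cluster count equals the sum of per-ORF counts
  cl <- clusters(inv)[["t1pks-2"]]
  expect_equal(countModules(cl),
               sum(vapply(orfs(cl), countModules, integer(1))))
})
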