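test_that("content-based cluster typing follows the domain machinery", {
  inv316 <- inv_tp_a0316()
  inv468 <- inv_tp_a0468()
  t316 <- vapply(clusters(inv316), classifyCluster, character(1))
  t468 <- vapply(clusters(inv468), classifyCluster, character(1))

  expect_equal(t316[["t2pks-1"]], "t2pks")
  expect_equal(t316[["t3pks-1"]], "t3pks")
  expect_equal(t316[["pks/nrps-4"]], "pks_nrps")
  expect_equal(t316[["nrps-2"]], "nrps")
  ## single multi-domain module is modular type-I, not type-III
  expect_equal(t316[["t1pks-3"]], "t1pks")

  ## strain-wide splits
  expect_equal(sum(t468 %in% c("t1pks", "t2pks", "t3pks")), 6L)
  expect_equal(sum(t468 == "nrps"), 5L)
  expect_equal(sum(t468 == "pks_nrps"), 4L)
  expect_equal(sum(t316 == "nrps"), 5L)
  expect_equal(sum(t316 == "pks_nrps"), 4L)

  ## typing agrees with the declared tags across both fixtures
  decl <- vapply(clusters(inv316), function(cl) cl@declaredType, character(1))
  expect_equal(unname(t316), unname(decl))
})

test_that("co-linear products reproduce the printed skeletons", {
  rep316 <- predictionReport(inv_tp_a0316())
  rownames(rep316) <- rep316$cluster_id
  expect_equal(rep316["nrps-5", "units"], "ser-pro")
  expect_equal(rep316["nrps-5", "length_name"], "dipeptide")
  expect_equal(rep316["nrps-5", "release"], "thioesterase")
  expect_equal(rep316["nrps-1", "units"], "x-thr-phe-ser-ile")
  expect_equal(rep316["nrps-1", "length_name"], "pentapeptide")
  expect_equal(rep316["pks/nrps-4", "length_name"], "hexaketide with gly")
  expect_equal(rep316["t1pks-4", "category"], "unpredictable")
  expect_equal(rep316["nrps-4", "category"], "unpredictable")
  ## the set of unpredictable clusters is exactly the incompletely
  ## sequenced ones
  expect_setequal(rep316$cluster_id[rep316$category == "unpredictable"],
                  c("t1pks-4", "nrps-4"))

  rep468 <- predictionReport(inv_tp_a0468())
  rownames(rep468) <- rep468$cluster_id
  expect_equal(rep468["nrps-7", "units"], "glu")
  expect_equal(rep468["nrps-7", "release"], "reductive")
  expect_equal(rep468["nrps-8", "units"], "val-pro")
  expect_equal(rep468["nrps-8", "length_name"], "dipeptide")
  expect_equal(rep468["nrps-9", "units"], "x-x")
  expect_equal(rep468["nrps-10", "units"], "x-x")
  expect_equal(rep468["nrps-6", "category"], "unpredictable")
  expect_equal(rep468["t2pks-2", "category"], "aromatic_polyketide")
  expect_equal(rep468["t3pks-2", "category"], "type3_polyketide")
})

test_that("trans-complemented clusters are flagged and match as multisets", {
  rep316 <- predictionReport(inv_tp_a0316())
  rownames(rep316) <- rep316$cluster_id
  printed <- list(
    "nrps-2" = c("x", "gly", "x"),
    "nrps-3" = c("x", "x", "cys", "cys"),
    "pks/nrps-1" = c("st", "pk", "x", "ala", "glu", "y", "thr", "ser", "y"),
    "pks/nrps-2" = c("ser", "x", "val", "pk"),
    "pks/nrps-3" = c("x", "pk", "x", "y", "pk", "asn", "ser"))
  for (id in names(printed)) {
    expect_false(rep316[id, "colinear"], info = id)
    got <- strsplit(rep316[id, "units"], "-(?=[a-z])", perl = TRUE)[[1]]
    expect_equal(sort(got), sort(printed[[id]]), info = id)
  }
  expect_equal(rep316["nrps-2", "length_name"], "tripeptide")
  expect_equal(rep316["nrps-3", "length_name"], "tetrapeptide")
  expect_equal(rep316["pks/nrps-1", "length_name"],
               "heptapeptide with polyketide moieties")

  ## peptide unit count equals extension-module-derived residue count for
  ## colinear NRPS clusters
  inv <- inv_tp_a0316()
  for (id in c("nrps-1", "nrps-5")) {
    cl <- clusters(inv)[[id]]
    p <- predictProduct(cl)
    expect_true(p@colinear)
    expect_length(units(p), countModules(cl) -
                    sum(vapply(modules(cl), function(m)
                      m@role == "loading", logical(1))))
  }
})

test_that("prediction is deterministic and degenerate inputs are handled", {
  cl <- clusters(inv_tp_a0316())[["pks/nrps-3"]]
  p1 <- predictProduct(cl)
  p2 <- predictProduct(cl)
  expect_identical(units(p1), units(p2))
  expect_identical(p1@lengthName, p2@lengthName)

  ## zero-module cluster -> unpredictable
  lone <- demoCluster("ACP")
  expect_equal(predictProduct(lone)@category, "unpredictable")
})

test_that("domain-level difference reports catch gained and lost domains", {
  inv <- inv_tp_a0468()
  tallylike <- clusters(inv)[["pks/nrps-5"]]
  ## synthetic stand-in for the reference lacking the methyltransferase:
  ## same architecture with plain KS/AT_m_/KR/ACP in the PKS module
  ref_rows <- lapply(orfs(tallylike), function(o)
    list(id = o@orfId, arch = serializeOrfArchitecture(o)))
  ref_orfs <- lapply(ref_rows, function(r)
    parseOrfArchitecture(sub("KS/AT_m_/MT/KR/ACP", "KS/AT_m_/KR/ACP",
                             r$arch, fixed = TRUE), r$id))
  ref <- geneCluster("tlm-like-synthetic", ref_orfs,
                     declaredType = "pks_nrps", strainId = "synthetic")
  diffs <- conservedAnnotationCheck(tallylike, ref)
  gained <- diffs[!is.na(diffs$gained) & nzchar(diffs$gained), ]
  expect_equal(nrow(gained), 1L)
  expect_equal(gained$gained, "MT")
  expect_equal(gained$lost, "")

  ## cluster vs itself -> empty difference report
  self <- conservedAnnotationCheck(tallylike, tallylike)
  expect_true(all(self$gained == "" | is.na(self$gained)))
  expect_true(all(self$lost == "" | is.na(self$lost)))

  ## an injected swap is reported exactly
  parent <- generateCluster(generatorConfig(seed = 42, nModules = 8), "t1pks")
  sers <- serialize_modules(parent)
  target <- grep("KR", sers)[2]
  mut_sers <- sers
  mut_sers[target] <- sub("KR", "MT", mut_sers[target])
  mut <- geneCluster("swapped", list(parseOrfArchitecture(
    paste(mut_sers, collapse = "-"), "m-1")), strainId = "synthetic")
  d <- conservedAnnotationCheck(mut, parent)
  chg <- d[!is.na(d$gained) & (nzchar(d$gained) | nzchar(d$lost)), ]
  expect_equal(nrow(chg), 1L)
  expect_equal(chg$gained, "MT")
  expect_equal(chg$lost, "KR")
})
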