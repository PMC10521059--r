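test_that("the inventory counts distinct genome models at the cutoff", {
  q <- tinyQueries()
  hits <- rbind(
    makeHits("Q_SPO11", "Eukaryota;Amoebozoa;T", c(1e-40, 1e-40, 1e-60),
             subject = c("m1", "m1", "m2")),   # two HSPs on m1 collapse
    makeHits("Q_DMC1", "Eukaryota;Amoebozoa;T", 1e-30, subject = "m3"),
    makeHits("Q_HOP2", "Eukaryota;Amoebozoa;T", 1e-10, subject = "m4"),
    makeHits("Q_HAP2", "Eukaryota;Amoebozoa;T", 1e-16, subject = "m5"),
    makeHits("Q_KAR2", "Eukaryota;Amoebozoa;T", 1e-20, subject = "m6"))
  inv <- toolkitInventory(q, hits)
  expect_identical(inv$n_copies[inv$gene_name == "SPO11"], 2L)
  expect_identical(inv$model_ids[inv$gene_name == "SPO11"], "m1,m2")
  # a hit at 1e-10 does not clear the 1e-15 cutoff
  expect_false(inv$present[inv$gene_name == "HOP2"])
  expect_false(inv$present[inv$gene_name == "XTRA"])
  md <- S4Vectors::metadata(inv)
  expect_equal(md$fraction_found, 4 / 6)
  expect_false(md$meiosis_complete)  # HOP2 missing
  # completing the meiosis class flips the flag
  hits2 <- rbind(hits, makeHits("Q_HOP2", "Eukaryota;Amoebozoa;T", 1e-20,
                                subject = "m7"))
  expect_true(S4Vectors::metadata(toolkitInventory(q, hits2))$meiosis_complete)
  expect_error(toolkitInventory(q[0, ], hits), "empty")
})

test_that("the inventory is monotone in the e-value cutoff", {
  set.seed(31)
  q <- tinyQueries()
  hits <- makeHits(sample(q$query_id, 40, replace = TRUE),
                   "Eukaryota;Amoebozoa;T",
                   10^runif(40, -40, -5),
                   subject = sprintf("m%02d", sample(20, 40, replace = TRUE)))
  cutoffs <- c(1e-30, 1e-20, 1e-15, 1e-10, 1e-5)
  counts <- vapply(cutoffs, function(ct)
    sum(toolkitInventory(q, hits, evalueCutoff = ct)$n_copies), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("detection matrices map values to +/- at the threshold", {
  det <- expand.grid(sample_id = paste0("YT", 42:49),
                     gene_id = c("TRSP10046", "TRSP9999"),
                     stringsAsFactors = FALSE)
  det$condition <- rep(c("small", "small", "small", "medium", "medium",
                         "medium", "large", "large"), 2)
  # HAP2-style pattern: detected in the five medium/large samples only
  det$value <- ifelse(det$gene_id == "TRSP10046" &
                        det$condition != "small", 5, 0)
  dm <- detectionMatrix(det, c("TRSP10046", "TRSP9999"))
  expect_identical(unname(detectionCalls(dm)["TRSP10046", ]),
                   c("-", "-", "-", "+", "+", "+", "+", "+"))
  expect_true(all(detectionCalls(dm)["TRSP9999", ] == "-"))
  expect_identical(colnames(dm), paste0("YT", 42:49))
  # a missing model id warns and yields an all '-' row
  expect_warning(dm2 <- detectionMatrix(det, c("TRSP10046", "ghost")),
                 "absent")
  expect_true(all(detectionCalls(dm2)["ghost", ] == "-"))
  # detection_min = 0 calls '+' wherever the gene appears (values >= 0)
  dm0 <- detectionMatrix(det, "TRSP9999", detectionMin = 0)
  expect_true(all(detectionCalls(dm0) == "+"))
  # column order follows the design even if rows arrive shuffled
  set.seed(5)
  dmS <- detectionMatrix(det[sample(nrow(det)), ],
                         c("TRSP10046", "TRSP9999"))
  expect_identical(detectionCalls(dmS), detectionCalls(dm))
})

test_that("condition summaries count detections per sample and condition", {
  det <- expand.grid(sample_id = paste0("YT", 42:49),
                     gene_id = c("gA", "gB"), stringsAsFactors = FALSE)
  det$condition <- rep(c("small", "small", "small", "medium", "medium",
                         "medium", "large", "large"), 2)
  det$value <- 0
  det$value[det$gene_id == "gA" & det$sample_id == "YT48"] <- 3
  dm <- detectionMatrix(det, c("gA", "gB"))
  cs <- conditionSummary(dm)
  expect_identical(unname(cs$per_condition), c(0L, 0L, 1L))
  expect_identical(cs$gene_conditions$gA, "large")
  expect_identical(cs$gene_conditions$gB, character(0))
  expect_identical(unname(cs$per_sample[c("YT48", "YT42")]), c(1, 0))
})

test_that("synthetic toolkit bundles recover the planted inventory", {
  p <- tinyParams(seed = 37, n_genes = 200)
  b <- generateBundle(p)
  inv <- toolkitInventory(b$queries, b$toolkit_hits)
  truth <- b$truth$toolkit
  expect_identical(inv$present, truth$present)
  expect_identical(inv$n_copies[inv$gene_name == "SPO11"], 2L)
  planted <- sort(strsplit(truth$model_ids[truth$gene_name == "SPO11"],
                           ",")[[1]])
  expect_identical(inv$model_ids[inv$gene_name == "SPO11"],
                   paste(planted, collapse = ","))
  # detection summaries: medium/large dominate small under the default law
  models <- unlist(strsplit(truth$model_ids[truth$present], ","))
  dm <- detectionMatrix(b$detection, models)
  cs <- conditionSummary(dm)
  expect_gt(cs$per_condition[["medium"]], cs$per_condition[["small"]])
  expect_gte(cs$per_condition[["large"]], cs$per_condition[["small"]])
})
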