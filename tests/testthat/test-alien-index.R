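test_that("the Alien Index matches its closed form on anchor points", {
  # symmetric inputs cancel exactly
  expect_identical(alienIndex(1e-10, 1e-10), 0)
  # (1e-5, 1e-30): pseudo-count negligible, AI = 25 ln 10
  expect_equal(alienIndex(1e-5, 1e-30), 25 * log(10), tolerance = 1e-12)
  # extreme point (1, 0): AI = ln(1 + c) - ln(c) = 200 ln 10 + ln(1 + 1e-200)
  expect_equal(alienIndex(1, 0), 200 * log(10), tolerance = 1e-12)
  expect_equal(alienIndex(1, 0), 460.517, tolerance = 1e-5)
  # inputs outside [0, 1] are rejected
  expect_error(alienIndex(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(alienIndex(0.5, 1.5), "\\[0, 1\\]")
  expect_error(alienIndex(0.5, 0.5, c = 0), "positive")
})

test_that("the Alien Index is antisymmetric, monotone and bounded", {
  set.seed(101)
  a <- runif(500)
  b <- runif(500)
  expect_equal(alienIndex(a, b), -alienIndex(b, a))
  bound <- log(1 + 1e-200) - log(1e-200)
  expect_true(all(abs(alienIndex(a, b)) <= bound))
  # the bound is attained exactly at the corners
  expect_equal(alienIndex(1, 0), bound)
  expect_equal(alienIndex(0, 1), -bound)
  # a weaker (larger) recipient e-value makes the gene look more alien;
  # a stronger (smaller) donor e-value does the same
  r <- 10^seq(-50, 0, length.out = 21)
  expect_true(all(diff(alienIndex(r, 1e-25)) > 0))
  expect_true(all(diff(alienIndex(1e-5, r)) < 0))
})

test_that("group-wise best hits respect membership, clamping and exclusion", {
  h <- rbind(
    makeHits("g1", "Eukaryota;Amoebozoa;T", c(1e-5, 1e-8),
             subject = c("r1", "r2")),
    makeHits("g1", "Bacteria;Proteobacteria;E", 1e-40, subject = "d1"))
  bb <- bestHitsByGroup(h)
  expect_equal(bb$bbh_recipient, 1e-8)
  expect_equal(bb$bbh_donor, 1e-40)
  expect_identical(bb$donor_superkingdom, "Bacteria")
  expect_identical(bb$donor_phylum, "Proteobacteria")
  # no recipient hits: stated default of 1.0
  hd <- makeHits("g2", "Viruses;Mimiviridae;H", 1e-70)
  bb2 <- bestHitsByGroup(hd)
  expect_identical(bb2$bbh_recipient, 1.0)
  # excluding the only recipient lineage restores the default
  bb3 <- bestHitsByGroup(h, excludeLineage = "Amoebozoa")
  expect_identical(bb3$bbh_recipient, 1.0)
  expect_equal(bb3$bbh_donor, 1e-40)
  # e-values above 1 are clamped before scoring
  hc <- makeHits("g3", "Eukaryota;Amoebozoa;T", 3)
  expect_identical(bestHitsByGroup(hc)$bbh_recipient, 1.0)
  # disjointness is enforced
  expect_error(bestHitsByGroup(h, recipientTaxa = "Bacteria"), "disjoint")
})

test_that("LGT calling applies the inclusive threshold", {
  tab <- data.frame(gene_id = c("a", "b", "c"),
                    ai = c(45.0, 44.999, 200))
  called <- callLgt(tab)
  expect_identical(called$is_candidate, c(TRUE, FALSE, TRUE))
  # strict comparator excludes the boundary
  expect_identical(callLgt(tab, comparator = ">")$is_candidate,
                   c(FALSE, FALSE, TRUE))
  # candidate set shrinks (weakly) as the threshold rises
  set.seed(3)
  tab2 <- data.frame(gene_id = sprintf("g%03d", 1:100),
                     ai = runif(100, -100, 200))
  sizes <- vapply(c(-50, 0, 45, 100, 150),
                  function(t) sum(callLgt(tab2, threshold = t)$is_candidate),
                  0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("planted LGTs are recovered exactly on a synthetic bundle", {
  p <- tinyParams(seed = 17, n_genes = 400)
  b <- generateBundle(p)
  res <- computeAlienIndex(b$gene_hits, geneIds = b$truth$genes$gene_id)
  truth <- sort(b$truth$genes$gene_id[b$truth$genes$is_lgt])
  expect_identical(sort(lgtCandidates(res)), truth)
  # donor attribution matches the planted donor phylum
  tab <- aiTable(res)
  tg <- b$truth$genes
  cand <- tab[tab$is_candidate, ]
  planted <- setNames(tg$donor_phylum, tg$gene_id)
  expect_identical(cand$donor_phylum, unname(planted[cand$gene_id]))
})

test_that("LGT summaries compute fractions, introns and expression", {
  p <- tinyParams(seed = 23, n_genes = 500)
  b <- generateBundle(p)
  res <- computeAlienIndex(b$gene_hits, geneIds = b$truth$genes$gene_id)
  calls <- classifyGenes(b$gene_hits, geneIds = b$truth$genes$gene_id)
  tg <- b$truth$genes
  s <- summarizeLgt(res, group = "bacteria", geneModels = b$genes,
                    detection = b$detection, calls = calls)
  expect_identical(s$n_group_matching, sum(tg$category == "bacteria"))
  expect_identical(s$n_candidates,
                   sum(tg$category == "bacteria" & tg$is_lgt))
  expect_equal(s$fraction, s$n_candidates / s$n_group_matching)
  expect_equal(sum(s$donor_phylum_distribution),
               if (s$n_candidates) 1 else numeric(0))
  # expression count equals the planted expressed flags for the group
  td <- b$truth$detection
  planted_expr <- td$gene_id[td$role == "lgt" & !is.na(td$expressed) &
                               td$expressed]
  bact_lgt <- tg$gene_id[tg$category == "bacteria" & tg$is_lgt]
  expect_identical(s$n_expressed, sum(bact_lgt %in% planted_expr))
  # all-single-exon candidates give a zero intron fraction
  tab <- data.frame(gene_id = c("x1", "x2"), bbh_recipient = 1,
                    bbh_donor = 1e-60, ai = alienIndex(1, 1e-60),
                    is_candidate = TRUE, donor_superkingdom = "Bacteria",
                    donor_phylum = "FCB group", donor_subject = "d")
  res2 <- new("AlienIndexResults", table = tab, threshold = 45,
              comparator = ">=", pseudocount = 1e-200)
  gm <- GenomicRanges::GRanges(c("s1:1-300", "s1:400-700"))
  S4Vectors::mcols(gm)$gene_id <- c("x1", "x2")
  S4Vectors::mcols(gm)$exon_count <- c(1L, 1L)
  S4Vectors::mcols(gm)$intron_count <- c(0L, 0L)
  s2 <- summarizeLgt(res2, group = "bacteria", geneModels = gm)
  expect_identical(s2$fraction_with_introns, 0)
  # unjoinable ids warn and are excluded from the intron fraction
  gm1 <- gm[1]
  expect_warning(s3 <- summarizeLgt(res2, group = "bacteria",
                                    geneModels = gm1), "missing from")
  expect_identical(s3$fraction_with_introns, 0)
})

test_that("viral LGT intron fraction concentrates near the planted rate", {
  p <- syntheticParams(seed = 29, n_scaffolds = 10, n_genes = 6000,
                       toolkit_queries = tinyQueries(), n_ssu_copies = 3,
                       ssu_length = 300)
  a <- generateAssembly(p)
  h <- generateHitTables(p, a)
  res <- computeAlienIndex(h$gene_hits, geneIds = a$truth$genes$gene_id)
  s <- summarizeLgt(res, group = "virus", geneModels = a$genes)
  expect_lt(abs(s$fraction_with_introns - 0.40), 0.05)
})
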