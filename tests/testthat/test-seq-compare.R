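test_that("global alignment scores and identities match hand computations", {
  a <- globalAlign("ACGT", "ACGT")
  expect_equal(a$score, 4)
  expect_equal(a$identity, 1)
  expect_equal(a$divergence, 0)

  b <- globalAlign("ACGT", "AGGT")
  expect_equal(b$score, 2)
  expect_equal(b$identity, 0.75)
  expect_equal(b$divergence, 0.25)

  expect_error(globalAlign("", "ACGT"), "non-empty")
  # gap columns: removing gaps recovers the inputs, no gap-gap columns
  g <- globalAlign("ACGTACGT", "ACGT")
  expect_identical(gsub("-", "", g$aligned_a), "ACGTACGT")
  expect_identical(gsub("-", "", g$aligned_b), "ACGT")
  ca <- strsplit(g$aligned_a, "")[[1]]
  cb <- strsplit(g$aligned_b, "")[[1]]
  expect_false(any(ca == "-" & cb == "-"))
  expect_identical(nchar(g$aligned_a), nchar(g$aligned_b))
})

test_that("alignment scores match exhaustive enumeration on short pairs", {
  set.seed(11)
  for (i in 1:120) {
    a <- randomDna(sample(1:6, 1))
    b <- randomDna(sample(1:6, 1))
    expect_equal(globalAlign(a, b)$score, bruteAlignScore(a, b),
                 label = paste(a, b))
  }
})

test_that("alignment score is symmetric and the DP bound holds under fuzz", {
  set.seed(13)
  for (i in 1:25) {
    a <- randomDna(sample(3:12, 1))
    b <- randomDna(sample(3:12, 1))
    expect_equal(globalAlign(a, b)$score, globalAlign(b, a)$score)
    expect_equal(globalAlign(a, a)$identity, 1)
    # a random explicit alignment never beats the DP optimum
    best <- globalAlign(a, b)$score
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    i1 <- 1; j1 <- 1; sc <- 0
    while (i1 <= length(ca) || j1 <= length(cb)) {
      mv <- sample(c("d", "u", "l"), 1)
      if (mv == "d" && i1 <= length(ca) && j1 <= length(cb)) {
        sc <- sc + if (ca[i1] == cb[j1]) 1 else -1
        i1 <- i1 + 1; j1 <- j1 + 1
      } else if (mv != "l" && i1 <= length(ca)) {
        sc <- sc - 2; i1 <- i1 + 1
      } else if (j1 <= length(cb)) {
        sc <- sc - 2; j1 <- j1 + 1
      }
    }
    expect_gte(best, sc)
  }
})

test_that("alignment scores agree with an independent aligner", {
  set.seed(17)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (i in 1:20) {
    a <- randomDna(sample(10:60, 1))
    b <- randomDna(sample(10:60, 1))
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2)
    expect_equal(globalAlign(a, b)$score, Biostrings::score(ref))
  }
})

test_that("terminal gap policy changes the identity denominator", {
  # a forced leading overhang is excluded from the columns by default
  r <- globalAlign("GGGACGT", "ACGT")
  expect_equal(r$n_columns, 4)
  expect_equal(r$identity, 1)
  r2 <- globalAlign("GGGACGT", "ACGT", countTerminalGaps = TRUE)
  expect_equal(r2$n_columns, 7)
  expect_equal(r2$identity, 4 / 7)
  # internal gap columns always count as differences
  ri <- globalAlign("AATTT", "AAGTTT")
  expect_lt(ri$identity, 1)
})

test_that("SSU reports flag divergence above the species-level cap", {
  s <- c(a = "ACGTACGTACGTACGTACGT", b = "ACGTACGTACGTACGTACGT")
  rep0 <- ssuReport(s)
  expect_equal(rep0$max_divergence, 0)
  expect_true(rep0$pass)
  expect_error(ssuReport(s[1]), "at least 2")

  # one copy 10% diverged: 2 substitutions over 20 bp
  set.seed(19)
  base <- randomDna(200)
  ch <- strsplit(base, "")[[1]]
  at <- sample(200, 20)
  ch[at] <- vapply(ch[at], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  far <- paste(ch, collapse = "")
  rep1 <- ssuReport(c(a = base, b = base, c = far))
  expect_equal(rep1$max_divergence, 0.10)
  expect_false(rep1$pass)

  d <- rep1$distance
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0))
})

test_that("neighbor joining recovers additive and ultrametric topologies", {
  # additive 4-taxon matrix for ((A,B),(C,D))
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["C", "D"] <- d["D", "C"] <- 7
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  tr <- njTree(d)
  ref <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
  # 3 taxa: the unique unrooted star
  d3 <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  tr3 <- njTree(d3)
  expect_identical(sort(tr3$tip.label), letters[1:3])
  expect_identical(tr3$Nnode, 1L)
  # ultrametric 5-taxon tree from its cophenetic distances
  set.seed(23)
  ref5 <- ape::rcoal(5)
  tr5 <- njTree(ape::cophenetic.phylo(ref5))
  expect_equal(ape::dist.topo(ape::unroot(tr5), ape::unroot(ref5)), 0,
               ignore_attr = TRUE)
  # invalid matrices are rejected
  bad <- d; bad["A", "B"] <- 99
  expect_error(njTree(bad), "symmetric")
  diag(d) <- 1
  expect_error(njTree(d), "zero diagonal")
})

test_that("donor nesting checks classify candidate placements", {
  # candidate identical to one donor reference
  labs <- c("cand", "don1", "don2", "rec1", "rec2")
  d <- matrix(10, 5, 5, dimnames = list(labs, labs))
  diag(d) <- 0
  d["cand", "don1"] <- d["don1", "cand"] <- 0
  d["cand", "don2"] <- d["don2", "cand"] <- 2
  d["don1", "don2"] <- d["don2", "don1"] <- 2
  d["rec1", "rec2"] <- d["rec2", "rec1"] <- 2
  tr <- njTree(d)
  expect_identical(donorNestingCheck(tr, "cand", c("don1", "don2"),
                                     c("rec1", "rec2")), "nested_in_donor")
  # symmetric construction: candidate equidistant from everything
  de <- matrix(10, 5, 5, dimnames = list(labs, labs))
  diag(de) <- 0
  tre <- njTree(de)
  expect_identical(donorNestingCheck(tre, "cand", c("don1", "don2"),
                                     c("rec1", "rec2")), "unresolved")
  # candidate inside the recipient cluster
  dr <- d
  dr["cand", "don1"] <- dr["don1", "cand"] <- 10
  dr["cand", "don2"] <- dr["don2", "cand"] <- 10
  dr["cand", "rec1"] <- dr["rec1", "cand"] <- 1
  dr["cand", "rec2"] <- dr["rec2", "cand"] <- 1
  trr <- njTree(dr)
  expect_identical(donorNestingCheck(trr, "cand", c("don1", "don2"),
                                     c("rec1", "rec2")),
                   "nested_in_recipient")
  expect_error(donorNestingCheck(tr, "nope", c("don1", "don2"),
                                 c("rec1", "rec2")), "absent")
})

test_that("planted LGT sequences nest with their donors on synthetic data", {
  # donor-like candidate: small distance to donors, large to recipients
  set.seed(29)
  donor_anc <- randomDna(300)
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    at <- sample(length(ch), k)
    ch[at] <- vapply(ch[at], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    paste(ch, collapse = "")
  }
  rec_anc <- randomDna(300)
  seqs <- c(cand = mutate(donor_anc, 5), don1 = mutate(donor_anc, 6),
            don2 = mutate(donor_anc, 8), rec1 = mutate(rec_anc, 6),
            rec2 = mutate(rec_anc, 8))
  tr <- njTree(divergenceMatrix(seqs))
  expect_identical(donorNestingCheck(tr, "cand", c("don1", "don2"),
                                     c("rec1", "rec2")), "nested_in_donor")
})
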