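# shared fixture builders for the test suite; everything is generated in
# code, nothing is read from disk except files the tests write themselves

# minimal hit-table rows with sensible defaults for untested columns
makeHits <- function(query, lineage, evalue, bitscore = 100,
                     subject = NULL) {
  n <- max(length(query), length(lineage), length(evalue), length(bitscore))
  if (is.null(subject)) subject <- sprintf("sub%03d", seq_len(n))
  data.frame(query_id = rep_len(query, n), subject_id = rep_len(subject, n),
             percent_identity = 50, alignment_length = 100L,
             mismatches = 10L, gap_opens = 0L, q_start = 1L, q_end = 100L,
             s_start = 1L, s_end = 100L, evalue = rep_len(evalue, n),
             bitscore = rep_len(bitscore, n),
             lineage = rep_len(lineage, n),
             superkingdom = sub(";.*$", "", rep_len(lineage, n)),
             phylum = vapply(strsplit(rep_len(lineage, n), ";", fixed = TRUE),
                             function(r) if (length(r) >= 2) r[2]
                             else NA_character_, ""),
             stringsAsFactors = FALSE)
}

# small query manifest for fast synthetic bundles
tinyQueries <- function() {
  data.frame(
    gene_name = c("SPO11", "DMC1", "HOP2", "HAP2", "KAR2", "XTRA"),
    class = c("meiosis_specific", "meiosis_specific", "meiosis_specific",
              "plasmogamy", "karyogamy", "other"),
    query_id = c("Q_SPO11", "Q_DMC1", "Q_HOP2", "Q_HAP2", "Q_KAR2",
                 "Q_XTRA"),
    stringsAsFactors = FALSE)
}

tinyParams <- function(seed = 1, ...) {
  args <- list(seed = seed, n_scaffolds = 8, n_genes = 60,
               n_ssu_copies = 5, ssu_length = 400,
               toolkit_queries = tinyQueries())
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(syntheticParams, args)
}

# brute-force N50: descending scan of cumulative sums
bruteN50 <- function(lens) {
  sl <- sort(lens, decreasing = TRUE)
  tot <- sum(sl)
  acc <- 0
  for (L in sl) {
    acc <- acc + L
    if (acc >= tot / 2) return(L)
  }
}

# exhaustive global-alignment score: enumerates every alignment recursively
bruteAlignScore <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      s <- if (ca[i] == cb[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1))
    }
    if (i <= length(ca)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(cb)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
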