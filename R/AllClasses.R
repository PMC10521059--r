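#' ScaffoldSet: an assembly with per-scaffold coverage
#'
#' Container for a set of assembly scaffolds together with the per-scaffold
#' read coverage used by the contamination screen. Sequences are stored as a
#' [Biostrings::DNAStringSet] restricted to the alphabet `{A,C,G,T,N}`;
#' coverage is a numeric vector parallel to the sequences (`NA` where no
#' coverage was supplied).
#'
#' @slot sequences A [Biostrings::DNAStringSet] of scaffold sequences with
#'   unique, non-empty names.
#' @slot coverage Numeric vector of per-scaffold coverage values, same length
#'   and order as `sequences`; non-negative or `NA`.
#'
#' @seealso [readScaffolds()], [assemblyStats()], [flagContaminants()]
#' @export
setClass("ScaffoldSet",
  representation(sequences = "DNAStringSet", coverage = "numeric"))

setValidity("ScaffoldSet", function(object) {
  msg <- character()
  ids <- names(object@sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    msg <- c(msg, "all scaffolds must be named")
  if (anyDuplicated(ids))
    msg <- c(msg, paste0("duplicate scaffold ids: ",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object@sequences) && any(Biostrings::width(object@sequences) == 0))
    msg <- c(msg, "empty scaffold sequences are not allowed")
  if (length(object@coverage) != length(object@sequences))
    msg <- c(msg, "coverage must be parallel to sequences")
  if (any(object@coverage < 0, na.rm = TRUE))
    msg <- c(msg, "coverage must be non-negative")
  if (length(object@sequences)) {
    af <- Biostrings::alphabetFrequency(object@sequences, collapse = TRUE)
    bad <- af[setdiff(names(af), c("A", "C", "G", "T", "N"))]
    if (sum(bad) > 0)
      msg <- c(msg, paste0("sequences contain letters outside {A,C,G,T,N}: ",
                           paste(names(bad)[bad > 0], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ScaffoldSet
#'
#' @param sequences A [Biostrings::DNAStringSet] (or named character vector)
#'   of scaffold sequences.
#' @param coverage Optional named numeric vector of per-scaffold coverage;
#'   names are matched against scaffold ids, unmatched scaffolds get `NA`.
#' @return A [ScaffoldSet-class] object.
#' @examples
#' ss <- ScaffoldSet(c(s1 = "ACGT", s2 = "GGCC"), coverage = c(s1 = 30))
#' scaffoldGC(ss)
#' @export
ScaffoldSet <- function(sequences, coverage = NULL) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  cov <- rep(NA_real_, length(sequences))
  names(cov) <- names(sequences)
  if (!is.null(coverage)) {
    if (is.null(names(coverage)))
      stop("coverage must be a named vector (names = scaffold ids)")
    hit <- match(names(coverage), names(sequences))
    cov[hit[!is.na(hit)]] <- unname(coverage)[!is.na(hit)]
  }
  new("ScaffoldSet", sequences = sequences, coverage = cov)
}

#' @describeIn ScaffoldSet-class number of scaffolds
#' @param x,object A `ScaffoldSet`.
#' @export
setMethod("length", "ScaffoldSet", function(x) length(x@sequences))

setMethod("show", "ScaffoldSet", function(object) {
  n <- length(object)
  tot <- sum(Biostrings::width(object@sequences))
  cat("ScaffoldSet with", n, "scaffolds,", tot, "bp total\n")
  if (n) {
    gc <- scaffoldGC(object)
    cat(sprintf("  assembly GC (N-excluded): %.4f\n", assemblyGC(object)))
    cat(sprintf("  coverage: %d/%d scaffolds with values\n",
                sum(!is.na(object@coverage)), n))
    if (any(is.na(gc)))
      cat("  note:", sum(is.na(gc)), "scaffold(s) with undefined GC (all-N)\n")
  }
})

#' Accessors for ScaffoldSet
#'
#' `scaffoldIds`, `scaffoldSeqs`, `scaffoldLengths`, `scaffoldGC` and
#' `scaffoldCoverage` extract per-scaffold fields; derived fields (length,
#' GC fraction) are computed from the sequences. `assemblyGC` gives the
#' base-wise GC fraction of the whole assembly, excluding `N`s.
#' GC fraction is `(#G + #C) / (#A + #C + #G + #T)` and is `NA` (flagged)
#' when the denominator is zero (all-`N` scaffolds).
#'
#' @param x A [ScaffoldSet-class].
#' @return A vector parallel to the scaffolds (or a single number for
#'   `assemblyGC`).
#' @name scaffold-accessors
NULL

#' @rdname scaffold-accessors
#' @export
scaffoldIds <- function(x) names(x@sequences)

#' @rdname scaffold-accessors
#' @export
scaffoldSeqs <- function(x) x@sequences

#' @rdname scaffold-accessors
#' @export
scaffoldLengths <- function(x) setNames(Biostrings::width(x@sequences), scaffoldIds(x))

#' @rdname scaffold-accessors
#' @export
scaffoldCoverage <- function(x) x@coverage

#' @rdname scaffold-accessors
#' @export
scaffoldGC <- function(x) {
  gcc <- Biostrings::letterFrequency(x@sequences, "GC")[, 1]
  acgt <- Biostrings::letterFrequency(x@sequences, "ACGT")[, 1]
  setNames(ifelse(acgt > 0, gcc / acgt, NA_real_), scaffoldIds(x))
}

#' @rdname scaffold-accessors
#' @export
assemblyGC <- function(x) {
  af <- Biostrings::alphabetFrequency(x@sequences, collapse = TRUE)
  acgt <- sum(af[c("A", "C", "G", "T")])
  if (acgt == 0) return(NA_real_)
  sum(af[c("G", "C")]) / acgt
}

#' AlienIndexResults: per-gene Alien Index scores and LGT calls
#'
#' Holds the per-gene Alien Index (AI) table produced by
#' [computeAlienIndex()]: best recipient-side and donor-side e-values,
#' the AI score, the LGT call at the configured threshold, and donor
#' attribution (superkingdom and the lineage rank immediately below it).
#'
#' @slot table `data.frame` with columns `gene_id`, `bbh_recipient`,
#'   `bbh_donor`, `ai`, `is_candidate`, `donor_superkingdom`, `donor_phylum`,
#'   `donor_subject`.
#' @slot threshold Numeric AI calling threshold (default 45).
#' @slot comparator `">="` or `">"`; how the threshold is applied.
#' @slot pseudocount Pseudo-count added to both e-values inside the logs.
#' @seealso [computeAlienIndex()], [callLgt()], [summarizeLgt()]
#' @export
setClass("AlienIndexResults",
  representation(table = "data.frame", threshold = "numeric",
                 comparator = "character", pseudocount = "numeric"))

setValidity("AlienIndexResults", function(object) {
  msg <- character()
  need <- c("gene_id", "bbh_recipient", "bbh_donor", "ai", "is_candidate",
            "donor_superkingdom", "donor_phylum")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, paste("table must have columns:", paste(need, collapse = ", ")))
  if (length(object@threshold) != 1 || !is.finite(object@threshold))
    msg <- c(msg, "threshold must be a single finite number")
  if (!object@comparator %in% c(">=", ">"))
    msg <- c(msg, "comparator must be \">=\" or \">\"")
  if (length(object@pseudocount) != 1 || object@pseudocount <= 0)
    msg <- c(msg, "pseudocount must be a single positive number")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AlienIndexResults", function(object) {
  tab <- object@table
  cat("AlienIndexResults:", nrow(tab), "genes,",
      sum(tab$is_candidate), "LGT candidates (AI",
      object@comparator, object@threshold, ")\n")
  sk <- table(tab$donor_superkingdom[tab$is_candidate])
  if (length(sk))
    cat("  candidate donors:",
        paste(names(sk), sk, sep = "=", collapse = ", "), "\n")
})

#' @describeIn AlienIndexResults-class the per-gene AI table
#' @param x An `AlienIndexResults` object.
#' @export
aiTable <- function(x) {
  stopifnot(is(x, "AlienIndexResults"))
  x@table
}

#' @describeIn AlienIndexResults-class gene ids of the LGT candidates
#' @export
lgtCandidates <- function(x) {
  stopifnot(is(x, "AlienIndexResults"))
  x@table$gene_id[x@table$is_candidate]
}

#' @describeIn AlienIndexResults-class the AI calling threshold
#' @export
aiThreshold <- function(x) {
  stopifnot(is(x, "AlienIndexResults"))
  x@threshold
}

#' DetectionMatrix: gene-by-sample transcript detection
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' toolkit-gene x sample detection table: assay `"value"` carries the raw
#' detection values (counts/abundances, `NA` where a gene model was absent
#' from the detection table) and assay `"detected"` the boolean calls at the
#' configured detection threshold. `colData(x)$condition` carries the
#' size-class label (`small`, `medium`, `large`) of every sample; columns
#' are kept in design order (small, then medium, then large).
#'
#' @seealso [detectionMatrix()], [conditionSummary()]
#' @export
setClass("DetectionMatrix", contains = "SummarizedExperiment")

setValidity("DetectionMatrix", function(object) {
  msg <- character()
  if (!all(c("value", "detected") %in% names(SummarizedExperiment::assays(object))))
    msg <- c(msg, "assays 'value' and 'detected' are required")
  cd <- SummarizedExperiment::colData(object)
  if (!"condition" %in% names(cd))
    msg <- c(msg, "colData must carry a 'condition' column")
  else if (!all(as.character(cd$condition) %in% .CONDITIONS))
    msg <- c(msg, "conditions must be small/medium/large")
  if ("detected" %in% names(SummarizedExperiment::assays(object)) &&
      anyNA(SummarizedExperiment::assay(object, "detected")))
    msg <- c(msg, "every detection cell must be defined")
  if (length(msg)) msg else TRUE
})

#' @describeIn DetectionMatrix-class character matrix of `"+"`/`"-"` calls
#' @param x A `DetectionMatrix`.
#' @export
detectionCalls <- function(x) {
  stopifnot(is(x, "DetectionMatrix"))
  d <- SummarizedExperiment::assay(x, "detected")
  m <- ifelse(d, "+", "-")
  dimnames(m) <- dimnames(d)
  m
}

#' @describeIn DetectionMatrix-class factor of per-sample size-class labels
#' @export
sampleConditions <- function(x) {
  stopifnot(is(x, "DetectionMatrix"))
  factor(as.character(SummarizedExperiment::colData(x)$condition),
         levels = .CONDITIONS)
}

setMethod("show", "DetectionMatrix", function(object) {
  cat("DetectionMatrix:", nrow(object), "gene models x", ncol(object),
      "samples\n")
  cond <- sampleConditions(object)
  cat("  samples:", paste0(colnames(object), " (", as.character(cond), ")",
                           collapse = ", "), "\n")
  m <- detectionCalls(object)
  show_n <- min(nrow(m), 10L)
  if (show_n) {
    print(m[seq_len(show_n), , drop = FALSE], quote = FALSE)
    if (nrow(m) > show_n) cat("  ...", nrow(m) - show_n, "more rows\n")
  }
})
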