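#' Assign a taxonomic call to each scaffold
#'
#' Summarizes scaffold-level homology hits into one of `eukaryote`,
#' `non_eukaryote` or `no_hit` per scaffold. The default rule gives the call
#' to the superkingdom holding the majority of summed bitscore among hits at
#' e-value at or below the cutoff (`bestsum`); `best_hit` uses the single
#' lowest-e-value hit instead. Ties in bitscore mass resolve to eukaryote —
#' conservative retention, since the screen errs toward keeping host genes.
#'
#' @param hits Hit `data.frame` (see [readHitTable()]) with `query_id` =
#'   scaffold id.
#' @param scaffoldIds Character vector of all scaffold ids to annotate
#'   (scaffolds without qualifying hits get `no_hit`).
#' @param evalueCutoff Qualification cutoff; hits with `evalue <= cutoff`
#'   participate. Default 1e-3.
#' @param method `"bestsum"` (default) or `"best_hit"`.
#' @return A `data.frame` with columns `scaffold_id`, `taxon_call`.
#' @examples
#' h <- data.frame(query_id = "s1", subject_id = letters[1:4],
#'                 evalue = 1e-20, bitscore = c(100, 90, 80, 50),
#'                 superkingdom = c("Bacteria", "Bacteria", "Bacteria",
#'                                  "Eukaryota"))
#' assignScaffoldTaxon(h, "s1")$taxon_call  # "non_eukaryote"
#' @export
assignScaffoldTaxon <- function(hits, scaffoldIds, evalueCutoff = 1e-3,
                                method = c("bestsum", "best_hit")) {
  method <- match.arg(method)
  call <- setNames(rep("no_hit", length(scaffoldIds)), scaffoldIds)
  if (!is.null(hits) && nrow(hits)) {
    q <- hits[hits$evalue <= evalueCutoff & hits$query_id %in% scaffoldIds, ,
              drop = FALSE]
    if (nrow(q)) {
      for (sid in unique(q$query_id)) {
        hh <- q[q$query_id == sid, , drop = FALSE]
        if (method == "bestsum") {
          mass <- tapply(hh$bitscore, hh$superkingdom, sum)
          top <- names(mass)[mass == max(mass)]
          sk <- if ("Eukaryota" %in% top) "Eukaryota" else top[1]
        } else {
          o <- order(hh$evalue, -hh$bitscore, hh$subject_id)
          sk <- hh$superkingdom[o[1]]
        }
        call[sid] <- if (sk == "Eukaryota") "eukaryote" else "non_eukaryote"
      }
    }
  }
  data.frame(scaffold_id = scaffoldIds, taxon_call = unname(call),
             stringsAsFactors = FALSE)
}

#' Flag contaminant scaffolds by the three-criterion rule
#'
#' A scaffold is marked as a contaminant if and only if it meets all three
#' criteria: (1) taxonomically designated non-eukaryote or no-hit, (2)
#' aberrant GC — more than `gcDelta` away from `gcCenter`, and (3) coverage
#' below `coverageCutoff`. Scaffolds with missing coverage cannot satisfy
#' the conjunction and are retained with a warning.
#'
#' @param annotations `data.frame` with columns `scaffold_id`, `taxon_call`
#'   (`eukaryote` / `non_eukaryote` / `no_hit`), `gc_fraction`, `coverage`
#'   (NA allowed), `length`.
#' @param gcCenter Center of the acceptable GC band, in (0,1). Convention:
#'   the assembly-wide length-weighted GC of the input assembly.
#' @param gcDelta Half-width of the acceptable GC band (default 0.08).
#' @param coverageCutoff Coverage threshold (default 10.0).
#' @param whitelist Optional scaffold ids never flagged (manual retention
#'   override).
#' @return A `data.frame` with columns `scaffold_id`, `criterion_taxonomy`,
#'   `criterion_gc`, `criterion_coverage`, `is_contaminant`.
#' @export
flagContaminants <- function(annotations, gcCenter, gcDelta = 0.08,
                             coverageCutoff = 10.0, whitelist = NULL) {
  need <- c("scaffold_id", "taxon_call", "gc_fraction", "coverage")
  miss <- setdiff(need, names(annotations))
  if (length(miss)) stop("annotations missing columns: ",
                         paste(miss, collapse = ", "))
  if (!(gcCenter > 0 && gcCenter < 1)) stop("gcCenter must lie in (0, 1)")
  if (!all(annotations$taxon_call %in%
           c("eukaryote", "non_eukaryote", "no_hit")))
    stop("taxon_call must be eukaryote/non_eukaryote/no_hit")
  crit_tax <- annotations$taxon_call != "eukaryote"
  crit_gc <- abs(annotations$gc_fraction - gcCenter) > gcDelta
  crit_cov <- annotations$coverage < coverageCutoff
  if (anyNA(crit_cov)) {
    warning(sum(is.na(crit_cov)),
            " scaffold(s) without coverage retained (criterion undefined)")
  }
  is_cont <- crit_tax & crit_gc & !is.na(crit_cov) & crit_cov
  if (!is.null(whitelist))
    is_cont[annotations$scaffold_id %in% whitelist] <- FALSE
  data.frame(scaffold_id = annotations$scaffold_id,
             criterion_taxonomy = crit_tax, criterion_gc = crit_gc,
             criterion_coverage = crit_cov, is_contaminant = is_cont,
             stringsAsFactors = FALSE)
}

#' Screen an assembly for contaminant scaffolds
#'
#' Convenience wrapper: annotates scaffolds ([assignScaffoldTaxon()]),
#' applies [flagContaminants()] with `gcCenter` defaulting to the
#' assembly-wide length-weighted GC, and returns decisions plus the retained
#' assembly and before/after statistics.
#'
#' @param scaffolds A [ScaffoldSet-class].
#' @param hits Scaffold-level hit `data.frame`.
#' @param gcCenter GC band center; default `assemblyGC(scaffolds)`.
#' @inheritParams flagContaminants
#' @inheritParams assignScaffoldTaxon
#' @return List with `decisions`, `retained` ([ScaffoldSet-class]),
#'   `stats_pre`, `stats_post`.
#' @export
screenAssembly <- function(scaffolds, hits, gcCenter = NULL, gcDelta = 0.08,
                           coverageCutoff = 10.0, evalueCutoff = 1e-3,
                           whitelist = NULL,
                           method = c("bestsum", "best_hit")) {
  stopifnot(is(scaffolds, "ScaffoldSet"))
  if (is.null(gcCenter)) gcCenter <- assemblyGC(scaffolds)
  ann <- assignScaffoldTaxon(hits, scaffoldIds(scaffolds),
                             evalueCutoff = evalueCutoff,
                             method = match.arg(method))
  ann$gc_fraction <- unname(scaffoldGC(scaffolds))
  ann$coverage <- unname(scaffoldCoverage(scaffolds))
  ann$length <- unname(scaffoldLengths(scaffolds))
  dec <- flagContaminants(ann, gcCenter = gcCenter, gcDelta = gcDelta,
                          coverageCutoff = coverageCutoff,
                          whitelist = whitelist)
  keep <- !dec$is_contaminant
  retained <- new("ScaffoldSet",
                  sequences = scaffoldSeqs(scaffolds)[keep],
                  coverage = scaffoldCoverage(scaffolds)[keep])
  list(decisions = dec, retained = retained,
       stats_pre = assemblyStats(scaffolds),
       stats_post = assemblyStats(retained))
}

#' Assembly summary statistics
#'
#' Computes the standard descriptive statistics of an assembly: total length,
#' scaffold count, base-wise GC percent (N-excluded), longest/shortest/mean
#' scaffold length, and N50. N50 is the length of the smallest scaffold in
#' the minimal descending-length prefix whose cumulative length reaches at
#' least half the total assembly length.
#'
#' @param scaffolds A [ScaffoldSet-class], [Biostrings::DNAStringSet], or
#'   (lengths-only statistics) a numeric vector of scaffold lengths.
#' @return A one-row `data.frame` with columns `total_length`, `n_scaffolds`,
#'   `gc_percent`, `longest`, `shortest`, `mean_length`, `n50`
#'   (`gc_percent` is `NA` when only lengths are supplied).
#' @examples
#' assemblyStats(c(40, 30, 20, 10))$n50   # 30
#' @export
assemblyStats <- function(scaffolds) {
  if (is(scaffolds, "DNAStringSet"))
    scaffolds <- ScaffoldSet(scaffolds)
  if (is(scaffolds, "ScaffoldSet")) {
    lens <- unname(scaffoldLengths(scaffolds))
    gc_pct <- 100 * assemblyGC(scaffolds)
  } else if (is.numeric(scaffolds)) {
    lens <- as.numeric(scaffolds)
    gc_pct <- NA_real_
  } else stop("unsupported input type")
  if (!length(lens)) stop("empty assembly")
  total <- sum(lens)
  sl <- sort(lens, decreasing = TRUE)
  n50 <- sl[which(cumsum(sl) >= total / 2)[1]]
  data.frame(total_length = total, n_scaffolds = length(lens),
             gc_percent = gc_pct, longest = max(lens), shortest = min(lens),
             mean_length = total / length(lens), n50 = n50)
}

#' Download a deposited assembly by accession
#'
#' Fetches the scaffold set of a WGS accession from the ENA browser API as
#' uncompressed FASTA. Requires network access.
#'
#' @param accession WGS set accession (e.g. `"JALMLS010000000"`).
#' @param dest Destination FASTA path.
#' @param timeout Seconds before giving up.
#' @return `dest`, invisibly. Errors if the download fails.
#' @export
fetchAssembly <- function(accession, dest = tempfile(fileext = ".fasta"),
                          timeout = 300) {
  url <- paste0("https://www.ebi.ac.uk/ena/browser/api/fasta/", accession,
                "?download=true")
  old <- getOption("timeout")
  on.exit(options(timeout = old))
  options(timeout = timeout)
  status <- tryCatch(utils::download.file(url, dest, mode = "wb",
                                          quiet = TRUE),
                     error = function(e) conditionMessage(e))
  if (!identical(status, 0L))
    stop("could not download ", accession, ": ", status)
  if (!file.exists(dest) || file.size(dest) == 0)
    stop("download of ", accession, " produced no data")
  invisible(dest)
}
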