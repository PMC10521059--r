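#' Classify gene models by protein best hit
#'
#' Partitions predicted gene models into `eukaryote`, `bacteria`, `archaea`,
#' `virus` and `orfan` classes from their protein homology hits. The best
#' hit of a gene is the qualifying hit (strictly `evalue < evalueCutoff`)
#' with the lowest e-value; ties are broken by maximum bitscore, then
#' lexicographically smallest subject id, making the call deterministic and
#' independent of input order. A gene with no qualifying hit is an ORFan.
#'
#' @param hits Hit `data.frame` (see [readHitTable()]) with `query_id` =
#'   gene id.
#' @param geneIds Optional character vector of all gene ids (genes absent
#'   from `hits` are classified as ORFans). Defaults to the ids present in
#'   `hits`.
#' @param evalueCutoff Strict upper bound on qualifying e-values
#'   (default 1e-3).
#' @return A `data.frame` with columns `gene_id`, `category`,
#'   `best_subject`, `best_evalue`, `best_bitscore`, `best_superkingdom`,
#'   `best_lineage` (best-hit columns `NA` for ORFans).
#' @examples
#' h <- data.frame(query_id = "g1", subject_id = c("a", "b"),
#'                 evalue = c(1e-50, 1e-20), bitscore = c(200, 100),
#'                 superkingdom = c("Bacteria", "Eukaryota"),
#'                 lineage = c("Bacteria;x", "Eukaryota;y"))
#' classifyGenes(h)$category  # "bacteria"
#' @export
classifyGenes <- function(hits, geneIds = NULL, evalueCutoff = 1e-3) {
  if (is.null(geneIds)) geneIds <- unique(hits$query_id)
  out <- data.frame(gene_id = geneIds, category = "orfan",
                    best_subject = NA_character_, best_evalue = NA_real_,
                    best_bitscore = NA_real_,
                    best_superkingdom = NA_character_,
                    best_lineage = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(hits) && nrow(hits)) {
    q <- hits[hits$evalue < evalueCutoff & hits$query_id %in% geneIds, ,
              drop = FALSE]
    if (nrow(q)) {
      o <- order(q$query_id, q$evalue, -q$bitscore, q$subject_id)
      q <- q[o, , drop = FALSE]
      best <- q[!duplicated(q$query_id), , drop = FALSE]
      i <- match(best$query_id, out$gene_id)
      out$category[i] <- unname(.SK_TO_CATEGORY[best$superkingdom])
      out$best_subject[i] <- best$subject_id
      out$best_evalue[i] <- best$evalue
      out$best_bitscore[i] <- best$bitscore
      out$best_superkingdom[i] <- best$superkingdom
      if ("lineage" %in% names(best)) out$best_lineage[i] <- best$lineage
    }
  }
  out
}

#' Summarize a taxonomic partition of gene models
#'
#' Exact counts and proportions per category over the five-way partition
#' (the partition is exhaustive and exclusive, so counts sum to the total
#' and proportions to 1).
#'
#' @param calls A `data.frame` from [classifyGenes()] (needs columns
#'   `gene_id`, `category`).
#' @return A `data.frame` with one row per category (`eukaryote`, `orfan`,
#'   `bacteria`, `archaea`, `virus`) and columns `category`, `count`,
#'   `proportion`, plus an attribute `total`.
#' @export
partitionSummary <- function(calls) {
  if (is.null(calls) || !nrow(calls)) stop("empty partition input")
  if (anyDuplicated(calls$gene_id))
    stop("each gene must be classified exactly once")
  bad <- setdiff(unique(calls$category), .CATEGORIES)
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  cat_order <- c("eukaryote", "orfan", "bacteria", "archaea", "virus")
  counts <- vapply(cat_order, function(k) sum(calls$category == k), 0L)
  out <- data.frame(category = cat_order, count = unname(counts),
                    proportion = unname(counts) / nrow(calls),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- nrow(calls)
  out
}
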