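#' Best e-values by recipient and donor group
#'
#' For each gene, finds the best (lowest) e-value among recipient-group hits
#' and among donor-group hits. A hit belongs to a group when any rank of its
#' lineage matches a taxon in the group's set; the groups must be disjoint.
#' Hits whose lineage contains `excludeLineage` are removed first (self-hit
#' guard). E-values are clamped to at most 1; a gene with no hits on a side
#' gets the missing-hit default of 1.0 for that side. The best donor hit's
#' superkingdom and the lineage rank immediately below it are retained for
#' donor attribution.
#'
#' @param hits Hit `data.frame` (see [readHitTable()]).
#' @param recipientTaxa Character set defining the recipient ("self") side;
#'   default `"Eukaryota"`.
#' @param donorTaxa Character set defining the donor ("foreign") side;
#'   default `c("Bacteria", "Archaea", "Viruses")`.
#' @param excludeLineage Optional taxon name; hits carrying it anywhere in
#'   their lineage are dropped before taking minima.
#' @param geneIds Optional vector of all gene ids to report (genes without
#'   hits get 1.0 / 1.0).
#' @return A `data.frame` with columns `gene_id`, `bbh_recipient`,
#'   `bbh_donor`, `donor_superkingdom`, `donor_phylum`, `donor_subject`.
#' @export
bestHitsByGroup <- function(hits,
                            recipientTaxa = "Eukaryota",
                            donorTaxa = c("Bacteria", "Archaea", "Viruses"),
                            excludeLineage = NULL, geneIds = NULL) {
  if (length(intersect(recipientTaxa, donorTaxa)))
    stop("recipient and donor groups must be disjoint")
  if (is.null(geneIds)) geneIds <- unique(hits$query_id)
  out <- data.frame(gene_id = geneIds, bbh_recipient = 1.0, bbh_donor = 1.0,
                    donor_superkingdom = NA_character_,
                    donor_phylum = NA_character_,
                    donor_subject = NA_character_, stringsAsFactors = FALSE)
  if (is.null(hits) || !nrow(hits)) return(out)
  h <- hits[hits$query_id %in% geneIds, , drop = FALSE]
  ranks <- strsplit(h$lineage, ";", fixed = TRUE)
  if (!is.null(excludeLineage)) {
    keep <- !vapply(ranks, function(r) excludeLineage %in% r, TRUE)
    h <- h[keep, , drop = FALSE]
    ranks <- ranks[keep]
  }
  if (!nrow(h)) return(out)
  h$evalue <- pmin(h$evalue, 1.0)
  in_rec <- vapply(ranks, function(r) any(r %in% recipientTaxa), TRUE)
  in_don <- vapply(ranks, function(r) any(r %in% donorTaxa), TRUE)
  rec <- h[in_rec, , drop = FALSE]
  if (nrow(rec)) {
    m <- tapply(rec$evalue, rec$query_id, min)
    i <- match(names(m), out$gene_id)
    out$bbh_recipient[i] <- unname(m)
  }
  don <- h[in_don, , drop = FALSE]
  if (nrow(don)) {
    o <- order(don$query_id, don$evalue, -don$bitscore, don$subject_id)
    don <- don[o, , drop = FALSE]
    best <- don[!duplicated(don$query_id), , drop = FALSE]
    i <- match(best$query_id, out$gene_id)
    out$bbh_donor[i] <- best$evalue
    br <- strsplit(best$lineage, ";", fixed = TRUE)
    out$donor_superkingdom[i] <- vapply(br, `[`, "", 1L)
    out$donor_phylum[i] <- vapply(br, function(r)
      if (length(r) >= 2) r[2] else NA_character_, "")
    out$donor_subject[i] <- best$subject_id
  }
  out
}

#' Alien Index
#'
#' The Alien Index (AI) contrasts a gene's best homology e-value within its
#' recipient (self) group against its best e-value within a candidate donor
#' group:
#' \deqn{AI = \ln(bbh_{recipient} + c) - \ln(bbh_{donor} + c)}
#' with pseudo-count `c` (default 1e-200). Large positive values indicate a
#' much stronger donor-side match, i.e. a foreign origin. With e-values
#' clamped to `[0, 1]`, `|AI|` is bounded by `ln((1 + c)/c)` (about 460.52
#' at the default `c`), attained exactly at `(1, 0)` and `(0, 1)`.
#'
#' @param bbhRecipient,bbhDonor Numeric vectors of best-hit e-values in
#'   `[0, 1]` (missing-hit default 1.0).
#' @param c Pseudo-count added inside both logarithms (natural logs).
#' @return Numeric vector of AI scores.
#' @examples
#' alienIndex(1e-10, 1e-10)   # 0
#' alienIndex(1e-5, 1e-30)    # 25 * log(10) ~ 57.56
#' @export
alienIndex <- function(bbhRecipient, bbhDonor, c = 1e-200) {
  if (length(c) != 1 || !is.finite(c) || c <= 0)
    stop("pseudo-count c must be a single positive number")
  if (any(!is.finite(bbhRecipient)) || any(!is.finite(bbhDonor)) ||
      any(bbhRecipient < 0 | bbhRecipient > 1) ||
      any(bbhDonor < 0 | bbhDonor > 1))
    stop("e-values must lie in [0, 1] (clamp before scoring)")
  log(bbhRecipient + c) - log(bbhDonor + c)
}

#' Call putative LGTs at an Alien Index threshold
#'
#' Sets (or resets) the candidate flags of an AI table: a gene is a putative
#' LGT when its AI meets the threshold (default `ai >= 45`; the comparator
#' is configurable to strict `>`). The candidate set is monotone
#' non-increasing in the threshold.
#'
#' @param x An [AlienIndexResults-class] or a `data.frame` with an `ai`
#'   column.
#' @param threshold AI calling threshold (default 45).
#' @param comparator `">="` (default) or `">"`.
#' @return Same type as `x`, with `is_candidate` updated (and, for
#'   `AlienIndexResults`, the threshold/comparator slots).
#' @export
callLgt <- function(x, threshold = 45, comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  cmp <- if (comparator == ">=") `>=` else `>`
  if (is(x, "AlienIndexResults")) {
    x@table$is_candidate <- cmp(x@table$ai, threshold)
    x@threshold <- threshold
    x@comparator <- comparator
    validObject(x)
    return(x)
  }
  if (!"ai" %in% names(x)) stop("x must carry an 'ai' column")
  x$is_candidate <- cmp(x$ai, threshold)
  x
}

#' Compute per-gene Alien Index results
#'
#' Runs the full AI stage: group-wise best e-values ([bestHitsByGroup()]),
#' AI scoring ([alienIndex()]) and candidate calling ([callLgt()]), with
#' donor attribution from the best donor-side hit.
#'
#' @inheritParams bestHitsByGroup
#' @param pseudocount Pseudo-count for [alienIndex()].
#' @param threshold,comparator Calling rule for [callLgt()].
#' @return An [AlienIndexResults-class].
#' @export
computeAlienIndex <- function(hits,
                              recipientTaxa = "Eukaryota",
                              donorTaxa = c("Bacteria", "Archaea", "Viruses"),
                              excludeLineage = NULL, geneIds = NULL,
                              pseudocount = 1e-200, threshold = 45,
                              comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  tab <- bestHitsByGroup(hits, recipientTaxa = recipientTaxa,
                         donorTaxa = donorTaxa,
                         excludeLineage = excludeLineage, geneIds = geneIds)
  tab$ai <- alienIndex(tab$bbh_recipient, tab$bbh_donor, c = pseudocount)
  tab$is_candidate <- FALSE
  res <- new("AlienIndexResults", table = tab, threshold = threshold,
             comparator = comparator, pseudocount = pseudocount)
  callLgt(res, threshold = threshold, comparator = comparator)
}

#' Summarize LGT candidates of one donor group
#'
#' Produces the headline LGT summary for a donor superkingdom: how many
#' genes match the group, how many are candidates, the candidate fraction,
#' the donor-phylum distribution among candidates, the number of candidates
#' with transcript support, and the fraction of candidates carrying one or
#' more introns. Group membership is taken from the gene-level taxonomic
#' `calls` when supplied (the paper-style "bacteria-matching genes"
#' denominator), otherwise from the best donor hit's superkingdom.
#'
#' @param results An [AlienIndexResults-class].
#' @param group One of `"bacteria"`, `"archaea"`, `"virus"`.
#' @param geneModels Optional [GenomicRanges::GRanges] from
#'   [readGeneModels()] (for intron content).
#' @param detection Optional long detection `data.frame` (for expression);
#'   see [readDetectionTable()].
#' @param calls Optional `data.frame` from [classifyGenes()].
#' @param detectionMin A candidate counts as expressed when detected at
#'   `value >= detectionMin` in at least one sample (default 1).
#' @return A list with `group`, `n_group_matching`, `n_candidates`,
#'   `fraction`, `donor_phylum_distribution` (named proportions summing
#'   to 1), `n_expressed`, `fraction_with_introns` (NA where the needed
#'   inputs were not supplied). Candidates whose ids cannot be joined to
#'   `geneModels` or `detection` are excluded from those fractions only,
#'   with a warning.
#' @export
summarizeLgt <- function(results, group = c("bacteria", "archaea", "virus"),
                         geneModels = NULL, detection = NULL, calls = NULL,
                         detectionMin = 1) {
  group <- match.arg(group)
  stopifnot(is(results, "AlienIndexResults"))
  tab <- aiTable(results)
  sk <- c(bacteria = "Bacteria", archaea = "Archaea", virus = "Viruses")[[group]]
  if (!is.null(calls)) {
    member <- calls$gene_id[calls$category == group]
    in_group <- tab$gene_id %in% member
  } else {
    in_group <- !is.na(tab$donor_superkingdom) & tab$donor_superkingdom == sk
  }
  n_group <- sum(in_group)
  cand <- tab[in_group & tab$is_candidate, , drop = FALSE]
  n_cand <- nrow(cand)
  phylum_dist <- numeric(0)
  if (n_cand) {
    ph <- table(cand$donor_phylum, useNA = "no")
    phylum_dist <- as.numeric(ph) / sum(ph)
    names(phylum_dist) <- names(ph)
  }
  frac_introns <- NA_real_
  if (!is.null(geneModels) && n_cand) {
    mc <- S4Vectors::mcols(geneModels)
    ic <- setNames(mc$intron_count, mc$gene_id)
    joined <- cand$gene_id %in% names(ic)
    if (any(!joined))
      warning(sum(!joined), " candidate(s) missing from gene models, ",
              "excluded from the intron fraction")
    if (any(joined))
      frac_introns <- mean(ic[cand$gene_id[joined]] >= 1)
  }
  n_expr <- NA_integer_
  if (!is.null(detection) && n_cand) {
    mx <- tapply(detection$value, detection$gene_id, max)
    joined <- cand$gene_id %in% names(mx)
    if (any(!joined))
      warning(sum(!joined), " candidate(s) missing from the detection ",
              "table, excluded from the expressed count")
    n_expr <- sum(mx[cand$gene_id[joined]] >= detectionMin)
  }
  list(group = group, n_group_matching = n_group, n_candidates = n_cand,
       fraction = if (n_group > 0) n_cand / n_group else NA_real_,
       donor_phylum_distribution = phylum_dist,
       n_expressed = n_expr, fraction_with_introns = frac_introns)
}
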