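#' Sex/meiosis gene-toolkit inventory
#'
#' Counts, for every toolkit query gene, the distinct genome gene models hit
#' at the stringent homology cutoff (default e-value <= 1e-15), collapsing
#' multiple HSPs to distinct model ids. Reports per-gene copy numbers plus
#' two manifest-level summaries: the fraction of queries found at all, and
#' whether the meiosis-specific class is complete (every meiosis-specific
#' query present).
#'
#' @param queries Query manifest `data.frame` (see [readToolkitQueries()]).
#' @param hits Hit `data.frame` of query proteins vs the genome proteome
#'   (`query_id` = query protein id, `subject_id` = genome gene model id).
#' @param evalueCutoff Inclusive e-value cutoff (default 1e-15).
#' @return A [S4Vectors::DataFrame] with columns `gene_name`, `class`,
#'   `n_copies`, `model_ids` (comma-joined), `present`;
#'   `S4Vectors::metadata()` carries `fraction_found` and
#'   `meiosis_complete`.
#' @export
toolkitInventory <- function(queries, hits, evalueCutoff = 1e-15) {
  if (is.null(queries) || !nrow(queries)) stop("empty toolkit query set")
  q <- if (!is.null(hits) && nrow(hits))
    hits[hits$evalue <= evalueCutoff, , drop = FALSE]
  else hits
  n_copies <- integer(nrow(queries))
  model_ids <- character(nrow(queries))
  for (i in seq_len(nrow(queries))) {
    mids <- if (!is.null(q) && nrow(q))
      sort(unique(q$subject_id[q$query_id == queries$query_id[i]]))
    else character(0)
    n_copies[i] <- length(mids)
    model_ids[i] <- paste(mids, collapse = ",")
  }
  out <- S4Vectors::DataFrame(gene_name = queries$gene_name,
                              class = queries$class,
                              n_copies = n_copies, model_ids = model_ids,
                              present = n_copies >= 1L)
  ms <- out$class == "meiosis_specific"
  S4Vectors::metadata(out) <- list(
    fraction_found = mean(out$present),
    meiosis_complete = all(out$present[ms]) && any(ms),
    evalue_cutoff = evalueCutoff)
  out
}

#' Build a gene-by-sample detection matrix
#'
#' Turns the long-format detection table into the Table-2-shaped matrix of
#' `+`/`-` calls for a chosen set of gene models: a cell is `+` when the
#' detection value is at least `detectionMin`. Columns follow the design
#' order (small, then medium, then large samples; YT42-YT49 in the default
#' design); row order follows `modelIds`. Gene models absent from the
#' detection table yield an all-`-` row with a warning.
#'
#' @param detection Long detection `data.frame` (see
#'   [readDetectionTable()]).
#' @param modelIds Character vector of gene model ids (matrix rows).
#' @param detectionMin Detection threshold on the value (default 1).
#' @return A [DetectionMatrix-class].
#' @export
detectionMatrix <- function(detection, modelIds, detectionMin = 1) {
  stopifnot(length(modelIds) >= 1)
  cond_of <- tapply(detection$condition, detection$sample_id,
                    function(x) x[1])
  samp <- names(cond_of)
  cond <- factor(unname(cond_of), levels = .CONDITIONS)
  o <- order(cond, samp)
  samp <- samp[o]
  cond <- cond[o]
  vals <- matrix(NA_real_, length(modelIds), length(samp),
                 dimnames = list(modelIds, samp))
  det <- detection[detection$gene_id %in% modelIds, , drop = FALSE]
  if (nrow(det))
    vals[cbind(match(det$gene_id, modelIds),
               match(det$sample_id, samp))] <- det$value
  absent <- !modelIds %in% detection$gene_id
  if (any(absent))
    warning(sum(absent), " gene model(s) absent from the detection table; ",
            "reported as all '-': ",
            paste(modelIds[absent], collapse = ", "))
  detected <- !is.na(vals) & vals >= detectionMin
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(value = vals, detected = detected),
    colData = S4Vectors::DataFrame(condition = cond, row.names = samp))
  new("DetectionMatrix", se)
}

#' Per-sample and per-condition detection summaries
#'
#' Counts detected genes per sample and per size-class condition (a gene
#' counts for a condition when detected in at least one of its samples),
#' and reports each gene's set of detecting conditions.
#'
#' @param x A [DetectionMatrix-class].
#' @return A list: `per_sample` (named counts), `per_condition` (named
#'   counts over small/medium/large), `gene_conditions` (named list of
#'   condition character vectors, empty for undetected genes).
#' @export
conditionSummary <- function(x) {
  stopifnot(is(x, "DetectionMatrix"))
  if (!nrow(x) || !ncol(x)) stop("empty detection matrix")
  det <- SummarizedExperiment::assay(x, "detected")
  cond <- sampleConditions(x)
  per_sample <- colSums(det)
  per_condition <- vapply(.CONDITIONS, function(k) {
    cols <- which(cond == k)
    if (!length(cols)) return(0L)
    sum(rowSums(det[, cols, drop = FALSE]) > 0)
  }, 0L)
  gene_conditions <- lapply(seq_len(nrow(det)), function(i)
    .CONDITIONS[.CONDITIONS %in% as.character(cond[det[i, ]])])
  names(gene_conditions) <- rownames(det)
  list(per_sample = per_sample, per_condition = per_condition,
       gene_conditions = gene_conditions)
}
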