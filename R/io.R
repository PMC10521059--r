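#' Read assembly scaffolds from FASTA
#'
#' Reads a scaffold FASTA into a [ScaffoldSet-class], deriving per-scaffold
#' length and GC fraction, and optionally attaching a per-scaffold coverage
#' table. Validation is strict: duplicate ids, empty sequences, and letters
#' outside `{A,C,G,T,N}` (either case) are hard errors naming the offending
#' record. File order is preserved. Scaffold ids are the first whitespace
#' token of each header.
#'
#' @param path Path to a FASTA file.
#' @param coverage Optional: a named numeric vector of per-scaffold coverage,
#'   or a path to a coverage TSV (see [readCoverageTable()]).
#' @return A [ScaffoldSet-class].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGT", ">s2", "GGCC"), fa)
#' ss <- readScaffolds(fa)
#' scaffoldGC(ss)   # 0.5, 1.0
#' @export
readScaffolds <- function(path, coverage = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate scaffold ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  w <- Biostrings::width(raw)
  if (any(w == 0))
    stop("empty sequence for record(s): ", paste(ids[w == 0], collapse = ", "))
  badrow <- grepl("[^ACGTNacgtn]", as.character(raw))
  if (any(badrow))
    stop("sequence letters outside {A,C,G,T,N} in record(s): ",
         paste(ids[badrow], collapse = ", "))
  seqs <- Biostrings::DNAStringSet(toupper(raw))
  names(seqs) <- ids
  if (is.character(coverage) && length(coverage) == 1)
    coverage <- readCoverageTable(coverage)
  ScaffoldSet(seqs, coverage = coverage)
}

#' Write scaffolds to FASTA
#'
#' @param x A [ScaffoldSet-class] or [Biostrings::DNAStringSet].
#' @param path Output FASTA path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
writeScaffolds <- function(x, path, width = 70L) {
  seqs <- if (is(x, "ScaffoldSet")) scaffoldSeqs(x) else x
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

# standard 12 BLAST tabular columns, 13th is the appended lineage
.HIT_COLUMNS <- c("query_id", "subject_id", "percent_identity",
                  "alignment_length", "mismatches", "gap_opens",
                  "q_start", "q_end", "s_start", "s_end",
                  "evalue", "bitscore", "lineage")

#' Read a BLAST tabular hit table with appended lineage
#'
#' Parses a tab-separated homology hit table in the 12-column BLAST tabular
#' dialect with one appended column holding the subject's semicolon-joined
#' taxonomy lineage (superkingdom first). E-value strings whose exponent is
#' below the double-denormal range are clamped to 0 with a warning. The
#' lineage is retained verbatim; derived columns `superkingdom` (first rank)
#' and `phylum` (second rank, `NA` if absent) are appended.
#'
#' @param path Path to the tab-separated file (no header).
#' @return A `data.frame` with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`, `lineage`,
#'   plus derived `superkingdom` and `phylum`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(paste(c("g1", "sbj1", 90, 100, 10, 0, 1, 100, 1, 100,
#'                    "1e-30", 200, "Bacteria;Proteobacteria;x"),
#'                  collapse = "\t"), f)
#' readHitTable(f)$superkingdom
#' @export
readHitTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 13)
    stop("hit table must have >= 13 tab-separated columns, found ", ncol(df))
  df <- df[, seq_len(13)]
  names(df) <- .HIT_COLUMNS
  ev_str <- df$evalue
  ev <- suppressWarnings(as.numeric(ev_str))
  if (anyNA(ev)) stop("unparseable e-value(s): ",
                      paste(unique(ev_str[is.na(ev)]), collapse = ", "))
  underflow <- ev == 0 & grepl("^[0-9.]*[1-9][0-9.]*[eE]-", ev_str)
  if (any(underflow))
    warning(sum(underflow), " e-value(s) below the representable range ",
            "clamped to 0")
  if (any(ev < 0)) stop("negative e-value(s) in hit table")
  for (col in c("percent_identity", "bitscore"))
    df[[col]] <- as.numeric(df[[col]])
  for (col in c("alignment_length", "mismatches", "gap_opens",
                "q_start", "q_end", "s_start", "s_end"))
    df[[col]] <- as.integer(df[[col]])
  df$evalue <- ev
  ranks <- strsplit(df$lineage, ";", fixed = TRUE)
  if (any(lengths(ranks) == 0) || any(!nzchar(vapply(ranks, `[`, "", 1L))))
    stop("empty lineage in hit table")
  sk <- vapply(ranks, `[`, "", 1L)
  bad <- !sk %in% .SUPERKINGDOMS
  if (any(bad))
    stop("unrecognized superkingdom(s): ",
         paste(unique(sk[bad]), collapse = ", "),
         " (expected one of ", paste(.SUPERKINGDOMS, collapse = ", "), ")")
  df$superkingdom <- sk
  df$phylum <- vapply(ranks, function(r) if (length(r) >= 2) r[2] else NA_character_, "")
  df
}

#' Write a hit table in BLAST tabular + lineage format
#'
#' @param hits A hit `data.frame` as returned by [readHitTable()] (derived
#'   columns are dropped on write).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeHitTable <- function(hits, path) {
  miss <- setdiff(.HIT_COLUMNS, names(hits))
  if (length(miss)) stop("hit table missing columns: ", paste(miss, collapse = ", "))
  out <- hits[, .HIT_COLUMNS]
  out$evalue <- sprintf("%.10e", out$evalue)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 annotation (via [rtracklayer::import]) and reduces it to
#' gene-level models: one range per `gene` feature (1-based inclusive
#' coordinates), with the exon count of the gene's primary transcript (the
#' first `mRNA` child in file order; exons attached directly to the gene are
#' also accepted) and the derived intron count (`exon_count - 1`).
#'
#' @param path Path to a GFF3 file.
#' @return A [GenomicRanges::GRanges] named by gene id with metadata columns
#'   `gene_id`, `exon_count`, `intron_count`.
#' @export
readGeneModels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- rtracklayer::import(path, format = "gff3")
  type <- as.character(g$type)
  genes <- g[type == "gene"]
  if (!length(genes)) stop("no gene features in ", path)
  gene_ids <- as.character(genes$ID)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids in ", path)
  mrna <- g[type == "mRNA"]
  exon <- g[type == "exon"]
  parent1 <- function(x) vapply(as.list(x$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, "")
  mrna_parent <- parent1(mrna)
  exon_parent <- parent1(exon)
  exon_count <- integer(length(genes))
  for (i in seq_along(genes)) {
    gid <- gene_ids[i]
    tx <- as.character(mrna$ID)[mrna_parent == gid]
    ex_idx <- if (length(tx)) which(exon_parent == tx[1]) else
      which(exon_parent == gid)
    if (!length(ex_idx))
      stop("gene with zero exons: ", gid)
    ex <- exon[ex_idx]
    if (any(GenomicRanges::start(ex) < GenomicRanges::start(genes[i])) ||
        any(GenomicRanges::end(ex) > GenomicRanges::end(genes[i])))
      stop("exon outside gene bounds for gene: ", gid)
    exon_count[i] <- length(ex_idx)
  }
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(genes),
    ranges = IRanges::IRanges(GenomicRanges::start(genes),
                              GenomicRanges::end(genes)),
    strand = GenomicRanges::strand(genes))
  names(out) <- gene_ids
  S4Vectors::mcols(out)$gene_id <- gene_ids
  S4Vectors::mcols(out)$exon_count <- exon_count
  S4Vectors::mcols(out)$intron_count <- exon_count - 1L
  out
}

#' Write gene models to GFF3
#'
#' Emits a GFF3 file with `gene`, `mRNA` and `exon` features for each gene
#' model. The exon/intron layout inside each gene span is synthesized
#' deterministically (introns of at most 75 bp, exons of equal size plus
#' remainder) since only the exon count is part of the gene-model contract;
#' a span of at least `2 * exon_count - 1` bp is required.
#'
#' @param models A [GenomicRanges::GRanges] as returned by [readGeneModels()]
#'   (metadata columns `gene_id`, `exon_count`).
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(models, path) {
  mc <- S4Vectors::mcols(models)
  if (!all(c("gene_id", "exon_count") %in% names(mc)))
    stop("models must carry gene_id and exon_count metadata columns")
  lines <- character()
  lines <- c(lines, "##gff-version 3")
  scaf <- as.character(GenomicRanges::seqnames(models))
  st <- GenomicRanges::start(models)
  en <- GenomicRanges::end(models)
  strand <- as.character(GenomicRanges::strand(models))
  strand[strand == "*"] <- "+"
  for (i in seq_along(models)) {
    gid <- mc$gene_id[i]
    k <- mc$exon_count[i]
    span <- en[i] - st[i] + 1L
    if (span < 2L * k - 1L)
      stop("gene span too short for ", k, " exons: ", gid)
    intron <- if (k > 1L) max(1L, min(75L, (span - k) %/% (k - 1L))) else 0L
    exon_total <- span - (k - 1L) * intron
    base <- exon_total %/% k
    sizes <- rep(base, k)
    sizes[k] <- sizes[k] + exon_total - base * k
    starts <- st[i] + cumsum(c(0L, sizes[-k] + intron))
    ends <- starts + sizes - 1L
    gff_row <- function(type, s, e, attrs)
      paste(scaf[i], "amoebaLGT", type, s, e, ".", strand[i], ".", attrs,
            sep = "\t")
    lines <- c(lines,
      gff_row("gene", st[i], en[i], paste0("ID=", gid)),
      gff_row("mRNA", st[i], en[i], paste0("ID=", gid, ".t1;Parent=", gid)),
      vapply(seq_len(k), function(j)
        gff_row("exon", starts[j], ends[j],
                paste0("ID=", gid, ".t1.exon", j, ";Parent=", gid, ".t1")), ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a per-scaffold coverage table
#'
#' TSV with header `scaffold_id<TAB>coverage`. Duplicate scaffold ids and
#' negative coverage are hard errors.
#'
#' @param path Path to the TSV.
#' @return `readCoverageTable`: a named numeric vector of coverage values.
#' @export
readCoverageTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("scaffold_id", "coverage") %in% names(df)))
    stop("coverage table needs columns scaffold_id, coverage")
  if (anyDuplicated(df$scaffold_id))
    stop("duplicate scaffold ids in coverage table")
  cov <- as.numeric(df$coverage)
  if (any(is.na(cov))) stop("unparseable coverage values")
  if (any(cov < 0)) stop("negative coverage values")
  setNames(cov, df$scaffold_id)
}

#' @rdname readCoverageTable
#' @param coverage Named numeric vector (names = scaffold ids).
#' @export
writeCoverageTable <- function(coverage, path) {
  df <- data.frame(scaffold_id = names(coverage),
                   coverage = formatC(unname(coverage), format = "g",
                                      digits = 8),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a per-sample transcript detection table
#'
#' Long-format TSV with header columns `gene_id`, `sample_id`, `condition`,
#' `value`: one row per (gene model, sample) pair with a non-negative
#' detection value (count or abundance) and the sample's size-class label
#' (`small`, `medium`, `large`).
#'
#' @param path Path to the TSV.
#' @return `readDetectionTable`: a `data.frame` with those four columns.
#' @export
readDetectionTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "sample_id", "condition", "value")
  if (!all(need %in% names(df)))
    stop("detection table needs columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  if (!all(df$condition %in% .CONDITIONS))
    stop("unknown condition label(s): ",
         paste(setdiff(unique(df$condition), .CONDITIONS), collapse = ", "))
  df$value <- as.numeric(df$value)
  if (any(is.na(df$value)) || any(df$value < 0))
    stop("detection values must be non-negative numbers")
  cond_per_sample <- tapply(df$condition, df$sample_id,
                            function(x) length(unique(x)))
  if (any(cond_per_sample > 1))
    stop("sample(s) with conflicting condition labels")
  if (anyDuplicated(df[, c("gene_id", "sample_id")]))
    stop("duplicate (gene_id, sample_id) rows in detection table")
  df
}

#' @rdname readDetectionTable
#' @param detection Long-format detection `data.frame`.
#' @export
writeDetectionTable <- function(detection, path) {
  need <- c("gene_id", "sample_id", "condition", "value")
  miss <- setdiff(need, names(detection))
  if (length(miss)) stop("detection table missing columns: ",
                         paste(miss, collapse = ", "))
  out <- detection[, need]
  out$value <- formatC(out$value, format = "g", digits = 8)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a toolkit query manifest
#'
#' TSV with header columns `gene_name`, `class`, `query_id` listing the
#' sex/meiosis toolkit query proteins. Classes are `meiosis_specific`,
#' `plasmogamy`, `karyogamy` or `other`.
#'
#' @param path Path to the TSV. Defaults to the manifest shipped with the
#'   package (the size-class study's 37-row table collapsed to gene names,
#'   padded with placeholder queries to the 95-gene set).
#' @return A `data.frame` with columns `gene_name`, `class`, `query_id`.
#' @export
readToolkitQueries <- function(path = system.file("extdata",
                                                  "toolkit_queries.tsv",
                                                  package = "amoebaLGT")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_name", "class", "query_id")
  if (!all(need %in% names(df)))
    stop("query manifest needs columns: ", paste(need, collapse = ", "))
  ok <- c("meiosis_specific", "plasmogamy", "karyogamy", "other")
  if (!all(df$class %in% ok))
    stop("unknown toolkit class(es): ",
         paste(setdiff(unique(df$class), ok), collapse = ", "))
  if (anyDuplicated(df[, c("gene_name", "class")]))
    stop("gene_name must be unique within class")
  df[, need]
}

#' Write a run manifest
#'
#' Records the parameters and seed of an analysis run as `key: value` lines,
#' so that thresholds and policies applied by a run are always recoverable.
#'
#' @param params Named list of parameters (scalars or short vectors).
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(params, path) {
  stopifnot(is.list(params), !is.null(names(params)))
  fmt <- vapply(params, function(v)
    paste(format(v, trim = TRUE, digits = 10), collapse = ","), "")
  writeLines(paste0(names(params), ": ", fmt), path)
  invisible(path)
}
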