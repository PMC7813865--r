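#' @title Readers and writers for methylome analysis tables
#' @name io
#' @description Delimited-text readers for beta matrices, sample sheets,
#'   probe annotation, RRBS count tables and probe blacklists, plus writers
#'   for result tables and BED exports. Delimiters are auto-detected between
#'   tab and comma on the header line and can be forced with `sep`.
NULL

#' CpG-island relation vocabulary
#'
#' The six Illumina manifest categories describing a probe's position
#' relative to the nearest CpG island (island, north/south shore within
#' 2 kb, north/south shelf 2-4 kb, open sea).
#' @export
CGI_LEVELS <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")

#' 15-state chromHMM vocabulary
#'
#' The core 15-state Roadmap chromHMM model labels (active/flanking/bivalent
#' promoters, transcription, enhancers, ZNF/repeats, heterochromatin,
#' Polycomb repression, quiescent).
#' @export
CHROMHMM_STATES <- c("TssA", "TssAFlnk", "TxFlnk", "Tx", "TxWk", "EnhG",
                     "Enh", "ZNF_Rpts", "Het", "TssBiv", "BivFlnk", "EnhBiv",
                     "ReprPC", "ReprPCWk", "Quies")

#' Disease-stage and culture-condition vocabularies
#' @export
STAGE_GROUPS <- c("HD", "MGUS", "SMM", "MM")

#' @rdname STAGE_GROUPS
#' @export
CULTURE_GROUPS <- c("mono", "cocult")

# Sniff the delimiter on the header line: tab wins over comma.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a probe-by-sample beta-value matrix
#'
#' Reads a delimited text file whose header row holds sample identifiers and
#' whose first column holds probe identifiers. Every value must be a
#' methylation fraction in \[0, 1\] or `NA`.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma.
#' @return Numeric matrix (probes x samples) with probe ids as rownames and
#'   sample ids as colnames.
#' @export
read_beta_matrix <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("malformed header: need a probe-id column plus at least one sample", call. = FALSE)
  probe_ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- probe_ids
  validate_beta_matrix(mat)
  mat
}

#' Validate beta-matrix invariants
#'
#' Checks axis uniqueness and the \[0, 1\] value range; errors name the first
#' offending probe/sample cell.
#' @param mat Numeric matrix with dimnames.
#' @return `mat`, invisibly.
#' @export
validate_beta_matrix <- function(mat) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("beta matrix must carry probe rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(mat)))
    stop("duplicate probe ids: ", rownames(mat)[duplicated(rownames(mat))][1L], call. = FALSE)
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample ids: ", colnames(mat)[duplicated(colnames(mat))][1L], call. = FALSE)
  bad <- which(!is.na(mat) & (mat < 0 | mat > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("beta value %.4g out of [0,1] at probe '%s', sample '%s'",
                 mat[bad[1L, 1L], bad[1L, 2L]],
                 rownames(mat)[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]]),
         call. = FALSE)
  }
  invisible(mat)
}

#' Read a sample sheet
#'
#' Expected columns: `sample_id`, `group`, and optionally `age`, `sex`,
#' `pair_id`. `group` must come from the stage vocabulary (HD/MGUS/SMM/MM)
#' or the culture vocabulary (mono/cocult); `sex` from \{F, M\}.
#'
#' @inheritParams read_beta_matrix
#' @param paired If `TRUE`, additionally require every `pair_id` to occur
#'   exactly twice, once per condition.
#' @return data.frame with one row per sample.
#' @export
read_sample_sheet <- function(path, sep = NULL, paired = FALSE) {
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_sample_sheet(df, paired = paired)
}

#' @rdname read_sample_sheet
#' @param sheet A sample-sheet data.frame to validate in place.
#' @export
validate_sample_sheet <- function(sheet, paired = FALSE) {
  required <- c("sample_id", "group")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols) > 0L)
    stop("sample sheet missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  known <- c(STAGE_GROUPS, CULTURE_GROUPS)
  bad <- setdiff(unique(sheet$group), known)
  if (length(bad) > 0L)
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(known, collapse = ", "), ")", call. = FALSE)
  if ("sex" %in% names(sheet)) {
    bad_sex <- setdiff(stats::na.omit(unique(sheet$sex)), c("F", "M"))
    if (length(bad_sex) > 0L)
      stop("unknown sex label(s): ", paste(bad_sex, collapse = ", "), call. = FALSE)
  }
  if (paired) {
    if (!"pair_id" %in% names(sheet))
      stop("paired design requires a pair_id column", call. = FALSE)
    tab <- table(sheet$pair_id)
    bad_pairs <- names(tab)[tab != 2L]
    if (length(bad_pairs) > 0L)
      stop("pair_id not occurring exactly twice: ", paste(bad_pairs, collapse = ", "), call. = FALSE)
    cond <- table(sheet$pair_id, sheet$group)
    if (any(cond > 1L))
      stop("a pair_id occurs twice within the same condition", call. = FALSE)
  }
  sheet
}

#' Read a probe annotation table
#'
#' Expected columns: `probe_id`, `chrom`, `pos` (1-based), `cgi_relation`,
#' `chromhmm_state`, `nearest_gene`, `tss_distance`, `blacklisted`.
#' Vocabulary columns are validated against [CGI_LEVELS] and
#' [CHROMHMM_STATES].
#'
#' @inheritParams read_beta_matrix
#' @return data.frame with one row per probe.
#' @export
read_probe_annotation <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_probe_annotation(df)
}

#' @rdname read_probe_annotation
#' @param annotation An annotation data.frame to validate in place.
#' @export
validate_probe_annotation <- function(annotation) {
  if (!all(c("probe_id", "chrom", "pos") %in% names(annotation)))
    stop("annotation requires probe_id, chrom, pos columns", call. = FALSE)
  if (anyDuplicated(annotation$probe_id))
    stop("duplicate probe_id in annotation", call. = FALSE)
  if ("cgi_relation" %in% names(annotation)) {
    bad <- setdiff(stats::na.omit(unique(annotation$cgi_relation)), CGI_LEVELS)
    if (length(bad) > 0L)
      stop("unknown cgi_relation label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if ("chromhmm_state" %in% names(annotation)) {
    bad <- setdiff(stats::na.omit(unique(annotation$chromhmm_state)), CHROMHMM_STATES)
    if (length(bad) > 0L)
      stop("unknown chromhmm_state label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if ("blacklisted" %in% names(annotation))
    annotation$blacklisted <- as.logical(annotation$blacklisted)
  annotation
}

#' Read an RRBS per-CpG count table
#'
#' Expected columns: `chrom`, `pos` (1-based), `meth_reads`, `total_reads`,
#' `group`. Counts must satisfy 0 <= meth_reads <= total_reads.
#'
#' @inheritParams read_beta_matrix
#' @return data.frame of per-site counts.
#' @export
read_rrbs_table <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "meth_reads", "total_reads", "group")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("RRBS table missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  if (any(df$meth_reads < 0 | df$total_reads < 0))
    stop("negative read counts in RRBS table", call. = FALSE)
  if (any(df$meth_reads > df$total_reads))
    stop("meth_reads exceeds total_reads at row ",
         which(df$meth_reads > df$total_reads)[1L], call. = FALSE)
  df
}

#' Read a probe blacklist
#'
#' One probe id per line; lines starting with `#` are comments.
#' @param path Path to the blacklist file.
#' @return Character vector of probe ids.
#' @export
read_blacklist <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Read an expression matrix, averaging duplicate gene rows
#'
#' Reads a gene-by-sample matrix of normalized log-scale expression. Rows
#' sharing a gene id are collapsed by their mean, mirroring probe-to-gene
#' averaging on array platforms.
#'
#' @inheritParams read_beta_matrix
#' @return Numeric matrix (genes x samples), gene ids unique.
#' @export
read_expression_matrix <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  collapse_gene_rows(mat, genes)
}

#' Collapse duplicate gene rows by averaging
#'
#' @param mat Numeric matrix whose rows may repeat gene ids.
#' @param genes Character vector of gene ids, one per row.
#' @return Matrix with one row per unique gene (first-appearance order).
#' @export
collapse_gene_rows <- function(mat, genes) {
  if (!anyDuplicated(genes)) {
    rownames(mat) <- genes
    return(mat)
  }
  idx <- split(seq_along(genes), factor(genes, levels = unique(genes)))
  out <- t(vapply(idx, function(i) colMeans(mat[i, , drop = FALSE]),
                  numeric(ncol(mat))))
  colnames(out) <- colnames(mat)
  out
}

#' Write result tables to a directory
#'
#' Each element of `tables` is written as `<name>.tsv` with a fixed column
#' order (as supplied), tab-separated, `NA` for missing, no quoting.
#'
#' @param tables Named list of data.frames.
#' @param out_dir Output directory, created if needed.
#' @return Character vector of file paths, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    path
  }, character(1L))
  invisible(paths)
}

#' Export a probe set as BED
#'
#' Writes 0-based half-open intervals `(pos - 1, pos)` for each probe found
#' in the annotation. Probes absent from the annotation are skipped and
#' reported, never silently dropped.
#'
#' @param probe_set Character vector of probe ids.
#' @param annotation Probe annotation data.frame (probe_id, chrom, pos).
#' @param path Output BED path.
#' @return Invisibly, a list with `n_written` and `skipped` (probe ids).
#' @export
export_bed <- function(probe_set, annotation, path) {
  hit <- match(probe_set, annotation$probe_id)
  skipped <- probe_set[is.na(hit)]
  if (length(skipped) > 0L)
    message("export_bed: skipped ", length(skipped),
            " probe(s) absent from annotation")
  keep <- probe_set[!is.na(hit)]
  idx <- hit[!is.na(hit)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED export: chrom start(0-based) end probe_id", con)
  if (length(keep) > 0L) {
    writeLines(sprintf("%s\t%d\t%d\t%s", annotation$chrom[idx],
                       as.integer(annotation$pos[idx]) - 1L,
                       as.integer(annotation$pos[idx]), keep), con)
  }
  invisible(list(n_written = length(keep), skipped = skipped))
}

#' Write a beta (or M, or expression) matrix as TSV
#'
#' First column `probe_id`, then one column per sample; inverse of
#' [read_beta_matrix()].
#' @param mat Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Name for the identifier column.
#' @export
write_matrix <- function(mat, path, id_col = "probe_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
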