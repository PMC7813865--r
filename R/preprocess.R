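#' Convert beta-values to M-values
#'
#' M = log2(beta / (1 - beta)) after clipping beta into
#' \[eps, 1 - eps\], so M is finite for every non-missing entry. The clip
#' bounds |M| at about 19.93 for the default eps and preserves ordering.
#'
#' @param beta Numeric vector or matrix of methylation fractions in \[0, 1\].
#' @param eps Clipping margin in (0, 0.5); default `1e-6`.
#' @return Object of the same shape on the M scale; `NA` propagates.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  stopifnot(eps > 0, eps < 0.5)
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Convert M-values back to beta-values
#'
#' beta = 2^M / (1 + 2^M); exact inverse of [beta_to_m()] away from the
#' clipping margin.
#'
#' @param m Numeric vector or matrix of M-values.
#' @return Methylation fractions in (0, 1).
#' @export
m_to_beta <- function(m) {
  x <- 2^m
  x / (1 + x)
}

#' Quantile-normalize a probe-by-sample matrix
#'
#' Forces every sample's empirical distribution onto the across-sample mean
#' quantile vector while preserving within-sample ranks; ties receive the
#' mean of the target quantiles spanned by their rank range. Delegates to
#' the standard array normalization routine.
#'
#' @param mat Numeric matrix, probes x samples, at least 2 samples.
#' @return Normalized matrix with the same dimnames.
#' @export
quantile_normalize <- function(mat) {
  if (ncol(mat) < 2L) {
    warning("quantile_normalize: single sample, returning input unchanged")
    return(mat)
  }
  if (any(colSums(!is.na(mat)) == 0L))
    stop("quantile_normalize: a sample column is entirely missing", call. = FALSE)
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Filter probes by chromosome and blacklist
#'
#' Removes sex-chromosome probes and/or culture-associated blacklisted
#' probes, preserving the order of retained probes. Probes absent from the
#' annotation are dropped with a logged count.
#'
#' @param mat Probe-by-sample matrix with probe rownames.
#' @param annotation Probe annotation with `probe_id`, `chrom` and
#'   optionally `blacklisted`.
#' @param drop_sex_chroms Remove probes on chrX/chrY (default `TRUE`).
#' @param drop_blacklist Remove probes flagged `blacklisted` (default `TRUE`).
#' @return Filtered matrix.
#' @export
filter_probes <- function(mat, annotation, drop_sex_chroms = TRUE,
                          drop_blacklist = TRUE) {
  hit <- match(rownames(mat), annotation$probe_id)
  if (anyNA(hit)) {
    message("filter_probes: dropping ", sum(is.na(hit)),
            " probe(s) absent from annotation")
    mat <- mat[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
  }
  keep <- rep(TRUE, nrow(mat))
  if (drop_sex_chroms) {
    sex <- annotation$chrom[hit] %in% c("chrX", "chrY", "X", "Y")
    keep <- keep & !sex
  }
  if (drop_blacklist && "blacklisted" %in% names(annotation)) {
    bl <- annotation$blacklisted[hit]
    bl[is.na(bl)] <- FALSE
    keep <- keep & !bl
  }
  mat[keep, , drop = FALSE]
}

#' Drop probes with excessive per-group missingness
#'
#' Removes probes whose beta is missing in more than `max_missing` of the
#' samples of any group, with a logged count.
#'
#' @param mat Probe-by-sample matrix.
#' @param sheet Sample sheet with `sample_id`, `group`.
#' @param max_missing Maximum tolerated missing fraction per group
#'   (default 0.2).
#' @return Filtered matrix.
#' @export
drop_high_missing <- function(mat, sheet, max_missing = 0.2) {
  groups <- split(sheet$sample_id, sheet$group)
  bad <- rep(FALSE, nrow(mat))
  for (ids in groups) {
    ids <- intersect(ids, colnames(mat))
    if (length(ids) == 0L) next
    frac <- rowMeans(is.na(mat[, ids, drop = FALSE]))
    bad <- bad | frac > max_missing
  }
  if (any(bad))
    message("drop_high_missing: removed ", sum(bad),
            " probe(s) missing in >", max_missing * 100, "% of a group")
  mat[!bad, , drop = FALSE]
}

#' Filter RRBS sites by coverage and compute methylation fractions
#'
#' Retains sites with at least `min_reads` total reads and annotates the
#' methylation fraction meth_reads / total_reads. With `per_group = TRUE`
#' (default) a site must pass the threshold in every group present, so that
#' group-wise comparisons use a common site set.
#'
#' @param table RRBS count table (chrom, pos, meth_reads, total_reads, group).
#' @param min_reads Minimum valid reads per CpG (default 5).
#' @param per_group Require the threshold in every group (default `TRUE`).
#' @return Filtered table with an added `fraction` column.
#' @export
rrbs_site_filter <- function(table, min_reads = 5, per_group = TRUE) {
  stopifnot(min_reads >= 1)
  keep <- table$total_reads >= min_reads
  out <- table[keep, , drop = FALSE]
  if (per_group && length(unique(table$group)) > 1L) {
    site <- paste(out$chrom, out$pos, sep = ":")
    n_groups <- length(unique(table$group))
    passing <- tapply(out$group, site, function(g) length(unique(g)))
    ok_sites <- names(passing)[passing == n_groups]
    out <- out[site %in% ok_sites, , drop = FALSE]
  }
  out$fraction <- ifelse(out$total_reads > 0,
                         out$meth_reads / out$total_reads, NA_real_)
  rownames(out) <- NULL
  out
}
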