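#' @title Stage set algebra, integration and enrichment
#' @name progression_integration
#' @description Combines per-stage DMP/DVP calls into progression-associated
#'   sets (MM-only, SMM-and-MM, all three stages), overlaps call sets,
#'   maps probes to nearest genes, tests differential expression, crosses
#'   methylation with expression direction, and computes genomic-context
#'   enrichment against a probe background.
NULL

#' Progression-associated probe sets
#'
#' From per-stage called sets (hyper and hypo separately for MGUS, SMM,
#' MM), selects the accumulative-change components: probes called only in
#' MM, shared by SMM and MM but not MGUS, and present in all three stages;
#' their union is the progression-associated set. A probe called with
#' conflicting directions across stages is excluded and logged.
#'
#' @param calls Named list with elements `MGUS`, `SMM`, `MM`, each a list
#'   with character vectors `hyper` and `hypo` (as from [called_sets()]).
#' @return Object of class `"progression_sets"`: per direction, the
#'   `mm_only`, `smm_and_mm`, `all_three` components and their `union`;
#'   plus `conflicted`, the excluded probe ids.
#' @export
progression_sets <- function(calls) {
  stopifnot(all(c("MGUS", "SMM", "MM") %in% names(calls)))
  dirs <- c("hyper", "hypo")
  # a probe hyper in one stage and hypo in another is direction-conflicted
  all_hyper <- unique(unlist(lapply(calls, `[[`, "hyper")))
  all_hypo <- unique(unlist(lapply(calls, `[[`, "hypo")))
  conflicted <- intersect(all_hyper, all_hypo)
  if (length(conflicted) > 0L)
    message("progression_sets: excluded ", length(conflicted),
            " probe(s) with conflicting directions across stages")
  out <- list(conflicted = conflicted)
  for (dr in dirs) {
    mgus <- setdiff(calls$MGUS[[dr]], conflicted)
    smm <- setdiff(calls$SMM[[dr]], conflicted)
    mm <- setdiff(calls$MM[[dr]], conflicted)
    comp <- list(
      mm_only = setdiff(mm, union(mgus, smm)),
      smm_and_mm = setdiff(intersect(smm, mm), mgus),
      all_three = intersect(intersect(mgus, smm), mm)
    )
    comp$union <- unique(c(comp$mm_only, comp$smm_and_mm, comp$all_three))
    # partition invariants, asserted on every run
    stopifnot(length(intersect(comp$mm_only, comp$smm_and_mm)) == 0L,
              length(intersect(comp$mm_only, comp$all_three)) == 0L,
              length(intersect(comp$smm_and_mm, comp$all_three)) == 0L,
              all(comp$union %in% mm))
    out[[dr]] <- comp
  }
  class(out) <- "progression_sets"
  out
}

#' @export
print.progression_sets <- function(x, ...) {
  for (dr in c("hyper", "hypo")) {
    cat(dr, ": MM-only ", length(x[[dr]]$mm_only),
        ", SMM&MM ", length(x[[dr]]$smm_and_mm),
        ", all three ", length(x[[dr]]$all_three),
        ", union ", length(x[[dr]]$union), "\n", sep = "")
  }
  invisible(x)
}

#' Overlap two call sets with direction concordance
#'
#' @param set_a,set_b Either character vectors of probe ids, or data.frames
#'   with `probe_id` and `direction` columns (called rows of a
#'   `dmp_result`/`dvp_result`).
#' @return List with `intersection` (probe ids), and, when both inputs
#'   carry directions, `concordant` and `discordant` subsets.
#' @export
overlap_sets <- function(set_a, set_b) {
  ids_a <- if (is.data.frame(set_a)) set_a$probe_id else set_a
  ids_b <- if (is.data.frame(set_b)) set_b$probe_id else set_b
  inter <- intersect(ids_a, ids_b)
  out <- list(intersection = inter, n = length(inter))
  if (is.data.frame(set_a) && is.data.frame(set_b) &&
      "direction" %in% names(set_a) && "direction" %in% names(set_b)) {
    dir_a <- set_a$direction[match(inter, set_a$probe_id)]
    dir_b <- set_b$direction[match(inter, set_b$probe_id)]
    out$concordant <- inter[dir_a == dir_b]
    out$discordant <- inter[dir_a != dir_b]
  }
  out
}

#' Map probes to the single nearest gene TSS
#'
#' Assigns each probe the gene whose transcription start site minimizes
#' |pos - tss_pos| on the same chromosome; equidistant ties go to the
#' lexicographically first gene symbol. The signed distance is negative
#' upstream of the TSS relative to the gene's strand.
#'
#' @param probes Character vector of probe ids.
#' @param annotation Probe annotation (probe_id, chrom, pos).
#' @param tss TSS table data.frame (gene, chrom, tss_pos, strand).
#' @return data.frame with `probe_id`, `gene`, `distance` (signed bp);
#'   probes on chromosomes with no TSS are unassigned (`NA`) and logged.
#' @export
nearest_gene_map <- function(probes, annotation, tss) {
  hit <- match(probes, annotation$probe_id)
  if (anyNA(hit))
    stop("probe(s) absent from annotation: ",
         paste(utils::head(probes[is.na(hit)], 3L), collapse = ", "),
         call. = FALSE)
  chrom <- annotation$chrom[hit]
  pos <- annotation$pos[hit]
  gene <- rep(NA_character_, length(probes))
  dist <- rep(NA_real_, length(probes))
  for (ch in unique(chrom)) {
    t_ch <- tss[tss$chrom == ch, , drop = FALSE]
    p_idx <- which(chrom == ch)
    if (nrow(t_ch) == 0L) next
    # sort TSSs; ties at the same position resolved to the first symbol
    t_ch <- t_ch[order(t_ch$tss_pos, t_ch$gene), , drop = FALSE]
    for (i in p_idx) {
      dd <- abs(pos[i] - t_ch$tss_pos)
      best <- which(dd == min(dd))
      if (length(best) > 1L) best <- best[order(t_ch$gene[best])][1L]
      gene[i] <- t_ch$gene[best]
      raw <- pos[i] - t_ch$tss_pos[best]
      dist[i] <- if (identical(t_ch$strand[best], "-")) -raw else raw
    }
  }
  n_un <- sum(is.na(gene))
  if (n_un > 0L)
    message("nearest_gene_map: ", n_un,
            " probe(s) on chromosomes with no TSS left unassigned")
  data.frame(probe_id = probes, gene = gene, distance = dist,
             stringsAsFactors = FALSE)
}

#' Differential expression by moderated t
#'
#' Per-gene empirical-Bayes moderated t between two groups on a normalized
#' log-scale expression matrix; a gene is called at p < `p_threshold`
#' (default 0.05) with direction given by the coefficient sign. Genes
#' constant across all samples are excluded with a logged count.
#'
#' @param expr Gene-by-sample expression matrix (log scale, duplicate gene
#'   rows already averaged).
#' @param sheet Sample sheet.
#' @param disease_group,control_group Group labels to compare.
#' @param p_threshold Significance threshold (default 0.05).
#' @param covariates Optional additive covariates (default none).
#' @return data.frame with `gene`, `log_fc`, `t`, `p`, `direction`
#'   (up/down in disease), `called`.
#' @export
differential_expression <- function(expr, sheet, disease_group,
                                    control_group, p_threshold = 0.05,
                                    covariates = character(0)) {
  dg <- build_two_group_design(sheet, disease_group, control_group,
                               covariates)
  ids <- intersect(dg$samples$sample_id, colnames(expr))
  design <- dg$design[ids, , drop = FALSE]
  sub <- expr[, ids, drop = FALSE]
  const <- row_vars(sub) == 0 | is.na(row_vars(sub))
  if (any(const))
    message("differential_expression: excluded ", sum(const),
            " constant gene(s)")
  sub <- sub[!const, , drop = FALSE]
  fit <- moderated_t_fit(sub, design, coef = "group")
  data.frame(gene = rownames(sub), log_fc = fit$coefficients, t = fit$t,
             p = fit$p.value,
             direction = ifelse(fit$coefficients >= 0, "up", "down"),
             called = !is.na(fit$p.value) & fit$p.value < p_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Integrate methylation and expression directions
#'
#' Crosses the methylation direction of DMP-associated genes with the
#' expression direction of differentially expressed genes. Each gene
#' appears once per (methylation direction, expression direction) pair in
#' one of the four categories hyper-down, hyper-up, hypo-down, hypo-up;
#' genes carrying DMPs in both directions are flagged ambiguous.
#'
#' @param dmp_genes data.frame with `gene` and `meth_direction`
#'   (hyper/hypo), e.g. called DMPs passed through [nearest_gene_map()].
#' @param de_calls data.frame from [differential_expression()]; only rows
#'   with `called == TRUE` are used.
#' @return List with `table` (gene, meth_direction, expr_direction,
#'   category, ambiguous) and `counts` (named category counts).
#' @export
integrate_meth_expr <- function(dmp_genes, de_calls) {
  de <- de_calls[de_calls$called, , drop = FALSE]
  mg <- unique(dmp_genes[!is.na(dmp_genes$gene),
                         c("gene", "meth_direction"), drop = FALSE])
  merged <- merge(mg, de[, c("gene", "direction")], by = "gene")
  if (nrow(merged) == 0L) {
    tab <- data.frame(gene = character(0), meth_direction = character(0),
                      expr_direction = character(0), category = character(0),
                      ambiguous = logical(0))
    counts <- stats::setNames(rep(0L, 4L), c("hyper-down", "hyper-up",
                                             "hypo-down", "hypo-up"))
    return(list(table = tab, counts = counts))
  }
  names(merged)[names(merged) == "direction"] <- "expr_direction"
  merged$category <- paste(merged$meth_direction, merged$expr_direction,
                           sep = "-")
  multi <- tapply(merged$meth_direction, merged$gene,
                  function(d) length(unique(d)) > 1L)
  merged$ambiguous <- unname(multi[merged$gene])
  merged <- merged[order(merged$gene, merged$category), , drop = FALSE]
  rownames(merged) <- NULL
  counts <- table(factor(merged$category,
                         levels = c("hyper-down", "hyper-up",
                                    "hypo-down", "hypo-up")))
  list(table = merged, counts = c(counts))
}

#' Genomic-context enrichment of a probe set
#'
#' For each level of a categorical annotation field (CpG-island relation or
#' chromHMM state), builds the disjoint 2x2 table of query vs
#' background-minus-query membership and applies [enrichment_2x2()]; also
#' reports the raw level fractions for distribution-style summaries.
#'
#' @param query_probes Character vector, a proper subset of
#'   `background_probes`.
#' @param annotation Probe annotation carrying `category_field`.
#' @param category_field `"cgi_relation"` or `"chromhmm_state"`.
#' @param background_probes Character vector of background probe ids
#'   (typically all probes surviving [filter_probes()]).
#' @return data.frame with one row per level: counts `a`,`b`,`c`,`d`,
#'   `odds_ratio`, `log_odds_ratio`, `p`, `query_frac`, `background_frac`.
#' @export
category_enrichment <- function(query_probes, annotation,
                                category_field = c("cgi_relation",
                                                   "chromhmm_state"),
                                background_probes) {
  category_field <- match.arg(category_field)
  if (length(query_probes) == 0L) {
    warning("category_enrichment: empty query")
    return(data.frame(level = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0),
                      odds_ratio = numeric(0), log_odds_ratio = numeric(0),
                      p = numeric(0), query_frac = numeric(0),
                      background_frac = numeric(0)))
  }
  if (!all(query_probes %in% background_probes))
    stop("query probes must be a subset of the background", call. = FALSE)
  rest <- setdiff(background_probes, query_probes)
  if (length(rest) == 0L)
    stop("query must be a proper subset of the background", call. = FALSE)
  levels_all <- if (category_field == "cgi_relation") CGI_LEVELS else
    CHROMHMM_STATES
  cat_q <- annotation[[category_field]][match(query_probes,
                                              annotation$probe_id)]
  cat_r <- annotation[[category_field]][match(rest, annotation$probe_id)]
  cat_b <- annotation[[category_field]][match(background_probes,
                                              annotation$probe_id)]
  present <- intersect(levels_all, unique(cat_b))
  rows <- lapply(present, function(lv) {
    a <- sum(cat_q == lv, na.rm = TRUE)
    b <- sum(cat_q != lv, na.rm = TRUE)
    cc <- sum(cat_r == lv, na.rm = TRUE)
    d <- sum(cat_r != lv, na.rm = TRUE)
    enr <- enrichment_2x2(a, b, cc, d)
    data.frame(level = lv, a = a, b = b, c = cc, d = d,
               odds_ratio = enr$odds_ratio,
               log_odds_ratio = enr$log_odds_ratio, p = enr$p.value,
               query_frac = a / length(cat_q),
               background_frac = sum(cat_b == lv, na.rm = TRUE) /
                 length(cat_b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
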