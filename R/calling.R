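#' @title DMP and DVP calling
#' @name dmp_dvp
#' @description Differentially methylated positions (DMPs) are called by a
#'   mean shift: empirical-Bayes moderated t on M-values adjusted for age
#'   and sex, combined with an absolute beta difference threshold.
#'   Differentially variable positions (DVPs) are called by a variance
#'   shift: Bartlett's test on beta-values at FDR < 0.05, regularized by a
#'   t-test (p < 0.05) to guard against single-outlier artifacts (the
#'   iEVORA scheme). A paired variant supports mono/co-culture designs.
NULL

# Build intercept + group + covariate design for a two-group comparison.
# Returns list(design, samples) after excluding samples with missing
# covariate values (logged).
build_two_group_design <- function(sheet, disease_group, control_group,
                                   covariates = character(0)) {
  sub <- sheet[sheet$group %in% c(disease_group, control_group), , drop = FALSE]
  if (length(covariates) > 0L) {
    have <- intersect(covariates, names(sub))
    if (length(have) < length(covariates))
      stop("covariate(s) absent from sample sheet: ",
           paste(setdiff(covariates, have), collapse = ", "), call. = FALSE)
    complete <- stats::complete.cases(sub[, covariates, drop = FALSE])
    if (any(!complete))
      message("excluding ", sum(!complete),
              " sample(s) with missing covariate values")
    sub <- sub[complete, , drop = FALSE]
  }
  for (grp in c(disease_group, control_group)) {
    if (sum(sub$group == grp) < 2L)
      stop("group '", grp, "' has fewer than 2 usable samples", call. = FALSE)
  }
  design <- cbind(intercept = 1, group = as.numeric(sub$group == disease_group))
  for (cv in covariates) {
    v <- sub[[cv]]
    if (is.numeric(v)) {
      design <- cbind(design, v)
      colnames(design)[ncol(design)] <- cv
    } else {
      f <- factor(v)
      mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(cv, levels(f)[-1L])
      design <- cbind(design, mm)
    }
  }
  rownames(design) <- sub$sample_id
  list(design = design, samples = sub)
}

#' Call differentially methylated positions (DMPs)
#'
#' A probe is called when the difference of group mean beta-values exceeds
#' `delta_threshold` (default 0.1, i.e. 10 percentage points) and the
#' moderated t-test on M-values is significant at `p_threshold` (default
#' raw p < 0.01; set `adjust = TRUE` to apply BH instead). Age and sex
#' enter the design as additive covariates; samples with missing covariate
#' values are excluded with a logged count.
#'
#' @param beta Probe-by-sample beta matrix (effect sizes are computed here).
#' @param M Matching M-value matrix (tests run here); if `NULL`, derived
#'   from `beta` via [beta_to_m()].
#' @param sheet Sample sheet with `sample_id`, `group` and the covariates.
#' @param disease_group,control_group Group labels to compare.
#' @param delta_threshold Minimum |delta beta| (default 0.1).
#' @param p_threshold Significance threshold (default 0.01).
#' @param covariates Additive covariate columns (default `c("age", "sex")`;
#'   use `character(0)` for none).
#' @param adjust Apply BH FDR and threshold q instead of raw p.
#' @return data.frame of class `"dmp_result"` with columns `probe_id`,
#'   `delta_beta`, `t`, `p`, (`q`), `direction` (hyper/hypo), `called`.
#' @export
call_dmps <- function(beta, M = NULL, sheet, disease_group, control_group,
                      delta_threshold = 0.1, p_threshold = 0.01,
                      covariates = c("age", "sex"), adjust = FALSE) {
  if (is.null(M)) M <- beta_to_m(beta)
  stopifnot(identical(dim(beta), dim(M)),
            identical(rownames(beta), rownames(M)))
  dg <- build_two_group_design(sheet, disease_group, control_group, covariates)
  ids <- intersect(dg$samples$sample_id, colnames(beta))
  if (length(ids) < nrow(dg$samples))
    stop("sample sheet entries missing from the beta matrix", call. = FALSE)
  design <- dg$design[ids, , drop = FALSE]
  fit <- moderated_t_fit(M[, ids, drop = FALSE], design, coef = "group")
  grp <- dg$samples$group[match(ids, dg$samples$sample_id)]
  delta <- rowMeans(beta[, ids[grp == disease_group], drop = FALSE],
                    na.rm = TRUE) -
           rowMeans(beta[, ids[grp == control_group], drop = FALSE],
                    na.rm = TRUE)
  res <- data.frame(probe_id = rownames(beta), delta_beta = delta,
                    t = fit$t, p = fit$p.value,
                    stringsAsFactors = FALSE, row.names = NULL)
  crit_p <- res$p
  if (adjust) {
    res$q <- bh_fdr(res$p)
    crit_p <- res$q
  }
  res$direction <- ifelse(delta >= 0, "hyper", "hypo")
  res$called <- !is.na(crit_p) & crit_p < p_threshold &
    abs(res$delta_beta) >= delta_threshold
  attr(res, "fit") <- fit
  class(res) <- c("dmp_result", "data.frame")
  res
}

#' Call differentially variable positions (DVPs)
#'
#' iEVORA-style calling on beta-values: Bartlett's test per probe with BH
#' FDR across probes (q < `fdr_threshold`), then a regularizing t-test
#' (p < `t_p_threshold`) to discard hits driven by a single outlier. Called
#' probes are ranked by t p-value ascending (ties by Bartlett q, then
#' probe id); direction is the sign of the group mean beta difference.
#'
#' @param beta Probe-by-sample beta matrix.
#' @param sheet Sample sheet.
#' @param disease_group,control_group Group labels to compare (>= 3 samples
#'   each).
#' @param fdr_threshold Bartlett FDR threshold (default 0.05).
#' @param t_p_threshold Regularizing t-test threshold (default 0.05); set
#'   to 1 to disable the regularization.
#' @param t_variant t-test flavour, `"welch"` (default) or `"student"`.
#' @return data.frame of class `"dvp_result"` with columns `probe_id`,
#'   `bartlett_stat`, `bartlett_p`, `bartlett_q`, `t_p`, `direction`,
#'   `called`, `rank` (NA for uncalled probes).
#' @export
call_dvps <- function(beta, sheet, disease_group, control_group,
                      fdr_threshold = 0.05, t_p_threshold = 0.05,
                      t_variant = "welch") {
  idx1 <- intersect(sheet$sample_id[sheet$group == disease_group],
                    colnames(beta))
  idx2 <- intersect(sheet$sample_id[sheet$group == control_group],
                    colnames(beta))
  if (length(idx1) < 3L || length(idx2) < 3L)
    stop("variance testing needs >= 3 samples per group", call. = FALSE)
  bt <- suppressMessages(row_bartlett(beta, idx1, idx2))
  n_excluded <- sum(is.na(bt$p.value))
  if (n_excluded > 0L)
    message("call_dvps: ", n_excluded,
            " zero-variance probe(s) excluded from FDR")
  q <- bh_fdr(bt$p.value)
  tt <- row_t(beta, idx1, idx2, variant = t_variant)
  res <- data.frame(probe_id = rownames(beta),
                    bartlett_stat = bt$statistic,
                    bartlett_p = bt$p.value,
                    bartlett_q = q,
                    t_p = tt$p.value,
                    stringsAsFactors = FALSE, row.names = NULL)
  res$direction <- ifelse(tt$mean_diff >= 0, "hyper", "hypo")
  res$called <- !is.na(q) & q < fdr_threshold &
    !is.na(res$t_p) & res$t_p < t_p_threshold
  res$rank <- NA_integer_
  if (any(res$called)) {
    called_idx <- which(res$called)
    ord <- order(res$t_p[called_idx], res$bartlett_q[called_idx],
                 res$probe_id[called_idx])
    res$rank[called_idx[ord]] <- seq_along(called_idx)
  }
  class(res) <- c("dvp_result", "data.frame")
  res
}

#' Call DMPs in a paired (mono vs co-culture) design
#'
#' Moderated t with fixed-effect pair blocking; the effect size is the mean
#' of within-pair beta differences (condition minus reference). Calling
#' uses the same joint criterion as [call_dmps()].
#'
#' @param beta,M Probe-by-sample matrices as in [call_dmps()].
#' @param sheet Sample sheet with `pair_id` and a two-level `group`.
#' @param condition_group,reference_group Condition labels (defaults
#'   `"cocult"` vs `"mono"`).
#' @inheritParams call_dmps
#' @return data.frame of class `"dmp_result"`.
#' @export
call_dmps_paired <- function(beta, M = NULL, sheet,
                             condition_group = "cocult",
                             reference_group = "mono",
                             delta_threshold = 0.1, p_threshold = 0.01) {
  if (is.null(M)) M <- beta_to_m(beta)
  sub <- sheet[sheet$group %in% c(condition_group, reference_group), ,
               drop = FALSE]
  tab <- table(sub$pair_id)
  bad <- names(tab)[tab != 2L]
  if (length(bad) > 0L)
    stop("incomplete pair(s): ", paste(bad, collapse = ", "), call. = FALSE)
  validate_sample_sheet(sub, paired = TRUE)
  ids <- sub$sample_id
  if (!all(ids %in% colnames(beta)))
    stop("sample sheet entries missing from the beta matrix", call. = FALSE)
  design <- cbind(intercept = 1,
                  group = as.numeric(sub$group == condition_group))
  rownames(design) <- ids
  fit <- moderated_t_fit(M[, ids, drop = FALSE], design, coef = "group",
                         block = sub$pair_id)
  cond_ids <- sub$sample_id[sub$group == condition_group]
  ref_ids <- sub$sample_id[sub$group == reference_group][
    match(sub$pair_id[sub$group == condition_group],
          sub$pair_id[sub$group == reference_group])]
  delta <- rowMeans(beta[, cond_ids, drop = FALSE] -
                    beta[, ref_ids, drop = FALSE], na.rm = TRUE)
  res <- data.frame(probe_id = rownames(beta), delta_beta = delta,
                    t = fit$t, p = fit$p.value,
                    stringsAsFactors = FALSE, row.names = NULL)
  res$direction <- ifelse(delta >= 0, "hyper", "hypo")
  res$called <- !is.na(res$p) & res$p < p_threshold &
    abs(res$delta_beta) >= delta_threshold
  attr(res, "fit") <- fit
  class(res) <- c("dmp_result", "data.frame")
  res
}

#' Split a call table into hyper/hypo probe id sets
#'
#' @param result A `dmp_result` or `dvp_result` data.frame.
#' @return List with `hyper` and `hypo` character vectors of called probes.
#' @export
called_sets <- function(result) {
  called <- result[result$called, , drop = FALSE]
  list(hyper = called$probe_id[called$direction == "hyper"],
       hypo = called$probe_id[called$direction == "hypo"])
}
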