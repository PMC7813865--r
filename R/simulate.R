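#' @title Synthetic methylome generator with planted effects
#' @name synthetic_data
#' @description Generates EPIC-like beta matrices (bimodal background,
#'   logit-normal noise, additive age/sex effects), planted mean-shift DMPs
#'   and outlier-driven variance DVPs across disease stages, probe
#'   annotation with CpG-island and chromHMM labels, expression matrices
#'   negatively coupled to promoter methylation, and RRBS count tables.
#'   Every generator is a pure function of its parameters and seed, and
#'   returns a truth table against which callers can be scored.
NULL

clip01 <- function(x, margin = 1e-4) pmin(pmax(x, margin), 1 - margin)

# Stage-pattern vocabulary for planted effects: which disease groups carry
# the effect. Mirrors the progression components plus stage-specific cases.
STAGE_PATTERNS <- list(
  mm_only = "MM",
  smm_mm = c("SMM", "MM"),
  all_three = c("MGUS", "SMM", "MM"),
  mgus_only = "MGUS",
  smm_only = "SMM"
)

#' Simulate an EPIC-like methylome with planted DMPs and DVPs
#'
#' Background beta-values per probe are drawn from a bimodal logit-scale
#' mixture (low-methylation mode near 0.1, high near 0.85) with per-sample
#' logit-normal noise and small additive age/sex effects. Planted DMPs
#' shift the affected disease groups' mean on the logit scale to hit the
#' target delta beta; planted DVPs convert a fraction of affected-group
#' samples into outliers shifted by a fixed beta amount, leaving the rest
#' untouched. Each planted probe carries a stage pattern (MM-only, SMM+MM,
#' all three, MGUS-only or SMM-only) recorded in the truth table.
#'
#' @param n_probes Number of probes (default 10000).
#' @param samples_per_group Named integer vector of samples per group;
#'   default `c(HD = 8, MGUS = 10, SMM = 8, MM = 9)`, the cohort sizes of a
#'   typical myeloma MSC study.
#' @param n_dmp,n_dvp Numbers of planted DMPs / DVPs (default 200 each).
#' @param effect_params List with `delta_beta` (target mean shift, default
#'   0.25), `outlier_frac` (fraction of affected samples shifted, default
#'   0.3), `outlier_shift` (beta shift of outliers, default 0.4) and
#'   `noise_sd` (logit-scale noise sd, default 0.05).
#' @param covariate_params List with `age_sd` and `sex_sd`, the sds of the
#'   per-probe logit-scale covariate coefficients (defaults 0.003, 0.05).
#' @param pattern_probs Probabilities over the five stage patterns
#'   (mm_only, smm_mm, all_three, mgus_only, smm_only).
#' @param seed Integer seed (mandatory).
#' @return List with `beta` (matrix), `sheet` (sample sheet) and `truth`
#'   (data.frame: probe_id, kind, stages, direction, delta_beta,
#'   outlier_frac, outlier_shift).
#' @export
simulate_methylome <- function(n_probes = 10000,
                               samples_per_group = c(HD = 8, MGUS = 10,
                                                     SMM = 8, MM = 9),
                               n_dmp = 200, n_dvp = 200,
                               effect_params = list(),
                               covariate_params = list(),
                               pattern_probs = c(mm_only = 0.3,
                                                 smm_mm = 0.25,
                                                 all_three = 0.25,
                                                 mgus_only = 0.1,
                                                 smm_only = 0.1),
                               seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  ep <- utils::modifyList(list(delta_beta = 0.25, outlier_frac = 0.3,
                               outlier_shift = 0.4, noise_sd = 0.05),
                          effect_params)
  cp <- utils::modifyList(list(age_sd = 0.003, sex_sd = 0.05),
                          covariate_params)
  if (ep$delta_beta <= 0 || ep$delta_beta >= 0.85)
    stop("infeasible delta_beta: no [0,1] headroom", call. = FALSE)
  if (ep$outlier_shift <= 0 || ep$outlier_shift >= 0.85)
    stop("infeasible outlier_shift", call. = FALSE)
  stopifnot(n_dmp + n_dvp <= n_probes, all(samples_per_group > 0))
  pattern_probs <- pattern_probs[names(STAGE_PATTERNS)]
  stopifnot(!anyNA(pattern_probs))
  set.seed(seed)

  groups <- rep(names(samples_per_group), samples_per_group)
  n_samples <- length(groups)
  sample_ids <- paste0(groups, "_",
                       unlist(lapply(samples_per_group, seq_len)))
  sheet <- data.frame(sample_id = sample_ids, group = groups,
                      age = sample(50:75, n_samples, replace = TRUE),
                      sex = sample(c("F", "M"), n_samples, replace = TRUE),
                      pair_id = NA_character_, stringsAsFactors = FALSE)

  probe_ids <- sprintf("cg%08d", seq_len(n_probes))
  planted_dmp <- if (n_dmp > 0) seq_len(n_dmp) else integer(0)
  planted_dvp <- if (n_dvp > 0) n_dmp + seq_len(n_dvp) else integer(0)
  # planted probes are listed first, then shuffled into the universe
  shuffle <- sample.int(n_probes)
  inv <- order(shuffle)
  planted_dmp <- inv[planted_dmp]
  planted_dvp <- inv[planted_dvp]

  # bimodal baseline on the logit scale
  high <- stats::runif(n_probes) < 0.5
  mu <- stats::rnorm(n_probes, mean = ifelse(high, stats::qlogis(0.85),
                                             stats::qlogis(0.10)), sd = 0.5)
  # planted probes get baselines with headroom for their effect
  dirs_dmp <- sample(c(1, -1), length(planted_dmp), replace = TRUE)
  base_dmp <- ifelse(dirs_dmp > 0,
                     stats::runif(length(planted_dmp), 0.20,
                                  0.95 - ep$delta_beta),
                     stats::runif(length(planted_dmp),
                                  0.05 + ep$delta_beta, 0.80))
  mu[planted_dmp] <- stats::qlogis(base_dmp)
  dirs_dvp <- sample(c(1, -1), length(planted_dvp), replace = TRUE)
  base_dvp <- ifelse(dirs_dvp > 0,
                     stats::runif(length(planted_dvp), 0.10,
                                  0.95 - ep$outlier_shift),
                     stats::runif(length(planted_dvp),
                                  0.05 + ep$outlier_shift, 0.90))
  mu[planted_dvp] <- stats::qlogis(base_dvp)

  age_coef <- stats::rnorm(n_probes, 0, cp$age_sd)
  sex_coef <- stats::rnorm(n_probes, 0, cp$sex_sd)
  age_c <- sheet$age - mean(sheet$age)
  is_m <- as.numeric(sheet$sex == "M")

  logit_vals <- matrix(mu, n_probes, n_samples) +
    outer(age_coef, age_c) + outer(sex_coef, is_m) +
    matrix(stats::rnorm(n_probes * n_samples, 0, ep$noise_sd),
           n_probes, n_samples)

  patterns <- sample(names(STAGE_PATTERNS), length(planted_dmp),
                     replace = TRUE, prob = pattern_probs)
  for (j in seq_along(planted_dmp)) {
    i <- planted_dmp[j]
    b0 <- stats::plogis(mu[i])
    b1 <- clip01(b0 + dirs_dmp[j] * ep$delta_beta, 0.02)
    shift <- stats::qlogis(b1) - stats::qlogis(b0)
    affected <- groups %in% STAGE_PATTERNS[[patterns[j]]]
    logit_vals[i, affected] <- logit_vals[i, affected] + shift
  }
  beta <- clip01(stats::plogis(logit_vals))

  patterns_dvp <- sample(names(STAGE_PATTERNS), length(planted_dvp),
                         replace = TRUE, prob = pattern_probs)
  for (j in seq_along(planted_dvp)) {
    i <- planted_dvp[j]
    for (grp in STAGE_PATTERNS[[patterns_dvp[j]]]) {
      cols <- which(groups == grp)
      n_out <- ceiling(ep$outlier_frac * length(cols))
      out_cols <- sample(cols, n_out)
      beta[i, out_cols] <- clip01(beta[i, out_cols] +
                                    dirs_dvp[j] * ep$outlier_shift)
    }
  }

  dimnames(beta) <- list(probe_ids, sample_ids)
  truth <- data.frame(
    probe_id = c(probe_ids[planted_dmp], probe_ids[planted_dvp]),
    kind = c(rep("DMP", length(planted_dmp)),
             rep("DVP", length(planted_dvp))),
    stages = c(vapply(patterns, function(p)
                 paste(STAGE_PATTERNS[[p]], collapse = ";"), character(1)),
               vapply(patterns_dvp, function(p)
                 paste(STAGE_PATTERNS[[p]], collapse = ";"), character(1))),
    direction = ifelse(c(dirs_dmp, dirs_dvp) > 0, "hyper", "hypo"),
    delta_beta = c(rep(ep$delta_beta, length(planted_dmp)),
                   rep(NA_real_, length(planted_dvp))),
    outlier_frac = c(rep(NA_real_, length(planted_dmp)),
                     rep(ep$outlier_frac, length(planted_dvp))),
    outlier_shift = c(rep(NA_real_, length(planted_dmp)),
                      rep(ep$outlier_shift, length(planted_dvp))),
    stringsAsFactors = FALSE
  )
  list(beta = beta, sheet = sheet, truth = truth)
}

#' Simulate a paired mono/co-culture methylome
#'
#' Paired donors measured in monoculture and after co-culture; a subset of
#' probes receives a constant within-pair beta shift.
#'
#' @param n_probes Number of probes.
#' @param n_pairs Number of donor pairs (default 3).
#' @param n_dmp Number of planted shifted probes.
#' @param delta_beta Within-pair beta shift (default 0.2).
#' @param noise_sd Logit noise sd (default 0.05).
#' @param seed Integer seed.
#' @return List with `beta`, `sheet` (mono/cocult with pair ids), `truth`.
#' @export
simulate_coculture <- function(n_probes = 2000, n_pairs = 3, n_dmp = 100,
                               delta_beta = 0.2, noise_sd = 0.05, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  probe_ids <- sprintf("cg%08d", seq_len(n_probes))
  pair_id <- rep(paste0("HD", seq_len(n_pairs)), each = 2L)
  group <- rep(c("mono", "cocult"), n_pairs)
  sample_ids <- paste0(pair_id, "_", group)
  planted <- sample.int(n_probes, n_dmp)
  dirs <- sample(c(1, -1), n_dmp, replace = TRUE)
  high <- stats::runif(n_probes) < 0.5
  mu <- stats::rnorm(n_probes, ifelse(high, stats::qlogis(0.85),
                                      stats::qlogis(0.10)), 0.5)
  mu[planted] <- stats::qlogis(ifelse(dirs > 0,
                                      stats::runif(n_dmp, 0.15,
                                                   0.90 - delta_beta),
                                      stats::runif(n_dmp,
                                                   0.10 + delta_beta, 0.85)))
  # per-pair baseline wobble plus sample noise
  pair_eff <- matrix(stats::rnorm(n_probes * n_pairs, 0, noise_sd),
                     n_probes, n_pairs)
  logit_vals <- matrix(mu, n_probes, 2 * n_pairs) +
    pair_eff[, rep(seq_len(n_pairs), each = 2L)] +
    matrix(stats::rnorm(n_probes * 2 * n_pairs, 0, noise_sd),
           n_probes, 2 * n_pairs)
  beta <- clip01(stats::plogis(logit_vals))
  cocult <- group == "cocult"
  for (j in seq_along(planted)) {
    i <- planted[j]
    beta[i, cocult] <- clip01(beta[i, cocult] + dirs[j] * delta_beta)
  }
  dimnames(beta) <- list(probe_ids, sample_ids)
  sheet <- data.frame(sample_id = sample_ids, group = group,
                      age = NA_integer_, sex = NA_character_,
                      pair_id = pair_id, stringsAsFactors = FALSE)
  truth <- data.frame(probe_id = probe_ids[planted], kind = "DMP",
                      stages = "cocult",
                      direction = ifelse(dirs > 0, "hyper", "hypo"),
                      delta_beta = delta_beta, outlier_frac = NA_real_,
                      outlier_shift = NA_real_, stringsAsFactors = FALSE)
  list(beta = beta, sheet = sheet, truth = truth)
}

# Fixed, roughly genome-like chromHMM state weights for sampling.
CHROMHMM_WEIGHTS <- c(TssA = 0.04, TssAFlnk = 0.03, TxFlnk = 0.01,
                      Tx = 0.08, TxWk = 0.14, EnhG = 0.02, Enh = 0.06,
                      ZNF_Rpts = 0.01, Het = 0.05, TssBiv = 0.02,
                      BivFlnk = 0.01, EnhBiv = 0.02, ReprPC = 0.04,
                      ReprPCWk = 0.07, Quies = 0.40)

#' Simulate probe annotation and a TSS table
#'
#' Places probes on synthetic chromosomes with strictly increasing
#' positions, draws CpG-island relations and chromHMM states from stated
#' fractions (optionally enriching Island membership among planted probes
#' to create a testable signal), flags a small blacklist, and lays out a
#' gene TSS table from which nearest-gene assignments are computed.
#'
#' @param probe_ids Character vector of probe ids to annotate.
#' @param cgi_fractions Named fractions over [CGI_LEVELS] (EPIC-like
#'   default); must sum to 1.
#' @param planted_probes Probe ids whose Island probability is multiplied
#'   by `island_enrichment` (renormalized).
#' @param island_enrichment Island over-representation factor among planted
#'   probes (default 1 = none).
#' @param n_chrom Number of autosomes (default 5).
#' @param sex_chrom_frac Fraction of (non-planted) probes on chrX/chrY
#'   (default 0.02).
#' @param blacklist_frac Fraction of non-planted probes flagged as
#'   culture-associated (default 0.01).
#' @param genes_per_chrom Genes per autosome in the TSS table (default 200,
#'   keeping probe-to-gene multiplicity modest at the simulated scale).
#' @param seed Integer seed.
#' @return List with `annotation` (probe_id, chrom, pos, cgi_relation,
#'   chromhmm_state, nearest_gene, tss_distance, blacklisted) and `tss`
#'   (gene, chrom, tss_pos, strand).
#' @export
simulate_annotation <- function(probe_ids,
                                cgi_fractions = c(Island = 0.31,
                                                  N_Shore = 0.12,
                                                  S_Shore = 0.10,
                                                  N_Shelf = 0.05,
                                                  S_Shelf = 0.05,
                                                  OpenSea = 0.37),
                                planted_probes = character(0),
                                island_enrichment = 1,
                                n_chrom = 5, sex_chrom_frac = 0.02,
                                blacklist_frac = 0.01,
                                genes_per_chrom = 200, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(abs(sum(cgi_fractions) - 1) < 1e-8,
            all(names(cgi_fractions) %in% CGI_LEVELS))
  set.seed(seed)
  n <- length(probe_ids)
  planted <- probe_ids %in% planted_probes
  autosomes <- paste0("chr", seq_len(n_chrom))
  chrom <- sample(autosomes, n, replace = TRUE)
  sex <- !planted & stats::runif(n) < sex_chrom_frac
  chrom[sex] <- sample(c("chrX", "chrY"), sum(sex), replace = TRUE)
  pos <- integer(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- cumsum(sample(500:5000, length(idx), replace = TRUE))
  }
  cgi <- character(n)
  cgi[!planted] <- sample(names(cgi_fractions), sum(!planted),
                          replace = TRUE, prob = cgi_fractions)
  if (any(planted)) {
    pf <- cgi_fractions
    pf["Island"] <- pf["Island"] * island_enrichment
    pf <- pf / sum(pf)
    cgi[planted] <- sample(names(pf), sum(planted), replace = TRUE,
                           prob = pf)
  }
  state <- sample(names(CHROMHMM_WEIGHTS), n, replace = TRUE,
                  prob = CHROMHMM_WEIGHTS)
  blacklisted <- !planted & stats::runif(n) < blacklist_frac

  tss_rows <- lapply(autosomes, function(ch) {
    span <- max(pos[chrom == ch], 1e6)
    data.frame(gene = sprintf("G%s_%02d", sub("chr", "", ch),
                              seq_len(genes_per_chrom)),
               chrom = ch,
               tss_pos = sort(sample.int(span, genes_per_chrom)),
               strand = sample(c("+", "-"), genes_per_chrom,
                               replace = TRUE),
               stringsAsFactors = FALSE)
  })
  tss <- do.call(rbind, tss_rows)
  annotation <- data.frame(probe_id = probe_ids, chrom = chrom, pos = pos,
                           cgi_relation = cgi, chromhmm_state = state,
                           stringsAsFactors = FALSE)
  ngm <- suppressMessages(nearest_gene_map(probe_ids, annotation, tss))
  annotation$nearest_gene <- ngm$gene
  annotation$tss_distance <- ngm$distance
  annotation$blacklisted <- blacklisted
  list(annotation = annotation, tss = tss)
}

#' Simulate expression coupled to planted promoter methylation
#'
#' Genes linked to planted DMPs (via the annotation's nearest-gene
#' assignment) receive, in the affected disease groups, an expression shift
#' whose sign opposes the methylation direction with probability
#' `coupling_prob` (and matches it otherwise); Gaussian noise is added on
#' the log scale.
#'
#' @param truth Truth table from [simulate_methylome()] with a `gene`
#'   column attached (see [link_truth_genes()]).
#' @param sheet Sample sheet from [simulate_methylome()].
#' @param genes Gene universe (character); linked genes must be included.
#' @param effect_size Log-scale shift magnitude (default 1, i.e. 2-fold).
#' @param noise_sd Log-scale noise sd (default 0.3).
#' @param coupling_prob Probability that a linked gene's shift opposes its
#'   methylation direction (default 0.9).
#' @param seed Integer seed.
#' @return List with `expr` (gene x sample matrix) and `truth` extended by
#'   `expr_sign` and `expr_magnitude`.
#' @export
simulate_expression <- function(truth, sheet, genes, effect_size = 1,
                                noise_sd = 0.3, coupling_prob = 0.9, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(coupling_prob >= 0, coupling_prob <= 1,
            "gene" %in% names(truth))
  set.seed(seed)
  linked <- which(truth$kind == "DMP" & !is.na(truth$gene))
  stopifnot(all(truth$gene[linked] %in% genes))
  n_g <- length(genes)
  n_s <- nrow(sheet)
  baseline <- stats::rnorm(n_g, 7, 1)
  expr <- matrix(baseline, n_g, n_s) +
    matrix(stats::rnorm(n_g * n_s, 0, noise_sd), n_g, n_s)
  dimnames(expr) <- list(genes, sheet$sample_id)
  truth$expr_sign <- NA_real_
  truth$expr_magnitude <- NA_real_
  # one expression effect per gene; genes whose linked probes disagree in
  # direction are left uncoupled (no programmed shift)
  gene_dirs <- tapply(truth$direction[linked], truth$gene[linked],
                      function(d) unique(d))
  conflicted <- names(gene_dirs)[lengths(gene_dirs) > 1L]
  seen <- character(0)
  for (j in linked) {
    g <- truth$gene[j]
    if (g %in% conflicted) next
    meth_dir <- if (truth$direction[j] == "hyper") 1 else -1
    if (g %in% seen) {
      # same-direction sibling probe: inherit the gene-level effect
      k <- which(truth$gene == g & !is.na(truth$expr_sign))[1L]
      truth$expr_sign[j] <- truth$expr_sign[k]
      truth$expr_magnitude[j] <- truth$expr_magnitude[k]
      next
    }
    oppose <- stats::runif(1) < coupling_prob
    sgn <- if (oppose) -meth_dir else meth_dir
    truth$expr_sign[j] <- sgn
    truth$expr_magnitude[j] <- effect_size
    seen <- c(seen, g)
    affected <- sheet$group %in% strsplit(truth$stages[j], ";")[[1L]]
    expr[g, affected] <- expr[g, affected] + sgn * effect_size
  }
  list(expr = expr, truth = truth)
}

#' Which planted probes affect a given group?
#'
#' @param truth Truth table from [simulate_methylome()].
#' @param group Group label (e.g. `"MM"`).
#' @return Logical vector over truth rows: the planted effect is present in
#'   `group`.
#' @export
truth_affects <- function(truth, group) {
  vapply(strsplit(truth$stages, ";", fixed = TRUE),
         function(s) group %in% s, logical(1))
}

#' Attach nearest-gene links to a truth table
#'
#' @param truth Truth table from [simulate_methylome()].
#' @param annotation Annotation from [simulate_annotation()].
#' @return `truth` with a `gene` column (the planted probe's nearest gene).
#' @export
link_truth_genes <- function(truth, annotation) {
  truth$gene <- annotation$nearest_gene[match(truth$probe_id,
                                              annotation$probe_id)]
  truth
}

#' Simulate an RRBS count table
#'
#' Per-site sequencing depth is Poisson; methylated read counts are
#' binomial with a site baseline fraction shifted on the logit scale per
#' group (emulating, for example, healthy / tumor-bearing / treated
#' animals).
#'
#' @param n_sites Number of CpG sites (default 500).
#' @param mean_depth Poisson mean depth (default 10), or the exact per-site
#'   depth when `fixed_depth = TRUE`.
#' @param group_effects Named logit-scale shifts per group (default
#'   `c(healthy = 0, vehicle = 1, treated = 0.2)`).
#' @param fixed_depth Use `mean_depth` as a constant depth instead of a
#'   Poisson draw (default `FALSE`).
#' @param seed Integer seed.
#' @return data.frame with chrom, pos, group, meth_reads, total_reads.
#' @export
simulate_rrbs <- function(n_sites = 500, mean_depth = 10,
                          group_effects = c(healthy = 0, vehicle = 1,
                                            treated = 0.2),
                          fixed_depth = FALSE,
                          seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(mean_depth >= 0)
  set.seed(seed)
  pos <- sort(sample.int(5e6, n_sites))
  base <- stats::runif(n_sites, 0.05, 0.95)
  rows <- lapply(names(group_effects), function(grp) {
    depth <- if (fixed_depth) rep(as.integer(mean_depth), n_sites) else
      stats::rpois(n_sites, mean_depth)
    frac <- stats::plogis(stats::qlogis(base) + group_effects[[grp]])
    data.frame(chrom = "chr1", pos = pos, group = grp,
               meth_reads = stats::rbinom(n_sites, depth, frac),
               total_reads = depth, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
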