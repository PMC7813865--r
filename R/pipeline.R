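#' @title End-to-end pipeline
#' @name pipeline
#' @description Orchestrates filter -> normalize -> per-stage DMP/DVP
#'   calling -> progression set algebra -> genomic-context enrichment ->
#'   optional expression integration from a single YAML (or list) config,
#'   writing result TSVs, BED exports, a plain-text summary of counts and a
#'   run manifest with md5 checksums for reproducibility.
NULL

default_thresholds <- function() {
  list(delta_beta = 0.1, dmp_p = 0.01, dvp_fdr = 0.05, dvp_t_p = 0.05,
       de_p = 0.05, rrbs_min_reads = 5)
}

# Load or simulate the pipeline inputs described by the config.
acquire_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sp <- config$simulate
    seed <- config$seed
    if (is.null(seed)) stop("config error: simulate mode requires a seed",
                            call. = FALSE)
    sim <- simulate_methylome(
      n_probes = sp$n_probes %||% 10000,
      n_dmp = sp$n_dmp %||% 200, n_dvp = sp$n_dvp %||% 200,
      effect_params = sp$effect_params %||% list(),
      seed = seed)
    ann <- simulate_annotation(
      rownames(sim$beta),
      planted_probes = sim$truth$probe_id,
      island_enrichment = sp$island_enrichment %||% 1,
      seed = seed + 1L)
    truth <- link_truth_genes(sim$truth, ann$annotation)
    expr <- NULL
    if (isTRUE(sp$expression %||% TRUE)) {
      ex <- simulate_expression(truth, sim$sheet, unique(ann$tss$gene),
                                coupling_prob = sp$coupling_prob %||% 0.9,
                                seed = seed + 2L)
      expr <- ex$expr
      truth <- ex$truth
    }
    return(list(beta = sim$beta, sheet = sim$sheet,
                annotation = ann$annotation, tss = ann$tss, expr = expr,
                truth = truth))
  }
  inp <- config$inputs
  if (is.null(inp) || is.null(inp$beta) || is.null(inp$sample_sheet) ||
      is.null(inp$annotation))
    stop("config error: need inputs (beta, sample_sheet, annotation) or a simulate block",
         call. = FALSE)
  beta <- read_beta_matrix(inp$beta)
  sheet <- read_sample_sheet(inp$sample_sheet)
  annotation <- read_probe_annotation(inp$annotation)
  if (!is.null(inp$blacklist)) {
    bl <- read_blacklist(inp$blacklist)
    annotation$blacklisted <- annotation$probe_id %in% bl
  }
  tss <- if (!is.null(inp$tss))
    utils::read.table(inp$tss, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  expr <- if (!is.null(inp$expression))
    read_expression_matrix(inp$expression) else NULL
  list(beta = beta, sheet = sheet, annotation = annotation, tss = tss,
       expr = expr, truth = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full stage-resolved methylome pipeline
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#'   Recognized fields: `seed`; `out_dir`; `inputs` (paths `beta`,
#'   `sample_sheet`, `annotation`, optional `tss`, `blacklist`,
#'   `expression`) or `simulate` (generator parameters); `thresholds`
#'   overriding the defaults (delta_beta 0.1, dmp_p 0.01, dvp_fdr 0.05,
#'   dvp_t_p 0.05, de_p 0.05).
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, a list with the per-stage calls, progression sets,
#'   enrichment and integration tables, the written file paths and the
#'   manifest path.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- out_dir %||% config$out_dir
  # the manifest records the scientific parameters, not the output location
  config_text <- yaml::as.yaml(config[setdiff(names(config), "out_dir")])
  if (is.null(out_dir)) stop("config error: out_dir required", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  thr <- utils::modifyList(default_thresholds(), config$thresholds %||% list())

  dat <- acquire_inputs(config)
  beta <- drop_high_missing(dat$beta, dat$sheet)
  beta <- filter_probes(beta, dat$annotation,
                        drop_sex_chroms = config$drop_sex_chroms %||% TRUE,
                        drop_blacklist = config$drop_blacklist %||% TRUE)
  beta <- quantile_normalize(beta)
  M <- beta_to_m(beta)

  stages <- intersect(c("MGUS", "SMM", "MM"), unique(dat$sheet$group))
  if (!"HD" %in% dat$sheet$group)
    stop("pipeline error at stage calling: no HD control samples",
         call. = FALSE)
  covars <- intersect(c("age", "sex"), names(dat$sheet))
  covars <- covars[vapply(covars, function(cv)
    !all(is.na(dat$sheet[[cv]])), logical(1))]

  dmps <- dvps <- list()
  for (st in stages) {
    dmps[[st]] <- call_dmps(beta, M, dat$sheet, st, "HD",
                            delta_threshold = thr$delta_beta,
                            p_threshold = thr$dmp_p, covariates = covars)
    dvps[[st]] <- suppressMessages(
      call_dvps(beta, dat$sheet, st, "HD", fdr_threshold = thr$dvp_fdr,
                t_p_threshold = thr$dvp_t_p))
  }

  prog_dmp <- prog_dvp <- NULL
  if (all(c("MGUS", "SMM", "MM") %in% stages)) {
    prog_dmp <- suppressMessages(progression_sets(lapply(dmps, called_sets)))
    prog_dvp <- suppressMessages(progression_sets(lapply(dvps, called_sets)))
  }

  tables <- list()
  for (st in stages) {
    tables[[paste0("dmp_", st)]] <- as.data.frame(dmps[[st]])
    tables[[paste0("dvp_", st)]] <- as.data.frame(dvps[[st]])
  }
  prog_table <- function(ps) {
    do.call(rbind, lapply(c("hyper", "hypo"), function(dr) {
      comp <- ps[[dr]]
      do.call(rbind, lapply(c("mm_only", "smm_and_mm", "all_three"),
                            function(cm) {
        if (length(comp[[cm]]) == 0L) return(NULL)
        data.frame(probe_id = sort(comp[[cm]]), direction = dr,
                   component = cm, stringsAsFactors = FALSE)
      }))
    }))
  }
  enrich <- list()
  if (!is.null(prog_dmp)) {
    tables$progression_dmp <- prog_table(prog_dmp)
    tables$progression_dvp <- prog_table(prog_dvp)
    background <- rownames(beta)
    for (dr in c("hyper", "hypo")) {
      q <- prog_dmp[[dr]]$union
      if (length(q) == 0L || length(q) >= length(background)) next
      for (fld in c("cgi_relation", "chromhmm_state")) {
        nm <- paste0("enrichment_", fld, "_", dr)
        enrich[[nm]] <- category_enrichment(q, dat$annotation, fld,
                                            background)
        tables[[nm]] <- enrich[[nm]]
      }
    }
  }

  integration <- NULL
  if (!is.null(dat$expr) && !is.null(dat$tss) && length(stages) > 0L) {
    st <- stages[length(stages)]
    de <- suppressMessages(
      differential_expression(dat$expr, dat$sheet, st, "HD",
                              p_threshold = thr$de_p))
    dmp_called <- dmps[[st]][dmps[[st]]$called, , drop = FALSE]
    if (nrow(dmp_called) > 0L) {
      gm <- suppressMessages(nearest_gene_map(dmp_called$probe_id,
                                              dat$annotation, dat$tss))
      dmp_genes <- data.frame(gene = gm$gene,
                              meth_direction = dmp_called$direction,
                              stringsAsFactors = FALSE)
      integration <- integrate_meth_expr(dmp_genes, de)
      tables[[paste0("integration_", st)]] <- integration$table
    }
    tables[[paste0("expression_", st)]] <- de
  }

  files <- write_results(tables, out_dir)
  if (!is.null(prog_dmp)) {
    bed_path <- file.path(out_dir, "progression_dmp.bed")
    suppressMessages(export_bed(
      sort(unique(c(prog_dmp$hyper$union, prog_dmp$hypo$union))),
      dat$annotation, bed_path))
    files <- c(files, bed_path)
  }

  # plain-text summary of counts per stage and direction
  summary_lines <- c("stage\tkind\thyper\thypo")
  for (st in stages) {
    cs_m <- called_sets(dmps[[st]])
    cs_v <- called_sets(dvps[[st]])
    summary_lines <- c(summary_lines,
      sprintf("%s\tDMP\t%d\t%d", st, length(cs_m$hyper), length(cs_m$hypo)),
      sprintf("%s\tDVP\t%d\t%d", st, length(cs_v$hyper), length(cs_v$hypo)))
  }
  if (!is.null(prog_dmp)) {
    summary_lines <- c(summary_lines,
      sprintf("progression\tDMP\t%d\t%d", length(prog_dmp$hyper$union),
              length(prog_dmp$hypo$union)),
      sprintf("progression\tDVP\t%d\t%d", length(prog_dvp$hyper$union),
              length(prog_dvp$hypo$union)))
  }
  summary_path <- file.path(out_dir, "summary.txt")
  writeLines(summary_lines, summary_path)
  files <- c(files, summary_path)

  # manifest: config, seed, package version, checksums of every output
  files <- sort(unname(files))
  sums <- tools::md5sum(files)
  manifest_path <- file.path(out_dir, "manifest.txt")
  writeLines(c(
    paste0("package_version: ",
           as.character(utils::packageVersion("methStages"))),
    paste0("seed: ", config$seed %||% "NA"),
    "config:",
    paste0("  ", strsplit(config_text, "\n")[[1L]]),
    "checksums:",
    sprintf("  %s  %s", unname(sums), basename(files))
  ), manifest_path)

  invisible(list(dmps = dmps, dvps = dvps, progression_dmp = prog_dmp,
                 progression_dvp = prog_dvp, enrichment = enrich,
                 integration = integration, truth = dat$truth,
                 files = files, manifest = manifest_path))
}
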