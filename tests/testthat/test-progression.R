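test_that("progression set algebra matches the worked example", {
  calls <- list(
    MGUS = list(hyper = "b", hypo = character(0)),
    SMM = list(hyper = c("b", "c"), hypo = character(0)),
    MM = list(hyper = c("b", "c", "d"), hypo = character(0))
  )
  ps <- progression_sets(calls)
  expect_identical(ps$hyper$mm_only, "d")
  expect_identical(ps$hyper$smm_and_mm, "c")
  expect_identical(ps$hyper$all_three, "b")
  expect_setequal(ps$hyper$union, c("b", "c", "d"))
  expect_length(ps$hypo$union, 0)

  # empty MM empties every component
  calls$MM <- list(hyper = character(0), hypo = character(0))
  ps2 <- progression_sets(calls)
  expect_length(ps2$hyper$union, 0)
})

test_that("direction conflicts are excluded with a log", {
  calls <- list(
    MGUS = list(hyper = "x", hypo = character(0)),
    SMM = list(hyper = character(0), hypo = "x"),
    MM = list(hyper = c("x", "y"), hypo = character(0))
  )
  expect_message(ps <- progression_sets(calls), "conflicting directions")
  expect_identical(ps$conflicted, "x")
  expect_identical(ps$hyper$mm_only, "y")
})

test_that("progression components equal per-probe brute-force membership", {
  set.seed(31)
  universe <- sprintf("cg%04d", 1:500)
  calls <- lapply(c(MGUS = 1, SMM = 2, MM = 3), function(i) {
    hyper <- sample(universe, 150)
    list(hyper = hyper, hypo = sample(setdiff(universe, hyper), 120))
  })
  ps <- suppressMessages(progression_sets(calls))
  conflicted <- ps$conflicted
  for (dr in c("hyper", "hypo")) {
    for (probe in setdiff(universe, conflicted)) {
      in_mgus <- probe %in% calls$MGUS[[dr]]
      in_smm <- probe %in% calls$SMM[[dr]]
      in_mm <- probe %in% calls$MM[[dr]]
      expect_identical(probe %in% ps[[dr]]$mm_only,
                       in_mm && !in_smm && !in_mgus)
      expect_identical(probe %in% ps[[dr]]$smm_and_mm,
                       in_mm && in_smm && !in_mgus)
      expect_identical(probe %in% ps[[dr]]$all_three,
                       in_mm && in_smm && in_mgus)
    }
    # pairwise disjoint, union within MM calls
    expect_length(intersect(ps[[dr]]$mm_only, ps[[dr]]$smm_and_mm), 0)
    expect_true(all(ps[[dr]]$union %in% calls$MM[[dr]]))
  }
})

test_that("set overlap counts match brute force and track directions", {
  expect_length(overlap_sets(c("a", "b"), c("c", "d"))$intersection, 0)
  expect_setequal(overlap_sets(c("a", "b"), c("a", "b"))$intersection,
                  c("a", "b"))
  set.seed(32)
  u <- sprintf("p%04d", 1:800)
  a <- sample(u, 300); b <- sample(u, 250)
  ov <- overlap_sets(a, b)
  expect_equal(ov$n, sum(vapply(u, function(x)
    x %in% a && x %in% b, logical(1))))

  da <- data.frame(probe_id = c("a", "b", "c"),
                   direction = c("hyper", "hypo", "hyper"))
  db <- data.frame(probe_id = c("b", "c", "d"),
                   direction = c("hypo", "hypo", "hyper"))
  ov2 <- overlap_sets(da, db)
  expect_setequal(ov2$intersection, c("b", "c"))
  expect_identical(ov2$concordant, "b")
  expect_identical(ov2$discordant, "c")
})

test_that("nearest-gene mapping obeys distance, strand and tie rules", {
  ann <- data.frame(probe_id = c("p1", "p2", "p3"),
                    chrom = c("chr1", "chr1", "chr9"),
                    pos = c(100, 480, 50), stringsAsFactors = FALSE)
  tss <- data.frame(gene = c("NEAR", "FAR"), chrom = "chr1",
                    tss_pos = c(50, 500), strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  res <- suppressMessages(nearest_gene_map(c("p1", "p2", "p3"), ann, tss))
  expect_identical(res$gene, c("NEAR", "FAR", NA))
  expect_equal(res$distance[1], 50)       # downstream of a + TSS
  expect_equal(res$distance[2], 20)       # 480 is downstream of a - TSS at 500
  # equidistant: lexicographically first symbol wins
  tss_tie <- data.frame(gene = c("ZZZ", "AAA"), chrom = "chr1",
                        tss_pos = c(90, 110), strand = "+",
                        stringsAsFactors = FALSE)
  tie <- nearest_gene_map("p1", ann, tss_tie)
  expect_identical(tie$gene, "AAA")
})

test_that("nearest-gene mapping equals brute-force search on random layouts", {
  set.seed(33)
  n <- 400
  ann <- data.frame(probe_id = sprintf("p%04d", 1:n),
                    chrom = sample(paste0("chr", 1:3), n, replace = TRUE),
                    pos = sample.int(1e6, n), stringsAsFactors = FALSE)
  tss <- data.frame(gene = sprintf("G%03d", 1:120),
                    chrom = sample(paste0("chr", 1:3), 120, replace = TRUE),
                    tss_pos = sample.int(1e6, 120),
                    strand = sample(c("+", "-"), 120, replace = TRUE),
                    stringsAsFactors = FALSE)
  res <- nearest_gene_map(ann$probe_id, ann, tss)
  for (i in sample(n, 80)) {
    cand <- tss[tss$chrom == ann$chrom[i], ]
    dd <- abs(ann$pos[i] - cand$tss_pos)
    best <- cand[dd == min(dd), ]
    expect_identical(res$gene[i], sort(best$gene)[1])
  }
})

test_that("differential expression recovers planted shifts and flips on swap", {
  set.seed(34)
  n <- 16
  sheet <- data.frame(sample_id = paste0("s", 1:n),
                      group = rep(c("MM", "HD"), each = n / 2))
  expr <- matrix(rnorm(50 * n, 7, 0.3), 50, n,
                 dimnames = list(sprintf("G%02d", 1:50), sheet$sample_id))
  expr["G01", sheet$group == "MM"] <- expr["G01", sheet$group == "MM"] + 1
  expr["G02", sheet$group == "MM"] <- expr["G02", sheet$group == "MM"] - 1
  expr["G03", ] <- 5  # constant gene
  res <- suppressMessages(
    differential_expression(expr, sheet, "MM", "HD"))
  expect_false("G03" %in% res$gene)
  expect_true(res$called[res$gene == "G01"])
  expect_identical(res$direction[res$gene == "G01"], "up")
  expect_true(res$called[res$gene == "G02"])
  expect_identical(res$direction[res$gene == "G02"], "down")
  swap <- suppressMessages(
    differential_expression(expr, sheet, "HD", "MM"))
  expect_identical(swap$direction[swap$gene == "G01"], "down")
})

test_that("methylation-expression integration crosses directions", {
  dmp_genes <- data.frame(gene = c("A", "B", "C", "C"),
                          meth_direction = c("hyper", "hypo", "hyper",
                                             "hypo"))
  de <- data.frame(gene = c("A", "B", "C", "D"),
                   direction = c("down", "up", "down", "up"),
                   called = c(TRUE, TRUE, TRUE, FALSE))
  res <- integrate_meth_expr(dmp_genes, de)
  expect_identical(res$table$category[res$table$gene == "A"], "hyper-down")
  expect_identical(res$table$category[res$table$gene == "B"], "hypo-up")
  # gene D has no DE call and is absent
  expect_false("D" %in% res$table$gene)
  # gene C carries both directions and is flagged ambiguous twice
  expect_true(all(res$table$ambiguous[res$table$gene == "C"]))
  # counts sum to the number of (gene, direction-pair) rows
  expect_equal(sum(res$counts), nrow(res$table))
})

test_that("category enrichment matches the 2x2 primitive and sums to one", {
  ann <- data.frame(probe_id = sprintf("p%03d", 1:100),
                    chrom = "chr1", pos = 1:100,
                    cgi_relation = rep(c("Island", "OpenSea"), c(20, 80)),
                    stringsAsFactors = FALSE)
  query <- ann$probe_id[1:10]                 # all Island
  res <- category_enrichment(query, ann, "cgi_relation", ann$probe_id)
  isl <- res[res$level == "Island", ]
  ref <- enrichment_2x2(10, 0, 10, 80)
  expect_equal(isl$odds_ratio, ref$odds_ratio)
  expect_equal(isl$p, ref$p.value)
  expect_gt(isl$odds_ratio, 1)
  expect_equal(sum(res$query_frac), 1)
  expect_equal(sum(res$background_frac), 1)

  expect_error(category_enrichment(ann$probe_id, ann, "cgi_relation",
                                   ann$probe_id), "proper subset")
  expect_warning(category_enrichment(character(0), ann, "cgi_relation",
                                     ann$probe_id), "empty query")
})
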