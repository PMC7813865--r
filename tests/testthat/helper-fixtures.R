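# Small in-code fixtures shared across tests.

tiny_beta <- function() {
  m <- matrix(c(0.1, 0.5, 0.9, 0.2, 0.6, 0.8), nrow = 3,
              dimnames = list(c("cg1", "cg2", "cg3"), c("s1", "s2")))
  m
}

write_tiny_beta <- function(mat, sep = "\t") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

tiny_annotation <- function(n = 10) {
  data.frame(
    probe_id = paste0("cg", seq_len(n)),
    chrom = rep(c("chr1", "chr2"), length.out = n),
    pos = seq(1000, by = 1000, length.out = n),
    cgi_relation = rep(CGI_LEVELS, length.out = n),
    chromhmm_state = rep(CHROMHMM_STATES, length.out = n),
    nearest_gene = paste0("G", seq_len(n)),
    tss_distance = rep(100L, n),
    blacklisted = rep(c(FALSE, FALSE, FALSE, FALSE, TRUE), length.out = n),
    stringsAsFactors = FALSE
  )
}

# Two-group beta matrix with per-probe baseline and optional planted shifts.
two_group_beta <- function(n_probes, n1, n2, noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  mu <- stats::qlogis(stats::runif(n_probes, 0.15, 0.85))
  mat <- stats::plogis(matrix(mu, n_probes, n1 + n2) +
    matrix(stats::rnorm(n_probes * (n1 + n2), 0, noise_sd), n_probes))
  dimnames(mat) <- list(sprintf("cg%05d", seq_len(n_probes)),
                        c(paste0("d", seq_len(n1)), paste0("c", seq_len(n2))))
  sheet <- data.frame(
    sample_id = colnames(mat),
    group = rep(c("MM", "HD"), c(n1, n2)),
    age = sample(50:75, n1 + n2, replace = TRUE),
    sex = sample(c("F", "M"), n1 + n2, replace = TRUE),
    stringsAsFactors = FALSE
  )
  list(beta = mat, sheet = sheet)
}

# Independent step-up BH oracle, coded from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exhaustive Fisher two-sided p oracle: enumerate all 2x2 tables with the
# observed margins and sum hypergeometric point masses <= observed.
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b          # row 1 total
  n <- c_ + d         # row 2 total
  k <- a + c_         # column 1 total
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(dens[dens <= obs * (1 + 1e-7)])
}
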