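check_primer_bounds <- function(p, params) {
  expect_true(p$length >= params$len_min && p$length <= params$len_max)
  expect_true(p$tm >= params$tm_min && p$tm <= params$tm_max)
  expect_true(p$gc >= params$gc_min && p$gc <= params$gc_max)
}

test_that("design succeeds in the 30 bp window on an unconstrained gene and satisfies all bounds", {
  w <- world_small()
  params <- w$spec$params
  g <- Filter(function(i) w$truth$expected_outcome[[match(i$gene_id, w$truth$gene_id)]] == "ok_window30",
              w$genes)[[1L]]
  ps <- design_primer_set(g, w$genome, params)
  expect_s3_class(ps, "fd_primer_set")
  expect_identical(ps$window_used, 30L)
  expect_setequal(names(ps$primers), c("5f", "5r", "3f", "3r"))
  for (p in ps$primers) check_primer_bounds(p, params)

  # the independent enumerator agrees a window-30 solution exists
  expect_identical(classify_design_feasibility(g, w$genome, params), "ok_window30")

  # window invariant: inner 3' termini within window_used of the codons
  b5 <- ps$b5 + 1L; b3e <- ps$b3
  expect_lte(abs(ps$primers$`5r`$w_start - b5), ps$window_used)
  expect_lte(abs(ps$primers$`3f`$w_end - b3e), ps$window_used)

  # flank amplicon lengths within [min_flank, max_flank]
  len5 <- ps$primers$`5r`$w_end - ps$primers$`5f`$w_start + 1L
  len3 <- ps$primers$`3r`$w_end - ps$primers$`3f`$w_start + 1L
  expect_true(len5 >= params$min_flank && len5 <= params$max_flank)
  expect_true(len3 >= params$min_flank && len3 <= params$max_flank)

  # role/strand semantics: binding matches the implied template strand
  W <- ps$W
  expect_identical(ps$primers$`5f`$binding_seq,
                   substr(W, ps$primers$`5f`$w_start, ps$primers$`5f`$w_end))
  expect_identical(ps$primers$`5r`$binding_seq,
                   dna_revcomp(substr(W, ps$primers$`5r`$w_start, ps$primers$`5r`$w_end)))
})

test_that("primer binding sequences are locally unique (mispriming guard)", {
  w <- world_small()
  ok <- Filter(function(x) !is_design_failure(x),
               lapply(w$genes, design_primer_set, genome = w$genome, params = w$spec$params))
  for (ps in ok) {
    fl <- ps$flanks
    lo <- max(0L, min(fl$five_prime$start, fl$three_prime$start) - 1000L)
    hi <- min(nchar(w$genome[[fl$contig]]),
              max(fl$five_prime$end, fl$three_prime$end) + 1000L)
    ctx <- substr(w$genome[[fl$contig]], lo + 1L, hi)
    for (p in ps$primers) {
      n_hits <- count_substring(ctx, p$binding_seq) + count_substring(ctx, dna_revcomp(p$binding_seq))
      expect_identical(n_hits, 1L)
    }
  }
})

test_that("homopolymer windows force the 75 bp fallback, confirmed by the enumerator", {
  fx <- make_window75_fixture()
  ps <- design_primer_set(fx$gene, fx$genome)
  expect_s3_class(ps, "fd_primer_set")
  expect_identical(ps$window_used, 75L)
  expect_identical(classify_design_feasibility(fx$gene, fx$genome), "ok_window75")
})

test_that("genes too close to a contig end fail with reason contig_end", {
  set.seed(5)
  genome <- fd_genome(c(c1 = random_dna(10000, 0.5)))
  g <- gene_model("g", "c1", 200L, 1100L, "+")
  fail <- design_primer_set(g, genome)
  expect_true(is_design_failure(fail))
  expect_identical(fail$reason, "contig_end")
})

test_that("design is deterministic", {
  w <- world_small()
  g <- Filter(function(i) w$truth$expected_outcome[[match(i$gene_id, w$truth$gene_id)]] != "fail_contig_end",
              w$genes)[[2L]]
  ps1 <- design_primer_set(g, w$genome, w$spec$params)
  ps2 <- design_primer_set(g, w$genome, w$spec$params)
  expect_identical(ps1, ps2)
})

test_that("attach_tails prepends the right tails and leaves binding untouched", {
  w <- world_small()
  g <- Filter(function(i) w$truth$expected_outcome[[match(i$gene_id, w$truth$gene_id)]] == "ok_window30",
              w$genes)[[1L]]
  ps <- design_primer_set(g, w$genome, w$spec$params)
  tailed <- attach_tails(ps, w$marker, w$vtails)
  expect_identical(tailed$primers$`5r`$tail_seq, w$marker$left_tail)
  expect_identical(tailed$primers$`3f`$tail_seq, w$marker$right_tail)
  expect_identical(tailed$primers$`5f`$tail_seq, unname(w$vtails[["five"]]))
  expect_identical(tailed$primers$`3r`$tail_seq, unname(w$vtails[["three"]]))
  for (role in names(ps$primers)) {
    expect_identical(tailed$primers[[role]]$binding_seq, ps$primers[[role]]$binding_seq)
    expect_true(startsWith(primer_full_seq(tailed$primers[[role]]),
                           tailed$primers[[role]]$tail_seq))
  }
  expect_error(attach_tails(tailed, w$marker, w$vtails), class = "fd_usage_error")

  # tailed amplicon ends share exactly tail_len terminal homology with the
  # marker (longest-common-affix oracle)
  amps <- flank_amplicons(tailed)
  expect_identical(oracle_affix(amps$five, w$marker$sequence), w$marker$tail_len)
  expect_identical(oracle_affix(w$marker$sequence, amps$three), w$marker$tail_len)

  # zero-length tails: output equals input
  m0 <- marker_cassette(w$marker$sequence, tail_len = 0L)
  t0 <- attach_tails(ps, m0, c("", ""))
  for (role in names(ps$primers)) {
    expect_identical(primer_full_seq(t0$primers[[role]]), ps$primers[[role]]$binding_seq)
  }
})

test_that("domain-only designs replace exactly the domain", {
  w <- world_small()
  g <- Filter(function(x) !is.na(x$domain_start) &&
                w$truth$expected_outcome[[match(x$gene_id, w$truth$gene_id)]] == "ok_window30",
              w$genes)[[1L]]
  ps <- design_domain_deletion(g, w$genome, w$spec$params)
  expect_s3_class(ps, "fd_primer_set")
  expect_identical(ps$flanks$target$start, g$domain_start)
  expect_identical(ps$flanks$target$end, g$domain_end)
  # ORF sequence outside the domain is preserved in the flanks
  cseq <- w$genome[[g$contig]]
  left_orf <- substr(cseq, g$orf_start + 1L, g$domain_start)
  go_left <- if (g$strand == "+") left_orf else dna_revcomp(left_orf)
  side <- if (g$strand == "+") "five_prime" else "five_prime" # 5' flank in gene orientation
  expect_true(grepl(go_left, ps$flanks[[side]]$seq, fixed = TRUE))

  no_dom <- gene_model("nd", g$contig, g$orf_start, g$orf_end, g$strand)
  expect_error(design_domain_deletion(no_dom, w$genome), class = "fd_precondition_error")
})

test_that("melting temperature is strand-symmetric and length-monotone at fixed composition", {
  set.seed(9)
  for (i in 1:20) {
    s <- random_dna(sample(18:28, 1), 0.5)
    expect_equal(dna_tm(s), dna_tm(dna_revcomp(s)), tolerance = 1e-9)
  }
  expect_lt(dna_tm(strrep("AT", 10)), dna_tm(strrep("GC", 10)))
})

test_that("primer report and YAML config round-trip", {
  skip_if_not_installed("yaml")
  w <- world_small()
  g <- Filter(function(i) w$truth$expected_outcome[[match(i$gene_id, w$truth$gene_id)]] == "ok_window30",
              w$genes)[[1L]]
  ps <- attach_tails(design_primer_set(g, w$genome, w$spec$params), w$marker, w$vtails)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_primer_report(list(ps), f)
  df <- read.delim(f)
  expect_identical(nrow(df), 4L)
  expect_setequal(df$role, c("5f", "5r", "3f", "3r"))
  expect_identical(df$full_seq, paste0(df$tail_seq, df$binding_seq))

  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(min_flank = 500L, tm_min = 54), yml)
  p2 <- design_params_from_yaml(yml)
  expect_identical(p2$min_flank, 500L)
  expect_identical(p2$tm_min, 54)
  yaml::write_yaml(list(bogus_key = 1), yml)
  expect_error(design_params_from_yaml(yml), class = "fd_format_error")
})
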