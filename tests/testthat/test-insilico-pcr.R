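test_that("binding sites: identity, palindromic symmetry, tails ignored", {
  set.seed(21)
  tmpl <- random_dna(2000, 0.5)
  primer <- substr(tmpl, 501, 522)
  sites <- find_binding_sites(tmpl, primer)
  expect_identical(nrow(sites), sum(count_substring(tmpl, primer),
                                    count_substring(tmpl, dna_revcomp(primer))))
  expect_true(any(sites$start == 500L & sites$strand == "+"))

  # a palindromic site is found once per strand at the same offset
  tmpl2 <- paste0(random_dna(300, 0.5), "GAATTC", random_dna(300, 0.5))
  s2 <- find_binding_sites(tmpl2, "GAATTC")
  expect_setequal(unique(s2$strand), c("-", "+"))
  expect_identical(unique(s2$start), 300L)

  # tail portion is ignored for matching
  p <- structure(
    list(role = "5f", binding_seq = primer, tail_seq = "TTTTTTTT",
         anchor = NULL, tm = 60, gc = 0.5, length = nchar(primer)),
    class = "fd_primer"
  )
  expect_identical(find_binding_sites(tmpl, p), sites)
})

test_that("mismatch tolerance respects the 3'-terminal exclusion zone", {
  set.seed(22)
  tmpl <- random_dna(500, 0.5)
  primer <- substr(tmpl, 201, 222)
  # mutate a middle base of the primer: still found with max_mismatch = 1
  mid <- primer
  substr(mid, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(mid, 10, 10))[1L]
  expect_identical(nrow(find_binding_sites(tmpl, mid, max_mismatch = 0L)), 0L)
  hits <- find_binding_sites(tmpl, mid, max_mismatch = 1L)
  expect_true(any(hits$start == 200L & hits$strand == "+"))
  # mutate the 3'-terminal base: never found on the + strand
  endm <- primer
  substr(endm, 22, 22) <- setdiff(c("A", "C", "G", "T"), substr(endm, 22, 22))[1L]
  hits2 <- find_binding_sites(tmpl, endm, max_mismatch = 1L)
  expect_false(any(hits2$start == 200L & hits2$strand == "+"))
})

test_that("binding sites agree with the naive sliding-window oracle (mismatch 1)", {
  set.seed(23)
  tmpl <- random_dna(8000, 0.5)
  for (i in 1:60) {
    primer <- if (i %% 3 == 0) {
      s <- sample(8000 - 22, 1)
      p <- substr(tmpl, s, s + 21) # planted (possibly mutated) site
      if (i %% 2 == 0) substr(p, 7, 7) <- "A"
      p
    } else {
      random_dna(22, 0.5)
    }
    got <- find_binding_sites(tmpl, primer, max_mismatch = 1L)
    want <- oracle_find_sites(tmpl, primer, max_mismatch = 1L)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(
        got[order(got$start, got$strand), c("start", "end", "strand")],
        want[order(want$start, want$strand), ],
        ignore_attr = TRUE
      )
    }
  }
})

test_that("simulate_pcr enumerates convergent pairs like the exhaustive oracle", {
  set.seed(24)
  fwd <- random_dna(20, 0.5)
  rev <- random_dna(20, 0.5)
  spacer <- function(n) random_dna(n, 0.5)
  # 2 forward and 2 reverse sites, all convergent pairs in range -> 4 products
  tmpl <- paste0(
    spacer(100), fwd, spacer(150), fwd, spacer(200),
    dna_revcomp(rev), spacer(120), dna_revcomp(rev), spacer(100)
  )
  prods <- simulate_pcr(tmpl, fwd, rev, max_product = 2000L)
  expect_identical(nrow(prods), 4L)
  want <- oracle_pcr_products(tmpl, fwd, rev, 2000L)
  expect_identical(prods$length, want$length)
  expect_true(all(prods$sequence == substring(tmpl, prods$fwd_start + 1L, prods$rev_end)))
  expect_false(is.unsorted(prods$length))

  # unique convergent pair: product equals the template slice
  tmpl1 <- paste0(spacer(80), fwd, spacer(300), dna_revcomp(rev), spacer(80))
  p1 <- simulate_pcr(tmpl1, fwd, rev, max_product = 1000L)
  expect_identical(nrow(p1), 1L)
  expect_identical(p1$sequence, substr(tmpl1, 81L, 81L + p1$length - 1L))
  expect_identical(p1$length, 20L + 300L + 20L)

  # divergent-only orientation: no product
  tmpl2 <- paste0(spacer(80), dna_revcomp(fwd), spacer(300), rev, spacer(80))
  expect_identical(nrow(simulate_pcr(tmpl2, fwd, rev, max_product = 1000L)), 0L)
})

test_that("build_null_locus swaps the target for the marker and nothing else", {
  w <- world_small()
  g <- Filter(function(i) w$truth$expected_outcome[[match(i$gene_id, w$truth$gene_id)]] == "ok_window30",
              w$genes)[[1L]]
  ps <- attach_tails(design_primer_set(g, w$genome, w$spec$params), w$marker, w$vtails)
  con <- build_deletion_construct(ps, w$marker, w$vector, route = "recombination")
  edited <- build_null_locus(w$genome, g, con)
  orf_len <- g$orf_end - g$orf_start
  expect_identical(
    nchar(edited[[g$contig]]),
    nchar(w$genome[[g$contig]]) + w$marker$length - orf_len
  )
  # differences confined to the replaced interval
  expect_identical(
    substr(edited[[g$contig]], 1L, g$orf_start),
    substr(w$genome[[g$contig]], 1L, g$orf_start)
  )
  expect_identical(
    substring(edited[[g$contig]], g$orf_start + w$marker$length + 1L),
    substring(w$genome[[g$contig]], g$orf_end + 1L)
  )
  expect_error(build_null_locus(edited, g, con), class = "fd_flank_mismatch_error")
})

test_that("diagnostic plans: external primers, allele-size identity, genotype bands", {
  w <- world_small()
  g <- Filter(function(i) w$truth$expected_outcome[[match(i$gene_id, w$truth$gene_id)]] == "ok_window30",
              w$genes)[[1L]]
  ps <- attach_tails(design_primer_set(g, w$genome, w$spec$params), w$marker, w$vtails)
  con <- build_deletion_construct(ps, w$marker, w$vector, route = "recombination")
  plan <- design_diagnostic(g, w$genome, con, w$spec$params)

  # both primers strictly outside the targeting sequence
  fl <- ps$flanks
  lo <- min(fl$five_prime$start, fl$three_prime$start)
  hi <- max(fl$five_prime$end, fl$three_prime$end)
  for (p in list(plan$fwd, plan$rev)) {
    expect_true(p$anchor$end <= lo || p$anchor$start >= hi)
    expect_true(p$anchor$end >= lo - w$spec$params$ext_offset &&
                  p$anchor$start <= hi + w$spec$params$ext_offset)
  }
  expect_identical(
    plan$null_len - plan$wt_len,
    w$marker$length - (g$orf_end - g$orf_start)
  )
  expect_identical(predict_genotype_bands(plan, "wt"), plan$wt_len)
  expect_identical(predict_genotype_bands(plan, "null"), plan$null_len)
  expect_identical(predict_genotype_bands(plan, "heterokaryon"),
                   sort(c(plan$wt_len, plan$null_len)))
  expect_identical(predict_genotype_bands(plan, "diploid"),
                   predict_genotype_bands(plan, "heterokaryon"))
  expect_error(predict_genotype_bands(plan, "triploid"), class = "fd_usage_error")

  # wt template yields the wt band only; null template the null band only
  null_genome <- build_null_locus(w$genome, g, con)
  wt_prod <- simulate_pcr(w$genome[[g$contig]], plan$fwd, plan$rev, max_product = 100000L)
  nl_prod <- simulate_pcr(null_genome[[g$contig]], plan$fwd, plan$rev, max_product = 100000L)
  expect_identical(wt_prod$length, plan$wt_len)
  expect_identical(nl_prod$length, plan$null_len)

  f <- withr::local_tempfile(fileext = ".json")
  write_diagnostic_plan(plan, f)
  js <- jsonlite::read_json(f)
  expect_identical(js$wt_len, plan$wt_len)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_band_predictions(plan, f2)
  expect_identical(nrow(read.delim(f2)), 4L)
})

test_that("equal-length alleles trigger a sound restriction-enzyme fallback", {
  fx <- make_equal_length_locus()
  params <- design_params()
  ps <- attach_tails(design_primer_set(fx$gene, fx$genome, params), fx$marker,
                     c(strrep("G", 29), strrep("C", 29)))
  con <- build_deletion_construct(ps, fx$marker, route = "fusion_pcr")
  t0 <- Sys.time()
  plan <- design_diagnostic(fx$gene, fx$genome, con, params)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_identical(plan$wt_len, plan$null_len)
  expect_false(plan$size_discriminable)
  expect_gte(nrow(plan$enzymes), 1L)
  # direct string-count recheck of every reported enzyme
  tab <- restriction_enzymes()
  null_genome <- build_null_locus(fx$genome, fx$gene, con)
  wt_seq <- simulate_pcr(fx$genome[["cEQ"]], plan$fwd, plan$rev, 100000L)$sequence
  nl_seq <- simulate_pcr(null_genome[["cEQ"]], plan$fwd, plan$rev, 100000L)$sequence
  for (nm in plan$enzymes$name) {
    site <- tab$recognition_site[tab$name == nm]
    expect_identical(count_substring(wt_seq, site), 0L)
    expect_gte(count_substring(nl_seq, site), 1L)
    expect_gte(count_substring(fx$marker$sequence, site), 1L)
  }
  expect_true("EcoRI" %in% plan$enzymes$name)
  expect_lt(elapsed, 1)
})
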