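test_that("load_genome reads, uppercases and validates FASTA", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1 some description", "acgt"), f)
  g <- load_genome(f)
  expect_s3_class(g, "fd_genome")
  expect_identical(unname(g[["c1"]]), "ACGT")
  expect_identical(nchar(g[["c1"]]), 4L)

  writeLines(c(">c1", "ACGT", ">c1", "GGCC"), f)
  expect_error(load_genome(f), class = "fd_format_error")

  writeLines(character(0), f)
  expect_error(load_genome(f), class = "fd_format_error")

  writeLines(c(">c1", "ACGU"), f)
  expect_error(load_genome(f), class = "fd_format_error")
})

test_that("genome FASTA round-trips byte-identically", {
  w <- world_big()
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_genome_fasta(w$genome, f1)
  g2 <- load_genome(f1)
  expect_identical(unclass(g2), unclass(w$genome))
  write_genome_fasta(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("load_annotation converts GFF3 1-based inclusive to 0-based half-open", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(">c1", strrep("ACGT", 50)), fa)
  genome <- load_genome(fa)
  writeLines(c(
    "##gff-version 3",
    "c1\t.\tgene\t11\t100\t.\t+\t.\tID=g1",
    "c1\t.\tgene\t120\t180\t.\t-\t.\tID=g2"
  ), gff)
  models <- load_annotation(gff, genome)
  expect_length(models, 2L)
  expect_identical(models[[1L]]$orf_start, 10L)
  expect_identical(models[[1L]]$orf_end, 100L)
  expect_identical(models[[2L]]$strand, "-")
  expect_identical(models[[2L]]$orf_start, 119L)

  writeLines(c("##gff-version 3", "c1\t.\tgene\t11\t300\t.\t+\t.\tID=g1"), gff)
  expect_error(load_annotation(gff, genome), class = "fd_coordinate_error")

  writeLines(c("##gff-version 3", "cZ\t.\tgene\t11\t100\t.\t+\t.\tID=g1"), gff)
  expect_error(load_annotation(gff, genome), class = "fd_coordinate_error")
})

test_that("synthetic annotation round-trips through GFF3 with consistent models", {
  w <- world_small()
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(w$genes, gff)
  models <- expect_no_warning(load_annotation(gff, w$genome))
  expect_length(models, length(w$genes))
  for (m in models) {
    clen <- nchar(w$genome[[m$contig]])
    expect_true(m$orf_start >= 0L && m$orf_end <= clen)
    orig <- w$genes[[which(vapply(w$genes, `[[`, character(1), "gene_id") == m$gene_id)]]
    expect_identical(m$orf_start, orig$orf_start)
    expect_identical(m$orf_end, orig$orf_end)
    expect_identical(m$strand, orig$strand)
    expect_identical(m$domain_start, orig$domain_start)
  }
})

test_that("extract_flanks arithmetic, strand mirror, and contig-end failure", {
  set.seed(3)
  cseq <- random_dna(20000, 0.5)
  genome <- fd_genome(c(c1 = cseq))
  g <- gene_model("g", "c1", 5000L, 5900L, "+")
  fl <- extract_flanks(g, genome)
  expect_identical(fl$five_prime$start, 4000L)
  expect_identical(fl$five_prime$end, 5000L)
  expect_identical(fl$three_prime$start, 5900L)
  expect_identical(fl$three_prime$end, 6900L)
  expect_identical(fl$five_prime$seq, substr(cseq, 4001, 5000))

  gm <- gene_model("g", "c1", 5000L, 5900L, "-")
  flm <- extract_flanks(gm, genome)
  expect_identical(flm$five_prime$seq, dna_revcomp(substr(cseq, 5901, 6900)))
  expect_identical(flm$three_prime$seq, dna_revcomp(substr(cseq, 4001, 5000)))

  near <- gene_model("g2", "c1", 300L, 1200L, "+")
  fail <- extract_flanks(near, genome)
  expect_true(is_design_failure(fail))
  expect_identical(fail$reason, "contig_end")
})

test_that("flank round-trip and strand-mirror invariants hold across a synthetic world", {
  w <- world_small()
  for (i in seq_along(w$genes)) {
    g <- w$genes[[i]]
    fl <- extract_flanks(g, w$genome)
    if (is_design_failure(fl)) {
      expect_identical(w$truth$expected_outcome[i], "fail_contig_end")
      next
    }
    # reassembly in gene orientation reproduces the genomic substring
    target_go <- if (g$strand == "+") fl$target$seq else dna_revcomp(fl$target$seq)
    rebuilt <- paste0(fl$five_prime$seq, target_go, fl$three_prime$seq)
    lo <- min(fl$five_prime$start, fl$three_prime$start)
    hi <- max(fl$five_prime$end, fl$three_prime$end)
    genomic <- substr(w$genome[[g$contig]], lo + 1L, hi)
    expect_identical(rebuilt, if (g$strand == "+") genomic else dna_revcomp(genomic))
    # no flank overlaps the replaced interval
    expect_true(fl$five_prime$end <= fl$target$start || fl$five_prime$start >= fl$target$end)
    expect_true(fl$three_prime$end <= fl$target$start || fl$three_prime$start >= fl$target$end)

    # mirror: the - strand extraction equals + strand on the reverse
    # complemented contig with mirrored coordinates
    clen <- nchar(w$genome[[g$contig]])
    mirrored_genome <- fd_genome(setNames(dna_revcomp(w$genome[[g$contig]]), g$contig))
    mg <- gene_model(
      g$gene_id, g$contig, clen - g$orf_end, clen - g$orf_start,
      if (g$strand == "+") "-" else "+"
    )
    flm <- extract_flanks(mg, mirrored_genome)
    expect_identical(flm$five_prime$seq, fl$five_prime$seq)
    expect_identical(flm$three_prime$seq, fl$three_prime$seq)
  }
})

test_that("domain-only extraction replaces the domain and errors without one", {
  w <- world_small()
  g <- Filter(function(x) !is.na(x$domain_start) &&
                w$truth$expected_outcome[[match(x$gene_id, w$truth$gene_id)]] != "fail_contig_end",
              w$genes)[[1L]]
  fl <- extract_flanks(g, w$genome, domain_only = TRUE)
  expect_identical(fl$target$start, g$domain_start)
  expect_identical(fl$target$end, g$domain_end)
  no_dom <- gene_model("nd", g$contig, g$orf_start, g$orf_end, g$strand)
  expect_error(extract_flanks(no_dom, w$genome, domain_only = TRUE),
               class = "fd_precondition_error")
})

test_that("failure reports serialize to TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_failure_report(list(design_failure("gA", "contig_end")), f)
  df <- read.delim(f)
  expect_identical(df$gene_id, "gA")
  expect_identical(df$reason, "contig_end")
})
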