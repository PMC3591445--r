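# Shared synthetic worlds, built once per test run.

.world_cache <- new.env(parent = emptyenv())

# 12-gene world for unit tests (2 edge genes, mixed strands)
world_small <- function() {
  if (is.null(.world_cache$small)) {
    spec <- synthetic_spec(
      seed = 11L, n_contigs = 2L, n_genes = 12L,
      fraction_edge_genes = 2 / 12
    )
    gen <- generate_genome(spec)
    mv <- generate_marker_and_vector(spec)
    .world_cache$small <- list(
      spec = spec, genome = gen$genome, genes = gen$genes, truth = gen$truth,
      marker = mv$marker, vector = mv$vector,
      vtails = vector_tails(mv$vector, spec$tail_length)
    )
  }
  .world_cache$small
}

# the acceptance-scale world: 200 genes, seed 1, defaults
world_big <- function() {
  if (is.null(.world_cache$big)) {
    spec <- synthetic_spec(seed = 1L)
    gen <- generate_genome(spec)
    mv <- generate_marker_and_vector(spec)
    .world_cache$big <- list(
      spec = spec, genome = gen$genome, genes = gen$genes, truth = gen$truth,
      marker = mv$marker, vector = mv$vector,
      vtails = vector_tails(mv$vector, spec$tail_length)
    )
  }
  .world_cache$big
}

# big-world primer designs (computed once); records elapsed design time
world_big_designs <- function() {
  if (is.null(.world_cache$big_designs)) {
    w <- world_big()
    t0 <- Sys.time()
    designs <- lapply(w$genes, design_primer_set, genome = w$genome, params = w$spec$params)
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    .world_cache$big_designs <- list(designs = designs, elapsed_s = elapsed)
  }
  .world_cache$big_designs
}

# a gene whose +/-30 bp windows are homopolymer runs but whose +/-75 bp
# windows are designable: forces the 75 bp fallback
make_window75_fixture <- function(seed = 42L) {
  set.seed(seed)
  s <- 1000L; orf_len <- 900L; e <- s + orf_len; clen <- 3000L
  polyA5 <- c(s - 30L, s + 59L)   # covers every candidate body anchored in window 30
  polyA3 <- c(e - 59L, e + 30L)
  seqv <- strsplit(random_dna(clen, 0.5), "")[[1L]]
  seqv[(polyA5[1L] + 1L):polyA5[2L]] <- "A"
  seqv[(polyA3[1L] + 1L):polyA3[2L]] <- "A"
  genome <- fd_genome(c(cX = paste(seqv, collapse = "")))
  list(genome = genome, gene = gene_model("gW75", "cX", s, e, "+"))
}

# a small custom locus whose marker length equals the ORF length, with EcoRI
# engineered to cut the marker only (the contig is scrubbed of EcoRI sites)
make_equal_length_locus <- function(seed = 7L) {
  set.seed(seed)
  orf_len <- 1732L
  s <- 1500L
  contig <- random_dna(1500L + orf_len + 1500L, 0.5)
  while (grepl("GAATTC", contig, fixed = TRUE)) {
    contig <- gsub("GAATTC", "GAATTA", contig, fixed = TRUE)
  }
  marker_seq <- random_dna(orf_len, 0.5)
  substr(marker_seq, 800L, 805L) <- "GAATTC"
  list(
    genome = fd_genome(c(cEQ = contig)),
    gene = gene_model("gEQ", "cEQ", s, s + orf_len, "+"),
    marker = marker_cassette(marker_seq, name = "mEQ", tail_len = 29L)
  )
}
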