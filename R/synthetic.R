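# synthetic_data: deterministic synthetic genomes, markers, vectors and
# transformant observations with known ground truth.

#' Specification for a synthetic genome
#'
#' The defaults describe the package's reference test world: 200
#' single-exon ORFs over 5 contigs at 50% GC, intergenic gaps wide enough
#' for full 1 kb flanks on both sides, a 1732 bp marker (the size of the
#' pyrG-Af cassette the design emulates), a 5726 bp circular vector (the
#' size of the pRS426 shuttle vector), 29 nt tails, 5% of genes placed
#' 200 bp from a contig end (too close for a 600 bp flank), and 19.5% of
#' genes marked essential in the truth table.
#'
#' @param seed integer seed; together with the spec it fully determines
#'   every emitted byte (Mersenne-Twister, fixed kinds).
#' @param n_contigs,n_genes layout counts.
#' @param orf_length_range,intergenic_range uniform length ranges (bp).
#' @param gc_content base composition.
#' @param fraction_edge_genes fraction of genes placed `edge_margin` bp
#'   from a contig end (at most two per contig).
#' @param fraction_essential fraction of genes flagged essential.
#' @param edge_margin distance of edge genes from the contig end (bp).
#' @param marker_length,vector_length,tail_length cassette geometry (bp/nt).
#' @param params the [design_params()] used to classify expected design
#'   outcomes for the truth table.
#' @return list of class `fd_synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_contigs = 5L, n_genes = 200L,
                           orf_length_range = c(900L, 2400L),
                           intergenic_range = c(2100L, 2600L),
                           gc_content = 0.5,
                           fraction_edge_genes = 0.05,
                           fraction_essential = 0.195,
                           edge_margin = 200L,
                           marker_length = 1732L,
                           vector_length = 5726L,
                           tail_length = 29L,
                           params = design_params()) {
  stopifnot(
    fraction_edge_genes >= 0, fraction_edge_genes <= 1,
    fraction_essential >= 0, fraction_essential <= 1,
    gc_content >= 0, gc_content <= 1,
    n_contigs >= 1L, n_genes >= 1L
  )
  if (marker_length < 2L * tail_length) {
    fd_stop("fd_spec_error", "marker_length must be at least twice tail_length")
  }
  n_edge <- round(n_genes * fraction_edge_genes)
  if (n_edge > 2L * n_contigs) {
    fd_stop("fd_spec_error", sprintf(
      "%d edge genes requested but only %d contig ends available", n_edge, 2L * n_contigs
    ))
  }
  structure(
    list(
      seed = as.integer(seed), n_contigs = as.integer(n_contigs),
      n_genes = as.integer(n_genes),
      orf_length_range = as.integer(orf_length_range),
      intergenic_range = as.integer(intergenic_range),
      gc_content = gc_content,
      fraction_edge_genes = fraction_edge_genes,
      fraction_essential = fraction_essential,
      edge_margin = as.integer(edge_margin),
      marker_length = as.integer(marker_length),
      vector_length = as.integer(vector_length),
      tail_length = as.integer(tail_length),
      params = params
    ),
    class = "fd_synthetic_spec"
  )
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(expr)
}

.runif_int <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq(range[1L], range[2L]), n, replace = TRUE)
}

#' Generate a synthetic genome with ground truth
#'
#' Places non-overlapping single-exon ORFs (random strand, central-half
#' kinase-domain sub-interval) separated by configurable intergenic gaps,
#' deliberately placing `fraction_edge_genes` of genes too close to a
#' contig end to yield a minimum flank. The truth table records per-gene
#' coordinates, the essential flag, and the expected design outcome
#' computed by the independent brute-force enumerator
#' ([classify_design_feasibility()]), not by [design_primer_set()].
#' Identical specs produce byte-identical outputs.
#'
#' @param spec an [synthetic_spec()].
#' @param dir optional output directory; when given, writes `genome.fasta`,
#'   `annotation.gff3` and `truth.tsv` there.
#' @return list with `genome` (`fd_genome`), `genes` (list of
#'   [gene_model()]), `truth` (data.frame: `gene_id`, `contig`, `orf_start`,
#'   `orf_end`, `strand`, `essential`, `expected_outcome`), and file paths
#'   when `dir` was given.
#' @export
generate_genome <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fd_synthetic_spec"))
  res <- .with_seed(spec$seed, {
    n <- spec$n_genes
    per <- ceiling(n / spec$n_contigs)
    contig_of <- rep(seq_len(spec$n_contigs), each = per)[seq_len(n)]
    n_edge <- round(n * spec$fraction_edge_genes)
    # first n_contigs edge slots are contig starts, the rest contig ends
    edge_start_contigs <- seq_len(min(n_edge, spec$n_contigs))
    edge_end_contigs <- seq_len(max(0L, n_edge - spec$n_contigs))
    essential_idx <- sample(n, round(n * spec$fraction_essential))

    orf_len <- .runif_int(n, spec$orf_length_range)
    strand <- sample(c("+", "-"), n, replace = TRUE)

    genes <- vector("list", n)
    seqs <- character(spec$n_contigs)
    gi <- 0L
    for (ct in seq_len(spec$n_contigs)) {
      idx <- which(contig_of == ct)
      lead <- if (ct %in% edge_start_contigs) spec$edge_margin else
        .runif_int(1L, spec$intergenic_range)
      tail_gap <- if (ct %in% edge_end_contigs) spec$edge_margin else
        .runif_int(1L, spec$intergenic_range)
      gaps <- .runif_int(max(0L, length(idx) - 1L), spec$intergenic_range)
      pos <- lead
      parts <- list(random_dna(lead, spec$gc_content))
      for (k in seq_along(idx)) {
        i <- idx[k]
        gi <- gi + 1L
        s <- pos
        e <- s + orf_len[i]
        dlen <- orf_len[i]
        genes[[i]] <- gene_model(
          sprintf("SYN%04d", i), sprintf("ctg%02d", ct), s, e, strand[i],
          domain_start = s + floor(0.25 * dlen),
          domain_end = s + floor(0.75 * dlen)
        )
        parts <- c(parts, random_dna(orf_len[i], spec$gc_content))
        pos <- e
        if (k < length(idx)) {
          parts <- c(parts, random_dna(gaps[k], spec$gc_content))
          pos <- pos + gaps[k]
        }
      }
      parts <- c(parts, random_dna(tail_gap, spec$gc_content))
      seqs[ct] <- paste(unlist(parts), collapse = "")
    }
    names(seqs) <- sprintf("ctg%02d", seq_len(spec$n_contigs))
    genome <- fd_genome(seqs)

    edge_gene <- logical(n)
    for (ct in edge_start_contigs) edge_gene[which(contig_of == ct)[1L]] <- TRUE
    for (ct in edge_end_contigs) {
      idx <- which(contig_of == ct)
      edge_gene[idx[length(idx)]] <- TRUE
    }
    list(genome = genome, genes = genes, essential_idx = essential_idx,
         edge_gene = edge_gene)
  })

  outcome <- vapply(seq_along(res$genes), function(i) {
    # expected outcome comes from the independent brute-force enumerator
    classify_design_feasibility(res$genes[[i]], res$genome, spec$params)
  }, character(1))
  truth <- data.frame(
    gene_id = vapply(res$genes, `[[`, character(1), "gene_id"),
    contig = vapply(res$genes, `[[`, character(1), "contig"),
    orf_start = vapply(res$genes, `[[`, integer(1), "orf_start"),
    orf_end = vapply(res$genes, `[[`, integer(1), "orf_end"),
    strand = vapply(res$genes, `[[`, character(1), "strand"),
    essential = seq_along(res$genes) %in% res$essential_idx,
    expected_outcome = outcome,
    stringsAsFactors = FALSE
  )
  out <- list(genome = res$genome, genes = res$genes, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out$fasta_path <- write_genome_fasta(res$genome, file.path(dir, "genome.fasta"))
    out$gff_path <- write_annotation_gff3(res$genes, file.path(dir, "annotation.gff3"))
    out$truth_path <- file.path(dir, "truth.tsv")
    write.table(truth, out$truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Write gene models as GFF3
#'
#' Emits `gene` features (1-based inclusive) plus `kinase_domain` child
#' features for models carrying a domain sub-interval.
#'
#' @param genes list of [gene_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in genes) {
    lines <- c(lines, paste(
      g$contig, "fungidel", "gene", g$orf_start + 1L, g$orf_end, ".", g$strand, ".",
      sprintf("ID=%s", g$gene_id), sep = "\t"
    ))
    if (!is.na(g$domain_start)) {
      lines <- c(lines, paste(
        g$contig, "fungidel", "kinase_domain", g$domain_start + 1L, g$domain_end,
        ".", g$strand, ".",
        sprintf("ID=%s.domain;Parent=%s", g$gene_id, g$gene_id), sep = "\t"
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# all k-mers of a string
.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, seq_len(n - k + 1L), seq(k, n)))
}

#' Generate a random marker cassette and gapped vector
#'
#' Random sequences at the spec GC with the guarantee that the marker end
#' regions and the exposed vector end regions share no 12-mer (on either
#' strand), so recombination junctions are never ambiguous. Bounded retries;
#' fails with a spec error if the constraint cannot be met.
#'
#' @param spec an [synthetic_spec()].
#' @param max_tries retry bound.
#' @return `list(marker = , vector = )` of [marker_cassette()] and
#'   [vector_backbone()].
#' @export
generate_marker_and_vector <- function(spec, max_tries = 20L) {
  stopifnot(inherits(spec, "fd_synthetic_spec"))
  .with_seed(spec$seed + 104729L, { # offset stream; fully determined by spec seed
    k <- 12L
    region <- max(50L, 2L * spec$tail_length)
    for (try in seq_len(max_tries)) {
      mseq <- random_dna(spec$marker_length, spec$gc_content)
      vseq <- random_dna(spec$vector_length, spec$gc_content)
      gap_start <- 100L
      gap_end <- 130L
      vec <- vector_backbone(vseq, gap_start, gap_end, name = "pGAP-syn")
      r <- vec$retained
      ends_m <- c(substr(mseq, 1L, region), substr(mseq, nchar(mseq) - region + 1L, nchar(mseq)))
      ends_v <- c(substr(r, 1L, region), substr(r, nchar(r) - region + 1L, nchar(r)))
      km <- unlist(lapply(c(ends_m, dna_revcomp(ends_m)), .kmers, k = k))
      kv <- unlist(lapply(c(ends_v, dna_revcomp(ends_v)), .kmers, k = k))
      if (!length(intersect(km, kv))) {
        return(list(
          marker = marker_cassette(mseq, name = "marker-syn", tail_len = spec$tail_length),
          vector = vec
        ))
      }
    }
    fd_stop("fd_spec_error", "could not generate marker/vector without shared end 12-mers")
  })
}

#' Simulate transformant observations from a truth table
#'
#' Each transformant is a targeted integration with probability
#' `targeting_rate`. Targeted events at essential genes produce the
#' heterokaryon pattern (growth only on non-selective medium, both alleles
#' detected); targeted events at non-essential genes produce stable haploid
#' nulls; untargeted events produce ectopic integrants (stable, wild-type
#' allele only). With `ensure_informative`, genes that drew no targeted
#' event are redrawn (bounded), so every gene has at least one informative
#' transformant.
#'
#' @param truth truth data.frame from [generate_genome()] (columns
#'   `gene_id`, `essential`).
#' @param n_transformants transformants per gene (default 6).
#' @param targeting_rate probability of homologous integration.
#' @param seed RNG seed.
#' @param ensure_informative redraw all-ectopic genes (bounded at 100
#'   redraws per gene).
#' @return list of [transformant_observation()].
#' @export
generate_observations <- function(truth, n_transformants = 6L, targeting_rate = 0.9,
                                  seed = 1L, ensure_informative = TRUE) {
  stopifnot(targeting_rate >= 0, targeting_rate <= 1)
  .with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(truth))) {
      gid <- truth$gene_id[i]
      ess <- isTRUE(truth$essential[i])
      targeted <- runif(n_transformants) < targeting_rate
      if (ensure_informative && targeting_rate > 0) {
        tries <- 0L
        while (!any(targeted) && tries < 100L) {
          targeted <- runif(n_transformants) < targeting_rate
          tries <- tries + 1L
        }
      }
      for (t in seq_len(n_transformants)) {
        tid <- sprintf("%s_T%d", gid, t)
        obs <- if (!targeted[t]) {
          transformant_observation(tid, gid, TRUE, TRUE, "wt", TRUE)
        } else if (ess) {
          transformant_observation(tid, gid, FALSE, TRUE, c("wt", "null"), FALSE)
        } else {
          transformant_observation(tid, gid, TRUE, TRUE, "null", TRUE)
        }
        out[[length(out) + 1L]] <- obs
      }
    }
    out
  })
}
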