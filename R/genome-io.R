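# genome_io: genome/annotation loading, coordinate-safe slicing, flank extraction.
# All internal intervals are 0-based half-open; GFF3 on disk is 1-based inclusive.

#' Load a genome from a FASTA file
#'
#' @param path path to a (multi-record) FASTA file.
#' @return named character vector of uppercase contig sequences, class
#'   `fd_genome`. Contig names are the first whitespace-delimited token of
#'   each header and must be unique.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) fd_stop("fd_format_error", sprintf("no such file: %s", path))
  # read as raw strings so invalid letters are rejected, not silently dropped
  ss <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) fd_stop("fd_format_error", sprintf(
      "not a readable FASTA file: %s (%s)", path, conditionMessage(e)
    ))
  )
  if (length(ss) == 0L) fd_stop("fd_format_error", "empty FASTA file")
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    fd_stop("fd_format_error", sprintf(
      "duplicate contig name(s): %s", paste(unique(nm[duplicated(nm)]), collapse = ", ")
    ))
  }
  seqs <- toupper(as.character(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    fd_stop("fd_format_error", sprintf(
      "contig %s contains characters outside {A,C,G,T,N}", nm[which(bad)[1L]]
    ))
  }
  names(seqs) <- nm
  structure(seqs, class = "fd_genome")
}

#' Construct a genome object from in-memory sequences
#'
#' @param seqs named character vector of contig sequences.
#' @return an `fd_genome`.
#' @export
fd_genome <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), !anyDuplicated(names(seqs)))
  seqs <- toupper(seqs)
  if (any(grepl("[^ACGTN]", seqs))) {
    fd_stop("fd_format_error", "sequence characters outside {A,C,G,T,N}")
  }
  structure(seqs, class = "fd_genome")
}

#' Write a genome to FASTA (80-column wrapped)
#'
#' @param genome an `fd_genome`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Gene model (single-exon ORF interval)
#'
#' A strand-aware ORF interval on a named contig, optionally carrying a
#' kinase-domain sub-interval for domain-only deletion of large genes.
#' Coordinates are 0-based half-open.
#'
#' @param gene_id identifier.
#' @param contig contig name.
#' @param orf_start,orf_end ORF interval, `0 <= orf_start < orf_end`.
#' @param strand `"+"` or `"-"`.
#' @param domain_start,domain_end optional kinase-domain sub-interval, which
#'   must lie within the ORF.
#' @return an object of class `fd_gene_model`.
#' @export
gene_model <- function(gene_id, contig, orf_start, orf_end, strand = "+",
                       domain_start = NA_integer_, domain_end = NA_integer_) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (!strand %in% c("+", "-")) fd_stop("fd_format_error", "strand must be '+' or '-'")
  orf_start <- as.integer(orf_start); orf_end <- as.integer(orf_end)
  if (is.na(orf_start) || is.na(orf_end) || orf_start < 0L || orf_start >= orf_end) {
    fd_stop("fd_coordinate_error", sprintf("invalid ORF interval for %s", gene_id))
  }
  has_dom <- !is.na(domain_start) && !is.na(domain_end)
  if (has_dom) {
    domain_start <- as.integer(domain_start); domain_end <- as.integer(domain_end)
    if (domain_start < orf_start || domain_end > orf_end || domain_start >= domain_end) {
      fd_stop("fd_coordinate_error", sprintf(
        "kinase-domain interval outside ORF for %s", gene_id
      ))
    }
  }
  structure(
    list(
      gene_id = gene_id, contig = contig,
      orf_start = orf_start, orf_end = orf_end, strand = strand,
      domain_start = if (has_dom) domain_start else NA_integer_,
      domain_end = if (has_dom) domain_end else NA_integer_
    ),
    class = "fd_gene_model"
  )
}

#' @export
print.fd_gene_model <- function(x, ...) {
  dom <- if (!is.na(x$domain_start)) {
    sprintf(", kinase domain [%d,%d)", x$domain_start, x$domain_end)
  } else ""
  cat(sprintf(
    "<gene %s> %s:[%d,%d) strand %s%s\n",
    x$gene_id, x$contig, x$orf_start, x$orf_end, x$strand, dom
  ))
  invisible(x)
}

#' Load gene models from a GFF3 file
#'
#' Reads `gene` features (1-based inclusive on disk) into 0-based half-open
#' [gene_model()]s, sorted by (contig, orf_start). Optional
#' `kinase_domain` features with a `Parent` attribute attach a domain
#' sub-interval to their parent gene. Features on unknown contigs or out of
#' contig bounds are rejected.
#'
#' @param path path to a GFF3 file.
#' @param genome an `fd_genome` the models must be consistent with.
#' @return list of `fd_gene_model`.
#' @export
load_annotation <- function(path, genome) {
  if (!file.exists(path)) fd_stop("fd_format_error", sprintf("no such file: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr), # 1-based inclusive
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(gr$type),
    stringsAsFactors = FALSE
  )
  df$ID <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID) else NA_character_
  df$Parent <- if ("Parent" %in% names(S4Vectors::mcols(gr))) {
    vapply(gr$Parent, function(p) if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
  } else NA_character_

  genes <- df[df$type %in% c("gene", "CDS"), , drop = FALSE]
  # when both gene and CDS share an ID keep the gene row
  genes <- genes[order(match(genes$type, c("gene", "CDS"))), , drop = FALSE]
  genes <- genes[!duplicated(genes$ID), , drop = FALSE]
  if (nrow(genes) == 0L) fd_stop("fd_format_error", "no gene/CDS features in GFF3")
  if (anyNA(genes$ID) || any(genes$ID == "")) {
    fd_stop("fd_format_error", "gene feature missing ID attribute")
  }
  doms <- df[df$type == "kinase_domain", , drop = FALSE]

  models <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (!g$contig %in% names(genome)) {
      fd_stop("fd_coordinate_error", sprintf(
        "gene %s references unknown contig %s", g$ID, g$contig
      ))
    }
    clen <- nchar(genome[[g$contig]])
    if (g$start < 1L || g$end > clen) {
      fd_stop("fd_coordinate_error", sprintf("gene %s out of contig bounds", g$ID))
    }
    strand <- if (g$strand %in% c("+", "-")) g$strand else "+"
    d <- doms[!is.na(doms$Parent) & doms$Parent == g$ID, , drop = FALSE]
    gene_model(
      g$ID, g$contig, g$start - 1L, g$end, strand,
      domain_start = if (nrow(d)) d$start[1L] - 1L else NA_integer_,
      domain_end = if (nrow(d)) d$end[1L] else NA_integer_
    )
  })
  ord <- order(
    vapply(models, `[[`, character(1), "contig"),
    vapply(models, `[[`, integer(1), "orf_start")
  )
  models[ord]
}

# design failure record -------------------------------------------------------

#' Typed design failure
#'
#' Returned (never raised) by the design operations when a gene cannot be
#' processed: `contig_end` (insufficient flank before a contig end),
#' `no_primer_in_window` (no acceptable inner-primer anchor in either the
#' 30 bp or 75 bp window) or `constraint_unsatisfiable` (window anchors
#' exist but no outer primer completes a flank amplicon in bounds).
#'
#' @param gene_id gene identifier.
#' @param reason one of `"contig_end"`, `"no_primer_in_window"`,
#'   `"constraint_unsatisfiable"`.
#' @return object of class `fd_design_failure`.
#' @export
design_failure <- function(gene_id, reason) {
  reason <- match.arg(reason, c("contig_end", "no_primer_in_window", "constraint_unsatisfiable"))
  structure(list(gene_id = gene_id, reason = reason), class = "fd_design_failure")
}

#' Test for a design failure
#' @param x any object.
#' @return `TRUE` if `x` is an `fd_design_failure`.
#' @export
is_design_failure <- function(x) inherits(x, "fd_design_failure")

#' @export
print.fd_design_failure <- function(x, ...) {
  cat(sprintf("<design failure> %s: %s\n", x$gene_id, x$reason))
  invisible(x)
}

#' Write a TSV failure report
#'
#' @param failures list of [design_failure()] objects.
#' @param path output TSV path (columns `gene_id`, `reason`).
#' @return `path`, invisibly.
#' @export
write_failure_report <- function(failures, path) {
  df <- data.frame(
    gene_id = vapply(failures, `[[`, character(1), "gene_id"),
    reason = vapply(failures, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# flank extraction ------------------------------------------------------------

# contig substring by 0-based half-open interval
.slice <- function(seq, start, end) substr(seq, start + 1L, end)

#' Extract homology flanks around a replaced interval
#'
#' The replaced interval is the annotated ORF, or the kinase-domain
#' sub-interval when `domain_only = TRUE`. Flanks abut the replaced interval
#' exactly, are reported in gene orientation (reverse complemented for minus
#' strand genes), and take length `min(max_flank, available sequence to the
#' contig end)`, failing with reason `"contig_end"` when less than
#' `min_flank` is available. Flanks may extend into neighbouring genes; the
#' caller sees the raw genomic sequence either way.
#'
#' @param gene an [gene_model()].
#' @param genome an `fd_genome`.
#' @param min_flank,max_flank flank length bounds in bp (defaults 600/1000).
#' @param domain_only replace only the kinase-domain interval.
#' @return an object of class `fd_flank_pair` with elements `five_prime` and
#'   `three_prime` (each `list(seq, start, end)` with genomic 0-based
#'   half-open intervals), `target` (the replaced interval), `gene_id`,
#'   `contig`, `strand`; or an [design_failure()].
#' @export
extract_flanks <- function(gene, genome, min_flank = 600L, max_flank = 1000L,
                           domain_only = FALSE) {
  stopifnot(inherits(gene, "fd_gene_model"), min_flank <= max_flank)
  if (!gene$contig %in% names(genome)) {
    fd_stop("fd_coordinate_error", sprintf("unknown contig %s", gene$contig))
  }
  if (domain_only && is.na(gene$domain_start)) {
    fd_stop("fd_precondition_error", sprintf(
      "gene %s has no kinase-domain annotation", gene$gene_id
    ))
  }
  cseq <- genome[[gene$contig]]
  clen <- nchar(cseq)
  s <- if (domain_only) gene$domain_start else gene$orf_start
  e <- if (domain_only) gene$domain_end else gene$orf_end
  avail_left <- s
  avail_right <- clen - e
  if (avail_left < min_flank || avail_right < min_flank) {
    return(design_failure(gene$gene_id, "contig_end"))
  }
  len_left <- min(max_flank, avail_left)
  len_right <- min(max_flank, avail_right)
  left <- list(seq = .slice(cseq, s - len_left, s), start = s - len_left, end = s)
  right <- list(seq = .slice(cseq, e, e + len_right), start = e, end = e + len_right)
  if (gene$strand == "+") {
    five <- left; three <- right
  } else {
    five <- list(seq = dna_revcomp(right$seq), start = right$start, end = right$end)
    three <- list(seq = dna_revcomp(left$seq), start = left$start, end = left$end)
  }
  structure(
    list(
      gene_id = gene$gene_id, contig = gene$contig, strand = gene$strand,
      five_prime = five, three_prime = three,
      target = list(start = s, end = e, seq = .slice(cseq, s, e)),
      domain_only = domain_only
    ),
    class = "fd_flank_pair"
  )
}
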