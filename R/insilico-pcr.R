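# insilico_pcr: primer binding-site search, PCR product prediction, null-locus
# construction, and diagnostic assay design with restriction fallback.

.primer_binding <- function(primer) {
  if (inherits(primer, "fd_primer")) primer$binding_seq else toupper(primer)
}

#' Find primer binding sites on a template
#'
#' Scans both strands for matches of the primer's binding portion (any 5'
#' tail is ignored) with at most `max_mismatch` mismatches; mismatches are
#' never tolerated in the 3 terminal bases at the primer 3' end. Intervals
#' are 0-based half-open on the template.
#'
#' @param template template DNA string.
#' @param primer an `fd_primer` or plain primer sequence.
#' @param max_mismatch maximum number of mismatches (default 0).
#' @param circular treat the template as circular.
#' @return data.frame with columns `start`, `end`, `strand` (`"+"` when the
#'   primer reads the top strand left to right), `mismatches`. Zero rows is
#'   a valid result.
#' @export
find_binding_sites <- function(template, primer, max_mismatch = 0L, circular = FALSE) {
  stopifnot(max_mismatch >= 0L)
  pat <- .primer_binding(primer)
  m <- nchar(pat)
  n <- nchar(template)
  subject_seq <- if (circular && n > 1L) paste0(template, substr(template, 1L, m - 1L)) else template
  subject <- Biostrings::DNAString(subject_seq)

  scan_one <- function(pattern, strand) {
    hits <- Biostrings::matchPattern(pattern, subject, max.mismatch = max_mismatch)
    starts <- BiocGenerics::start(hits)
    starts <- starts[starts <= n]
    if (!length(starts)) return(NULL)
    keep <- logical(length(starts))
    mism <- integer(length(starts))
    pat_codes <- utf8ToInt(pattern)
    for (i in seq_along(starts)) {
      obs <- utf8ToInt(substr(subject_seq, starts[i], starts[i] + m - 1L))
      d <- which(obs != pat_codes)
      mism[i] <- length(d)
      # the primer 3' terminus: rightmost matched base on "+", leftmost on "-"
      three_prime_zone <- if (strand == "+") (m - 2L):m else 1L:3L
      keep[i] <- !any(d %in% three_prime_zone)
    }
    if (!any(keep)) return(NULL)
    data.frame(
      start = starts[keep] - 1L, end = starts[keep] - 1L + m,
      strand = strand, mismatches = mism[keep], stringsAsFactors = FALSE
    )
  }
  out <- rbind(scan_one(pat, "+"), scan_one(dna_revcomp(pat), "-"))
  if (is.null(out)) {
    out <- data.frame(
      start = integer(0), end = integer(0),
      strand = character(0), mismatches = integer(0), stringsAsFactors = FALSE
    )
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Predict PCR products
#'
#' Reports every convergent forward/reverse site pair within `max_product`,
#' in both template orientations, sorted by product length. Product length
#' is the site-to-site span; primer tails are ignored.
#'
#' @param template template DNA string.
#' @param fwd,rev primers (`fd_primer` or sequence).
#' @param max_product maximum product length (bp).
#' @param max_mismatch maximum mismatches per site (default 0).
#' @param circular treat the template as circular.
#' @return data.frame of class `fd_pcr_products` with `fwd_start`,
#'   `fwd_end`, `rev_start`, `rev_end`, `length`, `sequence`.
#' @export
simulate_pcr <- function(template, fwd, rev, max_product = 10000L,
                         max_mismatch = 0L, circular = FALSE) {
  stopifnot(max_product > 0L)
  sf <- find_binding_sites(template, fwd, max_mismatch, circular)
  sr <- find_binding_sites(template, rev, max_mismatch, circular)
  n <- nchar(template)
  doubled <- paste0(template, template)
  res <- list()
  pair_up <- function(plus, minus) {
    if (nrow(plus) == 0L || nrow(minus) == 0L) return(NULL)
    grid <- expand.grid(i = seq_len(nrow(plus)), j = seq_len(nrow(minus)))
    out <- NULL
    for (k in seq_len(nrow(grid))) {
      p <- plus[grid$i[k], ]; q <- minus[grid$j[k], ]
      span_end <- q$end
      if (circular && span_end <= p$start) span_end <- span_end + n
      if (span_end <= p$start) next
      len <- span_end - p$start
      if (len < nchar(.primer_binding(fwd)) || len > max_product) next
      if (circular && len > n) next
      seq <- substr(doubled, p$start + 1L, span_end)
      out <- rbind(out, data.frame(
        fwd_start = p$start, fwd_end = p$end,
        rev_start = q$start, rev_end = q$end,
        length = len, sequence = seq, stringsAsFactors = FALSE
      ))
    }
    out
  }
  res[[1L]] <- pair_up(sf[sf$strand == "+", , drop = FALSE], sr[sr$strand == "-", , drop = FALSE])
  # swapped orientation: rev anneals the top strand, fwd the bottom strand
  swap <- pair_up(sr[sr$strand == "+", , drop = FALSE], sf[sf$strand == "-", , drop = FALSE])
  if (!is.null(swap) && nrow(swap)) {
    names(swap)[1:4] <- c("rev_start", "rev_end", "fwd_start", "fwd_end")
    res[[2L]] <- swap[, c("fwd_start", "fwd_end", "rev_start", "rev_end", "length", "sequence")]
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(
      fwd_start = integer(0), fwd_end = integer(0), rev_start = integer(0),
      rev_end = integer(0), length = integer(0), sequence = character(0),
      stringsAsFactors = FALSE
    )
  }
  out <- out[!duplicated(out[, c("fwd_start", "rev_start", "length")]), , drop = FALSE]
  out <- out[order(out$length, out$fwd_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fd_pcr_products", class(out))
  out
}

#' Replace the target interval by the marker in a genome
#'
#' Produces the null (deletion) locus: the replaced interval is substituted
#' by the marker cassette, in gene orientation (reverse complemented for
#' minus-strand genes). Residual vector tails are never integrated:
#' homologous recombination resolves within the flank homology. The
#' construct's flanks and target must match the genome exactly; applying the
#' edit twice therefore fails.
#'
#' @param genome an `fd_genome`.
#' @param gene the [gene_model()] the construct was designed for.
#' @param construct an `fd_deletion_construct` from
#'   [build_deletion_construct()] (carries target coordinates, marker and
#'   replaced-sequence provenance).
#' @return the edited `fd_genome`.
#' @export
build_null_locus <- function(genome, gene, construct) {
  stopifnot(inherits(construct, "fd_deletion_construct"))
  if (is.null(construct$target_start)) {
    fd_stop("fd_usage_error", "construct lacks target coordinates (use build_deletion_construct)")
  }
  ctg <- construct$contig
  if (!ctg %in% names(genome)) fd_stop("fd_coordinate_error", sprintf("unknown contig %s", ctg))
  cseq <- genome[[ctg]]
  s <- construct$target_start; e <- construct$target_end
  locus <- .slice(cseq, s, e)
  expected <- if (construct$strand == "-") dna_revcomp(construct$replaced_seq) else construct$replaced_seq
  if (!identical(locus, expected)) {
    fd_stop("fd_flank_mismatch_error", sprintf(
      "target locus of %s does not match the construct (already edited, or wrong genome)",
      construct$gene_id
    ))
  }
  # flank homology check: probe regions 100-140 bp from the target boundary,
  # guaranteed inside the homology arms (inner primer anchors float at most
  # 75 bp + one primer length around the codons, arms span >= min_flank)
  up <- .slice(cseq, max(0L, s - 140L), max(0L, s - 100L))
  dn <- .slice(cseq, min(nchar(cseq), e + 100L), min(nchar(cseq), e + 140L))
  probe_up <- if (construct$strand == "-") dna_revcomp(dn) else up
  probe_dn <- if (construct$strand == "-") dna_revcomp(up) else dn
  if (!grepl(probe_up, construct$sequence, fixed = TRUE) ||
      !grepl(probe_dn, construct$sequence, fixed = TRUE)) {
    fd_stop("fd_flank_mismatch_error", sprintf(
      "construct flanks of %s do not match the genome", construct$gene_id
    ))
  }
  marker_genomic <- if (construct$strand == "-") dna_revcomp(construct$marker_seq) else construct$marker_seq
  edited <- paste0(.slice(cseq, 0L, s), marker_genomic, .slice(cseq, e, nchar(cseq)))
  genome[[ctg]] <- edited
  genome
}

# restriction enzymes ---------------------------------------------------------

#' Packaged restriction enzyme table
#'
#' A fixed snapshot of 24 common enzymes with palindromic recognition sites
#' (mostly 6-cutters), used for the diagnostic digest fallback. No live
#' database dependency.
#'
#' @return data.frame with columns `name`, `recognition_site`.
#' @export
restriction_enzymes <- function() {
  path <- system.file("extdata", "restriction_enzymes.tsv", package = "fungidel")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Count recognition-site occurrences in a sequence
#'
#' Palindromic sites occur identically on both strands, so a single
#' top-strand scan suffices for the packaged table.
#'
#' @param seq DNA string.
#' @param site recognition site.
#' @return integer count.
#' @export
count_enzyme_sites <- function(seq, site) {
  Biostrings::countPattern(site, Biostrings::DNAString(seq))
}

#' Restriction fragment lengths from a linear template
#'
#' Cuts are placed at the start of each recognition site (gel-resolution
#' bookkeeping; enzyme-exact cut offsets within the site are not modeled).
#'
#' @param seq DNA string.
#' @param site recognition site.
#' @return integer vector of fragment lengths (the uncut length when the
#'   site is absent).
#' @export
digest_fragments <- function(seq, site) {
  hits <- .occurrences_one_strand(seq, site)
  n <- nchar(seq)
  if (!length(hits)) return(n)
  cuts <- sort(unique(hits - 1L))
  cuts <- cuts[cuts > 0L & cuts < n]
  if (!length(cuts)) return(n)
  diff(c(0L, cuts, n))
}

# diagnostic assay design -----------------------------------------------------

# enumerate/score an external diagnostic primer in a genomic window
# (gene-oriented working sequence `G`), 3' termini restricted to `p3_range`
.external_primer <- function(G, prof, p3_range, sense, params, boundary) {
  if (!length(p3_range)) return(NULL)
  cand <- .enumerate_candidates(prof, p3_range, sense = sense, params = params,
                                anchor_ref = boundary)
  if (is.null(cand)) return(NULL)
  cand[1L, , drop = FALSE]
}

#' Design a diagnostic PCR assay for one deletion
#'
#' Picks a primer pair situated strictly outside the targeting sequence
#' (the union of both homology flanks), within `ext_offset` bp beyond each
#' flank, predicts the wild-type and null product sizes, asserts the
#' allele-size identity `null_len - wt_len = marker_len - replaced_len`, and
#' when the size difference is below `min_gel_delta` reports every packaged
#' restriction enzyme that cuts within the marker of the null product but
#' never cuts the wild-type product.
#'
#' @param gene the [gene_model()].
#' @param genome the wild-type `fd_genome`.
#' @param construct the gene's `fd_deletion_construct`.
#' @param params an [design_params()].
#' @param require_discrimination when `TRUE` (default), failing to find any
#'   discriminating enzyme for a size-ambiguous locus is an error; with
#'   `FALSE` the plan is returned with an empty enzyme table (useful for
#'   genome-wide surveys where only the product sizes matter).
#' @return object of class `fd_diagnostic_plan` with elements `gene_id`,
#'   `fwd`, `rev`, `wt_len`, `null_len`, `size_discriminable`, `enzymes`
#'   (data.frame of enzyme name and comma-separated wt/null fragment
#'   lengths; zero rows when size alone discriminates).
#' @export
design_diagnostic <- function(gene, genome, construct, params = design_params(),
                              require_discrimination = TRUE) {
  fl <- extract_flanks(gene, genome, params$min_flank, params$max_flank,
                       domain_only = isTRUE(construct$target_start == gene$domain_start &&
                                              construct$target_end == gene$domain_end &&
                                              !is.na(gene$domain_start)))
  if (is_design_failure(fl)) {
    fd_stop("fd_diagnostic_failure", sprintf("flanks unavailable for %s", gene$gene_id))
  }
  cseq <- genome[[gene$contig]]
  clen <- nchar(cseq)
  # genomic span of the targeting sequence (both flanks + target)
  lo <- min(fl$five_prime$start, fl$three_prime$start)
  hi <- max(fl$five_prime$end, fl$three_prime$end)
  ext_lo <- max(0L, lo - params$ext_offset)
  ext_hi <- min(clen, hi + params$ext_offset)
  G <- .slice(cseq, ext_lo, ext_hi)
  if (gene$strand == "-") G <- dna_revcomp(G)
  prof <- .seq_profile(G)
  # 1-based positions on G of the upstream/downstream external segments
  n_up <- if (gene$strand == "+") lo - ext_lo else ext_hi - hi
  n_dn <- if (gene$strand == "+") ext_hi - hi else lo - ext_lo
  nG <- nchar(G)
  fwd_row <- .external_primer(
    G, prof, seq_len(max(0L, n_up)), sense = TRUE, params = params, boundary = n_up
  )
  rev_row <- .external_primer(
    G, prof, seq(nG - n_dn + 1L, length.out = max(0L, n_dn)), sense = FALSE,
    params = params, boundary = nG - n_dn + 1L
  )
  if (is.null(fwd_row) || is.null(rev_row)) {
    fd_stop("fd_diagnostic_failure", sprintf(
      "no external diagnostic primer designable for %s", gene$gene_id
    ))
  }
  to_genomic <- function(wstart, wend) {
    if (gene$strand == "+") c(ext_lo + wstart - 1L, ext_lo + wend)
    else c(ext_hi - wend, ext_hi - wstart + 1L)
  }
  mk <- function(row, role, sense) {
    g <- to_genomic(row$start, row$end)
    structure(
      list(
        role = role,
        binding_seq = if (sense) substr(G, row$start, row$end) else dna_revcomp(substr(G, row$start, row$end)),
        tail_seq = "",
        anchor = list(
          contig = gene$contig, start = g[1L], end = g[2L],
          strand = if (sense == (gene$strand == "+")) "+" else "-"
        ),
        tm = row$tm, gc = row$gc, length = row$length,
        w_start = row$start, w_end = row$end
      ),
      class = "fd_primer"
    )
  }
  fwd <- mk(fwd_row, "diag_f", TRUE)
  rev <- mk(rev_row, "diag_r", FALSE)

  max_prod <- (hi - lo) + 2L * params$ext_offset + construct$length
  wt <- simulate_pcr(cseq, fwd, rev, max_product = max_prod)
  null_genome <- build_null_locus(genome, gene, construct)
  null_seq <- null_genome[[gene$contig]]
  nl <- simulate_pcr(null_seq, fwd, rev, max_product = max_prod)
  if (nrow(wt) != 1L || nrow(nl) != 1L) {
    fd_stop("fd_diagnostic_failure", sprintf(
      "diagnostic primers for %s do not give a unique product (wt %d, null %d)",
      gene$gene_id, nrow(wt), nrow(nl)
    ))
  }
  wt_len <- wt$length[1L]
  null_len <- nl$length[1L]
  marker_len <- nchar(construct$marker_seq)
  replaced_len <- nchar(construct$replaced_seq)
  if (null_len - wt_len != marker_len - replaced_len) {
    fd_stop("fd_internal_error", sprintf(
      "allele-size identity violated for %s: %d != %d",
      gene$gene_id, null_len - wt_len, marker_len - replaced_len
    ))
  }
  size_disc <- abs(null_len - wt_len) >= params$min_gel_delta
  enz <- data.frame(
    name = character(0), wt_fragments = character(0), null_fragments = character(0),
    stringsAsFactors = FALSE
  )
  if (!size_disc) {
    marker_genomic <- if (gene$strand == "-") dna_revcomp(construct$marker_seq) else construct$marker_seq
    tab <- restriction_enzymes()
    for (i in seq_len(nrow(tab))) {
      site <- tab$recognition_site[i]
      if (count_enzyme_sites(wt$sequence[1L], site) > 0L) next
      if (count_enzyme_sites(marker_genomic, site) == 0L) next
      if (count_enzyme_sites(nl$sequence[1L], site) == 0L) next
      enz <- rbind(enz, data.frame(
        name = tab$name[i],
        wt_fragments = paste(digest_fragments(wt$sequence[1L], site), collapse = ","),
        null_fragments = paste(digest_fragments(nl$sequence[1L], site), collapse = ","),
        stringsAsFactors = FALSE
      ))
    }
    if (nrow(enz) == 0L && require_discrimination) {
      fd_stop("fd_diagnostic_failure", sprintf(
        "no packaged enzyme discriminates the %s alleles", gene$gene_id
      ))
    }
  }
  structure(
    list(
      gene_id = gene$gene_id, fwd = fwd, rev = rev,
      wt_len = wt_len, null_len = null_len,
      size_discriminable = size_disc, enzymes = enz
    ),
    class = "fd_diagnostic_plan"
  )
}

#' @export
print.fd_diagnostic_plan <- function(x, ...) {
  cat(sprintf(
    "<diagnostic plan %s> wt %d bp / null %d bp, %s\n",
    x$gene_id, x$wt_len, x$null_len,
    if (x$size_discriminable) "size-discriminable" else
      sprintf("digest fallback (%d enzyme(s))", nrow(x$enzymes))
  ))
  invisible(x)
}

#' Predicted diagnostic bands for a genotype
#'
#' Wild type yields the wild-type band only and a haploid null the null band
#' only; heterokaryons and diploids carry both alleles and yield both bands
#' (PCR alone cannot distinguish them; the distinction needs streak
#' stability, see [classify_transformant()]).
#'
#' @param plan an `fd_diagnostic_plan`.
#' @param genotype one of `"wt"`, `"null"`, `"heterokaryon"`, `"diploid"`.
#' @return sorted integer vector of band lengths.
#' @export
predict_genotype_bands <- function(plan, genotype) {
  stopifnot(inherits(plan, "fd_diagnostic_plan"))
  if (!is.character(genotype) || length(genotype) != 1L ||
      !genotype %in% c("wt", "null", "heterokaryon", "diploid")) {
    fd_stop("fd_usage_error", "genotype must be one of wt, null, heterokaryon, diploid")
  }
  switch(genotype,
    wt = plan$wt_len,
    null = plan$null_len,
    heterokaryon = ,
    diploid = sort(c(plan$wt_len, plan$null_len))
  )
}

#' Serialize a diagnostic plan to JSON
#' @param plan an `fd_diagnostic_plan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diagnostic_plan <- function(plan, path) {
  jsonlite::write_json(
    list(
      gene_id = plan$gene_id,
      fwd = list(seq = plan$fwd$binding_seq, contig = plan$fwd$anchor$contig,
                 start = plan$fwd$anchor$start, end = plan$fwd$anchor$end,
                 strand = plan$fwd$anchor$strand),
      rev = list(seq = plan$rev$binding_seq, contig = plan$rev$anchor$contig,
                 start = plan$rev$anchor$start, end = plan$rev$anchor$end,
                 strand = plan$rev$anchor$strand),
      wt_len = plan$wt_len, null_len = plan$null_len,
      size_discriminable = plan$size_discriminable,
      enzymes = plan$enzymes
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write band predictions for all genotype classes as TSV
#' @param plan an `fd_diagnostic_plan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_band_predictions <- function(plan, path) {
  genos <- c("wt", "null", "heterokaryon", "diploid")
  df <- data.frame(
    gene_id = plan$gene_id, genotype = genos,
    bands = vapply(genos, function(g) paste(predict_genotype_bands(plan, g), collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
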