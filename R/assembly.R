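# assembly_sim: yeast recombinational cloning into a gapped vector, the
# fusion-PCR alternative, and final linear construct amplification.

#' Circular vector backbone with a gap site
#'
#' The restriction "digestion" that linearizes the vector is modeled as a
#' pre-specified gap interval removed from the circle, exposing two ends
#' that recombine with the tailed outer flank amplicons.
#'
#' @param sequence circular vector DNA.
#' @param gap_start,gap_end 0-based half-open interval removed by digestion.
#' @param name vector name.
#' @return object of class `fd_vector_backbone`.
#' @export
vector_backbone <- function(sequence, gap_start, gap_end, name = "vector") {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  gap_start <- as.integer(gap_start); gap_end <- as.integer(gap_end)
  if (gap_start < 0L || gap_end > n || gap_start >= gap_end) {
    fd_stop("fd_coordinate_error", "gap interval outside vector sequence")
  }
  structure(
    list(
      name = name, sequence = sequence, length = n,
      gap_start = gap_start, gap_end = gap_end,
      # retained backbone, linearized at the gap: starts just after the gap,
      # ends just before it
      retained = paste0(
        substr(sequence, gap_end + 1L, n),
        substr(sequence, 1L, gap_start)
      )
    ),
    class = "fd_vector_backbone"
  )
}

#' Vector tails for the outer primers
#'
#' The 5f tail equals the terminal bases of the vector end upstream of the
#' gap; the 3r tail is the reverse complement of the initial bases of the
#' end downstream of the gap, so both tailed outer amplicon ends share
#' `tail_len` exact homology with the exposed vector ends.
#'
#' @param vector an [vector_backbone()].
#' @param tail_len tail length (nt).
#' @return `c(five = , three = )` character vector of tails.
#' @export
vector_tails <- function(vector, tail_len = 29L) {
  r <- vector$retained
  n <- nchar(r)
  if (n < 2L * tail_len) fd_stop("fd_spec_error", "vector ends shorter than the tail length")
  c(
    five = substr(r, n - tail_len + 1L, n),
    three = dna_revcomp(substr(r, 1L, tail_len))
  )
}

# longest exact suffix(a)/prefix(b) overlap, capped for efficiency
.affix_overlap <- function(a, b, cap = 200L) {
  kmax <- min(nchar(a), nchar(b), cap)
  na <- nchar(a)
  for (k in seq(kmax, 1L)) {
    if (substr(a, na - k + 1L, na) == substr(b, 1L, k)) return(k)
  }
  0L
}

.assembly_error <- function(msg) fd_stop("fd_assembly_error", msg)

# ordered overlap assembly; frags named; returns list(sequence, junctions)
.assemble_ordered <- function(frags, min_homology, circular = FALSE) {
  nms <- names(frags)
  n <- length(frags)
  pairs <- if (circular) cbind(seq_len(n), c(seq_len(n)[-1L], 1L)) else cbind(seq_len(n - 1L), seq_len(n)[-1L])
  overlaps <- integer(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    ov <- .affix_overlap(frags[[a]], frags[[b]])
    if (ov < min_homology) {
      .assembly_error(sprintf(
        "%s-%s junction: %d bp terminal homology < required %d bp",
        nms[a], nms[b], ov, min_homology
      ))
    }
    # ambiguity: the junction homology must identify a unique partner
    for (j in seq_len(n)) {
      if (j == b || j == a) next
      if (.affix_overlap(frags[[a]], frags[[j]]) >= min_homology) {
        .assembly_error(sprintf(
          "ambiguous: %s end matches both %s and %s", nms[a], nms[b], nms[j]
        ))
      }
    }
    overlaps[i] <- ov
  }
  seqs <- frags
  out <- seqs[[1L]]
  for (i in seq_len(n - 1L)) {
    out <- paste0(out, substring(seqs[[i + 1L]], overlaps[i] + 1L))
  }
  if (circular) {
    k <- overlaps[n]
    out <- substr(out, 1L, nchar(out) - k) # wrap-around overlap collapsed once
  }
  junctions <- data.frame(
    from = nms[pairs[, 1L]], to = nms[pairs[, 2L]], homology_bp = overlaps,
    stringsAsFactors = FALSE
  )
  list(sequence = out, junctions = junctions)
}

# orient marker so its left terminus overlaps the 5' amplicon end
.orient_marker <- function(flank5_amp, marker_seq, min_homology) {
  if (.affix_overlap(flank5_amp, marker_seq) >= min_homology) return(marker_seq)
  rc <- dna_revcomp(marker_seq)
  if (.affix_overlap(flank5_amp, rc) >= min_homology) return(rc)
  marker_seq # leave as-is; junction check will report the failure
}

#' Simulate yeast recombinational cloning (gap repair)
#'
#' Joins the gapped vector, the two tailed flank amplicons, and the marker
#' cassette through their exact terminal homologies, enforcing the assembly
#' order vector-5'flank-marker-3'flank-vector. Homology detection is exact
#' terminal matching; each junction must share at least `min_homology`
#' identical bases, and a fragment end whose homology matches more than one
#' partner aborts with an "ambiguous" error. Marker orientation is
#' normalized from the junction homologies.
#'
#' @param flank5_amp,flank3_amp tailed flank amplicon sequences (from
#'   [flank_amplicons()] after [attach_tails()]).
#' @param marker a [marker_cassette()] or plain marker sequence.
#' @param vector an [vector_backbone()].
#' @param min_homology minimum exact junction homology (bp, default 20).
#' @return list of class `fd_plasmid` with `sequence` (the circular plasmid,
#'   written from the retained-backbone start) and `junctions` (data frame
#'   of per-junction homology lengths).
#' @export
simulate_recombination <- function(flank5_amp, flank3_amp, marker, vector,
                                   min_homology = 20L) {
  marker_seq <- if (inherits(marker, "fd_marker_cassette")) marker$sequence else toupper(marker)
  marker_seq <- .orient_marker(flank5_amp, marker_seq, min_homology)
  asm <- .assemble_ordered(
    list(
      vector = vector$retained, flank5 = flank5_amp,
      marker = marker_seq, flank3 = flank3_amp
    ),
    min_homology = min_homology, circular = TRUE
  )
  structure(
    list(sequence = asm$sequence, junctions = asm$junctions, vector_name = vector$name),
    class = "fd_plasmid"
  )
}

.new_construct <- function(gene_id, sequence, route, marker_seq, replaced_seq,
                           plasmid_seq = NULL) {
  structure(
    list(
      gene_id = gene_id, sequence = sequence, length = nchar(sequence),
      route = route, marker_seq = marker_seq, replaced_seq = replaced_seq,
      plasmid_seq = plasmid_seq
    ),
    class = "fd_deletion_construct"
  )
}

#' @export
print.fd_deletion_construct <- function(x, ...) {
  cat(sprintf(
    "<deletion construct %s> %d bp via %s\n", x$gene_id, x$length, x$route
  ))
  invisible(x)
}

#' Simulate fusion-PCR construct assembly
#'
#' Fuses the two tailed flank amplicons to the marker through their shared
#' tail overlaps and amplifies with the outer primers, yielding a linear
#' construct whose flank-marker-flank core is identical to the
#' recombination route's amplified product.
#'
#' @inheritParams simulate_recombination
#' @param outer_primers `list(p5f, p3r)` of the (tailed) outer primers.
#' @param gene_id gene identifier recorded on the construct.
#' @param replaced_seq the replaced genomic interval sequence (provenance;
#'   optional).
#' @return an `fd_deletion_construct` with `route = "fusion_pcr"`.
#' @export
simulate_fusion_pcr <- function(flank5_amp, flank3_amp, marker, outer_primers,
                                min_homology = 20L, gene_id = NA_character_,
                                replaced_seq = "") {
  marker_seq <- if (inherits(marker, "fd_marker_cassette")) marker$sequence else toupper(marker)
  marker_seq <- .orient_marker(flank5_amp, marker_seq, min_homology)
  asm <- .assemble_ordered(
    list(flank5 = flank5_amp, marker = marker_seq, flank3 = flank3_amp),
    min_homology = min_homology, circular = FALSE
  )
  fused <- asm$sequence
  p5f <- outer_primers[[1L]]; p3r <- outer_primers[[2L]]
  s5 <- primer_full_seq(p5f)
  s3 <- primer_full_seq(p3r)
  # convergent orientation: 5f reads the top strand, 3r the bottom strand
  i5 <- .occurrences_one_strand(fused, s5)
  i3 <- .occurrences_one_strand(fused, dna_revcomp(s3))
  if (length(i5) != 1L || length(i3) != 1L || i3 + nchar(s3) - 1L <= i5) {
    .assembly_error("outer primers do not define one convergent amplicon on the fused product")
  }
  product <- substr(fused, i5, i3 + nchar(s3) - 1L)
  .new_construct(gene_id, product, "fusion_pcr", marker_seq, replaced_seq)
}

# 1-based start positions of exact matches of pattern on the given strand
.occurrences_one_strand <- function(subject, pattern) {
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject))
  BiocGenerics::start(m)
}

#' Amplify the final linear construct from an assembled plasmid
#'
#' PCR with the original tailed outer primers (5f/3r) on the circular
#' plasmid. Both primers must bind exactly once, convergently; the product
#' spans 5f through 3r and retains the residual vector tails at its outer
#' ends (they are physically present after PCR with tailed primers).
#'
#' @param plasmid an `fd_plasmid` (or circular DNA string).
#' @param p5f,p3r the tailed outer primers of the design.
#' @param gene_id,marker_seq,replaced_seq provenance recorded on the
#'   construct (optional).
#' @return an `fd_deletion_construct` with `route = "recombination"`.
#' @export
amplify_final_construct <- function(plasmid, p5f, p3r, gene_id = NA_character_,
                                    marker_seq = "", replaced_seq = "") {
  pl <- if (inherits(plasmid, "fd_plasmid")) plasmid$sequence else toupper(plasmid)
  n <- nchar(pl)
  s5 <- primer_full_seq(p5f)
  s3rc <- dna_revcomp(primer_full_seq(p3r))
  doubled <- paste0(pl, pl)
  hits5 <- .occurrences_one_strand(doubled, s5)
  hits3 <- .occurrences_one_strand(doubled, s3rc)
  # also reject primers binding the other strand as well
  extra5 <- .occurrences_one_strand(doubled, dna_revcomp(s5))
  extra3 <- .occurrences_one_strand(doubled, primer_full_seq(p3r))
  hits5 <- hits5[hits5 <= n]
  hits3 <- hits3[hits3 <= n]
  n_sites5 <- length(hits5) + length(extra5[extra5 <= n])
  n_sites3 <- length(hits3) + length(extra3[extra3 <= n])
  if (n_sites5 != 1L || n_sites3 != 1L) {
    fd_stop("fd_amplification_error", sprintf(
      "outer primers must bind the plasmid exactly once each (5f: %d, 3r: %d sites)",
      n_sites5, n_sites3
    ))
  }
  i5 <- hits5[1L]
  i3 <- hits3[1L]
  end3 <- i3 + nchar(s3rc) - 1L
  if (end3 <= i5) end3 <- end3 + n # wrap around the circle
  if (end3 - i5 + 1L > n) {
    fd_stop("fd_amplification_error", "primer sites do not define a convergent product")
  }
  product <- substr(doubled, i5, end3)
  .new_construct(gene_id, product, "recombination", marker_seq, replaced_seq,
                 plasmid_seq = pl)
}

#' Build a deletion construct end to end
#'
#' Convenience pipeline: takes a tailed primer set, assembles via the
#' requested route and returns the final linear construct with full
#' provenance (marker and replaced-interval sequences) needed by
#' [build_null_locus()] and [design_diagnostic()].
#'
#' @param pset a tailed `fd_primer_set`.
#' @param marker a [marker_cassette()].
#' @param vector an [vector_backbone()] (required for the recombination
#'   route).
#' @param route `"recombination"` or `"fusion_pcr"`.
#' @param min_homology minimum junction homology (bp).
#' @return an `fd_deletion_construct`.
#' @export
build_deletion_construct <- function(pset, marker, vector = NULL,
                                     route = c("recombination", "fusion_pcr"),
                                     min_homology = 20L) {
  route <- match.arg(route)
  if (!isTRUE(pset$tailed)) {
    fd_stop("fd_usage_error", "primer set must be tailed (see attach_tails)")
  }
  amps <- flank_amplicons(pset)
  replaced_seq <- substr(pset$W, pset$b5 + 1L, pset$b3)
  if (route == "recombination") {
    if (is.null(vector)) fd_stop("fd_usage_error", "recombination route requires a vector")
    pl <- simulate_recombination(amps$five, amps$three, marker, vector, min_homology)
    con <- amplify_final_construct(
      pl, pset$primers$`5f`, pset$primers$`3r`,
      gene_id = pset$gene_id, marker_seq = marker$sequence, replaced_seq = replaced_seq
    )
  } else {
    con <- simulate_fusion_pcr(
      amps$five, amps$three, marker,
      list(pset$primers$`5f`, pset$primers$`3r`),
      min_homology = min_homology, gene_id = pset$gene_id, replaced_seq = replaced_seq
    )
  }
  con$window_used <- pset$window_used
  con$strand <- pset$flanks$strand
  con$contig <- pset$flanks$contig
  con$target_start <- pset$flanks$target$start
  con$target_end <- pset$flanks$target$end
  con
}

#' Write constructs as multi-record FASTA
#'
#' @param constructs list of `fd_deletion_construct`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_construct_fasta <- function(constructs, path) {
  seqs <- vapply(constructs, `[[`, character(1), "sequence")
  names(seqs) <- vapply(constructs, `[[`, character(1), "gene_id")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Write a construct as a GenBank-style flat file
#'
#' Minimal flat file with LOCUS/FEATURES/ORIGIN blocks annotating the 5'
#' flank, marker and 3' flank intervals (located via the construct's marker
#' provenance).
#'
#' @param construct an `fd_deletion_construct` built with marker provenance.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_construct_genbank <- function(construct, path) {
  seq <- construct$sequence
  n <- nchar(seq)
  mpos <- if (nzchar(construct$marker_seq)) {
    .occurrences_one_strand(seq, construct$marker_seq)
  } else integer(0)
  lines <- c(
    sprintf("LOCUS       %s %d bp DNA linear", construct$gene_id, n),
    sprintf("DEFINITION  deletion construct (%s route).", construct$route),
    "FEATURES             Location/Qualifiers"
  )
  if (length(mpos) == 1L) {
    mlen <- nchar(construct$marker_seq)
    lines <- c(
      lines,
      sprintf("     misc_feature    1..%d", mpos - 1L),
      "                     /label=\"flank5\"",
      sprintf("     misc_feature    %d..%d", mpos, mpos + mlen - 1L),
      "                     /label=\"marker\"",
      sprintf("     misc_feature    %d..%d", mpos + mlen, n),
      "                     /label=\"flank3\""
    )
  }
  lines <- c(lines, "ORIGIN")
  for (i in seq(1L, n, by = 60L)) {
    block <- substr(seq, i, min(i + 59L, n))
    chunks <- substring(block, seq(1L, nchar(block), 10L),
                        pmin(seq(10L, nchar(block) + 9L, 10L), nchar(block)))
    lines <- c(lines, sprintf("%9d %s", i, paste(tolower(chunks), collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' Write an assembly log as JSON
#'
#' @param plasmid an `fd_plasmid` from [simulate_recombination()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_assembly_log <- function(plasmid, path) {
  jsonlite::write_json(
    list(
      vector = plasmid$vector_name,
      plasmid_length = nchar(plasmid$sequence),
      junctions = plasmid$junctions
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
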