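# cassette_design: constrained 5f/5r/3f/3r quartet design with positional
# windows around the start/stop codons, plus marker/vector tail attachment.

#' Design parameters for primer and construct design
#'
#' Defaults follow common practice for gap-repair knockout pipelines: primer
#' length 18-28 nt, nearest-neighbor Tm 55-65 C at 50 mM monovalent salt,
#' GC 30-70%, no 3'-terminal homopolymer run over 4, inner-primer anchor
#' windows of 30 bp (primary) and 75 bp (fallback) around the start/stop
#' codons, 0.6-1 kb flanks, and 29 nt assembly tails.
#'
#' @param len_min,len_max primer binding-portion length bounds (nt).
#' @param tm_min,tm_max melting temperature bounds (degrees C).
#' @param gc_min,gc_max GC-fraction bounds.
#' @param max_homopolymer_3p maximum single-base run length at the 3' end.
#' @param windows anchor windows (bp) tried in order for the inner primers.
#' @param min_flank,max_flank homology flank length bounds (bp).
#' @param tail_len assembly tail length (nt).
#' @param min_homology minimum exact junction homology for assembly (bp).
#' @param min_gel_delta minimum wild-type/null size difference resolvable on
#'   a gel (bp); below it the diagnostic plan must list restriction enzymes.
#' @param ext_offset how far beyond each flank the diagnostic primers may
#'   sit (bp).
#' @param context_bp extra genomic context used for the local primer
#'   uniqueness check (bp each side).
#' @param conc_nM,na_mM Tm model concentrations (see [dna_tm()]).
#' @return a list of class `fd_design_params`.
#' @export
design_params <- function(len_min = 18L, len_max = 28L,
                          tm_min = 55, tm_max = 65,
                          gc_min = 0.30, gc_max = 0.70,
                          max_homopolymer_3p = 4L,
                          windows = c(30L, 75L),
                          min_flank = 600L, max_flank = 1000L,
                          tail_len = 29L, min_homology = 20L,
                          min_gel_delta = 150L, ext_offset = 300L,
                          context_bp = 1000L,
                          conc_nM = 50, na_mM = 50) {
  stopifnot(
    len_min <= len_max, tm_min <= tm_max, gc_min <= gc_max,
    min_flank <= max_flank, all(windows > 0L)
  )
  structure(
    list(
      len_min = as.integer(len_min), len_max = as.integer(len_max),
      tm_min = tm_min, tm_max = tm_max, gc_min = gc_min, gc_max = gc_max,
      max_homopolymer_3p = as.integer(max_homopolymer_3p),
      windows = as.integer(windows),
      min_flank = as.integer(min_flank), max_flank = as.integer(max_flank),
      tail_len = as.integer(tail_len), min_homology = as.integer(min_homology),
      min_gel_delta = as.integer(min_gel_delta), ext_offset = as.integer(ext_offset),
      context_bp = as.integer(context_bp), conc_nM = conc_nM, na_mM = na_mM
    ),
    class = "fd_design_params"
  )
}

#' Read design parameters from a YAML config file
#'
#' Unknown keys are rejected; missing keys take the [design_params()]
#' defaults. Requires the `yaml` package.
#'
#' @param path YAML file path.
#' @return an `fd_design_params`.
#' @export
design_params_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    fd_stop("fd_usage_error", "the 'yaml' package is required to read YAML configs")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(design_params))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    fd_stop("fd_format_error", sprintf("unknown design parameter(s): %s", paste(bad, collapse = ", ")))
  }
  do.call(design_params, vals)
}

# marker cassette --------------------------------------------------------------

#' Selectable marker cassette
#'
#' Wraps a marker sequence (the default fixture emulates the 1732 bp
#' pyrG-Af cassette used for Aspergillus gene replacement) and derives the
#' two tails inner primers must carry so that tailed flank amplicons share
#' `tail_len` exact terminal homology with the cassette ends: the left tail
#' is the reverse complement of the cassette's left terminus (carried by
#' primer 5r), the right tail is the cassette's right terminus itself
#' (carried by primer 3f).
#'
#' @param sequence marker DNA sequence.
#' @param name marker name.
#' @param tail_len tail length in nt.
#' @return object of class `fd_marker_cassette`.
#' @export
marker_cassette <- function(sequence, name = "marker", tail_len = 29L) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 2L * tail_len) {
    fd_stop("fd_spec_error", "marker shorter than twice the tail length")
  }
  structure(
    list(
      name = name, sequence = sequence, length = n, tail_len = as.integer(tail_len),
      left_tail = dna_revcomp(substr(sequence, 1L, tail_len)),
      right_tail = substr(sequence, n - tail_len + 1L, n)
    ),
    class = "fd_marker_cassette"
  )
}

# candidate machinery ----------------------------------------------------------

# Enumerate scored primer candidates on a profiled working sequence.
# starts3p: allowed 1-based positions of the primer 3' terminus.
# sense: TRUE for primers reading left-to-right on the working sequence
# (3' terminus is the rightmost binding base), FALSE for antisense primers
# (3' terminus is the leftmost binding base).
.enumerate_candidates <- function(prof, starts3p, sense, params, anchor_ref = NULL) {
  lens <- seq(params$len_min, params$len_max)
  grid <- expand.grid(p3 = starts3p, len = lens)
  if (sense) {
    ends <- grid$p3
    starts <- grid$p3 - grid$len + 1L
  } else {
    starts <- grid$p3
    ends <- grid$p3 + grid$len - 1L
  }
  keep <- starts >= 1L & ends <= prof$n
  if (!any(keep)) return(NULL)
  starts <- starts[keep]; ends <- ends[keep]
  cand <- .profile_eval(prof, starts, ends, if (sense) "right" else "left",
                        conc_nM = params$conc_nM, na_mM = params$na_mM)
  cand$p3 <- if (sense) cand$end else cand$start
  ok <- cand$n_count == 0L &
    cand$tm >= params$tm_min & cand$tm <= params$tm_max &
    cand$gc >= params$gc_min & cand$gc <= params$gc_max &
    cand$run3 <= params$max_homopolymer_3p
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  cand$anchor_dist <- if (is.null(anchor_ref)) 0L else abs(cand$p3 - anchor_ref)
  cand[order(abs(cand$tm - 60), cand$anchor_dist, cand$start), , drop = FALSE]
}

# count exact occurrences of s (either strand) in context
.occurrences <- function(context_dna, s) {
  Biostrings::countPattern(s, context_dna) +
    Biostrings::countPattern(dna_revcomp(s), context_dna)
}

# working design frame: flanks + replaced interval in gene orientation,
# with coordinate mapping back to the contig
.design_frame <- function(gene, genome, params, domain_only) {
  fl <- extract_flanks(gene, genome, params$min_flank, params$max_flank, domain_only)
  if (is_design_failure(fl)) return(fl)
  target_go <- if (gene$strand == "+") fl$target$seq else dna_revcomp(fl$target$seq)
  W <- paste0(fl$five_prime$seq, target_go, fl$three_prime$seq)
  b5 <- nchar(fl$five_prime$seq)           # 0-based index of replaced start in W
  b3 <- b5 + nchar(target_go)              # 0-based index just past replaced end
  cseq <- genome[[gene$contig]]
  clen <- nchar(cseq)
  if (gene$strand == "+") {
    gstart <- fl$five_prime$start           # genomic 0-based of W position 1
    ctx_lo <- max(0L, gstart - params$context_bp)
    ctx_hi <- min(clen, fl$three_prime$end + params$context_bp)
    context <- .slice(cseq, ctx_lo, ctx_hi)
  } else {
    gend <- fl$five_prime$end               # genomic end; W pos 1 maps to gend-1
    ctx_lo <- max(0L, fl$three_prime$start - params$context_bp)
    ctx_hi <- min(clen, gend + params$context_bp)
    context <- dna_revcomp(.slice(cseq, ctx_lo, ctx_hi))
  }
  list(
    flanks = fl, W = W, prof = .seq_profile(W), b5 = b5, b3 = b3,
    context_dna = Biostrings::DNAString(context),
    to_genomic = function(wstart, wend) { # W 1-based inclusive -> genomic 0-based half-open
      if (gene$strand == "+") {
        g0 <- fl$five_prime$start
        c(g0 + wstart - 1L, g0 + wend)
      } else {
        gend <- fl$five_prime$end
        c(gend - wend, gend - wstart + 1L)
      }
    }
  )
}

.make_primer <- function(role, frame, gene, row, sense) {
  bind_top <- substr(frame$W, row$start, row$end)
  binding <- if (sense) bind_top else dna_revcomp(bind_top)
  g <- frame$to_genomic(row$start, row$end)
  sense_strand <- gene$strand
  anti_strand <- if (gene$strand == "+") "-" else "+"
  structure(
    list(
      role = role, binding_seq = binding, tail_seq = "",
      anchor = list(
        contig = gene$contig, start = g[1L], end = g[2L],
        strand = if (sense) sense_strand else anti_strand
      ),
      tm = row$tm, gc = row$gc, length = row$length,
      w_start = row$start, w_end = row$end
    ),
    class = "fd_primer"
  )
}

#' @export
print.fd_primer <- function(x, ...) {
  cat(sprintf(
    "<primer %s> %s%s (%d nt, Tm %.1f, GC %.2f) %s:[%d,%d)%s\n",
    x$role, if (nzchar(x$tail_seq)) paste0(x$tail_seq, "+") else "", x$binding_seq,
    x$length, x$tm, x$gc, x$anchor$contig, x$anchor$start, x$anchor$end, x$anchor$strand
  ))
  invisible(x)
}

#' Full primer sequence (tail + binding portion)
#' @param primer an `fd_primer`.
#' @return character scalar.
#' @export
primer_full_seq <- function(primer) paste0(primer$tail_seq, primer$binding_seq)

# pick (inner, outer) primer pair for one flank side.
# inner_cands: window-constrained candidates, already score-sorted.
# outer side: sense outer primer for the 5' side (role 5f), antisense for 3'.
.resolve_side <- function(side, frame, gene, params, inner_cands) {
  prof <- frame$prof
  if (side == "five") {
    # outer 5f: sense, binding within [1, b5]
    p3_range <- seq(params$len_min, frame$b5)
    outer_all <- .enumerate_candidates(prof, p3_range, sense = TRUE, params = params)
  } else {
    # outer 3r: antisense, binding within (b3, n]
    p3_range <- seq(frame$b3 + 1L, prof$n - params$len_min + 1L)
    outer_all <- .enumerate_candidates(prof, p3_range, sense = FALSE, params = params)
  }
  if (is.null(outer_all)) return(NULL)
  for (i in seq_len(nrow(inner_cands))) {
    inner <- inner_cands[i, ]
    if (side == "five") {
      # amplicon [a_outer_start, inner$end]; length in [min_flank, max_flank]
      amp_right <- inner$end
      ok <- outer_all$start >= amp_right - params$max_flank + 1L &
        outer_all$start <= amp_right - params$min_flank + 1L &
        outer_all$end < inner$start # primers must not overlap
      amp_len <- amp_right - outer_all$start + 1L
    } else {
      amp_left <- inner$start
      ok <- outer_all$end <= amp_left + params$max_flank - 1L &
        outer_all$end >= amp_left + params$min_flank - 1L &
        outer_all$start > inner$end
      amp_len <- outer_all$end - amp_left + 1L
    }
    outer <- outer_all[ok, , drop = FALSE]
    if (nrow(outer) == 0L) next
    # prefer Tm closeness, then longer homology arm, then leftmost
    outer <- outer[order(abs(outer$tm - 60), -amp_len[ok], outer$start), , drop = FALSE]
    inner_seq <- substr(frame$W, inner$start, inner$end)
    if (.occurrences(frame$context_dna, inner_seq) != 1L) next
    for (j in seq_len(nrow(outer))) {
      outer_seq <- substr(frame$W, outer$start[j], outer$end[j])
      if (.occurrences(frame$context_dna, outer_seq) == 1L) {
        return(list(inner = inner, outer = outer[j, ]))
      }
    }
  }
  NULL
}

.design_core <- function(gene, genome, params, domain_only) {
  frame <- .design_frame(gene, genome, params, domain_only)
  if (is_design_failure(frame)) return(frame)
  prof <- frame$prof
  B5 <- frame$b5 + 1L       # 1-based position of first replaced base
  B3e <- frame$b3           # 1-based position of last replaced base
  saw_inner <- FALSE
  for (w in params$windows) {
    # 5r: antisense inner primer, 3' terminus within w of the start codon
    r5 <- .enumerate_candidates(
      prof, seq(max(1L, B5 - w), min(prof$n, B5 + w)),
      sense = FALSE, params = params, anchor_ref = B5
    )
    # 3f: sense inner primer, 3' terminus within w of the stop codon
    f3 <- .enumerate_candidates(
      prof, seq(max(1L, B3e - w), min(prof$n, B3e + w)),
      sense = TRUE, params = params, anchor_ref = B3e
    )
    if (is.null(r5) || is.null(f3)) next
    saw_inner <- TRUE
    five <- .resolve_side("five", frame, gene, params, r5)
    if (is.null(five)) next
    three <- .resolve_side("three", frame, gene, params, f3)
    if (is.null(three)) next
    primers <- list(
      `5f` = .make_primer("5f", frame, gene, five$outer, sense = TRUE),
      `5r` = .make_primer("5r", frame, gene, five$inner, sense = FALSE),
      `3f` = .make_primer("3f", frame, gene, three$inner, sense = TRUE),
      `3r` = .make_primer("3r", frame, gene, three$outer, sense = FALSE)
    )
    return(structure(
      list(
        gene_id = gene$gene_id, primers = primers, window_used = w,
        flanks = frame$flanks, params = params, tailed = FALSE,
        W = frame$W, b5 = frame$b5, b3 = frame$b3,
        domain_only = domain_only
      ),
      class = "fd_primer_set"
    ))
  }
  design_failure(
    gene$gene_id,
    if (saw_inner) "constraint_unsatisfiable" else "no_primer_in_window"
  )
}

#' Design the 5f/5r/3f/3r deletion primer quartet
#'
#' Searches anchor windows in order (30 bp, then the 75 bp fallback) for
#' inner primers (5r/3f) whose 3' termini fall within the window of the
#' start/stop codon, then completes each side with an outer primer (5f/3r)
#' giving a flank amplicon within `[min_flank, max_flank]`. Candidates are
#' scored by `|Tm - 60|`, then anchor distance to the codon, then leftmost
#' coordinate; the search is fully deterministic. Returned primers carry no
#' tails (see [attach_tails()]).
#'
#' @param gene an [gene_model()].
#' @param genome an `fd_genome`.
#' @param params an [design_params()].
#' @return an `fd_primer_set`, or an [design_failure()] with the most
#'   specific reason (`contig_end`, `no_primer_in_window`,
#'   `constraint_unsatisfiable`). Never raises for design infeasibility.
#' @export
design_primer_set <- function(gene, genome, params = design_params()) {
  .design_core(gene, genome, params, domain_only = FALSE)
}

#' Design a kinase-domain-only deletion primer quartet
#'
#' Identical to [design_primer_set()] but the replaced interval is the
#' annotated kinase-domain sub-interval and the anchor windows are taken
#' around the domain boundaries. Used for genes too large for efficient
#' whole-ORF replacement.
#'
#' @inheritParams design_primer_set
#' @return an `fd_primer_set` or [design_failure()].
#' @export
design_domain_deletion <- function(gene, genome, params = design_params()) {
  if (is.na(gene$domain_start)) {
    fd_stop("fd_precondition_error", sprintf(
      "gene %s has no kinase-domain annotation", gene$gene_id
    ))
  }
  .design_core(gene, genome, params, domain_only = TRUE)
}

#' @export
print.fd_primer_set <- function(x, ...) {
  cat(sprintf(
    "<primer set %s> window %d bp, %s%s\n",
    x$gene_id, x$window_used,
    if (x$tailed) "tailed" else "untailed",
    if (isTRUE(x$domain_only)) ", domain-only" else ""
  ))
  for (p in x$primers) print(p)
  invisible(x)
}

#' Attach marker and vector tails to a primer quartet
#'
#' Inner primers gain marker-complementary tails (5r the marker left tail,
#' 3f the marker right tail); outer primers gain the vector tails (5f the
#' upstream vector end, 3r the downstream vector end). Binding portions are
#' unchanged.
#'
#' @param pset an untailed `fd_primer_set`.
#' @param marker a [marker_cassette()].
#' @param vector_tails length-2 character vector `c(five, three)` of vector
#'   tails, e.g. from [vector_tails()]. Zero-length tails are permitted.
#' @return the tailed `fd_primer_set`.
#' @export
attach_tails <- function(pset, marker, vector_tails) {
  stopifnot(inherits(pset, "fd_primer_set"), inherits(marker, "fd_marker_cassette"))
  if (isTRUE(pset$tailed)) {
    fd_stop("fd_usage_error", "primer set is already tailed")
  }
  stopifnot(length(vector_tails) == 2L)
  pset$primers$`5r`$tail_seq <- marker$left_tail
  pset$primers$`3f`$tail_seq <- marker$right_tail
  pset$primers$`5f`$tail_seq <- toupper(vector_tails[[1L]])
  pset$primers$`3r`$tail_seq <- toupper(vector_tails[[2L]])
  pset$tailed <- TRUE
  pset$marker_name <- marker$name
  pset
}

#' Flank amplicon sequences implied by a primer set
#'
#' The 5' flank amplicon runs from the 5f primer 5' end to the 5r primer
#' site, the 3' amplicon from 3f to 3r, each with any primer tails at the
#' ends (tails are incorporated into PCR products).
#'
#' @param pset an `fd_primer_set` (tailed or not).
#' @return `list(five = , three = )` of amplicon sequences in gene
#'   orientation.
#' @export
flank_amplicons <- function(pset) {
  p <- pset$primers
  five_core <- substr(pset$W, p$`5f`$w_start, p$`5r`$w_end)
  three_core <- substr(pset$W, p$`3f`$w_start, p$`3r`$w_end)
  list(
    five = paste0(p$`5f`$tail_seq, five_core, dna_revcomp(p$`5r`$tail_seq)),
    three = paste0(p$`3f`$tail_seq, three_core, dna_revcomp(p$`3r`$tail_seq))
  )
}

#' Write a primer report TSV
#'
#' One row per primer with full/binding/tail sequences, genomic anchor,
#' thermodynamics and the window used.
#'
#' @param psets list of `fd_primer_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_primer_report <- function(psets, path) {
  rows <- do.call(rbind, lapply(psets, function(ps) {
    do.call(rbind, lapply(ps$primers, function(p) {
      data.frame(
        gene_id = ps$gene_id, role = p$role,
        full_seq = primer_full_seq(p), binding_seq = p$binding_seq,
        tail_seq = p$tail_seq, anchor_contig = p$anchor$contig,
        anchor_start = p$anchor$start, anchor_end = p$anchor$end,
        strand = p$anchor$strand, tm = round(p$tm, 2), gc = round(p$gc, 3),
        window_used = ps$window_used, stringsAsFactors = FALSE
      )
    }))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
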