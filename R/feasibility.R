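# Naive enumerative feasibility classifier. This is deliberately a separate,
# brute-force code path from design_primer_set()'s vectorized search: the
# synthetic-data generator uses it to fill the truth table, so design outcomes
# are always checked against an independent enumeration.

# single-candidate validity under the design constraints (plain string ops)
.naive_ok <- function(seq3p, params, threeprime) {
  L <- nchar(seq3p)
  if (L < params$len_min || L > params$len_max) return(FALSE)
  if (grepl("N", seq3p, fixed = TRUE)) return(FALSE)
  gc <- dna_gc(seq3p)
  if (gc < params$gc_min || gc > params$gc_max) return(FALSE)
  tm <- dna_tm(seq3p, conc_nM = params$conc_nM, na_mM = params$na_mM)
  if (is.na(tm) || tm < params$tm_min || tm > params$tm_max) return(FALSE)
  end3 <- if (threeprime == "right") substr(seq3p, L - params$max_homopolymer_3p, L) else
    substr(seq3p, 1L, params$max_homopolymer_3p + 1L)
  if (nchar(end3) > params$max_homopolymer_3p &&
      length(unique(strsplit(end3, "")[[1L]])) == 1L) {
    return(FALSE)
  }
  TRUE
}

.naive_unique <- function(context_dna, s) {
  .occurrences(context_dna, s) == 1L
}

# does any outer primer complete a flank amplicon in [min_flank, max_flank]?
.naive_outer_exists <- function(W, context_dna, params, side, inner_start, inner_end, b5, b3) {
  n <- nchar(W)
  lens <- seq(params$len_min, params$len_max)
  if (side == "five") {
    amp_right <- inner_end
    for (a in seq(max(1L, amp_right - params$max_flank + 1L), amp_right - params$min_flank + 1L)) {
      for (L in lens) {
        e <- a + L - 1L
        if (e > b5 || e >= inner_start) next
        s <- substr(W, a, e)
        if (.naive_ok(s, params, "right") && .naive_unique(context_dna, s)) return(TRUE)
      }
    }
  } else {
    amp_left <- inner_start
    for (e in seq(amp_left + params$min_flank - 1L, min(n, amp_left + params$max_flank - 1L))) {
      for (L in lens) {
        a <- e - L + 1L
        if (a <= b3 || a <= inner_end) next
        s <- substr(W, a, e)
        if (.naive_ok(s, params, "left") && .naive_unique(context_dna, s)) return(TRUE)
      }
    }
  }
  FALSE
}

#' Classify design feasibility by brute-force enumeration
#'
#' Exhaustively enumerates inner-primer anchors in each window and, for each
#' acceptable inner primer, searches for a completing outer primer, under
#' exactly the constraint set of [design_primer_set()]. Returns the
#' classification only (no primer set); used by the synthetic-genome
#' generator to record expected design outcomes independently of the
#' optimized design search.
#'
#' @inheritParams design_primer_set
#' @param domain_only classify the kinase-domain-only design.
#' @return one of `"fail_contig_end"`, `"ok_window30"`, `"ok_window75"`
#'   (more generally `"ok_window<w>"` for the configured windows) or
#'   `"constraint_unsatisfiable"`.
#' @export
classify_design_feasibility <- function(gene, genome, params = design_params(),
                                        domain_only = FALSE) {
  frame <- .design_frame(gene, genome, params, domain_only)
  if (is_design_failure(frame)) return(paste0("fail_", frame$reason))
  W <- frame$W
  n <- nchar(W)
  b5 <- frame$b5; b3 <- frame$b3
  B5 <- b5 + 1L; B3e <- b3
  lens <- seq(params$len_min, params$len_max)
  for (w in params$windows) {
    side5 <- FALSE
    for (p in seq(max(1L, B5 - w), min(n, B5 + w))) {       # 5r 3' terminus
      for (L in lens) {
        q <- p + L - 1L
        if (q > n) next
        s <- substr(W, p, q)
        if (!.naive_ok(s, params, "left")) next
        if (!.naive_unique(frame$context_dna, s)) next
        if (.naive_outer_exists(W, frame$context_dna, params, "five", p, q, b5, b3)) {
          side5 <- TRUE; break
        }
      }
      if (side5) break
    }
    if (!side5) next
    side3 <- FALSE
    for (t in seq(max(1L, B3e - w), min(n, B3e + w))) {     # 3f 3' terminus
      for (L in lens) {
        a <- t - L + 1L
        if (a < 1L) next
        s <- substr(W, a, t)
        if (!.naive_ok(s, params, "right")) next
        if (!.naive_unique(frame$context_dna, s)) next
        if (.naive_outer_exists(W, frame$context_dna, params, "three", a, t, b5, b3)) {
          side3 <- TRUE; break
        }
      }
      if (side3) break
    }
    if (side3) return(paste0("ok_window", w))
  }
  "constraint_unsatisfiable"
}
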