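# Independent oracles, deliberately separate from the package's search and
# assembly code paths: naive sliding-window primer matching, exhaustive
# product pairing, string-concatenation assembly, longest-common-affix.

# naive sliding-window binding-site scan (vectorized over positions only);
# same contract as find_binding_sites: 0-based half-open, no mismatch in the
# 3 bases at the primer 3' terminus
oracle_find_sites <- function(template, primer, max_mismatch = 0L) {
  tc <- utf8ToInt(template)
  n <- length(tc)
  m <- nchar(primer)
  scan <- function(pat, zone) {
    pc <- utf8ToInt(pat)
    npos <- n - m + 1L
    if (npos < 1L) return(integer(0))
    # exhaustive position scan; surviving set pruned exactly as mismatches
    # accumulate (pure bookkeeping, every position is still examined)
    pos <- seq_len(npos)
    mism <- integer(npos)
    for (j in seq_len(m)) {
      mism <- mism + (tc[pos + j - 1L] != pc[j])
      if (j %in% c(4L, 8L, 16L)) {
        keep <- mism <= max_mismatch
        pos <- pos[keep]
        mism <- mism[keep]
      }
    }
    keep <- mism <= max_mismatch
    pos <- pos[keep]
    if (!length(pos)) return(integer(0))
    zone_ok <- vapply(pos, function(p) {
      all(tc[p + zone - 1L] == pc[zone])
    }, logical(1))
    pos[zone_ok]
  }
  plus <- scan(primer, zone = (m - 2L):m)
  minus <- scan(dna_revcomp(primer), zone = 1L:3L)
  rbind(
    if (length(plus)) data.frame(start = plus - 1L, end = plus - 1L + m, strand = "+"),
    if (length(minus)) data.frame(start = minus - 1L, end = minus - 1L + m, strand = "-")
  )
}

# exhaustive convergent pairing from oracle site lists
oracle_pcr_products <- function(template, fwd, rev, max_product) {
  sf <- oracle_find_sites(template, fwd)
  sr <- oracle_find_sites(template, rev)
  out <- NULL
  pair <- function(plus, minus) {
    if (is.null(plus) || is.null(minus)) return(NULL)
    res <- NULL
    for (i in seq_len(nrow(plus))) {
      for (j in seq_len(nrow(minus))) {
        len <- minus$end[j] - plus$start[i]
        if (len >= nchar(fwd) && len <= max_product && minus$end[j] > plus$start[i]) {
          res <- rbind(res, data.frame(start = plus$start[i], end = minus$end[j], length = len))
        }
      }
    }
    res
  }
  sf_p <- if (!is.null(sf)) sf[sf$strand == "+", , drop = FALSE] else NULL
  sr_m <- if (!is.null(sr)) sr[sr$strand == "-", , drop = FALSE] else NULL
  sr_p <- if (!is.null(sr)) sr[sr$strand == "+", , drop = FALSE] else NULL
  sf_m <- if (!is.null(sf)) sf[sf$strand == "-", , drop = FALSE] else NULL
  out <- rbind(pair(sf_p, sr_m), pair(sr_p, sf_m))
  if (is.null(out)) return(out)
  out <- out[!duplicated(out), , drop = FALSE]
  out[order(out$length, out$start), , drop = FALSE]
}

# expected assembled plasmid by plain concatenation of the known parts:
# retained vector + flank5 core + marker + flank3 core (tails are the
# collapsed overlaps, so each homology region appears exactly once)
oracle_plasmid <- function(pset, marker, vector) {
  amps <- flank_amplicons(pset)
  tl <- nchar(pset$primers$`5f`$tail_seq)
  core5 <- substr(amps$five, tl + 1L, nchar(amps$five) - marker$tail_len)
  core3 <- substr(amps$three, marker$tail_len + 1L, nchar(amps$three) - tl)
  paste0(vector$retained, core5, marker$sequence, core3)
}

# expected final linear construct: full 5' amplicon + marker + full 3'
# amplicon with the two tail overlaps collapsed
oracle_construct <- function(pset, marker) {
  amps <- flank_amplicons(pset)
  paste0(
    amps$five,
    substr(marker$sequence, marker$tail_len + 1L, nchar(marker$sequence)),
    substr(amps$three, marker$tail_len + 1L, nchar(amps$three))
  )
}

# longest common affix (suffix of a / prefix of b)
oracle_affix <- function(a, b) {
  k <- 0L
  na <- nchar(a)
  for (i in seq_len(min(na, nchar(b)))) {
    if (substr(a, na - i + 1L, na) == substr(b, 1L, i)) k <- i
  }
  k
}

count_substring <- function(x, s) {
  if (nchar(s) == 0L) return(0L)
  n <- 0L
  i <- 1L
  repeat {
    hit <- regexpr(s, substr(x, i, nchar(x)), fixed = TRUE)
    if (hit == -1L) break
    n <- n + 1L
    i <- i + hit # overlapping occurrences count
  }
  n
}
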