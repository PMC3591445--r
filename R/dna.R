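# Nearest-neighbor thermodynamics (SantaLucia 1998 unified parameters).
# dH in kcal/mol, dS in cal/(mol K), keyed by top-strand dinucleotide.
.NN_DH <- c(
  AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
  CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
  GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
  TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9
)
.NN_DS <- c(
  AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
  CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
  GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
  TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2
)
# initiation terms: terminal G/C vs terminal A/T
.NN_INIT_DH <- c(GC = 0.1, AT = 2.3)
.NN_INIT_DS <- c(GC = -2.8, AT = 4.1)
.GAS_CONSTANT <- 1.987 # cal/(mol K)

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
dna_revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANTGCAN", s))))
  }, character(1), USE.NAMES = FALSE)
}

#' GC fraction of DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return numeric vector of GC fractions in `[0, 1]`.
#' @export
dna_gc <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  ifelse(n == 0L, NA_real_, gc / n)
}

#' Oligonucleotide melting temperature (nearest-neighbor model)
#'
#' Duplex melting temperature under the unified nearest-neighbor
#' parameter set (SantaLucia 1998) with the entropic salt correction
#' `dS + 0.368 * (n - 1) * ln([Na+])` and `Tm = dH / (dS + R ln(C/4))`.
#'
#' @param x character vector of primer sequences (A/C/G/T only; an `N`
#'   yields `NA`).
#' @param conc_nM total strand concentration in nM (default 50, the usual
#'   PCR primer default).
#' @param na_mM monovalent cation concentration in mM (default 50).
#' @return numeric vector of melting temperatures in degrees Celsius.
#' @export
dna_tm <- function(x, conc_nM = 50, na_mM = 50) {
  vapply(toupper(x), function(s) {
    n <- nchar(s)
    if (n < 2L || grepl("[^ACGT]", s)) return(NA_real_)
    di <- substring(s, seq_len(n - 1L), seq(2L, n))
    dH <- sum(.NN_DH[di])
    dS <- sum(.NN_DS[di])
    ends <- c(substr(s, 1L, 1L), substr(s, n, n))
    for (b in ends) {
      key <- if (b %in% c("G", "C")) "GC" else "AT"
      dH <- dH + .NN_INIT_DH[[key]]
      dS <- dS + .NN_INIT_DS[[key]]
    }
    dS <- dS + 0.368 * (n - 1L) * log(na_mM / 1000)
    dH * 1000 / (dS + .GAS_CONSTANT * log(conc_nM * 1e-9 / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Random DNA sequence
#'
#' Draws bases i.i.d. at a specified GC content using the session RNG
#' (callers control determinism with `set.seed`).
#'
#' @param n sequence length in bases.
#' @param gc target GC fraction (default 0.5).
#' @return a single DNA string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# longest run of a single base ending at each position (vectorized helper)
.run_lengths_ending <- function(codes) {
  n <- length(codes)
  if (n == 0L) return(integer(0))
  r <- integer(n)
  r[1L] <- 1L
  for (i in seq_len(n - 1L) + 1L) {
    r[i] <- if (codes[i] == codes[i - 1L]) r[i - 1L] + 1L else 1L
  }
  r
}

# Precomputed per-sequence arrays used by the vectorized primer search:
# cumulative GC/N counts, cumulative nearest-neighbor dH/dS sums, and
# homopolymer run lengths in both directions. All 1-based over `seq`.
.seq_profile <- function(seq) {
  codes <- utf8ToInt(seq)
  n <- length(codes)
  is_gc <- codes == utf8ToInt("G") | codes == utf8ToInt("C")
  is_n <- !(is_gc | codes == utf8ToInt("A") | codes == utf8ToInt("T"))
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  di <- if (n >= 2L) paste0(bases[-n], bases[-1L]) else character(0)
  dh <- .NN_DH[di]
  ds <- .NN_DS[di]
  dh[is.na(dh)] <- 0 # stacks containing N never survive the N filter
  ds[is.na(ds)] <- 0
  list(
    n = n,
    cum_gc = c(0L, cumsum(is_gc)),
    cum_n = c(0L, cumsum(is_n)),
    cum_dh = c(0, cumsum(dh)),
    cum_ds = c(0, cumsum(ds)),
    end_gc = is_gc,
    run_end = .run_lengths_ending(codes),
    run_start = rev(.run_lengths_ending(rev(codes)))
  )
}

# Vectorized candidate evaluation against a .seq_profile.
# starts/ends are 1-based inclusive windows on the profiled sequence.
# Returns data.frame with tm, gc, n_count, run3 (homopolymer run length at
# the primer 3' end; `threeprime = "right"` for sense primers, "left" for
# antisense primers whose 3' terminus is the leftmost template base).
.profile_eval <- function(prof, starts, ends, threeprime, conc_nM = 50, na_mM = 50) {
  len <- ends - starts + 1L
  n_gc <- prof$cum_gc[ends + 1L] - prof$cum_gc[starts]
  n_n <- prof$cum_n[ends + 1L] - prof$cum_n[starts]
  dH <- prof$cum_dh[ends] - prof$cum_dh[starts]
  dS <- prof$cum_ds[ends] - prof$cum_ds[starts]
  init_key <- function(idx) ifelse(prof$end_gc[idx], 1L, 2L)
  dh_init <- c(.NN_INIT_DH[["GC"]], .NN_INIT_DH[["AT"]])
  ds_init <- c(.NN_INIT_DS[["GC"]], .NN_INIT_DS[["AT"]])
  dH <- dH + dh_init[init_key(starts)] + dh_init[init_key(ends)]
  dS <- dS + ds_init[init_key(starts)] + ds_init[init_key(ends)]
  dS <- dS + 0.368 * (len - 1L) * log(na_mM / 1000)
  tm <- dH * 1000 / (dS + .GAS_CONSTANT * log(conc_nM * 1e-9 / 4)) - 273.15
  run3 <- if (identical(threeprime, "right")) prof$run_end[ends] else prof$run_start[starts]
  data.frame(
    start = starts, end = ends, length = len,
    tm = tm, gc = n_gc / len, n_count = n_n, run3 = run3
  )
}
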