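---
title: "Models and methods: deletion construct design and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: deletion construct design and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fungidel)
```

This vignette documents the models, parameters, numerical choices and open
design decisions behind `fungidel`. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## Coordinates and sequence model

All internal intervals are **0-based half-open**; GFF3 input/output is
1-based inclusive and converted at the boundary. This makes every length a
simple difference and removes off-by-one ambiguity from flank and amplicon
arithmetic. Sequences are uppercase strings over `{A,C,G,T,N}`. `N` bases are
permitted in genomes and flanks, but any primer candidate overlapping an `N`
is rejected. Gene models are single-exon ORF intervals; multi-exon models are
out of scope.

## The replaced interval and the primer windows

The deletion replaces the annotated ORF, from the first base of the start
codon through the last base of the stop codon, exactly as annotated. The
positional tolerance in the underlying protocol ("within 30 bp of the start
and stop codons, widened to 75 bp when necessary") is interpreted as a
constraint on the **primer anchors**, not on the replacement boundary: the 3′
terminus of the inner reverse primer (5r) must fall within `window` bp of the
start codon, and the 3′ terminus of the inner forward primer (3f) within
`window` bp of the stop codon. Windows are tried in order (30, then 75) and
`window_used` records the first that succeeded. Fixing the replaced interval
at the annotated codons keeps the deletion deterministic while the window
gives the search freedom where the local sequence is hostile; the flank
amplicons may therefore begin or end up to `window + primer length` bases
away from the codon, which is physically accurate for the protocol being
modeled. For very large genes, `design_domain_deletion()` replaces only an
annotated kinase-domain sub-interval, anchoring the windows to the domain
boundaries instead — emulating the fallback used in practice when whole-ORF
replacement becomes inefficient for multi-kilobase genes.

Flanks abut the replaced interval exactly, are reported in gene orientation
(reverse complemented for minus-strand genes) and take length
`min(max_flank, sequence available to the contig end)`, with defaults
600–1000 bp. A gene closer than `min_flank` to a contig end is a typed
failure (`contig_end`), never an exception: genome-wide loops collect
failures as data. Whether the original pipeline shortened flanks for tightly
packed genes is unstated in the source material; we chose hard failure below
`min_flank`, and we allow flanks to extend into neighbouring genes (the
protocol does not forbid it).

## Primer thermodynamics and scoring

Melting temperatures use the unified nearest-neighbor parameter set
(SantaLucia 1998) with the entropic salt correction
`ΔS + 0.368 (n−1) ln[Na+]` at **50 mM monovalent salt** and a **50 nM**
primer concentration (`Tm = ΔH / (ΔS + R ln(C/4)) − 273.15`). The defaults —
length 18–28 nt, Tm 55–65 °C, GC 30–70%, no single-base run longer than 4 at
the 3′ terminus — are ordinary knockout-pipeline values; the exact parameters
of the original design software were never published, so these are this
package's own stated defaults, all configurable through `design_params()`
(or a YAML file via `design_params_from_yaml()`). Note that under this Tm
model an 18–22-mer at 50% GC sits below 55 °C, so accepted primers are
typically 23–28 nt.

Candidates are scored deterministically: minimize `|Tm − 60|`, then the
anchor distance to the codon, then the leftmost coordinate. For the outer
primers, where anchor distance is meaningless, the tie-break after Tm prefers
the **longer** flank amplicon (more homology for recombination) and then the
leftmost coordinate. Whether the original pipeline preferred maximal or
minimal flank length within 0.6–1 kb is unstated; maximal homology is our
choice. There is no randomness anywhere in the search: identical inputs give
byte-identical designs.

Every accepted binding sequence must occur exactly once (either strand) in
the two flanks plus 1 kb of genomic context — a local mispriming guard, not a
genome-wide off-target search (a stated non-goal).

## Tails and assembly

The marker's left tail is the reverse complement of its left terminus and is
carried by 5r; its right terminus itself is carried by 3f; the outer primers
carry the two exposed vector ends. This makes each tailed amplicon share
exactly `tail_len` (default 29 nt) terminal identity with its assembly
partner. One documented discrepancy in the source material: its running text
places cassette tails on 5r and 3r, while its design figure places them on 5r
and 3f. Only the figure's version yields a connected assembly
(vector–flank–marker–flank–vector), so the figure is followed.

`simulate_recombination()` models gap repair as **exact** terminal homology
matching (longest common suffix/prefix, capped at 200 bp for efficiency)
with a `min_homology` threshold of 20 bp; real gap repair tolerates
mismatches, but no data exist to parameterize that, and exactness keeps the
simulation deterministic. Vector digestion is modeled as a pre-specified gap
interval, not enzyme simulation. A fragment end whose homology matches more
than one junction partner aborts as ambiguous; the synthetic generator
guarantees marker and vector ends share no 12-mer so this cannot happen in
the stated world. Marker orientation is normalized from the junctions in
both routes (gap repair is orientation-agnostic in vivo; the tails fix the
orientation of the product either way). The final construct amplified with
5f/3r **retains** the residual vector tails at its outer ends — they are
physically present after PCR with tailed primers — and the length identity
`construct = flank5_amp + marker + flank3_amp − 2·tail_len` is asserted in
the tests. Whether the production pipeline trimmed those tails before
transformation is unstated; we retain and document.

## In silico PCR and diagnostics

Binding-site search scans both strands for matches of the binding portion
(tails ignored), with `max_mismatch` mismatches allowed but never within the
3 terminal bases at the 3′ end (a mismatched 3′ terminus does not prime).
Diagnostics default to `max_mismatch = 0`. Product length is the
site-to-site span. `build_null_locus()` substitutes the replaced interval by
the marker in gene orientation, never integrating vector tails
(recombination resolves within the flank homology), and refuses templates
whose locus no longer matches the construct — so applying the edit twice
fails.

Diagnostic primers sit strictly outside the union of both flanks, within
`ext_offset` (default 300 bp, our parameter — the source protocol gives no
distance) beyond them. The wild-type/null size difference always equals
`marker_len − replaced_len` and is asserted on every plan. When
`|Δ| < min_gel_delta` (default 150 bp; the source says only "sufficient to
distinguish on a gel", so the number is ours) the plan must list at least one
packaged enzyme that cuts within the marker of the null product and never
cuts the wild-type product. The enzyme table is a fixed snapshot of 24
common palindromic sites (no live database dependency); because all sites
are palindromic a single-strand scan suffices. Digest fragment boundaries
are placed at the start of each recognition site — gel-resolution
bookkeeping, not enzyme-exact cut offsets. For genome-wide surveys where
only sizes matter, `require_discrimination = FALSE` returns plans with an
empty enzyme table instead of failing on loci where no packaged enzyme
happens to discriminate.

## Heterokaryon rescue

`classify_transformant()` is a decision table over colony-scale booleans:
growth on selective/non-selective media, the allele set detected by
diagnostic PCR, and streak stability. Stable + null-only → haploid null;
non-selective growth only + both alleles → heterokaryon; stable + both
alleles → diploid (discarded from evidence); stable + wild-type only →
ectopic integrant (neutral evidence — the source does not say how ectopics
were scored when mixed with heterokaryons); anything else is inconclusive.
Microscopic germling phenotypes are out of computational scope and folded
into the heterokaryon evidence. `call_gene()` requires 6 transformants by
default (the protocol's number, configurable); one verified haploid null
forces `non_essential`, otherwise any heterokaryon gives `essential`, else
`undetermined`. Monotonicity (adding a haploid null never flips a call
toward essential) and exclusivity are property-tested.

## The synthetic world

The generator's defaults are the package's stated test world, chosen once:
200 single-exon ORFs (900–2400 bp, uniform) over 5 contigs at 50% GC;
intergenic gaps 2100–2600 bp so non-edge genes never need neighbour
sequence for a full 1 kb flank; 5% of genes placed 200 bp from a contig end
(exactly 10 with the defaults, two edge slots per contig) to exercise the
`contig_end` failure path; 19.5% of genes flagged essential (the essential
fraction of the kinome survey the package ships); a 1732 bp marker (the
printed size of the *pyrG* cassette), a 5726 bp vector (the size of pRS426)
and 29 nt tails. All randomness flows from a single seed through R's
Mersenne-Twister with fixed `sample.kind`, so artifacts are byte-reproducible
across sessions and releases.

The truth table's expected design outcome is computed by
`classify_design_feasibility()`, a deliberately naive brute-force enumerator
that shares the constraint definitions but none of the search machinery of
`design_primer_set()`; the acceptance suite demands 100% agreement between
the two on the 200-gene world. What a green run establishes: the search is
complete and sound **for this world** — uniform base composition, no
repeats, no introns, clean annotations. What it does not establish:
behaviour on real genomes with repetitive flanks (the local-uniqueness guard
would reject; no genome-wide screen exists), biased composition, or
annotation errors. Simulated transformant observations are similarly
idealized: targeting is a Bernoulli event (default rate 0.7 in the
acceptance run), patterns are noiseless, and genes with no targeted event
among their 6 transformants are redrawn (bounded) so every gene is
informative — real data would instead yield `undetermined` calls.

## Known limitations

No primer-dimer or hairpin thermodynamics; no genome-wide off-target
priming; no gel-mobility or heteroduplex modeling; no transformation
efficiency or production success-rate modeling (the published genome-wide
percentages depend on the real genome and wet-lab outcomes and are
deliberately not reproduced); single-exon models only. The kinome dataset is
a transcription: group paths are carried verbatim (with `Unclassified/Ank`
normalizing an "ankyrin-domain" annotation), free-text phenotypes are mapped
to a controlled tag vocabulary shipped alongside the table, and the two
distinct kinases that share the name An-Psk1 are disambiguated by their
systematic ids.
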