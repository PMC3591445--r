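# fungidel

Design and in silico verification of gene deletion constructs for filamentous
fungi.

## The problem

Systematic gene-function studies in fungi such as *Aspergillus nidulans* rely
on replacing each open reading frame with a selectable marker (e.g. the
*A. fumigatus* *pyrG* cassette) by homologous recombination. Building such a
resource at genome scale means, for every gene:

1. extracting 0.6–1 kb homology flanks on each side of the ORF;
2. designing a constrained four-primer set (**5f/5r/3f/3r**) where the inner
   primers (5r, 3f) must anchor their 3′ termini within ±30 bp of the start
   and stop codons (±75 bp fallback when the near sequence is undesignable),
   and the outer primers close a flank amplicon of 600–1000 bp;
3. adding 5′ tails: marker-complementary on the inner primers,
   vector-complementary on the outer primers, so the two flank amplicons, the
   marker and a gapped shuttle vector assemble by yeast recombinational
   cloning (gap repair) — or, when that fails, by fusion PCR with the same
   primers;
4. verifying transformants by diagnostic PCR with primers *outside* the
   targeting sequence: the wild-type and null alleles differ by
   `marker_len − replaced_len` bp, and when that difference is too small to
   resolve on a gel, by a restriction enzyme that cuts only within the
   marker of the null allele;
5. calling essentiality by **heterokaryon rescue**: a lethal deletion is
   maintained in a heterokaryon whose uninucleate conidia fail on selective
   medium, while a dispensable gene yields streak-stable haploid nulls;
   stable transformants carrying both alleles are diploids and are discarded.

`fungidel` implements this pipeline end to end as composable R functions,
models every step deterministically, and ships (a) a transcription of a
published *A. nidulans* kinome deletion survey (131 kinases with deletion
status and phenotype annotations) with its summary statistics, and (b) a
synthetic-genome generator with ground truth so the whole pipeline is
testable without downloads.

## Worked example

```r
library(fungidel)

spec  <- synthetic_spec(seed = 42, n_contigs = 2, n_genes = 10, fraction_edge_genes = 0.1)
world <- generate_genome(spec)              # FASTA/GFF3-equivalent world + truth table
mv    <- generate_marker_and_vector(spec)   # 1732 bp marker, 5726 bp gapped vector

gene <- world$genes[[3]]
pset <- design_primer_set(gene, world$genome, spec$params)
pset <- attach_tails(pset, mv$marker, vector_tails(mv$vector, spec$tail_length))
pset
#> <primer set SYN0003> window 30 bp, tailed
#> <primer 5f> GGCGCTGTGACCGTTCCCCATTCTGTGTA+AGCCATTGGCAGCGAAGTCAGTTC (24 nt, Tm 60.0, GC 0.54) ctg01:[7357,7381)+
#> <primer 5r> AGACGACCGATATGTAGAGCCATCGCATA+TGAGAGCCTTCATGAGAAGGGCGATTT (27 nt, Tm 60.0, GC 0.48) ctg01:[8074,8101)-
#> <primer 3f> CCCCGCTTTAGTTGATTCTGGACGTGCAC+CCAGGACAAGTTCATGGTCATCATCCCT (28 nt, Tm 60.0, GC 0.50) ctg01:[10056,10084)+
#> <primer 3r> ATGATTTAGAACTTCTACAGTCCGGTGCT+AGACTGCCCGTCGTGGTTATGCTAA (25 nt, Tm 60.0, GC 0.52) ctg01:[10636,10661)-
```

Each primer prints as `tail+binding`: 5r carries the reverse complement of
the marker's left terminus, 3f the marker's right terminus, 5f/3r the two
exposed vector ends. Assembly via either route gives the same construct:

```r
construct <- build_deletion_construct(pset, mv$marker, mv$vector, route = "recombination")
construct
#> <deletion construct SYN0003> 3139 bp via recombination

plan <- design_diagnostic(gene, world$genome, construct, spec$params)
plan
#> <diagnostic plan SYN0003> wt 4220 bp / null 3955 bp, size-discriminable
predict_genotype_bands(plan, "heterokaryon")
#> [1] 3955 4220
```

The wild-type minus null difference (here 265 bp = 1997 bp ORF replaced by
the 1732 bp marker) is exactly `marker_len − replaced_len`; a heterokaryon
or diploid shows both bands. Transformant plate observations then resolve
the gene call:

```r
obs <- generate_observations(world$truth[3, ], targeting_rate = 0.7, seed = 7)
call_gene(obs)
#> <gene call SYN0003> non_essential (ectopic_integrant x2, haploid_null x4)
```

The packaged kinome dataset reproduces the published survey counts:

```r
summarize_kinome(load_kinome_table())
#> Kinome summary: 131 kinases, 128 deleted
#>   essential: 25 (19.5%), terminal phenotype defined for 23
#>   non-essential: 103, with >=1 phenotype: 43
#>   groups: AGC=13 CAMK=15 CK1=2 CMGC=27 STE=12 Other=25 Unclassified=11 Atypical=26
#>   sub-tallies: Atypical/HisK=15 CMGC/SRPK=7 Ffk=11
```

## Scope notes

The original resource's genome-wide production percentages (primer design,
amplification and construct success rates) depend on the real *A. nidulans*
genome and wet-lab outcomes and are deliberately not reproduced; the
property-based checks above replace them. See `vignettes/construct-design.Rmd`
for the model, parameter and tie-break documentation.
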