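# ccs16s

Curation, denoising and error profiling for full-length 16S rRNA gene
amplicons sequenced as circular consensus (CCS) reads on long-read
single-molecule platforms — plus a mock-community read simulator so the whole
pipeline is testable against a known truth without downloading anything.

It is aimed at microbial ecologists and method developers who want to curate
CCS amplicon data the way mock-community benchmarking says it should be
curated, or to study how curation choices propagate into error rates and OTU
inflation.

## What it does

CCS errors are roughly uniform along the read, so per-base quality trimming
is useless (correct calls and errors carry the maximum quality value about
equally often). Curation instead operates on whole reads and their
abundances:

1. **Parse** FASTQ in the PacBio dialect: a quality of 0 encodes an
   ambiguous call and becomes `N`; pass counts and predicted error rates ride
   in the header (`@id;np=<int>;pe=<float>`) or a sidecar table.
2. **Demultiplex/orient/trim** against paired 16-nt symmetric barcodes and
   degenerate primers (IUPAC-aware), trying both strand orientations.
3. **Screen**: homopolymer runs ≤ 8, insert length near the region's
   expectation, ≤ 1 mismatch per barcode and per primer, ≥ 10 passes,
   predicted error ≤ 0.01%.
4. **Measure** the true error rate against mock references by global
   alignment: per-read error rate
   `(n_sub + n_ins + n_del) / (n_match + n_sub + n_ins + n_del)`, error-type
   mixture, substitution matrix, deleted/inserted base composition, and the
   1-nt variant spectrum.
5. **Flag chimeras** against all enumerated single-breakpoint bimeras of the
   references: chimeric iff `d_ref − d_chimera ≥ 3`.
6. **Pre-cluster** (denoise): sort by abundance, merge each sequence into the
   first more-abundant sequence within `floor(L/100)` differences (2 nt at
   250 nt, 14 nt at 1,458 nt).
7. **Cluster OTUs** by average neighbor (UPGMA) at a 3% distance cutoff, and
   estimate rarefied richness with the closed form
   `Σᵢ 1 − C(N−nᵢ, d)/C(N, d)`.
8. **Simulate** mock-community CCS reads with the measured error structure
   (rate 0.65%; insertions/deletions/substitutions 31.2/17.9/50.9%; deletions
   striking G 39.4%, A 24.3%, C 18.3%, T 18.0%; max-quality fractions
   0.805/0.800/0.804) with a per-read truth table.

## Worked example

```r
library(ccs16s)

refs <- make_mock_references(n_templates = 21, length = 253,
                             divergence = 0.10, seed = 7)
sim  <- simulate_ccs_reads(refs, n_reads = 500,
                           error_model(orient_flip_prob = 0), seed = 8)
aln  <- align_to_best_reference(sim$reads, refs, band = 30)
tally_errors(aln, reads = sim$reads)
#> CCS error profile: 425 errors over 126628 aligned positions (error rate 0.3356%)
#>   type mix: sub 55.1%, ins 30.6%, del 14.4%
#>   deleted-base composition: A 24.6%, C 24.6%, G 27.9%, T 23.0%
```

500 reads give 425 errors, an observed rate of 0.34% for this draw (the
configured mean is 0.65% with heavy read-to-read dispersion), with an
error-type mixture near the configured 50.9/31.2/17.9% — the mixture
sharpens to within a fraction of a percent at the test suite's 10⁵-error
scale.

The full pipeline on simulated V4 reads:

```r
run_pipeline(pipeline_config(region = "V4", n_reads = 1000L, seed = 7L))
#> CCS curation pipeline run (region V4 , seed 7 )
#>            stage reads_in reads_out error_rate
#>      demultiplex     1000       931
#>  chimera_removal      931       931
#>     basic_screen      931       931    0.1596%
#>    error_filters      931       246  0.006427%
#>       precluster      246       246         0%
#> reads retained: 24.6%; precluster threshold: 2 nt (25 -> 21 unique sequences)
#> OTUs at 0.03 cutoff: 21 (templates alone give 21)
```

Reading the report: 6.9% of reads fail demultiplexing (errors in their
barcodes/primers), the basic screen leaves an observed error rate of 0.16%,
the error-correlated filters cut it 25-fold while keeping a quarter of the
reads, and pre-clustering absorbs the last error variants — after which the
1,000 noisy reads collapse to exactly the 21 mock community templates and
the OTU count matches the template count, i.e. no error-driven OTU
inflation survives curation.

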