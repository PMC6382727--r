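# quidsig

Somatic mutational-signature and CpG-island enrichment analysis for tongue
carcinoma cohorts, built around the genomic hallmark of betel-quid-associated
tumours: a CpG-methylation-type C>T process acting at NCG trinucleotides
(strongest at GCG), distinct from the APOBEC-type TCN process that dominates
tongue carcinoma in the general population.

The package is for cancer-genomics analysts who have somatic SBS catalogs
(VCF or MAF), a reference FASTA and a CpG-island BED, and want a tested,
reproducible implementation of the full analysis chain:

1. **96-class context matrix** — every single-base substitution is collapsed
   to the pyrimidine strand and classified by substitution type and 5'/3'
   flanking bases into the 96 COSMIC classes.
2. **De-novo signature extraction** — nonnegative matrix factorization
   minimizing the Frobenius reconstruction error `‖M − P·E‖_F`, with rank
   selection by bootstrap signature stability (silhouette on cosine distance
   over Monte-Carlo resampled catalogs) together with the reconstruction
   error, for K = 1..15.
3. **Reference matching** — cosine similarity of extracted signatures to a
   reference panel, with complete-linkage hierarchical clustering of the
   union (Newick export).
4. **CpG-island enrichment** — mutation rate in island core windows
   (island ± 50 nt) versus flank windows (501–1000 nt outward from each
   edge), as a rate-ratio fold change with a two-sided Fisher's exact test,
   decomposed over the 6 substitution types and the 16 C>T context classes.
5. **Cohort statistics** — mutation loads with one-way ANOVA, exposure
   proportion contrasts (unpaired t-test), gene mutation-frequency 2×2
   Fisher tests.
6. **Synthetic cohorts** — a first-class simulator that generates reference
   genomes with CpG islands and catalogs drawn from signature mixtures with
   a controlled island-core rate elevation, so every stage is testable
   without patient data.

## Worked example

Simulate a betel-quid-type cohort, build its context matrix, refit
exposures against the generating signatures and test the island enrichment:

```r
library(quidsig)

sim <- simulateCohort(bqTcProfile("wgs"), seed = 1)
sim$catalog
#> MutationCatalog: 49255 SBS record(s), 5 sample(s)

cm <- buildContextMatrix(sim$catalog, sim$genome)
cm
#> ContextMatrix: 5 sample(s) x 96 classes, 49255 classified SBS

pr <- exposureProportions(nnlsExposures(sim$signatures, cm))
round(rowMeans(pr), 3)
#>  SigNCG  SigTCN SigFlat
#>   0.523   0.061   0.416

et <- perClassEnrichment(sim$catalog, sim$windows, sim$genome)
subset(et, family == "all")
#>   class family nCore nFlank coreBp flankBp     fold       pValue
#> 1   all    all  1074    520 110000  100000 1.877622 4.270675e-34
```

The exposure means say the NCG-type process contributes about half of the
mutations in this cohort (the emulated dominant-signature mean is 53%); the
enrichment row says island cores carry mutations at 1.88 times the flanking
rate in this one five-genome draw (the emulated elevation is 2.05; pooling
several simulated genomes tightens the estimate), with a Fisher p-value far
below 0.05.

For real data, replace the simulated inputs:

```r
genome  <- readReference("hg19.fa")
islands <- readRegions("cpgIslands.bed")
catalog <- readVcfCatalog("tumour.vcf", sampleId = "P1", genome = genome)
windows <- buildWindows(islands, genome)
perClassEnrichment(catalog, windows, genome)
```

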