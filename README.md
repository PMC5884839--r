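# niptkmer

Alignment-free detection of fetal trisomies from low-coverage whole-genome
sequencing of maternal plasma cell-free DNA (NIPT), for people building or
studying NIPT analysis pipelines.

Instead of mapping reads, the package counts a pre-validated set of
chromosome-specific 25-mers directly in raw FASTQ data:

1. **List building** — for each chromosome, keep the canonical k-mers
   (lexicographic min of k-mer and reverse complement) that are unique
   genome-wide, do not overlap any allele of a common polymorphism
   (MAF ≥ 1%), avoid low-complexity/pseudoautosomal regions, and have
   Poisson-plausible counts (cumulative probability cut-offs 0.01–0.99) in
   every deep-coverage control individual.
2. **Counting** — one pass over a sample's reads yields per-chromosome
   counts K<sub>sc</sub> and the sample GC fraction GC<sub>S</sub>.
3. **Calling** — with per-chromosome coverage C<sub>sc</sub> = K<sub>sc</sub>/L<sub>c</sub>,
   an OLS model per autosome, β̂ = (XᵀX)⁻¹Xᵀy (no intercept), predicts
   C′<sub>sc</sub> from the other autosome coverages plus GC on a euploid
   reference cohort; D<sub>sc</sub> = (C<sub>sc</sub> − C′<sub>sc</sub>)/C′<sub>sc</sub>
   is z-scored against the reference (Z<sub>sc</sub>), and a chromosome is
   called `elevated` when Z<sub>sc</sub> > 3.5 (one-sided; the normal tail
   beyond 3.5 SD is ≈ 0.023%). Four sex-stratified X/Y models determine
   fetal sex, and the Mahalanobis distance of (D, GC) from the reference
   population serves as sample QC. If n% of cfDNA is fetal, a trisomy
   shifts the affected chromosome's coverage by (100 + 1.5 n)/(100 + n) − 1
   (≈ 4.5% at n = 10), which is what the z-score must resolve.

A seeded simulator generates every input at toy scale — reference genome
with planted repeats and excluded regions, VCF/BED truth, deep-coverage
controls, and maternal/fetal cfDNA read mixtures with configurable fetal
fraction, trisomy and fetal sex — so the whole method is testable end to
end. See the methods vignette (`vignettes/niptkmer-methods.Rmd`) for the
model, its assumptions and all tunables.

## Worked example

The default configuration simulates a cohort of 60 euploid reference, 10
euploid test and 5 trisomic test pregnancies (fetal fraction 10%) on a
680 kb toy genome and runs the complete pipeline (≈ 7 minutes):

```r
library(niptkmer)
scenario <- simulate_scenario(sim_config(), seed = 7)
res <- run_scenario(scenario)

res$lists$L_c
#>  chr1  chr2  chr3  chr4  chr5  chr6  chrX  chrY
#> 91429 89402 82603 83012 78110 72630 24179 15507

calls <- res$calls$calls
subset(calls, chrom == "chr6" & sample_id %in%
         res$plan$sample_id[res$plan$role == "trisomic_test"],
       select = c(sample_id, D, Z, call))
#>     sample_id          D        Z     call
#> 566      S071 0.04581120 6.312130 elevated
#> 576      S072 0.05754067 7.928304 elevated
#> 582      S073 0.04842922 6.672860 elevated
#> 590      S074 0.05305782 7.310624 elevated
#> 598      S075 0.05072072 6.719083 elevated
```

`L_c` are the final per-chromosome list sizes after filtering (the X and Y
lists are smallest, as in real genomes). Each trisomic sample's chromosome 6
shows the ≈ 5% coverage excess expected at a 10% fetal fraction and a
z-score far above the 3.5 cut-off, while euploid samples stay within it;
`res$calls$samples` carries the inferred fetal sex (all correct here), the
per-hypothesis sex-model z-scores and the Mahalanobis QC distance.

A command-line interface mirroring the three steps (plus `simulate`) is
installed as `exec/niptkmer`:

```sh
niptkmer simulate --scenario scenario.yaml --seed 1 --out sim/
niptkmer make-lists --reference sim/genome.fa --snps sim/variants.vcf \
    --exclude sim/exclude.bed --controls sim/control01.fastq.gz --out lists/
niptkmer count --lists lists/ --fastq sample.fastq.gz --out row.tsv
niptkmer call --matrix matrix.tsv --reference-ids refs.tsv --cutoff 3.5 --out calls.tsv
```

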