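# dogscan

Detection and analysis of **downstream-of-gene (DoG) readthrough
transcripts** from RNA-seq coverage.

Under transcription-inhibition stress (e.g. the TFIIH inhibitors triptolide
or THZ1), and under other stresses like osmotic shock or heat shock,
termination downstream of the polyadenylation site fails for a subset of
genes and RNA polymerase II continues elongating for kilobases past the
annotated 3′ end. The resulting chromatin-associated long noncoding RNAs —
DoG transcripts — appear in RNA-seq coverage as contiguous signal extending
past a gene's transcription end site (TES). dogscan is for computational
biologists who want to call, validate, quantify and compare such regions
without depending on any external web service or pre-processed download.

## What it computes

**Discovery.** For each gene, consecutive windows of width *w* (default
500 bp) are examined downstream of the TES. With estimated window read count
*r* = (Σ per-base depth)/(read length), the window FPKM is

    FPKM = r / ((w / 1000) · (N / 10^6)),   N = library size,

and extension continues while FPKM ≥ 0.2 and the window does not cross the
TSS-side boundary of another gene. A DoG is reported when the region reaches
4 kb (inclusive); all thresholds are configurable via `dog_params()`.

**ChIP-seq filters.** Because non-stranded libraries cannot attribute
downstream signal, two filters use RNAP II promoter-proximal pausing peaks:
a DoG covering another gene that has an RNAP II peak inside the DoG region
is discarded (likely transcription of the downstream gene), and a DoG is
kept only if its parent gene has a peak within ±500 bp of its TSS
(evidence the parent is transcriptionally engaged).

**Differential expression.** Region counts are normalised by
median-of-ratios size factors; per region,
log2FC = log2((mean treated + 1)/(mean control + 1)) is tested with a
moderated negative-binomial Wald statistic (within-condition
method-of-moments dispersion moderated toward the common value, floor 0.01,
two-sided normal tail).

**Comparison & correlation.** DoG sets are intersected/differenced by gene
id, length distributions are binned half-open, and gene-body vs DoG log2FC
pairs (p ≤ 0.05 on both sides) are summarised by Pearson correlation and
classified Upregulated / Downregulated / NoChange with inclusive ±1.2
boundaries.

**Synthetic data.** `simulate_dataset()` generates GTF + bedGraph + peak BED
+ truth-table datasets with planted readthrough, interfering downstream
genes and promoter peaks, so every stage is testable offline. See the
methods vignette (`vignettes/dogscan-methods.Rmd`) for the model and the
design rationale.

## Worked example

```r
library(dogscan)
library(GenomicRanges)

sim <- make_paper_shaped_dataset("small", seed = 1)   # 60 genes, 2 x 2 samples
dogs <- lapply(sim$tracks, function(trk)
  call_dogs_all(sim$genes, trk, dog_params(), expressed_only = TRUE))
sapply(dogs, length)
#> control_rep1 control_rep2 treated_rep1 treated_rep2
#>            9            9           33           33

treated <- merge_replicates(dogs[c("treated_rep1", "treated_rep2")], label = "treated")
control <- merge_replicates(dogs[c("control_rep1", "control_rep2")], label = "control")
c(treated = length(treated), control = length(control),
  shared = length(common_dogs(treated, control)),
  treated_only = length(exclusive_dogs(treated, control)))
#>      treated      control       shared treated_only
#>           33            9            6           27
```

The treated condition produces far more DoGs than the control, a fraction
of DoG genes is shared between conditions, and set relations are exact
(33 = 6 + 27). Filtering against the condition's RNAP II peaks removes
interference calls and promoter-less parents:

```r
trt_f <- filter_promoter_peak(
  filter_downstream_interference(treated, sim$peaks$treated, sim$genes),
  sim$peaks$treated, sim$genes)
length(trt_f)
#> [1] 20
head(trt_f, 3)
#> GRanges object with 3 ranges and 4 metadata columns:
#>            seqnames        ranges strand |     gene_id length_bp mean_fpkm   sample_id
#>   SIMG0016     chrS 192724-200223      - |    SIMG0016      7500  0.335467     treated
#>   SIMG0017     chrS 206215-216214      - |    SIMG0017     10000  5.257900     treated
#>   SIMG0022     chrS 288401-292400      - |    SIMG0022      4000  7.198250     treated
```

Each record is a readthrough region attached to its parent gene: its
length and the mean FPKM of the whole region. Differential testing of the
union DoG set between conditions:

```r
union_dogs <- merge_replicates(list(treated, control), label = "union")
dog_regions <- granges(union_dogs)
mcols(dog_regions) <- S4Vectors::DataFrame(region_id = union_dogs$gene_id, kind = "dog")
cm <- count_regions(dog_regions, sim$tracks, 50)
cm$samples$condition <- sim$sample_sheet$condition
res <- diff_test(cm, control_label = "control", treated_label = "treated")
head(res[order(res$p_value), ], 5)
#>   region_id base_mean    log2fc p_value kind
#> 1  SIMG0004  109.3177  7.778967       0  dog
#> 4  SIMG0010  275.3777 -9.107885       0  dog
#> 6  SIMG0017  489.9204  9.937875       0  dog
#> 7  SIMG0022  269.8844  9.078868       0  dog
#> 8  SIMG0023 1073.1866 11.068357       0  dog

length_histogram(treated, seq(4000, 12000, by = 2000))
#>   [4000,6000)   [6000,8000)  [8000,10000) [10000,12000)
#>            10            11             9             3
```

Positive log2FC marks DoG regions induced by the treatment (planted in the
treated condition only); the strongly negative one is a control-specific
DoG. `run_pipeline()` orchestrates the same graph from a YAML config and
writes `dogs/`, `filtered/`, `diff/`, `compare/`, `report.tsv` and a
`manifest.yaml` with parameters and input checksums.

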