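# microsynt

Microsatellite-anchored synteny mapping and comparative statistics for
pairs of draft genome assemblies.

## The problem

Comparing two fragmented draft assemblies of closely related species —
say, two congeneric insects a few tens of millions of years diverged —
rarely needs whole-genome alignment. Microsatellites (SSRs: tandem repeats
of 1–6 bp motifs) are dense, easy to detect, and their unique flanking
sequence pins each locus to a single orthologous position in both genomes.
From the resulting one-to-one marker map one can read off conserved synteny
blocks, count intra- and inter-chromosomal rearrangements, link scaffolds,
and place unanchored scaffolds onto chromosomes.

`microsynt` implements that pipeline for R, together with the surrounding
comparative statistics such studies report:

* **SSR detection** (`find_ssrs`, `extract_flanks`): maximal perfect tandem
  repeats with MISA-style minimum unit counts, canonical motif naming
  (minimum over rotations and reverse complement), flanks truncated at
  scaffold ends and N runs.
* **Marker matching** (`match_markers`): semi-global flank alignment in both
  orientations, reciprocal best hit with a tie margin — a partial one-to-one
  homology map.
* **Synteny mapping** (`build_blocks`, `classify_rearrangements`,
  `link_scaffolds`, `place_unplaced`, `summarize_synteny`): greedy chaining
  of order/orientation-consistent markers with a singleton-ignore rule;
  rearrangements counted as events (an inversion is one event, not two
  boundaries); breakpoints localized to inter-marker intervals.
* **Assembly statistics** (`summarize_assembly`, `nstat`, `split_contigs`):
  sequence length, span, scaffold/contig counts and N50s under explicit
  gap and length-filter conventions.
* **Protein-domain evolution** (`scan_expansions`, `compare_repeat_numbers`,
  `unique_domains`, `collapse_consecutive`): Fisher's exact
  expansion/contraction tests on once-per-gene occurrence counts, domain
  arrangement clustering, and within-protein repeat-number comparison.
* **Methylation prediction** (`cpg_oe`, `classify_genes`): CpG observed/
  expected ratio per gene body, `CpG[O/E] < 1` marking historically
  methylated genes.
* **Synthetic data with ground truth** (`simulate_assembly_pair`,
  `simulate_domain_tables`, `simulate_methylome`): assembly pairs descended
  from a common ancestor with a known history of inversions and
  translocations, domain tables with implanted expansions and repeat
  shifts, and two-class CpG gene sets — plus evaluation helpers
  (`evaluate_matches`, `evaluate_events`) that score any run against the
  truth tables.

The core statistic for methylation prediction is the CpG depletion ratio

    CpG[O/E] = (n_CpG × L) / (n_C × n_G)

computed on non-N bases; the synteny machinery is combinatorial (maximal
monotone marker runs) rather than parametric.

## Worked example

Simulate a 2 Mb, 3-chromosome assembly pair with 2 inversions and 1
translocation, run the full analysis, and compare against the known truth:

```r
library(microsynt)

sim <- simulate_assembly_pair(sim_params(
  genome_size = 2e6, n_chromosomes = 3,
  n_inversions = 2, n_translocations = 1,
  markers_per_event = 5, seed = 7))

res <- run_synteny_analysis(sim$a$assembly, sim$b$assembly,
                            sim$a$chrom_map, sim$b$chrom_map)
res$summary
#> Synteny summary: 9 blocks on 3 reference scaffolds
#>   block length (ref): mean 0.18 Mb, median 0.17 Mb, total 1.6 Mb
#>   coverage: reference 81.1%, partner 86.9%; 0 blocks > threshold
#>   rearrangements: 2 intra-, 1 inter-chromosomal

res$events[, c("type", "ref_scaffold", "partner_chrom", "bp1_end", "bp2_start")]
#>    type ref_scaffold partner_chrom bp1_end bp2_start
#> 1 intra       A_chr1          chr1  364561    473865
#> 2 intra       A_chr2          chr2  397791    524594
#> 3 inter       A_chr3          chr1  260760    334659

ev <- evaluate_events(res$events, sim)
sprintf("true events recovered: %d/%d intra, %d/%d inter",
        ev$n_intra, ev$true_intra, ev$n_inter, ev$true_inter)
#> "true events recovered: 2/2 intra, 1/1 inter"
```

The two implanted inversions appear as the two intra-chromosomal events and
the translocation as the inter-chromosomal one; each event's breakpoint
interval (`bp1_end`/`bp2_start` are the inner marker bounds) contains the
true breakpoint. The same objects feed the summary statistics:

```r
summarize_assembly(sim$b$assembly)
#> Assembly statistics: sim_B
#>   Total sequence length  2.0 Mb
#>   Total assembly length  2.0 Mb
#>   Number of scaffolds    3
#>   Scaffold N50           666.6 Kb
#>   Number of contigs      3
#>   Contig N50             666.6 Kb
```

For file-based workflows, `run_pipeline("config.yaml")` chains
reading, scanning, matching and mapping, and writes TSV/BED/JSON outputs;
`inst/cli/microsynt.R` wraps the same functions as a command-line tool with
`simulate`, `stats`, `ssr`, `match`, `synteny`, `domains`, and `cpg`
subcommands.

Real assemblies are analyzed the same way: read each FASTA with
`read_fasta()`, supply a scaffold-to-chromosome TSV via
`read_chromosome_map()` for whichever assembly is anchored, and expect
run times of minutes for a pair of ~250 Mb genomes.

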