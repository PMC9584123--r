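# seedmapr

Seed-hash short-read mapping with pile-up variant calling and RPKM
quantification, plus a read simulator and evaluation harness — an R
package with an Rcpp alignment core and a command-line front end.

## The problem and the approach

Aligning short sequencing reads to a reference is the computational
bottleneck of most NGS workflows, and the accuracy-critical one: a
uniquely mapped read placed at the wrong locus silently corrupts every
downstream variant call and expression estimate. seedmapr implements a
seed-hash mapper built for predictable accuracy:

1. **Whole-reference k-mer index.** Every position of every N-free k-mer
   (seed length *s* ∈ [6, 14], default 10) over the entire reference set,
   forward strand only; the mapper queries the read and its reverse
   complement.
2. **Seeds → hotspots.** A read of length *L* yields
   *m₀ = ⌊L/s⌋* non-overlapping seeds (plus a tail-anchored one). Seed
   hits vote for candidate read starts; candidates within an *indel band*
   *b* (default 5) are merged into one hotspot, so short indels do not
   fragment a locus.
3. **Prioritized verification.** Hotspots are verified best-first by
   end-to-end unit-cost dynamic programming in a ±*b* window, under an
   error allowance — an absolute count (default 5) or a percentage of the
   read length for variable-length data. A pigeonhole bound (an alignment
   with *d* edits keeps ≥ *m₀ − d* intact seeds) lets the search stop
   early without ever missing a co-optimal location.
4. **Classification.** All distinct best locations are kept: one →
   `unique`, several → `multi` (all reported), none → `unmapped`. Unique
   reads alone feed the pile-up, the Fisher's-exact-test variant caller,
   and RPKM quantification.

By the same pigeonhole logic the chance that an error-carrying read loses
its true locus is `(1 − (1−p)^s)^m₀` — about 6.4 × 10⁻¹¹ for 100-nt reads
at 1% error with 10-nt seeds — which is why mappers of this family can
hold mismapping rates below 10⁻⁹.

## A worked example

```r
library(seedmapr)

g   <- simulate_genome(100000, seed = 1)            # 100 kb random genome
sim <- simulate_reads(g, 5000, 100, sub_rate = 0.01, seed = 2)
idx <- build_index(g, seed_length = 10)
idx
#> <seed_index> seed length 10 over 1 reference(s), 100,000 nt, 99,991 indexed positions

rec <- map_reads(sim$reads, idx, mapping_params(max_errors = 5))
glance(rec)
#> # A tibble: 1 × 6
#>   total unique multi unmapped mapping_rate empty_input
#>   <int>  <int> <int>    <int>        <dbl> <lgl>
#> 1  5000   4998     0        2        1.000 FALSE

evaluate_mapping(rec, sim$truth)
#>   total mapped_unique mapped_multi unmapped unique_correct sensitivity mismap_rate
#> 1  5000          4998            0        2           4998      0.9996           0
```

5,000 reads with ~1 substitution each: 4,998 map uniquely and **every one
of them lands at its true origin** (`mismap_rate = 0`); the two unmapped
reads drew more than five errors and are correctly rejected rather than
guessed. From here `build_pileup(rec, g)` + `call_variants()` produce
variant calls (written with `write_vcf()`), and against a transcript
reference `quantify_expression()` returns counts and RPKM.

The same pipeline is scriptable from a shell via
`inst/scripts/seedmapr.R`, with subcommands `index`, `map`, `call`,
`pileup-at`, `quant`, `quant-compare`, `simulate` and `evaluate`.

## Package layout

| | |
|---|---|
| `R/`, `src/` | mapper, index, pile-up/variants, quantification, simulator; hot paths in C++ (Rcpp) |
| `inst/scripts/seedmapr.R` | command-line front end |
| `scripts/acceptance.R` | end-to-end reproduction script |
| `tests/testthat/` | unit, property and acceptance tests (all fixtures generated in code) |
| `vignettes/seed-hash-mapping.Rmd` | the methods vignette: model, parameters, tie-breaks, limitations |
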