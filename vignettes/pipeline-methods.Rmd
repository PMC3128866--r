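---
title: "Methods: comparative floral transcriptomics of outcrossing and selfing genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative floral transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The analysis

`mateseq` implements, as a tested and reusable pipeline, a comparative
floral-transcriptome analysis for a four-genotype design: one outcrossing
genotype, two genotypes from independently derived selfing populations of
the same species, and a selfing outgroup species. The pipeline takes
per-sample assembled contigs and per-sample short paired reads, and
produces a consensus reference transcriptome, per-sample diploid genotype
calls with a paralogy screen, pairwise divergence and Watterson's
$\theta_W$ over a conservative locus set, FPKM expression with bootstrap
correlation intervals, count-based differential expression under FDR
control, and Fisher's-exact GO enrichment. A synthetic-data module
generates the whole study design with known truth, which is how the
package validates itself.

The package is organised as an analysis: the numbered scripts under
`analysis/` are thin narrative drivers (simulate, trim, build the
consensus, genotype, population genetics, expression, enrichment), each
writing its tables under `results/`, while every computation lives in
package functions so the test suite and the acceptance script can call
them directly. No separate command-line tool is provided: the scripts are
the command-line surface.

# The synthetic study and what it emulates

`sim_config()` fixes the simulated study conditions; the defaults are the
conditions all tests run under.

* **Loci.** `n_loci` transcripts with log-normal lengths averaging about
  900 bp (floor 300 bp, rounded to whole codons). Sequences are built from
  stop-free codons so each locus translates cleanly into its guide
  protein.
* **Divergence.** The outgroup species sits at 0.048 substitutions/site
  from the ingroup ancestor; each ingroup genotype mutates at half the
  intraspecific rate (default 0.010) so that *pairwise* ingroup divergence
  matches the configured value. Substitutions are uniform random base
  changes (Jukes–Cantor-like); there are no indels, which keeps ungapped
  alignment placement column-exact and lets the consensus and genotype
  oracles be exact.
* **Mating system.** A locus is heterozygous with probability 0.20 in the
  outcrosser and 0.05 in each selfing genotype (the outgroup is a selfing
  species and uses the selfer rate). A heterozygous locus carries
  $1 + \mathrm{Poisson}(2\ \mathrm{per\ kb})$ heterozygous sites on its
  second haplotype. There is no established quantitative per-mating-system
  rate; these values reproduce the qualitative ordering (outcrosser well
  above selfers) without asserting real counts.
* **Paralogy.** A fraction (default 5%) of loci is duplicated before
  genotype divergence and the copy mutated to 97% identity. Paralog copies
  produce reads but no contig of their own, emulating assembly collapse of
  young duplicates — exactly the situation the downstream paralogy screen
  is designed to catch: reads from the missing copy mis-map onto the
  retained copy and masquerade as heterozygosity in every genotype,
  including the selfers.
* **Expression.** Log-scale expression is a factor model giving
  correlation 0.90 between ingroup pairs and 0.60 between the outgroup and
  any ingroup genotype, with log-normal marginals. Five percent of loci are
  differentially expressed in all three selfing genotypes (half up, half
  down, 4-fold). Fragment counts are multinomial with probability
  proportional to expression weight times length.
* **Reads.** Paired 40 bp reads from Normal(200, 20) fragments, sampled to
  20-fold coverage. Base qualities follow a deterministic decay from ~Q38
  to ~Q15 across the read, shifted so the mean implied error probability
  equals the configured error rate (default 0.01); errors are then drawn
  at exactly the probability each emitted quality implies. Setting the
  error rate to zero emits maximal qualities and no errors — the exact
  substring contract several tests rely on.
* **Assembler artifacts.** Five percent of transcripts are split into two
  contigs (overlapping or slightly disjoint), five percent emit a second
  >99%-identical contig from the other haplotype (allelic near-duplicates),
  and short junk contigs below 100 bp are added.

What the generator does **not** emulate: alternative splicing, indels
(available nowhere in the model), coverage-dependent assembler errors,
adapter contamination, or mapping-quality structure. Tests passing on this
generator therefore demonstrate correctness of the pipeline's logic and
statistics under the stated model, not robustness to every artifact of
real data.

# Read trimming

Reads are trimmed per the protocol: strip terminal 'N' runs, then truncate
immediately before the first run of two consecutive bases below Q20
(error probability 0.01), and discard reads shorter than 20 bp. Two
readings were possible and are fixed as: a lone sub-threshold base never
triggers truncation, and the first base of the triggering pair is removed
along with everything after it. N-stripping precedes the quality scan
because terminal N runs carry no usable quality signal. Mates are trimmed
independently and, by default, a pair is dropped if either mate dies, so
fragment counting downstream always sees complete pairs.

# Similarity search and ortholog grouping

An internal seed-and-extend aligner stands in for BLASTn: exact 16-mer
seeds on both strands, ungapped extension along each seeded diagonal
maximising match $-\,2\times$ mismatch (the same quantity used as the hit
score; no E-values are computed), with the best local segment kept per
query/subject pair. Because the simulator is substitution-only, ungapped
extension is exact; on real data with indels an external aligner's
tabular output (BLAST outfmt 6) can be ingested instead via
`read_hits()`.

Redundancy collapse removes contigs more than 99% identical over at least
95% of the shorter contig, keeping the longer one (ties by lexicographic
id), processed in decreasing length order to a deterministic fixpoint.

Ortholog groups come from reciprocal best hits over all six sample pairs,
filtered by the grouping criteria (alignment $\ge$ 200 bp, identity
$\ge$ 90%, aligned proportion > 80% of the shorter sequence), merged by
transitive closure. "Found in more than two samples" is read as "at least
two samples", the reading consistent with pairwise reciprocal best hits
producing two-member groups; `min_samples` makes the stricter reading
available. When a closure pulls two contigs of one sample, the one with
the higher summed hit score stays and the loser returns to the leftovers,
preserving the at-most-one-member-per-sample ortholog semantics.

Consensus sequences orient members to the group's longest member, place
them by best-hit diagonal offset, and take per-column majorities with
ties resolved by the longest covering member; overhangs are retained, so
a longer member lengthens the consensus. Extension incorporates unplaced
contigs with >95% identity over >50 bp whose tail extends the consensus;
"no unalignable segments" is operationalised as no run of 10 or more
consecutive mismatching columns in the mutual overlap (no tolerance is
stated anywhere; mismatch runs are the only possible unalignable structure
in an ungapped model). Contigs extending two different consensuses are
ambiguous and logged, not merged.

Fragment joining translates each consensus in six frames, shortlists
candidate guide proteins by shared 8-residue words, and aligns the best
frame to the guide by local dynamic programming with identity scoring.
Consensuses sharing a best guide whose residue intervals overlap by at
most 15 and order consistently are concatenated in guide order with an
N-spacer of three times the implied residue gap. Singletons of at least
1000 bp join the reference when their guide alignment covers at least 50
residues at 60% identity or better — a deliberate stand-in for the
classic BLASTx E-value criterion, which has no meaning without E-value
machinery; it is a substitution, not an equivalence. A final redundancy
collapse guards against reintroduced duplicates.

The chimera screen compares each final sequence to a trusted set (the
simulation's truth loci in tests) and flags pairs sharing a
$\ge$ 100 bp region at $\ge$ 95% identity whose mutual overlap also
contains a maximal low-identity block of $\ge$ 50 bp (column identity
smoothed over an 11-column window, block counted where it stays below
80%). Requiring the *block* to reach 50 bp — rather than any 50 bp window
touching it — keeps short terminal junk below the threshold from firing
the flag.

# Read mapping and genotype calling

The internal mapper places each read ungapped at its minimal-mismatch
position across both strands, seeded by every read k-mer (k = 20) against
the reference index. Short-read aligners of the BWA family expose a
"fraction of missing alignments" parameter with no analogue in an exact
mapper; it is replaced by a per-read mismatch budget of
$\lfloor 0.05 \cdot \mathrm{length} \rfloor + 1$. Reads with two or more
equally good placements are excluded as ambiguous rather than placed
randomly: output stays deterministic, and the biologically relevant case —
*diverged* paralogs — still mis-maps and feeds the paralogy screen.
Externally produced SAM is ingested into the same structure.

Sites are called with a simplified Maq-style Bayesian model over the ten
unordered diploid genotypes: an observed base $b$ with quality-implied
error $\varepsilon$ contributes $P(b \mid XX) = 1-\varepsilon$ (else
$\varepsilon/3$), heterozygotes emit the average of their two homozygote
distributions, heterozygotes share a prior of 0.001 (configurable; there is no
canonical value) and homozygotes the rest. The call is the maximum
posterior with consensus quality $Q = -10\log_{10}(1 - p_{\max})$ capped
at 99; a site is ambiguous when coverage $\le 5$ or $Q \le 13$
($P = 0.05$), both thresholds read literally as strict inequalities.
Mapping quality does not enter the model (the mapper emits unique-best
placements only) — a documented deviation from Maq. Error probabilities
are clamped to $[10^{-6}, 0.75]$ so zero-quality observations cannot
produce degenerate likelihoods.

Locus genotypes assemble called sites into IUPAC sequences ('N' for
ambiguous), count heterozygous sites, and mark a locus present when mean
coverage across it strictly exceeds 5. The paralogy screen then classifies
each locus: UNTESTABLE when present in at most one selfer, SUSPECT when
one or more heterozygous sites appear in two or more selfing genotypes
(residual heterozygosity under selfing is the signature of collapsed
paralogs), CLEAN otherwise.

# Population genetics

The conservative set keeps loci present in every sample and homozygous in
every selfer; the analysis additionally intersects it with CLEAN loci.
SNP counting compares only sites where both calls are unambiguous
homozygous bases; heterozygous outcrosser sites are excluded rather than
counted as half differences (no convention is established; exclusion avoids
fractional conventions, and the half-difference alternative is a
configuration away in `count_snps`'s comparability rule). Each pair
therefore has its own comparable-site denominator. Watterson's
$\theta_W = S/(a_n L)$ counts segregating sites among the $n$ ingroup
sequences over columns unambiguous in all of them.

# Expression statistics

A fragment is a read pair with at least one uniquely mapped mate; pairs
split across loci are discarded and logged. FPKM is
$\mathrm{count} \cdot 10^9 / (\mathrm{length} \cdot \mathrm{total})$,
which makes $\sum_i \mathrm{FPKM}_i \ell_i \cdot N/10^9 = \sum_i c_i$ an
exact identity the tests assert. Between-sample correlations are Pearson
on log FPKM; loci with zero FPKM in either sample are excluded by default
(log of zero is undefined and there is no single accepted zero
convention), with a pseudocount path available. Confidence intervals are
percentile bootstrap over loci (10,000 replicates in the analysis
scripts; smaller, clearly stated replicate counts in tests where the
property under test does not need more).

Differential expression replaces the original tool's Bayesian
transcript-level model with a two-sided exact binomial test of each
locus's count in sample A against the proportion implied by the two
library totals, with Benjamini–Hochberg q-values at FDR 0.05 — the same
decision contract (per-locus p, FDR control) with a transparent test.
Fold changes from this substitution are not comparable to those of
transcript-level Bayesian models and are reported descriptively only. Shared
differential-expression sets intersect per-selfer results requiring
consistent direction.

GO enrichment takes a pre-propagated gene-to-term map as given and runs
the standard two-tailed Fisher's exact test (sum of all tables with
probability not exceeding the observed table's — stated explicitly
because two-tailed exact tests have competing definitions), BH-corrected.

# Numerical and design choices

* Deterministic tie-breaks everywhere randomness is not wanted: best hits
  by score then lexicographic subject; collapse winners by length then id;
  consensus ties by the longest covering member; ambiguous mappers
  excluded. Two runs of any stage under the same seed are byte-identical,
  and the report manifests (md5 of every table) make that checkable.
* All thresholds involving "exceeds" are strict (`> 5` coverage, `> 13`
  quality, `> 99%` collapse identity, `> 80%` aligned proportion).
* The factor-model correlations require
  `expr_corr_outgroup <= expr_corr_ingroup`; the config rejects the
  reverse.
* Problem sizes in the tests and acceptance script were chosen once as
  desk-scale versions of the emulated design: 500 loci for the end-to-end run,
  10,000 simulated sites for caller concordance, 10 seeds of 50 loci for
  paralog sensitivity, 20 replicates of 60 loci for $\theta_W$ recovery,
  200 datasets for bootstrap coverage, 1000 loci for the
  differential-expression null.
* `ingroup_div_scale` lets a test configure an asymmetric topology (one
  selfer splitting from the outcrosser lineage more recently) and check
  that estimated divergences order accordingly.

# Known limitations

The aligner and mapper are ungapped: data with real indels needs an
external aligner through the SAM/tabular ingest paths. The enrichment
module does not propagate the GO graph. The genotype caller ignores
mapping quality. Quantities that depend on real sequencing data (locus totals,
heterozygous-locus counts, conservative-set sizes, correlation values)
are validated as directional properties only; no desk-scale simulation
can or should reproduce real-data counts, and the tests do not claim to.
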