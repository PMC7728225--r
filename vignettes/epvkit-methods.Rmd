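---
title: "Methods: annotating an entomopoxvirus genome and partitioning its dual-host expression"
author: "epvkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating an entomopoxvirus genome and partitioning its dual-host expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The biological problem

Some parasitoid wasps carry a heritable, mutualistic poxvirus in the venom
gland. The virus is injected into the wasp's host insect (a fly larva)
during oviposition, where it is highly virulent and promotes survival of
the developing wasp. The striking feature of such a symbiosis is
*functional partitioning*: replication-associated viral genes are
up-regulated in the wasp tissue that amplifies the virus, while virulence
genes are up-regulated in the parasitized fly. epvkit implements the
genome-annotation and expression-analysis machinery needed to quantify
this partitioning for a linear double-stranded DNA poxvirus genome, plus a
fully seeded synthetic-data generator so that every stage can be validated
against known ground truth.

## Genome annotation

**Genome model.** A genome is one linear dsDNA record over `A,C,G,T,N`.
All features use 0-based, half-open, forward-strand coordinates
internally; GFF3 export converts to the 1-based inclusive convention. This
single convention keeps interval arithmetic (unions, midpoints, window
extraction) unambiguous.

**ORF calling.** Real poxvirus annotations combine automated callers with
manual curation; for reproducibility epvkit uses one deterministic rule.
In each of the six reading frames, every stop-to-stop segment contributes
at most one ORF: from the *first* ATG of the segment to the stop codon
(the longest ORF per stop). The stop codon is inside the coordinates but
outside the protein; `protein_length` counts the initial methionine, and
the default threshold `min_aa = 50` applies to that count. Codons
containing `N` are not translated: they terminate the segment scan and no
ORF spans them, so no residue is ever fabricated from missing sequence. A
reading frame that runs off a genome end without a stop yields nothing.
The test suite checks the caller against an independent brute-force
enumerator (every ATG, translated codon by codon) on hundreds of random
genomes.

**Repetitive-ORF filter.** Manual discarding of "highly repetitive"
protein calls is replaced by two explicit rules: discard when the most
frequent amino acid reaches 50% of the protein, or when the Shannon
entropy of the overlapping dipeptide distribution falls below 2 bits.
A two-letter alternation (`ARARAR...`) has dipeptide entropy ≈ 1 bit and
is discarded; a protein using all 20 residues sits near `log2(19) ≈ 4.2`
bits and survives. Proteins shorter than two residues have no dipeptides
and are kept. Both thresholds are arguments.

**Inverted terminal repeats.** Poxvirus genomes end in inverted terminal
repeats (ITRs): the reverse complement of the right terminus equals the
left terminus. Detection is a seed-and-extend anchored at the termini: the
first `min_seed = 25` bases must match exactly, and the reported length is
the maximal `L ≤ floor(G/2)` whose cumulative mismatch fraction stays
within `max_mismatch_frac` (default 0.02). With a nonzero tolerance the
extension can legitimately run a few bases past a planted repeat on chance
matches (the mismatch budget grows with `L`), so exact-length recovery is
only guaranteed — and only asserted — at `max_mismatch_frac = 0`.

**Genome metrics.** GC content is computed over called bases only; `N` is
absence of information, not AT. Coding density is the fraction of the
genome covered by the *union* of ORF intervals with both strands pooled,
so overlapping ORFs are not double-counted; the union choice is stated
explicitly because summary statistics published for real genomes rarely
define it, and summed ORF lengths would differ whenever ORFs overlap.

**Early-promoter motif.** Entomopoxvirus early genes carry the conserved
promoter `TGAAAXXXXA` (positions 1–5 `TGAAA`, 6–9 free, 10 `A`) upstream
of the start codon, read on the coding strand by the virion transcription
machinery. The scanner takes the 100 bp immediately 5′ of each ORF's ATG
*on the ORF's strand* (for minus-strand ORFs, the reverse complement of
the forward bases 3′ of the ORF end), truncating at genome ends, and
reports every — possibly overlapping — occurrence with its offset (1 = the
motif ends on the base adjacent to the ATG). The window excludes the ATG
itself. Matches are deliberately not masked against neighbouring coding
sequence: in a gene-dense genome upstream windows routinely overlap
neighbours, and the motif definition makes no such exclusion.

## Functional classification

External homology and domain evidence (in practice the digest of BLAST /
profile searches) enters as a table per ORF: a poxvirus core-gene name, a
Bro-N domain flag (the defining feature of the BRO multigene family), a
virulence-homology flag, and an any-other-function flag. Exactly one
category is assigned by a fixed priority: core replication, then BRO, then
virulence homology, then other function, then — for genes with no assigned
function at all — the early-promoter category if at least one motif hit
exists, else unknown. The priority encodes the convention that a conserved
replication role outranks family membership, which outranks a
single-domain virulence call; promoter-only virulence candidates are by
definition genes with *no* other evidence. The core-gene census compares
recovered core-gene names against a 49-name reference list
(`poxvirus_core_genes`, VACV-style locus tags); duplicate assignments
count once with a warning.

## Comparative genomics

Synteny between two genomes is summarised as a dot plot of shared genes at
their interval midpoints (the anchor must be fixed somewhere; the midpoint
is symmetric under strand flips). Collinear blocks are maximal-cardinality
chains of dots monotone in both genomes — increasing/increasing (`same`)
or increasing/decreasing (`inverted`, the "negative linear arrangement"
of an inverted segment). Chains are found by a longest-monotone-
subsequence dynamic program and extracted greedily (longest chain first,
its points removed, repeat) down to `min_genes = 4`; a parameter-free
combinatorial criterion was chosen over gap- or distance-penalised
chaining because any penalty would be an uncalibrated free parameter at
these scales (tens of core genes). Note that greedy extraction means a
later block is maximal only within the points the earlier blocks left
behind, and that when an increasing and a decreasing run share the axis a
maximal chain may mix points of both.

Phylogeny preparation follows the standard supermatrix recipe: per-gene
protein alignments are trimmed of columns in which *more* than half the
taxa carry a gap (strictly greater — a 4-taxon column with exactly two
gaps survives), then concatenated over an identical taxon set. Tree
inference itself is out of scope; the trimmed supermatrix is written as
FASTA for external tools. Cross-genome metric tables report mean ± sample
SD (n−1) over all genomes except a designated focal genome, the usual way
one contrasts an outlier genome against its family background.

## Expression partitioning

**Normalisation.** FPKM: `count / ((length/1000) · (total/10^6))` with
per-sample totals from the count matrix itself.

**Test.** The published analysis used an RNA-seq pipeline whose internal
model is not reproducible from its description; epvkit substitutes a
defined, auditable test. Per gene, `y = log2(FPKM + 1)` and the two hosts
are compared with a Welch two-sample t-test; the log2 fold change is the
difference of group means of `y` (wasp over fly — a difference of log
means, not the log of a ratio of means, stated because the two differ).
The pseudocount of 1 bounds the transform at zero counts; at the FPKM
magnitudes of these data (tens to thousands) its bias is negligible.
Genes with zero variance in both groups get `p = 1` at equal means
(no evidence) and `p = 0` otherwise (a noiseless difference). P-values are
adjusted by Benjamini–Hochberg step-up and called significant at
`q < 0.05`. The test is deliberately swappable: the package's
contribution is the partition bookkeeping, not the test internals.

**Clustering.** Significant genes are clustered on their
`log10(FPKM + 1)` sample profiles by Ward-linkage agglomerative
clustering on Euclidean distances (`hclust(method = "ward.D2")`, the
Lance–Williams Ward criterion), cut at `k = 2`. Clusters are then *named*
by effect sign — higher mean log2fc becomes `up_in_wasp` — with a
deterministic lexicographic tie-break, so labels never depend on merge
order or a random start.

**Partition summary.** The headline quantities are the DE fraction, the
two cluster sizes, the category × {up, down, not-DE} contingency, the
percentage of core-replication genes in the up-in-wasp cluster, the
percentage of virulence genes (all three subcategories) in the
down-in-wasp cluster, and per-cluster mean log2 fold changes. Because a
published "average fold change" can be read as signed or absolute, both
are reported; the absolute reading is what the linear "about 5× up /
more than 10× down" conversions use. Percentages are rounded to one
decimal, matching how such results are conventionally printed.

## The synthetic-data generator

The generator exists so that every pipeline stage has a ground truth.

**Genome.** `ITR | interior | revcomp(ITR)`. Defaults model the study
system at roughly one-fifth scale: 50 kb, 2 kb ITRs, 40 ORFs with
category proportions matching a 193-gene annotation (9 core, 6 BRO, 2
homology, 7 promoter-only, 4 other, 12 unknown) and 30.1% background GC.
ORFs are placed non-overlapping on random strands, each as an in-frame
stop barrier followed by `ATG`, random sense codons, and a stop — the
barrier guarantees the planted ATG is the first in its segment, so the
deterministic caller recovers planted coordinates exactly. Three guards
make recovery clean rather than merely probable: spacers are scrubbed of
`TGAAA`/`TTTCA` so no upstream window carries an accidental promoter
motif (each promoter-category gene then receives exactly one planted
motif, offset ≤ 46 bp); the planted motif's free positions exclude the
one 4-mer that would make it self-reverse-complementary; and the interior
base adjacent to each ITR is forced to break terminal complementarity so
exact-match detection stops exactly at the planted length. Spacer minima
(≥ 103 bp) keep every 100 bp window inside scrubbed sequence.

**Counts.** Six replicates per host. Fly-group means are log-uniform on
[50, 500]; the wasp-group mean is the fly mean times `2^lfc` with
category-level planted effects (+2.3 core, −3.4 all virulence
subcategories, 0 elsewhere) plus per-gene N(0, 0.5²) jitter on the
affected categories — jitter makes clustering non-trivial without turning
null categories into real effects, which would contaminate the null
control. Counts are negative binomial with
`variance = mu + dispersion · mu²` (`dispersion = 0.05`; Poisson at 0),
the parameterisation standard in count-model work.

One design point deserves emphasis. Depth normalisation measures
*relative* abundance, so a planted fold change is identifiable from FPKM
only if total expression is conserved between the hosts; otherwise every
gene inherits a compositional shift of `−log2(Σμ·2^lfc / Σμ)` (about 0.7
at the default effects — large enough to make null genes significantly
"DE"). The generator therefore rescales the base abundances of the
down-regulated genes by the unique factor that balances total
up-regulation against total down-regulation. This is not a trick: it
encodes the partitioning hypothesis itself — the viral transcript pool
shifts composition between hosts at conserved output — and it makes each
planted log2fc exactly the expected FPKM-scale difference. A consequence
worth noting for realism: virulence genes end up highly expressed in the
fly, as observed in the real system.

**What passing synthetic tests does and does not show.** The generator
emulates the *structural* features the algorithms key on (ITRs, clean ORF
cassettes, planted motifs, category-level expression shifts with NB
noise). It does not emulate overlapping or nested genes, sequencing or
assembly error, GC heterogeneity along the genome, host-read
contamination, gene-level dispersion variation, or any correlation
between expression and genomic position. Recovery of planted truth
therefore validates the implementations and their contracts, not the
biological accuracy of any particular published estimate.

## Problem sizes and numerical choices

The validation suites use 100 random genomes of 1–10 kb for ORF-caller
oracle equivalence, 100 permutations of up to 15 points for the
collinear-block oracle, a 500-gene 6 + 6 study for effect recovery
(category mean log2fc within ±0.3 / ±0.4 of the planted +2.3 / −3.4,
cluster-versus-truth adjusted Rand index ≥ 0.9), and a 500-gene null run
(DE fraction ≤ 7% at `q < 0.05`). Ties in cluster naming and chain
selection are broken lexicographically or by genomic position — never by
randomness — and all simulation randomness flows from explicit integer
seeds, so identical seeds give byte-identical genomes, counts and
artifacts.

## Known limitations

The single ORF rule cannot represent programmed frameshifts or
non-AUG starts; ITR detection assumes the repeat begins exactly at
position 0 (real termini may carry short unique caps); the Welch-on-log
test is a pragmatic stand-in for a count model and will be conservative
at very low counts; collinear blocks ignore gene orientation within the
chain; and the core-gene reference list shipped with the package is a
naming convention, not a curated orthology resource — users with a
curated list should pass their own.
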