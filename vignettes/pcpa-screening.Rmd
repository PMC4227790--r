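---
title: "Screening promoter-proximal intronic polyadenylation and cryptic 3' splice sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening promoter-proximal intronic polyadenylation and cryptic 3' splice sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcpascreen)
```

## The biological model

RNA polymerase II transcripts are normally protected from intronic poly(A)
signals by U1 snRNP ("telescripting"). When that protection fails at a
promoter-proximal signal, the transcript undergoes premature cleavage and
polyadenylation (PCPA): the upstream exon and the retained intron prefix
become a *composite terminal exon*. Because that composite exon still
carries the authentic 5' splice site, a sufficiently strong intronic
branch-point/acceptor pair between the 5' splice site and the poly(A) signal
can be spliced to it, producing a cryptically spliced PCPA product (CSPP).
Four isoform classes therefore matter: the annotated mRNA, the PCPA
transcript, the CSPP transcript, and the read-through pre-mRNA that ignores
the intronic signal and is not polyadenylated there.

`pcpascreen` implements the in-silico side of this biology: a positional
screen for PCPA-prone introns, consensus-value calling of cryptic acceptors,
construction of the isoform and reporter models, and a 3' RACE simulator
that predicts which amplicons discriminate the isoforms.

## The screen and its parameters

Stage 1 keeps an intronic signal hexamer when all of the following hold,
measured along the transcript (never as raw genomic deltas, so minus-strand
genes behave identically):

| parameter | default | meaning |
|---|---|---|
| `signal_set` | `AATAAA` | hexamers searched; the canonical signal only, variants opt-in |
| `max_tss_dist` | 5000 nt | TSS to hexamer start, transcript path, inclusive |
| `allowed_intron_ordinals` | 1, 2 | host intron position in transcription order |
| `min_intron_len` | 1000 nt | host intron length |
| `max_5ss_dist` | 1000 nt | 5' splice site to hexamer start, inclusive |
| `refined_max_5ss_dist` | 500 nt | refinement bound, **strict** (`< 500`) |

The deliberate asymmetry — inclusive 5 kb/1 kb bounds but a strict 500 bp
refinement — preserves the distinction between "within" and "less than" in
the screen's defining criteria. Distances are measured to the hexamer's
first base, and a hexamer straddling an exon/intron boundary is not
intronic. When an annotation carries several transcripts per gene, each is
screened independently; gene-level funnel counts deduplicate, keeping the
hit with the smallest TSS distance as a transcript's "best" (promoter
proximity is the screen's organising principle).

Stage 2 scans the region between the 5' splice site and each
refinement-passing hexamer for a 7-mer branch site followed by a 14-mer
acceptor window. The acceptor layout is 13 intronic positions ending in the
invariant AG plus one exonic position; the cryptic junction falls after the
AG. Both windows are scored with the classical Shapiro–Senapathy consensus
value,

$$\mathrm{CV}(w) = 100\,\frac{S - S_{\min}}{S_{\max} - S_{\min}},\qquad
S = \sum_p F[p, w_p],$$

and kept when CV ≥ 39.41 (acceptor) and CV ≥ 50.16 (branch). These
thresholds are used as raw consensus values. The branch 7-mer must end 18–44
nt upstream of the junction (`branch_spacing`), the standard metazoan
branch-point distance range; the source screen specified only "followed by",
so the window is exposed as a parameter. When several branch windows
qualify, the pair reports the strongest (ties: nearest the junction, then
5'-most) — a deterministic rule shared with the package's brute-force test
oracle. Called sites are ranked by distance to the poly(A) signal, ties
toward the higher acceptor CV, then the 5'-most site; rank 1 is the
cleavage-proximal site that minigene mutagenesis inactivates first.

Two choices here were genuinely open. First, web splice-site scorers do not
document their exact normalisation or window registration, so this package
implements the classical consensus-value formula above and treats the window
layout as a property of the matrix file (`exonic_from`, `required`), letting
users substitute tool-exact matrices. Second, published thresholds could be
percentile-calibrated rather than raw; they are treated as raw CV defaults
and exposed in `screen_params()`.

### The shipped matrices

`default_matrices()` loads plain-text frequency tables from
`inst/extdata/matrices/`. They are *synthetic defaults* constructed from the
consensus descriptions of the human signals — a pyrimidine-rich acceptor
tract, C-biased −3, invariant AG, G-biased first exonic base, and a
yUnAy-type branch heptamer with a near-invariant branch-point adenosine —
not a copy of any published compilation. Every package test and acceptance
property (consensus scoring 100/0, threshold sharpness, recovery) is
matrix-agnostic, so swapping in compilation-derived tables changes no
contract. Production genome scans should use such tables.

## Transcript, cis-element and reporter models

`build_transcript()` materialises each isoform as segments plus sequence:

* **PCPA**: upstream exon(s) + host-intron prefix ending at the modeled
  cleavage position. The cleavage site is `cleavage_offset` (default 15 nt)
  past the hexamer end — the true offset is not fixed by the upstream
  literature, which anchors RACE primers "immediately upstream of the
  cleavage site", so it is a free, surfaced parameter.
* **CSPP**: the PCPA model with the interval from the authentic 5' splice
  site to the cryptic junction excised, which yields the length identity
  `len(CSPP) = len(PCPA) − junction_offset` that the tests assert for every
  construct. CSPP construction additionally requires an intact GT donor, so
  a donor mutation abolishes CSPP but not PCPA.
* **read-through**: exons plus intron sequence continuing past the cleavage
  position, not polyadenylated.

Polyadenylated kinds carry a modeled 30-A tail (`polya_tail_len`), the
minimum structure oligo-dT-primed RACE needs. Cis-elements default to the
−157..+51 fragment around the hexamer; reporter constructs accept insertion
into the intron or the 3' exon, with optional neutralisation of the vector
poly(A) cassette by the exact `aataaa → ggatcc` substitution. Targeted
mutations are minimal: GT→GA for donors, AATAAA→GGATCC for signals, AG→AT
for cryptic acceptors — with one guard: in an A-rich context AG→AT can
itself complete a new AATAAA, in which case AG→AC is applied instead (C
occurs in no signal hexamer).

## 3' RACE simulation

Reverse transcription is modeled by appending the adaptor tag's reverse
complement after the tail of every polyadenylated transcript; read-through
templates produce no cDNA and can never amplify. The first round pairs a
gene-specific forward primer with the adaptor primer; the nested round uses
a chimeric primer of 12 Ts plus an anchor complementary to the sequence
immediately upstream of the cleavage site, so it amplifies exactly the
templates sharing that terminus. Anchor length is configurable (default 8
nt) since gene-specific anchor sequences are not published. Matching is
exact — the discrimination logic depends on perfect anchors — and cycle
numbers (>35 first round; 10/15/20 nested for mRNA/PCPA/CSPP) are carried as
metadata, not simulated kinetically: in the wet assay cycles tune detection
sensitivity, which a deterministic simulator cannot meaningfully model.
Amplicons are classified by diagnostic junction 16-mers: exon/intron
boundary retained → PCPA; exon joined to the cryptic junction → CSPP;
annotated exon–exon junction → mRNA; none → ambiguous.

## The synthetic-genome generator

`generate_toy_genome()` builds one gene per contig on alternating strands:
3 exons of 150–250 nt, a host first intron of 1100–1600 nt (comfortably
above the 1 kb rule), remaining introns 400–800 nt, uniform background
composition, 100 nt flanks. Each non-decoy gene carries one AATAAA planted
300–420 nt from the 5' splice site (passing the strict refinement) and
`n_cryptic_sites` branch/acceptor pairs planted at 30/120/260 nt from the
signal — the three-site cascade geometry — with windows sampled into
consensus-value bands (default 65–95, above both thresholds) by
`sample_motif_with_cv()`, a seeded hill-climbing sampler. Decoy modes plant
the same real elements in positions that fail one rule (last intron, or
1500 nt from the 5' splice site).

Scrubbing makes recovery exact rather than probabilistic: unplanted
hexamers are destroyed by point edits, spurious above-threshold acceptor
registers lose their AG, and background branch windows that would prop up a
deliberately sub-threshold planted site are weakened base by base —
replacements drawn only from C/G so no edit can create a hexamer, and only
outside planted footprints. Sampled windows are rejected if they contain a
signal hexamer or a stray AG (which would open an unscrubbable register
inside a footprint); a gene whose constraints cannot be satisfied is
regenerated, and impossible geometry fails fast with the gene named.
Generation is fully deterministic under a seed, to the byte.

What the generator does *not* emulate: realistic base composition, repeats,
splice-site context beyond the planted motifs, multi-isoform annotation, or
read-level noise. Passing tests therefore demonstrate the correctness of
the screen's logic under known ground truth — not calling performance on
real genomes, where matrix quality and annotation choice dominate.

## Verification strategy and problem sizes

The test suite compares the production screen — hit by hit, acceptor by
acceptor, including CVs and ranks — against naive nested-loop reference
implementations on about 100 miniature genes (total genome under 50 kb:
exons ~60 nt, host introns ~150 nt, with the positional parameters scaled to
`min_intron_len = 100`, `max_5ss_dist = 100`, refinement < 80 while keeping
the rule structure and the CV thresholds untouched). Recovery and threshold
sharpness run across 20 seeds at that scale; the mutation cascade, length
identities and RACE checks run at the default scale on 2-gene genomes.
These sizes were chosen so the full suite and the acceptance script each
complete in about a minute while still covering both strands, both intron
ordinals, decoys and every boundary case; all quantities are scale-free
properties, not estimates that improve with n.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open internally; writers emit each format's
native convention (BED 0-based half-open, GTF 1-based closed). `N` never
matches any motif and windows containing `N` are skipped with a warning
rather than scored. A region shorter than the matrix width yields an empty
scan, a motif longer than its target an empty hit list, an empty annotation
an empty, zero-filled funnel; single-exon genes simply have no introns.
Frequency matrices must have rows summing to 1 (tolerance 1e-6). All
tie-breaks (branch choice, site ranking, gene-level best hit) are total
orders, making every output deterministic given the input.

## Known limitations

* The default matrices are descriptive stand-ins (see above).
* The screen scores no donor strength and no polypyrimidine tract beyond
  what the acceptor matrix captures.
* `fraction_genes_with_proximal_intronic_pA` applies the TSS-distance
  criterion alone, deliberately looser than the full stage-1 rule set, and
  is labeled as such in the funnel.
* PCR efficiency, annealing thermodynamics and gel mobility are out of
  scope; the RACE simulator is a combinatorial, not a physical, model.
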