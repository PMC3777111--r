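# kinclass

Draft kinome annotation for predicted proteomes: identification of
eukaryotic protein kinase (ePK) superfamily members and their
classification into the hierarchical Hanks–Hunter group/family/subfamily
vocabulary (e.g. `CMGC/CDK/CDC2`), for genome annotators and comparative
kinomics.

Profile searches alone miss the kinases that matter most to a curator:
conserved *unusual* kinases (Bub, Bud32, Haspin, SCYL, SLOB) and protein
kinase-like atypical kinases (RIO, ABC1) score poorly against models
built from typical kinases, while divergent *twilight* sequences carry
recognisable catalytic motifs without passing any profile threshold.
`kinclass` combines three signals in a three-phase pipeline:

1. **Candidate selection** — every protein is scored against a
   position-specific profile built from a curated kinase-domain
   alignment (column log-odds
   `s_c(a) = log2(((n_c(a) + τ·b_a)/(N + τ))/b_a)`, affine-gap local
   alignment); a relaxed E-value cutoff shrinks the search space without
   losing divergent kinases.
2. **Identification** — candidates the profile would miss are *rescued*
   when their top hit against a curated reference kinome database is
   strong (rank-1 E ≤ 1e−20 by default), inheriting category `aPK` or
   `unusual_ePK`; the rest pass a functional-residue motif gate (each
   alignment column's *viable* residues weighted `1/|viable set|`,
   inverse to column variability, normalised to [0, 1]) and two profile
   score cutoffs, separating high-confidence ePKs from twilight hits
   ("protein kinase subdomain-containing proteins") and subthreshold
   rejects.
3. **Classification** — the first *n* (default 3) labelled top
   similarity hits must agree at a level, and assert it, for that level
   to be called: full depth on unanimity (subfamily additionally gated
   by `log10 E ≤ −30`), partial group or group/family calls otherwise,
   unclassified on group disagreement ("serine/threonine protein
   kinase", flagged), and a conservative TK→TKL rewrite outside
   metazoan mode (`-m`).

The result is a **draft kinome**: per-protein calls with classification
depth 0–3, a summary with the kinome as a percentage of the proteome and
missing *core* kinases (labels present in every designated reference
kinome), a phylogenetic profile against the reference species, gene
product names, and the parameter file of the run.  An evaluation module
scores a draft kinome against a curated truth set at identification,
partial- and full-classification levels (TPR = TP/P, PPV, FDR, F, with
the paper-table conventions for partial credit: correct-but-shallower
is a partial TP, any wrong assertion is FP), macro-averages across
species, and traces ROC curves over any cutoff.  A deterministic
synthetic-data generator plants typical, unusual, species-specific,
atypical, twilight and non-kinase sequences with matching truth for
end-to-end validation.

## Worked example

```r
library(kinclass)

# synthetic study world: reference db + alignment + 250-protein proteome
# (50 planted kinases) + truth + calibrated cutoffs
fx <- make_fixture(fixture_spec(seed = 1))
kinome <- call_kinome(fx$scores, fx$params)
kinome
#> Draft kinome: 50 kinases in a proteome of 250 proteins
#>           aPK           ePK non_candidate  subthreshold      twilight
#>             5            40           188             6             6
#>   unusual_ePK
#>             5

summarize_kinome(kinome, fx$db)
#> Total kinases:         50
#> Unclassified:          0
#> Percent of proteome:  20%
#> Per group:
#>   Atypical: 5
#>   G1: 13
#>   ...
#> Missing core kinases:  8

confusion_metrics(confusion_counts(fx$truth, kinome, "identification"))
#> TPR=1.0000 PPV=1.0000 FDR=0.0000 F=1.0000
```

All 50 planted kinases are recovered with no false positives: the 40
ePKs include the 4 species-specific plants (classified only to group
depth), all 5 unusual kinases are rescued despite sub-threshold profile
scores, the 5 atypical copies inherit `aPK`, and the 6 twilight plants
are recorded outside the kinome.  The missing-core list names the
reference labels absent from this (deliberately small) proteome.

Real data run through the same functions with a user-supplied reference
FASTA (`>id|species|group/family/subfamily|ePK` headers or a companion
TSV) and domain alignment, optionally substituting HMMER and BLAST
output files for the native search engines:

```r
db  <- load_reference("refdb.fasta")
aln <- read_alignment("alignment.fasta")
kin <- annotate_proteome("proteome.fasta", db, aln, default_params())
write_outputs(kin, db, "kinome_out")
```

or from the shell via the thin CLI wrapper:

```sh
Rscript inst/scripts/kinclass.R annotate --proteome proteome.fasta \
    --refdb refdb.fasta --alignment alignment.fasta -o kinome_out
```

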