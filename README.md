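# homint

Homology-based prediction of protein–protein interface residues in R.

## The problem

Knowing *which residues* of a protein touch its binding partners guides
mutagenesis, docking and the interpretation of disease variants, but solved
complex structures exist for only a fraction of known proteins. When a
query protein has sequence homologs that *are* part of experimentally
solved complexes, their observed interfaces can be transferred onto the
query through the alignment. `homint` implements this transfer rigorously,
in two flavours:

* **NPS (non-partner-specific)** — predict the union of a protein's
  interface residues over all partners, from BLASTP hits against a template
  database of structurally characterised chains.
* **PS (partner-specific)** — given a query *pair* A–B, find
  *homo-interologs*: pairs (A′, B′) of homologs of A and B that interact
  within one solved complex, and transfer A′'s interface *with B′* onto A.
  Partner specificity matters most for transient complexes, whose union
  interfaces look poorly conserved even when each pairwise interface is
  highly conserved.

## The method

Each BLASTP hit is summarised by six alignment statistics: log *EVal*
(natural log; −450 when *EVal* = 0), identity and positive scores (% of
alignment columns), log *LAL* (local alignment length), and the two length
fractions *LAL*/len(query) and *LAL*/len(template). Hits fall into
**Safe / Twilight 1 / Twilight 2 / Dark homology zones** via threshold
tables (e.g. NPS Safe: log EVal ≤ −100, positive ≥ 80 %, log LAL ≥ 5.2);
prediction uses the strictest populated zone. Within a zone, templates are
ranked by a linear **interface-conservation (IC) model**,

    IC_nps = −0.5655 − 0.0004·logEVal + 0.0037·PositiveScore + 0.1057·logLAL
    IC_ps  = −0.505  + 0.001·avgLogEVal + 0.009·avgPositive + 0.341·Frac_AA′ + 0.205·Frac_BB′

where IC is the Matthews correlation between transferred and true labels.
The at most K = 10 best templates then vote per query position: an aligned
template residue votes for or against interface status (abstaining on
unresolved `?` positions and gaps), and a residue is called an interface
residue when the positive-vote fraction is ≥ 0.5.

Gold-standard labels come from structures: a residue is an interface
residue when it is a surface residue (relative solvent accessibility
≥ 5 %, Shrake–Rupley on the unbound chain) with any atom within 4 Å of a
partner chain. Templates are retained only from X-ray structures at
≤ 3.5 Å resolution with ≥ 3 interface residues; self hits and same-species
near-identical hits (≥ 95 % identity) are removed.

A synthetic generator (`make_complex()`, `mutate_homolog()`,
`make_ps_scenario()`) builds toy complexes with analytically known contacts
and homolog families with exact ground-truth alignments, so the whole
pipeline is testable offline.

## Worked example

```r
library(homint); library(dplyr)

sim   <- make_complex(seed = 42, len_range = c(55, 65), contact_patch_size = 6)
truth <- label_interfaces(sim$complex)          # structure-derived labels
qchain <- sim$complex$chains$chain[1]
qseq   <- sim$complex$chains$sequence[1]
qlab   <- truth$label[truth$chain == qchain]

tms <- lapply(1:3, function(i)
  mutate_homolog(qseq, qlab, sub_rate = 0.15, interface_bias = 0.8,
                 template_id = paste0("tmpl", i), seed = i))
hits <- alignment_stats(bind_rows(lapply(tms, `[[`, "record")))
classify_zone_nps(hits) |> select(template_id, log_eval, positive_score, log_lal, zone)
#>   template_id log_eval positive_score log_lal zone
#> 1 tmpl1          -68.0           87.3    4.01 Twilight1
#> 2 tmpl2          -71.0           92.7    4.01 Twilight1
#> 3 tmpl3          -71.0           90.9    4.01 Twilight1
```

All three templates land in Twilight Zone 1 (log EVal ≤ −50, positive
≥ 65 %, log LAL ≥ 4): usable, though not Safe. Predict and evaluate:

```r
labels    <- bind_rows(lapply(tms, `[[`, "labels"))
templates <- tibble(chain = paste0("tmpl", 1:3),
                    sequence = sapply(tms, `[[`, "sequence"),
                    species = c("E.coli", "B.subtilis", "T.thermophilus"),
                    method = "xray", resolution = 2.1)
kept <- filter_homologs(hits, qseq, "H.sapiens", templates, labels)
pred <- predict_nps(qchain, qseq, kept, labels)
glance(pred)
#>   query_id predicted zone      n_templates n_positions n_called n_no_vote
#> 1 cx_A     TRUE      Twilight1           3          55        6         0
tidy(pred) |> filter(call == 1)
#>   query_id   pos aa    vote_score n_votes  call
#> 1 cx_A         2 I              1       3     1
#> 2 cx_A         3 D              1       3     1
#> ...                                    (6 rows: positions 2-7)
evaluate_predictions(tidy(pred), truth)$overall |>
  select(basis, sensitivity, specificity, accuracy, cc)
#>   basis   sensitivity specificity accuracy    cc
#> 1 protein           1           1        1     1
#> 2 residue           1           1        1     1
```

All six residues of the generated contact patch are recovered; sensitivity
and precision (which this package, following the field's older usage,
reports as "specificity") are 1. `predict_ps()` works analogously from
`find_interologs()` output, and `autoplot()` draws the vote profile.

A thin command-line front end (`inst/cli/homint.R`) exposes
`predict-nps`, `predict-ps`, `label`, `evaluate` and `simulate`
subcommands over files (FASTA, BLAST tabular, label TSV, PDB).

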