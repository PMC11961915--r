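# pol3kit

Computational derivation and evaluation of RNA polymerase III (Pol III)
promoters for CRISPR guide expression in monocots.

CRISPR endonucleases such as LbCas12a need their guide RNAs (crRNAs)
transcribed in the nucleus, which in plants is routinely done from U6/U3
snRNA Pol III promoters. Only a handful of such promoters are characterized
in maize, and repeating the same promoter across a multiplexed construct
invites clonal instability and silencing. `pol3kit` addresses this by
deriving *novel* Pol III promoters from a training set of monocot U6/U3
promoters, and by quantifying the genome-editing outcomes those promoters
enable — from amplicon reads down to population-level "advanceable plant"
statistics.

The package is aimed at plant biotechnologists and computational biologists
building crRNA expression constructs: it covers the full path
training set → motif discovery → scoring model → sequence design →
promoter grammar validation → cassette assembly → editing analysis,
plus seeded synthetic-data generators for every input so each step is
testable against known ground truth.

## The model

**Promoter grammar.** Monocot U6/U3 promoters carry three conserved
elements upstream of the transcription start site (TSS): a TATA box near
−30, the upstream sequence element (USE, consensus `TCCCACATCG`) whose
spacing to the TATA box is a major determinant of Pol III recognition, and
one or more monocot-specific promoter elements (MSP, consensus `RGCCCR`)
5′ of the USE.

**Motif discovery.** Training windows (−500 to +50 around the TSS) are cut
into 5 equal positional bins; every 6-mer is counted per bin in foreground
and background, scored by a one-sided binomial upper-tail test against the
background per-position rate, and enriched words are greedily merged
(Hamming distance ≤ 1 from each seed) into IUPAC consensi.

**Promoter-likeness score.** For a sequence *x* scored against a trained
model,

```
S(x) = w_f · (1/P) Σ_p log f_b(p)(w_p)            position-specific 6-mer frequency
     + w_e · (1/P) Σ_p log [ f_b(p)(w_p) / g_b(p)(w_p) ]   enrichment vs background
     + w_h · H(dinucleotides of x)                dinucleotide entropy (nats)
```

where `w_p` is the 6-mer starting at position *p*, `b(p)` its positional
bin, `f` and `g` the pseudocount-smoothed training and background
frequency tables, and `H ≤ log 16`. Terms are per-position means, so
weights (default 1, 1, 1) are length-scale-free and 500-bp designs are
comparable with 280–300-bp trimmed promoters.

**Design.** Starting from a random sequence with one MSP, USE and TATA
instance seeded at training-consistent offsets (and locked), single-base
substitutions are proposed under Metropolis simulated annealing with
geometric cooling, maximizing `S(x)`. Finished designs are trimmed 5′-only
to 280–300 bp, keeping every grammar element.

**Editing analysis.** Reads are aligned glocally (global in the read,
local in the amplicon) with affine gaps; a fragment carries an indel iff
an inserted/deleted base intersects the PAM + protospacer window
(`Indel% = 100 × indel reads / total reads`). Population summaries report
the mean indel rate and the fraction of plants strictly over the 10%
"advanceable" threshold; promoter activity is called against a control's
mean − SD at every assayed site.

## Worked example

```r
library(pol3kit)

## 1. synthetic training set (42 U6 + 24 U3, known element truth) + model
ts <- generate_training_set(training_set_spec(seed = 1))
model <- train_model(ts$records, bg_seed = 1)
model
#> <promoter_score_model> 6-mers, 5 bins, window -500/+50, U6_and_U3, 66 training seqs

## 2. position-binned motif discovery recovers the grammar
head(motif_table(discover_motifs(ts$records, bg_seed = 1)), 3)
#>   consensus bin_index bin_start bin_end fg_count bg_count enrichment_p log_odds
#> 1    KCCCAC         3      -170     -60       67        3     1.23e-63     2.83
#> 2    CCCACA         3      -170     -60       48        1     4.13e-59     3.48
#> 3    RGCCCR         3      -170     -60       66        3     3.10e-56     2.61

## 3. design, trim, validate
design <- design_promoter(model, design_config(schedule = anneal_schedule(seed = 7)))
design
#> <designed_promoter> 500 bp, total score -5.4688 (seed 7)
spacing <- learn_spacing(ts$records)
trimmed <- trim_promoter(design, spacing = spacing, model = model)  # 280 bp
ann <- annotate_elements(promoter_record("GSP_demo", trimmed, nchar(trimmed)),
                         spacing = spacing)
ann$annotations[ann$annotations$primary, c("element", "start", "end", "matched_seq")]
#>   element start  end matched_seq
#> 1    TATA   -30  -24      TATAAA
#> 2     USE   -63  -53  TCCCACATCG
#> 3     MSP  -140 -134      AGCCCG

## 4. crRNA cassette (promoter + LbCas12a repeat + spacer + poly-T)
build_cassette("GSP_demo", trimmed, "AGCCTACGGAGCTACGGACATCG", mode = "simplex")
#> <crrna_cassette> GSP_demo, simplex, 1 spacer(s), 331 bp

## 5. simulated edited amplicon reads -> indel calls (exact at error rate 0)
site <- synthetic_target_site(seed = 11)
sim <- generate_edited_reads(edit_sim_spec(site, true_edit_rate = 0.42,
                                           n_fragments = 1000, seed = 12))
call_reads(sim$pairs, site)
#> <amplicon_callset> synthetic_site: 420/1000 fragments with indel (42.0%), 0 dropped

## 6. per-plant population summary (copy-number filtered, >10% advanceable)
pop <- generate_population(data.frame(construct_id = "GSP_demo_1PX1",
                                      n_plants = 40, shape1 = 4, shape2 = 1.8),
                           seed = 13)
summarize_population(pop$plants)[, 1:5]
#>    construct_id n_plants mean_indel_pct n_advanceable advanceable_rate_pct
#> 1 GSP_demo_1PX1       33           74.4            33                  100
```

The trimmed design annotates as a valid promoter (all three elements, both
spacing gaps inside the learned rule); the cassette length is exactly
promoter + 21-nt repeat + 23-nt spacer + 7-nt terminator; the caller
recovers the generator's planted 42% edit rate exactly; and the population
summary reports the 33 of 40 plants that survive the one/two-copy filter,
all of them above the advanceable threshold.

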