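# repeatnet

Nucleotide-level annotation of four classes of genomic repetitive
elements — HSAT2,3 satellites, alphoid (alpha) satellite, Alu SINEs and
LINE-1 retrotransposons — with a small recurrent neural network, for
anyone who needs per-base repeat tracks or masks without an alignment
library: genome annotators, repeat biologists, and pipeline authors who
want a trainable, seedable annotator that learns from existing
RepeatMasker-style annotations and transfers them to new assemblies.

## Method

Sliding windows (342 bp, step 50 by default) of the sequence and its
reverse complement are one-hot encoded over `{A,C,G,T,N}` and processed
by a **shared-weight bidirectional GRU**: one weight set reads both
strands, per-position outputs are averaged in forward coordinates, and
an **additive attention** layer scores each position against the
averaged final hidden state to form a context vector.  A position-wise
softmax yields class probabilities `p_i^c`.  Overlapping windows are
combined per position by the maximum, then scored as

```
q_i = min(max_c p_i^c, 0.99),   c_i = argmax_c p_i^c
s_i = ln(q_i/(1-q_i))           if c_i is a repeat class
s_i = -10 ln(q_i/(1-q_i))       if c_i = no-repeat
```

and segmented by the all-maximal-scoring-segments algorithm extended by
a minimum-score threshold and an X-drop rule.  Segments inherit their
majority class, are split into single-class runs, filtered at >50 bp,
and written as BED5.  Training uses class-balanced batches (fraction
`r` of each batch must contain repeats, evenly across the four
classes), substitution-noise augmentation, Adam, and early stopping
with patience 10 on a validation sequence.  Evaluation offers per-base
confusion matrices, FPR/FNR, multi-class and one-vs-rest Matthews
correlation, and boundary matching with a ±δ bp tolerance.

A structural genome simulator (tandem ATTCC-motif arrays, 171 bp
monomer arrays, dispersed 300 bp and truncated 6 kb consensus copies,
all mutated and planted in uniform background with exact truth BED)
makes the whole pipeline trainable and testable offline.

## Worked example

```r
library(repeatnet)

lib_seed <- 97L   # one repeat-family library shared by both genomes
train_sim <- simulate_genome(sim_config(genome_length = 200000L,
                                        seed = 11L, library_seed = lib_seed))
val_sim   <- simulate_genome(sim_config(genome_length = 60000L,
                                        seed = 12L, library_seed = lib_seed))
test_sim  <- simulate_genome(sim_config(genome_length = 100000L,
                                        seed = 13L, library_seed = lib_seed))
train_sim
#> <sim_result> sim: 200000 bp, 45 planted elements
#>   ALPHOID    3762 bp (1.88%)
#>   ALU        9921 bp (4.96%)
#>   HSAT23     4015 bp (2.01%)
#>   LINE1     16394 bp (8.20%)

lab <- function(s) records_to_label_track(s$truth, nchar(s$sequence))
model <- build_model(model_config(recurrent_units = 32L), seed = 1L)
fit <- train(model, train_sim$sequence, lab(train_sim),
             val_sim$sequence, lab(val_sim), train_config(seed = 1L))

track <- predict_sequence(fit$model, test_sim$sequence, step = 50L)
segments <- call_segments(track)
head(segments, 3)
#>   start  end class_id class_name    score length
#> 1  1190 2950        4      LINE1 6356.055   1760
#> 2  5100 5942        2    ALPHOID 3856.319    842
#> 3  6192 6451        3        ALU 1145.591    259

pred <- segments_to_label_track(segments, nchar(test_sim$sequence))
mcc_k(confusion(pred, lab(test_sim)))
#> [1] 0.8895391
```

Training runs about seven minutes on one CPU core (early stopping after
~50 epochs).  The MCC value is the 5-class Matthews correlation over
all 100,000 test positions — each segment is a called repeat interval
with its class and summed position score; per-class FPR/FNR and
boundary metrics come from `evaluate_prediction()`.  Numbers vary
mildly with the seeds (MCC roughly 0.80-0.89 across seeds under these
conditions).

The same pipeline is available from the shell via the installed
`repeatnet` script (`exec/repeatnet`):

```sh
repeatnet simulate --config sim.cfg --out-dir fixture/
repeatnet train    --fasta fixture/genome.fa --labels fixture/truth.bed \
                   --config train.cfg --out model/
repeatnet predict  --fasta fixture/genome.fa --model model/ --out pred.bed
repeatnet evaluate --pred pred.bed --gold fixture/truth.bed --out metrics.txt
```

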