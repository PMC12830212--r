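# cncgat

Bifunctional lncRNA classification with k-mer De Bruijn graph attention
networks.

## The problem

Some transcripts annotated as long non-coding RNAs also encode functional
micropeptides — they are *bifunctional* (coding **and** non-coding, often
called cncRNAs). Recognizing them from sequence alone matters for RNA
biology and biomarker discovery, but the signal is subtle: a short open
reading frame with a plausible translation-initiation context buried in an
otherwise non-coding transcript. `cncgat` is an R implementation of a
graph-attention approach to this problem, aimed at computational biologists
who want a self-contained, inspectable pipeline with built-in
interpretability analytics and a synthetic benchmark generator.

## The model

1. **Graph construction.** Each transcript `N1 N2 … NL` is segmented into
   overlapping k-mers (default k = 3) and converted into a directed
   De Bruijn graph: nodes are the distinct k-mers, an edge `N1N2N3 → N2N3N4`
   carries the count `W_ij` of the spanning (k+1)-mer. Edge weights are
   normalized as

   `W̃_ij = W_ij / sqrt( Σ_p W_ip · Σ_q W_qj )`

   (out-weight sum of the source times in-weight sum of the target), which
   removes absolute-abundance effects while preserving local topology.

2. **Node features.** k-mers are treated as words and embedded with a CBOW
   word2vec model (d = 64) trained on the k-mer "sentences" of the training
   transcripts; the embedding of a k-mer is the feature vector `h_i` of its
   node.

3. **Graph attention.** A multi-head GAT layer (K = 3 heads, 64 hidden
   units per head) computes, for node i with in-neighborhood N(i),

   `h'_i = ‖_k ( α_ii^k W^k h_i + Σ_{j∈N(i)} α_ij^k W^k h_j )`

   with attention coefficients from a softmax of
   `LeakyReLU(aᵀ[W h_i ‖ W h_j])`, biased multiplicatively by the
   normalized De Bruijn edge weights so that the count structure of the
   transcript informs attention. Mean readout over nodes and a two-layer
   fully connected head with a logistic output give `P(bifunctional)`.

4. **Training and ensembling.** Stratified 5-fold cross-validation, Adam
   (lr 1e-4, batch 64, up to 200 epochs), binary cross-entropy, early
   stopping on validation loss (patience 10). The five fold models form an
   ensemble; the reported probability is the mean of their outputs,
   thresholded at 0.5.

5. **Interpretability.** Per-node attention entropy
   `H_i = −Σ_j α_ij log2 α_ij`, entropy–frequency correlations, class
   rank shifts of k-mer entropy, attention-weight interaction networks
   with edge-percolated-component (EPC) centrality, and chi-squared motif
   enrichment (e.g. of the Kozak-like hexamer `GCCATG`).

Evaluation uses ACC, SN, SP, MCC (from the confusion counts) and the
rank-based (Mann–Whitney midrank) AUC.

## Worked example

Because the curated bifunctional-lncRNA databases are external resources,
the package ships a synthetic generator that plants the relevant signal
structure: positives contain one ORF opened by a `GCCATG` Kozak-context
start, negatives have boosted in-frame stop-codon density and no long ORF.

```r
library(cncgat)

train <- generateDataset(syntheticConfig(n_pos = 200, n_neg = 200, seed = 101))
test  <- generateDataset(syntheticConfig(n_pos = 50,  n_neg = 50,  seed = 102))

ens  <- trainEnsemble(train, trainConfig(seed = 1))
pred <- predictEnsemble(ens, test)
m    <- computeMetrics(classLabels(test), pred$probability)
sprintf("AUC=%.3f ACC=%.3f MCC=%.3f SN=%.3f SP=%.3f",
        m$AUC, m$ACC, m$MCC, m$SN, m$SP)
#> "AUC=0.947 ACC=0.850 MCC=0.701 SN=0.880 SP=0.820"
```

The ensemble separates the two synthetic classes almost perfectly by rank
(AUC 0.947): at the default 0.5 threshold, 85% of held-out transcripts are
labeled correctly and the MCC of 0.70 shows the errors are balanced across
classes rather than concentrated in one. Training takes about two minutes
on one CPU core.

Interpretability on the same data:

```r
prof <- entropyProfiles(ens, transcripts(test), classLabels(test))
rs   <- rankShift(prof[prof$label == 1, ], prof[prof$label == 0, ])
head(rs$kmer[order(-rs$shift)])   # k-mers with the largest positive shift
enr  <- motifEnrichment(transcripts(train)[classLabels(train) == 1],
                        transcripts(train)[classLabels(train) == 0],
                        "GCCATG")
```

`ATG` ranks among the top positively shifted 3-mers (higher
attention-entropy rank in positives), and the planted `GCCATG` motif is
strongly enriched in the positive class — the attention mechanism
re-discovers the planted translation-initiation signal.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("scripts", "cncgat.R", package = "cncgat"))')
Rscript $CLI simulate --out data --n-pos 100 --n-neg 100 --seed 7
Rscript $CLI train    --positives data/positives.fasta --negatives data/negatives.fasta --out model
Rscript $CLI predict  --model model --input data/positives.fasta --out pred.tsv
Rscript $CLI interpret --model model --input data/positives.fasta --labels labels.tsv --out reports
Rscript $CLI evaluate --predictions pred.tsv --labels labels.tsv --out metrics.json
```

Every command writes a JSON run manifest (command, configuration, seeds,
paths, timing) next to its outputs.

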