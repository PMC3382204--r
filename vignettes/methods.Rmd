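---
title: "Methods: combined topological features for candidate gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined topological features for candidate gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`topocand` operationalizes guilt-by-association on a protein–protein
interaction network. The working hypothesis is that genes whose network
context resembles that of known disease genes are themselves more likely
to be disease-associated. "Network context" is summarized by six per-gene
measurements relative to the positive (known disease) set: degree D,
disease-neighbor count N, disease-neighbor ratio R = N/D, betweenness
centrality B, local clustering coefficient C, and the mean shortest-path
length M to the disease genes. A support-vector machine trained on
positives versus sampled negatives turns these into a decision rule, and
repetition over many balanced negative draws turns a single brittle
decision into a stable vote.

The assumptions worth stating explicitly:

* the network is treated as undirected, unweighted and simple — evidence
  scores, direction and multiplicity of interactions are discarded at
  load time;
* negatives are *unverified*: "not currently known to be a disease gene
  and not differentially expressed" is the best available proxy, which is
  precisely why each round uses only a small random sample of them
  (balanced resampling) and the final call intersects many rounds;
* the test pool (differentially expressed genes within disease loci) is
  assumed to contain the discoverable true positives; anything outside it
  is never called.

## Pipeline stages and their parameters

| parameter | default | meaning / why |
|---|---|---|
| `de_alpha` | 0.05 | per-gene two-sided t-test cutoff; no multiple-testing correction, matching the method's stated procedure (the cross-profile intersection acts as the de-facto stringency filter) |
| `alpha` | 0.05 | Wilcoxon rank-sum disparity threshold per feature |
| `p_min`, `t_min`, `f_max` | 0.55 / 0.55 / 0.45 | the effectiveness rule: the method's description ("relatively higher precision and TPR, lower FPR") is qualitative, so the rule is made explicit and configurable; a ranked decision trace is written so users can reproduce the qualitative choice |
| `n_rounds_screen` | 1000 | randomized balanced rounds per feature/subset evaluation |
| `cv_folds` | 10 | stratified folds inside each round |
| `n_rounds_predict` | 10000 | randomized rounds for the final candidate vote |
| `agreement` | 1.0 | fraction of rounds a test gene must be called positive; 1.0 is the strict intersection rule. The fraction is exposed because a strict intersection over 10,000 stochastic rounds is brittle; the call fraction is strictly more informative and contains the strict rule as a special case |
| `classifier` | RBF, C = 1 | kernel and hyperparameters are not dictated by the method description; an RBF C-SVM with γ = 1/(n_features · mean feature variance) on z-scored features is the standard default. The solver is an in-package SMO, validated against libsvm |

Features are z-scored per training split; without scaling, B (orders of
magnitude ~10^4 on realistic networks) would dominate an RBF kernel.
Zero-variance columns are mapped to zeros rather than dropped, so a
degenerate feature can never crash a round (it simply carries no
information).

## Numerical and procedural choices

* **Betweenness convention.** Fractional (Brandes) credit
  σ_st(v)/σ_st over unordered pairs, unnormalized. The plain-language
  definition ("count of shortest paths through the node") is ambiguous
  when shortest paths are not unique; fractional counting is the field
  standard and the test oracle uses the same convention via an
  independent all-pairs enumeration.
* **Leave-one-out features.** N, R and M of a gene that is itself a
  positive are computed against the positive set minus that gene
  (default on, switchable). Without this, positives receive a
  self-distance of 0 in M and trivially separable N/R, leaking the label
  into the features and inflating screening metrics.
* **Unreachable genes.** M is undefined for a gene with no path to any
  positive; such genes get max(finite M) + 1 (imputation count logged)
  so the classifier still sees every gene. Row-dropping is the
  alternative and is deliberately not the default: the genes most likely
  to be unreachable are exactly the isolated negatives.
* **R and C at low degree.** R = 0 when D = 0 and C = 0 when D < 2;
  isolated or near-isolated genes are maximally un-disease-like under
  both measures.
* **Paired combination search.** All 2^n − 1 subsets of the retained
  features are evaluated against the *same* per-round negative draws and
  fold assignments, so subset ranking is a paired comparison and not
  confounded by resampling noise. The selection rule is explicit:
  maximize TPR − FPR (Youden), tie-break by precision, then smaller
  subset, then a canonical subset key — making the winner invariant to
  input order. A precision-first rule is available.
* **Fold re-randomization.** Folds are re-drawn in every round (not
  fixed across rounds); both the negative sample and the fold assignment
  are part of a round's randomness, driven by one per-round seed from
  the master seed sequence.
* **Tie handling in the Wilcoxon screen** uses the normal approximation
  with tie correction and continuity correction; at realistic set sizes
  (hundreds to thousands of genes) the exact test is neither feasible
  nor necessary.
* **t-test.** Welch (unequal variance) by default, pooled selectable;
  the method description says only "t-test". A gene with zero variance
  and equal means in both groups gets p = 1 rather than an error.
* **Test-set disjointness.** Genes in both the DE∩loci pool and the
  positive set are removed from the test set: the three sets are kept
  pairwise disjoint. Differentially expressed genes outside every locus
  are deliberately unlabeled — excluded from negatives (by the negative
  definition) and from the test set (by the test definition).

## What the synthetic generator emulates — and what it does not

`generate_network()` plants a disease module on a preferential-attachment
background: module genes are wired to each other with probability
`module_p` (default 0.15) and to random background genes with probability
`cross_p` (default 0.005), on a background of 2,000 genes with
`attach_m = 3`. The defaults were chosen once to reproduce, at a scale
that runs in minutes, the qualitative regularities reported for real
disease genes: module genes end up hub-like (higher D), mutually adjacent
(higher N, R), with densely wired neighborhoods (higher C) and short
mutual distances (lower M). Sixty module genes are handed to the pipeline
as known positives; forty are withheld as the recovery target.

`synthetic_fixture()` additionally plants the hidden genes as
differentially expressed (case shift 2σ, σ = 1, 8 case / 8 control
samples, 3 independent profiles — small-microarray scale) and as locus
genes, alongside 300 random background locus genes of which 150 are
decoy DE genes. The decoys matter: they make the test pool contain
topologically unremarkable genes, so recovery precision is a meaningful
number (without them nearly every test gene would be a planted positive
and any classifier would look perfect).

What the generator does **not** emulate: the heavy-tailed degree
distribution of curated interactomes beyond what preferential attachment
gives, study-specific expression artifacts (batch effects, probe-level
noise, platform differences), locus structure as genomic intervals, and
annotation bias (real "known disease genes" are better studied and
better connected partly *because* they are known). A green synthetic
benchmark therefore establishes that the pipeline recovers planted
topological signal — not that it would rank true disease genes above
study bias on real data.

## Known limitations

* Betweenness is computed exactly; on networks beyond ~10^5 edges this
  becomes the dominant cost and an approximate variant would be needed.
* The effectiveness thresholds (0.55/0.55/0.45) are a reasonable default
  for balanced two-class rounds but are not adaptive; on worlds where
  every feature is strong, everything passes and the combination stage
  does the real selection.
* Near the performance ceiling, a single near-perfect feature can tie or
  marginally beat larger combinations in the paired search; the
  tie-break then prefers the smaller subset, which is the intended
  behavior but means the "optimal combination" is not guaranteed to be
  multi-feature.
* The strict intersection rule (agreement = 1.0) becomes ever harder to
  satisfy as rounds grow; the call fraction output makes this explicit,
  and 0.95 is a pragmatic operating point on the synthetic benchmark.
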