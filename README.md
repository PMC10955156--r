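# hetDTI

Drug–target interaction (DTI) prediction from a heterogeneous collection of
biological networks, for computational pharmacologists and method developers
who want a self-contained, fully tested R implementation of
network-diffusion + graph-convolution link prediction.

Experimental DTI discovery is slow and expensive; computational ranking of
candidate pairs narrows the search. A single association matrix is too
sparse to do this well, but the context around drugs and proteins —
drug–drug interactions, drug–disease and drug–side-effect associations,
protein–protein interactions, protein–disease associations, chemical
structure and sequence similarity — carries strong signal. `hetDTI`
integrates all of it.

## The method

Given drug/protein/disease/side-effect node sets, six association networks
and two precomputed similarity matrices:

1. **Similarity inventory** — each association network becomes a
   within-type similarity network via the Jaccard coefficient
   `Sim(i,j) = |N(i) ∩ N(j)| / |N(i) ∪ N(j)|`; with the precomputed
   matrices this gives 4 drug and 3 protein similarity networks. The
   drug–protein label matrix `Y` never enters the inventory.
2. **Diffusion states** — on each network, a random walk with restart
   `r^{t+1} = (1−p) r^t Â + p r^0` (row-normalised `Â = D⁻¹A`, restart
   probability `p = 0.5`) yields a topology-aware signature per node.
3. **Shared embedding** — the log diffusion matrices `L = log(S + 1/n)` of
   one node type are jointly factorised,
   `min Σ_r ‖X (W^r)ᵀ − L^r‖²_F`, by one SVD of their concatenation;
   `X = U_d Σ_d^0.5` are the shared node features.
4. **Feature update + bilinear decoder** — one spectral graph-convolution
   layer `H = σ(D̃^{-1/2}(A+I)D̃^{-1/2} X W)` per node type, then
   `Y_rec = H_drug D_r P_rᵀ H_proteinᵀ`, with the GCN weights and the
   projections `D_r, P_r` trained by full-batch gradient descent on the
   masked squared loss `Σ (y_ij − ŷ_ij)²`.

Evaluation follows the field's protocol: negatives sampled at 1:1 or 1:10,
stratified 10-fold cross-validation, AUROC (Mann–Whitney, half-credit ties)
and AUPR (non-interpolated), optional redundancy filters that drop DTIs
involving near-duplicate drugs (similarity > 0.6) or homologous proteins
(sequence identity > 0.4). A seeded synthetic generator with planted
low-rank structure makes every stage testable offline.

## Worked example

```r
library(hetDTI)

sim <- simulateHetNet()        # default planted-structure collection
sim$set
#> HetNetSet
#>   nodes: 50 drugs, 80 proteins, 30 diseases, 20 side effects
#>   associations: drug_protein, drug_disease, protein_disease, drug_side_effect
#>   intra-type: drug_drug, protein_protein
#>   precomputed similarities: drug_chemical, protein_sequence
#>   label matrix: 274 known interactions

# cross-validated evaluation (embedding dims = 20% of the node counts)
rep <- crossValidate(sim$set, list(embedding = list(dDrug = 10L, dProtein = 16L)))
rep
#> EvalReport: 10 folds, 1:10 negative sampling, seed 1
#>   AUROC 0.8966 +/- 0.0286 | AUPR 0.6668 +/- 0.0932

# train on all known interactions and rank the unknown pairs
fit <- runPipeline(list(mode = "predict",
                        embedding = list(dDrug = 10L, dProtein = 16L)),
                   set = sim$set, quiet = TRUE)
fit$model
#> DTIModel: decoder 10 x 16 (k = 10), feature update ON (relu), final loss 160.423

writeScoreMatrix(fit$scores, "top.tsv", topK = 5, trainMask = labelMatrix(sim$set))
#> d013  p023  0.6843461198
#> d050  p033  0.6479317755
#> d050  p077  0.6463252963
#> d048  p002  0.6353706202
#> d015  p023  0.6352592415
```

The report says: ranking held-out pairs (10 negatives per positive, so a
9.1% prevalence), the model places a true interaction above a non-interaction
~90% of the time, and its precision–recall area of 0.67 is ~7× the
prevalence baseline. The score file lists the strongest novel predictions
(known training pairs excluded), ties broken deterministically.

Real collections are read from plain TSV files — edge lists per association
network, dense similarity tables, one id per line registries — with
`readHetNetSet()`; `writeHetNetSet()` writes the same layout. A thin CLI
(`system.file("cli", "hetdti.R", package = "hetDTI")`) exposes `simulate`,
`embed`, `train`, `evaluate`, `predict` and `sweep` subcommands over YAML
configs.

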