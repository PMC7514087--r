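# pfdclust

Density peak clustering with a **potential-field-diffusion** density
measure, for point sets where classic density peak clustering (DPC) fails:
clusters of very different density, and non-convex shapes where one wrong
label assignment cascades along the nearest-denser chain.

## The method in brief

On the K-nearest-neighbor graph, a mutual-KNN pair (i, j) with common
neighbors ω(i,j) = σ(i) ∩ σ(j) gets the potential field

    θ(i,j) = |ω(i,j)|² / Σ_{p∈ω(i,j)} (d²_ip + d²_jp)

amplified by the k-layer diffusion mass of all K^k directed walks leaving i
through the graph,

    S_k(i) = Σ_{m∈σ(i)} Σ_{n∈σ(m)} … (d²_im + d²_mn + …),
    Θ(i,j) = θ(i,j) · S_k(i).

Because θ scales as 1/d² and S_k as d², local point spacing cancels in Θ:
density peaks are found by neighborhood topology, so sparse clusters are
not drowned out by dense ones. Local density ρ_i sums the K strongest
similarities of i; δ_i is the distance to the nearest strictly denser
point; the m largest γ = ρ·δ seed the clusters. Non-centers are allocated
in two steps: breadth-first propagation along *similar points* (pairs
sharing more than ⌈(K+1)/2⌉ common neighbors), then KNN majority voting
with a growing neighborhood for the remainder — both deterministic, both
designed to stop attached allocation errors.

The package also provides the classic DPC baseline (cutoff and Gaussian
kernels, halo rule), AMI/ARI/FMI validation indices, min-max normalization
with mean imputation, seeded generators for six classic benchmark shapes,
and a CLI.

## Worked example

```r
library(pfdclust)

P <- make_fixture("jain_moons", seed = 1)   # 373 points, 2 crescents, 1:2 density
cl <- pfd_dpc(P, m = 2, K = 13, k = 3)
cl
#> pfd_dpc clustering: 373 points, 2 clusters (K = 13, k = 3)
#> cluster sizes: 124 249
#> allocation phases: center=2 knn_vote=259 similar_bfs=112
cluster_metrics(P$y_true, cl$labels)
#> ami ari fmi
#>   1   1   1

# the same data defeats the classic baseline and the no-diffusion ablation
base <- dpc(P, m = 2, dpc_params(2, "percent", "cutoff"))
cluster_metrics(P$y_true, base$labels)[["ami"]]
#> [1] -0.0009907181
abl <- pfd_dpc(P, m = 2, params = pfd_params(K = 13, k = 3, diffusion = FALSE))
table(P$y_true[abl$centers])   # both centers land in the dense crescent
#> 1
#> 2
```

Both crescents are recovered exactly (all three indices 1) because the
diffusion factor keeps the sparse upper crescent's γ competitive; without
it, both top-γ candidates sit in the dense crescent and the sparse cluster
is never seeded.

### Command line

```sh
inst/scripts/pfdclust synth --shape ring_blobs --seed 1 --output ring.txt
inst/scripts/pfdclust cluster --input ring.txt --n-clusters 3 --K 26 --k 3 \
    --output pred.txt --decision-graph dg.tsv
inst/scripts/pfdclust eval --pred pred.txt --truth truth.txt
inst/scripts/pfdclust sweep --input ring.txt --n-clusters 3 --K-range 4:50
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the full pipeline from scratch on the six seeded benchmark shapes
at their reference parameters, prints the AMI/ARI/FMI each run achieves
together with the baseline contrast on the ring fixture, and writes the
results JSON.

`reproduce_benchmarks(dir)` additionally reruns the published per-dataset
parameters against a local copy of the six original benchmark files (not
redistributed here) and tabulates achieved vs. published index values.
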