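# bbdisp

Base-level beta-binomial modeling of RNA-seq read-start counts, for
comparing two samples (or two groups) position by position.

RNA-seq coverage within a gene is wildly non-uniform — random-hexamer
priming can change the number of reads starting at neighbouring bases a
hundredfold — so gene-level count models leave information on the table and
position-level Poisson models are misspecified.  `bbdisp` compares two
samples through the *proportion* of reads at each base: with counts
`n_ij` and `m_ij` starting at base `j` of gene `i` in the two samples,

    n_ij | t_ij ~ BetaBinomial(t_ij; p_i, theta_ij),      t_ij = n_ij + m_ij

where `p_i` is one proportion per gene and `theta_ij` the per-position
overdispersion rate.  The package's core is a *dynamic* overdispersion
model,

    log theta_ij = log D + sum_k sum_h beta_kh I(b_ijk = h) + gamma log t_ij

with a depth exponent `gamma`, 240 local-sequence coefficients `beta_kh`
over an 80-nt window around the read start (reference base G), and a
pair-specific library scale `D`.  `gamma` and `beta` are trained on
replicate pairs via a method-of-moments dispersion estimate and least
squares; `D` and the gene proportions are then fitted per test pair by
maximum likelihood, and genes are tested by a likelihood-ratio chi-square
(one degree of freedom per sample pair, summed across pairs).  Nested model
comparison (binomial, constant-theta, depth-only, depth+sequence) by
likelihood, nested chi-square and AIC is built in, as are the
dispersion-versus-depth, positional and coefficient diagnostics and a
ground-truth simulator.

Who this is for: anyone modeling base-level RNA-seq fluctuation between
replicates or conditions — e.g. for spike-in-calibrated differential
expression, QC of library-preparation protocols (depth dependence, priming
bias, 3'-tail artifacts), or as a reference implementation of
depth-dependent beta-binomial dispersion estimation.

## Worked example

Train the depth-only (`bb+D+g`) dispersion model on four simulated
replicate libraries, then test a two-sample comparison in which 10 of 400
genes truly changed (proportion 0.6 versus 0.5):

```r
library(bbdisp)

reps  <- simulate_replicates(sim_config(G = 100, gene_length = 500, seed = 1),
                             n_samples = 4)
model <- train(replicate_pair_set(reps), variant = "primer_free")
model
#> overdispersion model 'primer_free' (strand antisense): log D = -0.1601, gamma = -0.8266
#>   n = 41603, residual variance = 1.4280, in-sample R2 = 0.491

sim   <- simulate_pair(sim_config(G = 400, gene_length = 500,
                                  de_fraction = 0.025, de_p = 0.6, seed = 2))
state <- fit_test_pair(sim$pairs, model, pipeline_config(), mode = "comparison")
res   <- lrt_genes(list(state))
head(res[order(res$pvalue), ], 5)
#>     gene_id p_hat chi2 df pvalue qvalue untestable
#> 41    g0041 0.598 2443  1      0      0      FALSE
#> 79    g0079 0.602 2308  1      0      0      FALSE
#> 111   g0111 0.600 2222  1      0      0      FALSE
#> 114   g0114 0.598 2384  1      0      0      FALSE
#> 174   g0174 0.602 2421  1      0      0      FALSE
```

The trained depth exponent (`gamma = -0.83`, truth −0.8) says dispersion
falls roughly like `t^-0.8` with depth; the in-sample R² of about 0.49
means the depth term explains half the variance of the log dispersion
estimates.  All 10 truly changed genes are recovered at `q < 0.05` (33
genes total pass; the extra calls reflect that the neutral proportion is
estimated from all genes, changed ones included — see the vignette's
discussion of this contamination).  On a fully null pair the same pipeline
yields uniform p-values (about 5% of genes below 0.05).

A thin command-line front end wraps the same functions:

```sh
bbdisp simulate --config sim.json --out fixtures/
bbdisp train    --counts fixtures/counts.tsv --fasta fixtures/genes.fa \
                --samples fixtures/samples.tsv --out model.tsv --variant primer_free
bbdisp test     --counts test.tsv --model model.tsv --samples groups.tsv --out results.tsv
bbdisp compare  --counts fixtures/counts.tsv --samples fixtures/samples.tsv \
                --model-primer-free model.tsv --out comparison.tsv
bbdisp profile  --counts fixtures/counts.tsv --samples fixtures/samples.tsv --out-prefix prof
```

Every run writes a JSON manifest (command, parameters, input checksums,
version) next to its output.

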