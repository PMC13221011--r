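# flowrosetta

Statistical replication of flow cytometry cell clusters: analyze a measured
2-D cluster (for example in FSC-A x SSC-A scatter space), decipher its
distributional parameters, and generate fully synthetic, per-event-labelled
replicates that are statistically equivalent to the original. Synthetic
replicates give clustering and gating methods something real samples cannot:
a ground truth.

## The model

Each cluster is described in a frame aligned with its principal axis
(rotation measured in degrees clockwise from vertical). The projection (X)
dimension follows a skew-Gaussian density

    f_X(x; mu, sigma, alpha) = (2/sigma) * phi(z) * Phi(alpha * z),
    z = (x - mu)/sigma,

and the principal-axis (Y) dimension a symmetric tail-shape family

    f_Y(y; mu, sigma, beta) = (2 / (sigma * C(beta))) * phi(z) * Phi(beta * |z|),
    C(beta) = 1 + (2/pi) * arctan(beta),

where `phi`/`Phi` are the standard normal density and CDF. A support-line
generator samples clusters from these families (projection offsets from the
skew family; mirrored principal-axis magnitudes from the tail family). The
analysis routine inverts the process: optimal clustering with silhouette
selection, principal-axis alignment with outer-point trimming, permanent
z-score outlier removal, and a constrained, truncation-aware EM fit of
per-dimension mixtures with BIC component selection. Fitted parameters
translate directly into generator arguments; corrections for manually gated
(core-clustered) overlapping clusters (doubled SD scaling, cube/fourth-power
moment compensation, density adjustment) and a dual-pass principal-axis
skewness-kurtosis covariance (PASKC) replication method handle real data.
Generator and report skew share one unit convention: distribution shape
`alpha = 2*pi * skew` (the division by pi and 2 applied when fitted shapes
are reported).

## Worked example

```r
library(flowrosetta)

ev <- two_cluster_fixture(seed = 1)   # built-in two-cluster benchmark
ev
#> <labeled_events: 6000 events, channels FSC-A/SSC-A, 2 labelled clusters>

an <- rosetta_analyze(ev, rosetta_config(), seed = 1)
an
#> <rosetta_analysis: 2 cluster(s), silhouette 0.819>
#>  cluster_id events rotation_deg x_mean     x_sd    x_skew   x_bic y_mean
#>           1   5000      324.476 100037 187.3032 0.0457411 65799.2 100023
#>           2   1000      349.071 102945  98.4254 0.0485137 11855.4 100194
#>     y_sd y_kurtosis   y_bic full_bic silhouette
#>  399.908   0.466648 74499.8 140299.0    0.81868
#>  300.489  -0.660770 13475.2  25330.6    0.81868
```

The report rows read: cluster 1 (5000 events) sits at principal-axis
rotation 324.5 degrees (generated: 325), centre near (100037, 100023)
(generated support-line centre: (100000, 100000), plus the skew-family
offset the fit partially absorbs), fitted scales 187/400 a.u. (generated:
200/400), skew 0.046 and kurtosis 0.467 (generated: 0.100/0.400 — the skew
of a 5000-event cluster is near its information bound, so single-run values
scatter; 13-seed averages centre on the targets). Regenerating is one line:

```r
replica <- sample_dataset(report_to_generator_args(an$report, seed = 2))
distribution_compare(ev, replica)
```

Gated replication of an overlapping (core-clustered) cluster:

```r
g <- rect_gate(c(95000, 105000), c(95000, 105000), name = "core")
res <- gated_replication_pipeline(ev, g, rosetta_config(), seed = 3)
res$factors   # SD scalings, their cube/fourth-power moment factors, density
```

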