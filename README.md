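# chmnet

Co-prescription network analysis of Chinese herbal medicine (CHM) claims
data: cohort filtering, association rule mining, network clustering and
core-herb identification, with a synthetic claims generator for fully
reproducible testing.

## What problem this solves

CHM prescriptions for conditions like endometriosis contain six or seven
products each — herbal formulas (HF) and single herbs (SH) combined around
a core ("sovereign") medicinal. Claims databases record millions of such
prescriptions, but the sources are access-restricted and the interesting
structure is combinatorial, not marginal. `chmnet` is for
pharmacoepidemiologists and TCM researchers who want the standard analytic
chain as tested, scriptable R:

1. **Inclusion/exclusion cascade** over claims-style visit tables:
   specialty-established index diagnosis, inclusive age window (default
   20–50 completed years), primary-position diagnosis code (default prefix
   `617`, configurable), exclusion of visits with acupuncture/moxibustion/
   manual therapy, CHM-dispensing visits only. Every step is counted in an
   attrition report.
2. **Association rule mining** (from-scratch Apriori) over per-visit item
   sets, with the three standard screens

   ```
   support(A ∪ B) = P(A, B)                >= 0.01
   confidence(A→B) = P(A, B) / P(A)        >= 0.30
   lift(A→B) = confidence / P(B)           >  1      (strict)
   ```

3. **Co-prescription network**: top-30 pairs by support as edges,
   single-item prevalence on nodes, Clauset–Newman–Moore greedy modularity
   clustering (via igraph), per-cluster and global core identification
   (prevalence, then support-weighted degree), GraphML/JSON/edge-list
   export.
4. **Utilization tables**: prevalence-ranked HF/SH tables with mean dose
   (g/day) and duration (days/visit), items-per-prescription distribution.
5. **Synthetic cohorts** with planted cluster structure, a calibrated
   marginal model (realized prevalences match targets), and single-cause
   decoy visits — the recovery ground truth for everything above.

## Worked example

```r
library(chmnet)

spec <- plantedCohortSpec(nPatients = 2000L)   # 6 planted clusters, boost 8
gen  <- generateCohort(spec, seed = 1)
res  <- filterCohort(gen$cohort)               # cascade + attrition
tx   <- asTransactions(res$cohort)

rules <- deriveRules(mineFrequentItemsets(tx))
pairs <- topCombinations(rules, size = 2, k = 30)
net   <- identifyCores(detectClusters(buildNetwork(pairs, itemSupport(tx))))
net
evaluateRecovery(net, gen$truth)
```

prints

```
CoPrescriptionNetwork: 22 nodes, 30 edges; 6 clusters, modularity 0.587
  global core: HF001
$nClusters
[1] 6
$ari
[1] 1
$globalCore
[1] "HF001"
```

Read: the top-30 combination network decomposes into 6 clusters that match
the planted ground truth exactly (adjusted Rand index 1), and the most
prevalent formula (`HF001`, the Gui-Zhi-Fu-Ling-Wan analogue planted at
28.1% prevalence) is identified as the global core — the network-level
"sovereign medicinal". `print(res$attrition)` shows the cascade counts;
`prevalenceTable(res$cohort, "HF")` the formula utilization table.

A command-line front end with the same stages
(`generate | filter | mine | network | summarize | run-all`) is installed
at `system.file("scripts/chmnet.R", package = "chmnet")`, and
`runPipeline()` executes the whole chain from one YAML/JSON config with an
MD5-checksummed artifact manifest (two runs with the same seed are
byte-identical).

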