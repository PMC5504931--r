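#include <Rcpp.h>
using namespace Rcpp;

// Draw the item set of each visit by sequential odds-proportional sampling
// without replacement. Cluster boosts multiply an item's odds while its
// cluster is "active": the visit's seeded cluster, plus the cluster of any
// already-chosen item. With all boosts equal to 1 this reduces to the
// exponential-race sampler the marginal calibration assumes.
//
// k:           prescription size per visit
// w:           calibrated base odds per catalog item
// cluster:     0-based cluster index per item, -1 for none
// boost:       odds multiplier per cluster (>= 1)
// seedCluster: 0-based seeded cluster per visit, -1 for none
// always:      items with target prevalence 1 (always included first)
//
// Returns a list of 1-based, sorted item index vectors.
// [[Rcpp::export]]
List sample_visit_items(IntegerVector k, NumericVector w,
                        IntegerVector cluster, NumericVector boost,
                        IntegerVector seedCluster, LogicalVector always) {
  const int n = k.size(), m = w.size(), nc = boost.size();
  List out(n);
  std::vector<double> cur(m);
  std::vector<bool> active(std::max(nc, 1));
  std::vector<bool> taken(m);
  std::vector<int> chosen;

  for (int v = 0; v < n; ++v) {
    std::fill(active.begin(), active.end(), false);
    std::fill(taken.begin(), taken.end(), false);
    chosen.clear();
    if (seedCluster[v] >= 0) active[seedCluster[v]] = true;
    const int kk = std::min(k[v], m);
    for (int i = 0; i < m && (int)chosen.size() < kk; ++i) {
      if (always[i]) {
        taken[i] = true;
        chosen.push_back(i);
        if (cluster[i] >= 0) active[cluster[i]] = true;
      }
    }
    while ((int)chosen.size() < kk) {
      double tot = 0.0;
      for (int i = 0; i < m; ++i) {
        double wi = taken[i] ? 0.0 : w[i];
        if (wi > 0.0 && cluster[i] >= 0 && active[cluster[i]])
          wi *= boost[cluster[i]];
        cur[i] = wi;
        tot += wi;
      }
      if (tot <= 0.0) break;
      const double u = unif_rand() * tot;
      double acc = 0.0;
      int pick = -1, lastPos = -1;
      for (int i = 0; i < m; ++i) {
        if (cur[i] <= 0.0) continue;
        acc += cur[i];
        lastPos = i;
        if (u <= acc) { pick = i; break; }
      }
      if (pick < 0) pick = lastPos;  // fp slack at the upper end
      taken[pick] = true;
      chosen.push_back(pick);
      if (cluster[pick] >= 0) active[cluster[pick]] = true;
    }
    std::sort(chosen.begin(), chosen.end());
    IntegerVector res(chosen.size());
    for (size_t j = 0; j < chosen.size(); ++j) res[j] = chosen[j] + 1;
    out[v] = res;
  }
  return out;
}
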