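#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// k-nearest-donor matching on predicted values: for each missing case,
// find the k observed cases with the closest predicted value and draw one
// of their observed outcomes uniformly (using R's RNG so results are
// reproducible under set.seed()).
// [[Rcpp::export]]
NumericVector pmm_match(NumericVector pred_mis, NumericVector pred_obs,
                        NumericVector y_obs, int k) {
  int nm = pred_mis.size();
  int no = pred_obs.size();
  if (no == 0) stop("no observed donors");
  if (k < 1) k = 1;
  if (k > no) k = no;

  // sort donors by predicted value
  std::vector<int> idx(no);
  for (int i = 0; i < no; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    return pred_obs[a] < pred_obs[b];
  });
  std::vector<double> ps(no);
  std::vector<double> ys(no);
  for (int i = 0; i < no; ++i) {
    ps[i] = pred_obs[idx[i]];
    ys[i] = y_obs[idx[i]];
  }

  NumericVector out(nm);
  std::vector<int> cand;
  cand.reserve(k);
  for (int i = 0; i < nm; ++i) {
    double p = pred_mis[i];
    int r = std::lower_bound(ps.begin(), ps.end(), p) - ps.begin();
    int l = r - 1;
    cand.clear();
    while ((int)cand.size() < k && (l >= 0 || r < no)) {
      if (l < 0) cand.push_back(r++);
      else if (r >= no) cand.push_back(l--);
      else if (p - ps[l] <= ps[r] - p) cand.push_back(l--);
      else cand.push_back(r++);
    }
    int j = (int)(unif_rand() * cand.size());
    if (j == (int)cand.size()) j--;  // guard against unif_rand() == 1
    out[i] = ys[cand[j]];
  }
  return out;
}
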