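#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Haplotype-class bookkeeping for EHH: carriers start in one class at the
// core and split as flanking alleles differ.  A missing call isolates its
// haplotype (it can match nothing).  EHH = sum_h C(n_h,2) / C(n,2).

static double ehh_from_classes(const std::vector<int>& cls, int n) {
  std::unordered_map<int, int> cnt;
  for (int c : cls) cnt[c]++;
  double num = 0.0;
  for (auto& kv : cnt) num += (double)kv.second * (kv.second - 1) / 2.0;
  return num / ((double)n * (n - 1) / 2.0);
}

// refine classes with the alleles at site j; returns next fresh class id
static int refine(std::vector<int>& cls, const IntegerMatrix& H, int j,
                  const std::vector<int>& carriers, int next_id) {
  std::unordered_map<long long, int> remap;
  for (size_t i = 0; i < cls.size(); ++i) {
    int a = H(j, carriers[i]);
    if (a == NA_INTEGER) {        // missing isolates the haplotype
      cls[i] = next_id++;
      continue;
    }
    long long key = (long long)cls[i] * 4 + a;
    auto it = remap.find(key);
    if (it == remap.end()) {
      remap.emplace(key, next_id);
      cls[i] = next_id++;
    } else {
      cls[i] = it->second;
    }
  }
  return next_id;
}

// EHH values along one flank. dir = +1 (rightwards) or -1.
// Emits sites until EHH < truncation (inclusive of the crossing value),
// max_extent is exceeded, or the chromosome ends.
// [[Rcpp::export]]
DataFrame cpp_ehh_side(IntegerMatrix H, NumericVector pos,
                       IntegerVector carriers, int core, int dir,
                       double truncation, double max_extent) {
  int M = H.nrow();
  std::vector<int> car(carriers.begin(), carriers.end());
  int n = car.size();
  std::vector<int> cls(n, 0);
  int next_id = 1;
  std::vector<int> sites;
  std::vector<double> ehh;
  for (int j = core + dir; j >= 0 && j < M; j += dir) {
    if (std::abs(pos[j] - pos[core]) > max_extent) break;
    next_id = refine(cls, H, j, car, next_id);
    double e = ehh_from_classes(cls, n);
    sites.push_back(j + 1);  // 1-based for R
    ehh.push_back(e);
    if (e < truncation) break;
  }
  return DataFrame::create(_["site"] = sites, _["ehh"] = ehh);
}

// Integrated EHH (iHH) along one flank: trapezoid rule over physical
// distance, each inter-SNP gap capped at max_gap.  Integration stops once
// EHH drops below truncation (the final below-truncation trapezoid is
// included).  Returns {ihh, decayed} where decayed=0 means EHH never fell
// below truncation before max_extent / chromosome end.
static void ihh_one(const IntegerMatrix& H, const NumericVector& pos,
                    const std::vector<int>& car, int core, int dir,
                    double truncation, double max_extent, double max_gap,
                    double* ihh, bool* decayed) {
  int M = H.nrow();
  int n = car.size();
  std::vector<int> cls(n, 0);
  int next_id = 1;
  double e_prev = 1.0;
  double p_prev = pos[core];
  double acc = 0.0;
  *decayed = false;
  for (int j = core + dir; j >= 0 && j < M; j += dir) {
    if (std::abs(pos[j] - pos[core]) > max_extent) break;
    next_id = refine(cls, H, j, car, next_id);
    double e = ehh_from_classes(cls, n);
    double gap = std::abs(pos[j] - p_prev);
    if (gap > max_gap) gap = max_gap;
    acc += 0.5 * (e_prev + e) * gap;
    e_prev = e;
    p_prev = pos[j];
    if (e < truncation) { *decayed = true; break; }
  }
  *ihh = acc;
}

// iHH for both alleles at one core site.
// Returns (ihh_ancestral, ihh_derived, flag); flag=1 when either allele's
// EHH failed to decay below truncation within max_extent on either flank.
// [[Rcpp::export]]
NumericVector cpp_ihh_site(IntegerMatrix H, NumericVector pos, int core,
                           double truncation, double max_extent,
                           double max_gap) {
  int nh = H.ncol();
  std::vector<int> car_a, car_d;
  for (int h = 0; h < nh; ++h) {
    int a = H(core, h);
    if (a == 0) car_a.push_back(h);
    else if (a == 1) car_d.push_back(h);
  }
  NumericVector out(3);
  if (car_a.size() < 2 || car_d.size() < 2) {
    out[0] = NA_REAL; out[1] = NA_REAL; out[2] = 1;
    return out;
  }
  double ihh_a = 0, ihh_d = 0, v;
  bool dec, all_dec = true;
  for (int dir = -1; dir <= 1; dir += 2) {
    ihh_one(H, pos, car_a, core, dir, truncation, max_extent, max_gap, &v, &dec);
    ihh_a += v; all_dec = all_dec && dec;
    ihh_one(H, pos, car_d, core, dir, truncation, max_extent, max_gap, &v, &dec);
    ihh_d += v; all_dec = all_dec && dec;
  }
  out[0] = ihh_a;
  out[1] = ihh_d;
  out[2] = all_dec ? 0 : 1;
  return out;
}

// Genome scan: iHH for every site with minor allele count >= min_mac.
// Columns: freq_der, ihh_a, ihh_d, flag (1 = undecayed / unusable).
// [[Rcpp::export]]
NumericMatrix cpp_ihs_scan(IntegerMatrix H, NumericVector pos,
                           double truncation, double max_extent,
                           double max_gap, int min_mac) {
  int M = H.nrow(), nh = H.ncol();
  NumericMatrix out(M, 4);
  for (int s = 0; s < M; ++s) {
    int n1 = 0, nc = 0;
    for (int h = 0; h < nh; ++h) {
      int a = H(s, h);
      if (a == NA_INTEGER) continue;
      nc++;
      if (a == 1) n1++;
    }
    double freq = nc > 0 ? (double)n1 / nc : NA_REAL;
    out(s, 0) = freq;
    if (n1 < min_mac || (nc - n1) < min_mac) {
      out(s, 1) = NA_REAL; out(s, 2) = NA_REAL; out(s, 3) = 1;
      continue;
    }
    NumericVector r = cpp_ihh_site(H, pos, s, truncation, max_extent, max_gap);
    out(s, 1) = r[0];
    out(s, 2) = r[1];
    out(s, 3) = r[2];
  }
  return out;
}
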