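// Exact direct-method stochastic simulation of the PolII-compartment
// recycling model.  Seven reaction channels:
//   0  DNAon + PolII -> mRNA + DNAon + PolII   rate l*beta*P      (re-inject)
//   1  DNAon + PolII -> mRNA + DNAon           rate (1-l)*beta*P  (loss)
//   2  DNAon -> DNAoff                         rate lambda_off
//   3  DNAoff -> DNAon                         rate lambda_on
//   4  mRNA -> 0                               rate d*M
//   5  0 -> PolII                              rate gamma (variant: only P==0)
//   6  PolII -> 0                              rate delta*P
// A private 64-bit RNG keeps the simulator independent of R's RNG stream;
// ensemble realisations derive sub-seeds from the master seed via splitmix64.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

struct Xoshiro {
  // xorshift-based generator (splitmix64-seeded mt-like quality is enough here)
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0,1)
  double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

struct MicroPar {
  double gamma, beta, delta, d, lambda_on, lambda_off, l;
  bool no_accumulation;
};

MicroPar unpack(const NumericVector& p) {
  MicroPar mp;
  mp.gamma = p["gamma"]; mp.beta = p["beta"]; mp.delta = p["delta"];
  mp.d = p["d"]; mp.lambda_on = p["lambda_on"]; mp.lambda_off = p["lambda_off"];
  mp.l = p["l"];
  mp.no_accumulation = p["variant"] > 0.5;
  return mp;
}

inline void channel_rates(const MicroPar& mp, long P, long M, int on,
                          double* a) {
  const double tx = on ? mp.beta * static_cast<double>(P) : 0.0;
  a[0] = mp.l * tx;
  a[1] = (1.0 - mp.l) * tx;
  a[2] = on ? mp.lambda_off : 0.0;
  a[3] = on ? 0.0 : mp.lambda_on;
  a[4] = mp.d * static_cast<double>(M);
  a[5] = mp.no_accumulation ? (P == 0 ? mp.gamma : 0.0) : mp.gamma;
  a[6] = mp.delta * static_cast<double>(P);
}

// one realisation; returns final state, optionally recording events
void ssa_run(const MicroPar& mp, double t_end,
             long& P, long& M, int& on, double& t, Xoshiro& rng,
             std::vector<double>* rec_t, std::vector<long>* rec_P,
             std::vector<long>* rec_M, std::vector<int>* rec_on,
             R_xlen_t max_events, bool& truncated, bool& stalled) {
  truncated = false; stalled = false;
  double a[7];
  R_xlen_t ev = 0;
  for (;;) {
    channel_rates(mp, P, M, on, a);
    double a0 = 0.0;
    for (int i = 0; i < 7; ++i) a0 += a[i];
    if (a0 <= 0.0) { stalled = true; t = t_end; return; }
    const double tau = -std::log(rng.unif()) / a0;
    if (t + tau > t_end) { t = t_end; return; }
    t += tau;
    double r = rng.unif() * a0;
    int ch = 0;
    for (; ch < 6; ++ch) { if (r < a[ch]) break; r -= a[ch]; }
    switch (ch) {
      case 0: ++M; break;
      case 1: ++M; --P; break;
      case 2: on = 0; break;
      case 3: on = 1; break;
      case 4: --M; break;
      case 5: ++P; break;
      case 6: --P; break;
    }
    if (rec_t) {
      rec_t->push_back(t); rec_P->push_back(P);
      rec_M->push_back(M); rec_on->push_back(on);
      if (++ev >= max_events) { truncated = true; return; }
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".micro_ssa_trajectory")]]
List micro_ssa_trajectory(NumericVector params, double t_end,
                          IntegerVector init, double seed,
                          double max_events = 5e6) {
  MicroPar mp = unpack(params);
  Xoshiro rng(static_cast<uint64_t>(seed));
  long P = init[0], M = init[1];
  int on = init[2];
  double t = 0.0;
  std::vector<double> rt; std::vector<long> rP, rM; std::vector<int> ron;
  rt.push_back(0.0); rP.push_back(P); rM.push_back(M); ron.push_back(on);
  bool truncated = false, stalled = false;
  ssa_run(mp, t_end, P, M, on, t, rng, &rt, &rP, &rM, &ron,
          static_cast<R_xlen_t>(max_events), truncated, stalled);
  const R_xlen_t n = static_cast<R_xlen_t>(rt.size());
  NumericVector time(n); IntegerVector polII(n), mRNA(n), dna(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    time[i] = rt[i]; polII[i] = static_cast<int>(rP[i]);
    mRNA[i] = static_cast<int>(rM[i]); dna[i] = ron[i];
  }
  return List::create(_["time"] = time, _["polII"] = polII,
                      _["mRNA"] = mRNA, _["dna_on"] = dna,
                      _["t_final"] = t, _["truncated"] = truncated,
                      _["stalled"] = stalled);
}

// [[Rcpp::export(name = ".micro_ssa_ensemble")]]
IntegerMatrix micro_ssa_ensemble(NumericVector params, int n_cells,
                                 double t_burnin, IntegerVector init,
                                 double master_seed) {
  MicroPar mp = unpack(params);
  IntegerMatrix out(n_cells, 2);
  for (int c = 0; c < n_cells; ++c) {
    uint64_t sub = splitmix64(static_cast<uint64_t>(master_seed) +
                              0x51ed2701ULL * static_cast<uint64_t>(c + 1));
    Xoshiro rng(sub);
    long P = init[0], M = init[1];
    int on = init[2];
    double t = 0.0;
    bool truncated = false, stalled = false;
    ssa_run(mp, t_burnin, P, M, on, t, rng, nullptr, nullptr, nullptr, nullptr,
            0, truncated, stalled);
    out(c, 0) = static_cast<int>(P);
    out(c, 1) = static_cast<int>(M);
    if ((c & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  colnames(out) = CharacterVector::create("polII", "mRNA");
  return out;
}
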