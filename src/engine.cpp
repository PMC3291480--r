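// Fast session engine. Semantically identical to the R reference engine in
// R/sessions.R: both consume the R RNG stream in the same order and keep the
// same floating-point association, so event logs agree exactly under a
// common seed (enforced by the engine-parity tests).
//
// Memory is held as a flat chronological event list (type, site, success,
// step). All behavioral quantities are sums over events of
// pow(max(now - step, 1), -d), which equals the per-chunk sums of the chunk
// formulation because strengths are additive over uses.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Events {
  std::vector<int> type;     // 0 = cache, 1 = recovery
  std::vector<int> site;     // 1-based site id
  std::vector<int> succ;     // recovery success flag (0/1); 0 for cache
  std::vector<int> step;
  void add(int ty, int si, int su, int st_) {
    type.push_back(ty); site.push_back(si); succ.push_back(su); step.push_back(st_);
  }
};

struct Log {
  std::vector<int> step, session, action, tray, site;
  // session: 0 caching, 1 recovery
  // action: 0 cache, 1 recache_immediate, 2 recover_success,
  //         3 recover_fail, 4 recache_recovery
  void add(int st_, int se, int ac, int tr, int si) {
    step.push_back(st_); session.push_back(se); action.push_back(ac);
    tray.push_back(tr); site.push_back(si);
  }
};

inline double weight(int now, int step, double d) {
  double t = (double)(now - step);
  if (t < 1.0) t = 1.0;
  return std::pow(t, -d);
}

inline double draw_unif() {
  double r = unif_rand();
  return r;
}

inline double draw_noise(double n) {
  if (n == 0.0) return 0.0;
  double r = draw_unif();
  while (r <= 0.0 || r >= 1.0) r = draw_unif();
  return n * std::log((1.0 - r) / r);
}

// argmax over util with exact-tie uniform break; returns index into ids
inline int argmax_tie(const std::vector<double>& util) {
  double m = util[0];
  for (size_t i = 1; i < util.size(); ++i) if (util[i] > m) m = util[i];
  std::vector<int> ties;
  for (size_t i = 0; i < util.size(); ++i) if (util[i] == m) ties.push_back((int)i);
  if (ties.size() == 1) return ties[0];
  double u = draw_unif();
  int k = (int)ties.size();
  int idx = (int)std::floor(u * k);
  if (idx > k - 1) idx = k - 1;
  return ties[idx];
}

} // namespace

// [[Rcpp::export]]
List cpp_run_trial(IntegerVector site_tray, IntegerVector site_row,
                   IntegerVector site_col, List phases,
                   IntegerVector recovery_sites, int n_caches,
                   List par, IntegerVector init_type, IntegerVector init_site,
                   IntegerVector init_succ, IntegerVector init_step,
                   int init_clock) {
  const double d = as<double>(par["d"]);
  const double n = as<double>(par["n"]);
  const double st = as<double>(par["st"]);
  const int recache_cap = as<int>(par["recache_cap"]);
  const bool risk_session = as<bool>(par["risk_session"]);

  const int S = site_tray.size();
  Events ev;
  for (int i = 0; i < init_type.size(); ++i)
    ev.add(init_type[i], init_site[i], init_succ[i], init_step[i]);
  int clock = init_clock;

  std::vector<int> worms(S + 1, 0);
  std::vector<bool> cached(S + 1, false);
  std::vector<bool> qual(S + 1, false);
  int out_of_tray = 0, eaten = 0, worms_given = 0;
  Log lg;

  int T = 0;
  for (int i = 0; i < S; ++i) if (site_tray[i] > T) T = site_tray[i];
  std::vector<int> c_initial(T + 1, 0), c_place(T + 1, 0), c_imm(T + 1, 0),
      c_fail(T + 1, 0), c_recached(T + 1, 0);

  // mark a site as actually cached: it and its grid neighbors (same tray,
  // Chebyshev distance <= 1) qualify for the safety-risk assessment
  auto mark_cached = [&](int s) {
    if (cached[s]) return;
    cached[s] = true;
    int tr = site_tray[s - 1], ro = site_row[s - 1], co = site_col[s - 1];
    for (int j = 1; j <= S; ++j) {
      if (site_tray[j - 1] == tr &&
          std::abs(site_row[j - 1] - ro) <= 1 &&
          std::abs(site_col[j - 1] - co) <= 1) qual[j] = true;
    }
  };

  // ---- caching phases -------------------------------------------------
  // inhibition of return is within-session: only events encoded since the
  // session started inhibit
  const int caching_start = clock;
  for (int p = 0; p < phases.size(); ++p) {
    List ph = phases[p];
    IntegerVector offered = ph["sites"];
    const double oa = as<double>(ph["oa"]);
    const int near_tray = as<int>(ph["near_tray"]);
    const double cr = as<double>(ph["cr"]);
    const int no = offered.size();

    std::vector<int> idx(S + 1, -1);
    for (int i = 0; i < no; ++i) idx[offered[i]] = i;

    for (int worm = 0; worm < n_caches; ++worm) {
      ++worms_given;
      int chain = 0;
      for (;;) {
        // decide where to cache: C_k = O_k + I_k + noise
        std::vector<double> ior(no, 0.0);
        for (size_t e = 0; e < ev.type.size(); ++e) {
          if (ev.type[e] == 0 && ev.step[e] >= caching_start) {
            int j = idx[ev.site[e]];
            if (j >= 0) ior[j] += weight(clock, ev.step[e], d);
          }
        }
        std::vector<double> util(no);
        for (int i = 0; i < no; ++i) {
          double o = (near_tray > 0 && site_tray[offered[i] - 1] == near_tray)
                       ? oa : 0.0;
          util[i] = o + (-ior[i]);
        }
        if (n > 0) for (int i = 0; i < no; ++i) util[i] = util[i] + draw_noise(n);
        int site = offered[argmax_tie(util)];

        worms[site] += 1;
        mark_cached(site);
        lg.add(clock, 0, chain == 0 ? 0 : 1, site_tray[site - 1], site);
        c_place[site_tray[site - 1]] += 1;
        if (chain == 0) c_initial[site_tray[site - 1]] += 1;
        ev.add(0, site, 0, clock);
        ++clock;

        bool again = false;
        if (cr > 0 && chain < recache_cap) {
          if (draw_unif() < cr) again = true;
        }
        if (!again) break;
        worms[site] -= 1;
        c_imm[site_tray[site - 1]] += 1;
        lg.add(clock, 0, 2, site_tray[site - 1], site);
        ev.add(1, site, 1, clock);
        ++clock;
        ++chain;
      }
    }
  }

  // ---- recovery session ----------------------------------------------
  const int nr = recovery_sites.size();
  std::vector<int> ridx(S + 1, -1);
  for (int i = 0; i < nr; ++i) ridx[recovery_sites[i]] = i;
  const int session_start = clock;
  const int since = risk_session ? session_start : 0;
  const int breaker = 50 * nr;
  int steps = 0;
  bool flagged = false;

  auto worms_left = [&]() {
    int tot = 0;
    for (int i = 0; i < nr; ++i) tot += worms[recovery_sites[i]];
    return tot;
  };

  while (worms_left() > 0) {
    if (++steps > breaker) { flagged = true; break; }
    // decide where to recover: R_k = F_k + I_k + noise
    std::vector<double> fsum(nr, 0.0), ssum(nr, 0.0), usum(nr, 0.0);
    for (size_t e = 0; e < ev.type.size(); ++e) {
      int j = ridx[ev.site[e]];
      if (j < 0) continue;
      if (ev.type[e] == 0) {
        fsum[j] += weight(clock, ev.step[e], d);
      } else if (ev.step[e] >= session_start) {
        double w = weight(clock, ev.step[e], d);
        if (ev.succ[e]) ssum[j] += w;
        else usum[j] += w;
      }
    }
    std::vector<double> util(nr);
    for (int i = 0; i < nr; ++i)
      util[i] = fsum[i] + (-(ssum[i] + usum[i]));
    if (n > 0) for (int i = 0; i < nr; ++i) util[i] = util[i] + draw_noise(n);
    int site = recovery_sites[argmax_tie(util)];
    int tr = site_tray[site - 1];

    if (worms[site] > 0) {
      worms[site] -= 1;
      lg.add(clock, 1, 2, tr, site);
      ev.add(1, site, 1, clock);
      ++clock;
      // safety risk of this tray: S = A_u / (A_u + A_s) over qualifying
      // sites, summed per site in ascending site order (matches the R
      // reference associativity)
      double a_s = 0.0, a_u = 0.0;
      for (int s = 1; s <= S; ++s) {
        if (site_tray[s - 1] != tr || !qual[s]) continue;
        double ws = 0.0, wu = 0.0;
        for (size_t e = 0; e < ev.type.size(); ++e) {
          if (ev.type[e] != 1 || ev.site[e] != s || ev.step[e] < since) continue;
          double w = weight(clock, ev.step[e], d);
          if (ev.succ[e]) ws += w; else wu += w;
        }
        a_s += ws;
        a_u += wu;
      }
      double Srisk = (a_u + a_s > 0.0) ? a_u / (a_u + a_s) : 0.0;
      if (Srisk > st) {
        out_of_tray += 1;
        c_recached[tr] += 1;
        lg.add(clock - 1, 1, 4, tr, site);
      } else {
        eaten += 1;
      }
    } else {
      c_fail[tr] += 1;
      lg.add(clock, 1, 3, tr, site);
      ev.add(1, site, 0, clock);
      ++clock;
    }
  }

  return List::create(
    _["log_step"] = wrap(lg.step), _["log_session"] = wrap(lg.session),
    _["log_action"] = wrap(lg.action), _["log_tray"] = wrap(lg.tray),
    _["log_site"] = wrap(lg.site),
    _["ev_type"] = wrap(ev.type), _["ev_site"] = wrap(ev.site),
    _["ev_succ"] = wrap(ev.succ), _["ev_step"] = wrap(ev.step),
    _["clock"] = clock, _["worms_at"] = wrap(std::vector<int>(worms.begin() + 1, worms.end())),
    _["out_of_tray"] = out_of_tray, _["eaten"] = eaten,
    _["worms_given"] = worms_given, _["flagged"] = flagged,
    _["ct_initial"] = wrap(std::vector<int>(c_initial.begin() + 1, c_initial.end())),
    _["ct_place"] = wrap(std::vector<int>(c_place.begin() + 1, c_place.end())),
    _["ct_imm"] = wrap(std::vector<int>(c_imm.begin() + 1, c_imm.end())),
    _["ct_fail"] = wrap(std::vector<int>(c_fail.begin() + 1, c_fail.end())),
    _["ct_recached"] = wrap(std::vector<int>(c_recached.begin() + 1, c_recached.end())));
}
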