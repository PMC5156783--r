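// Fast tissue engine. Mirrors, step for step, the pure-R reference
// implementation in R/tissue.R (step_tissue / update_zones / divide_cell):
// a frozen-state (Jacobi) sweep computes every cell's free specific growth
// rate g and relaxation rate Gamma from the pre-step state (with li and lr
// already advanced), every transverse fragment is updated with the
// linearized-implicit rule lambda *= 1 + dt*gbar/(1 + dt*Gammabar) where
// gbar, Gammabar average over the N files, visible lengths are
// reconstituted as member-fragment sums, zones are refreshed and due
// division-zone cells are split, inserting the new wall into the fragment
// partition leaf-wide. Cells are stored in flat arrays indexed by creation
// order (never reindexed); per-file spatial order is kept in `forder`;
// fragment spatial order is kept in a doubly linked chain so a split is
// O(1) while the per-step fragment pass can run cache-friendly in id order.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Params {
  double Lw, alpha, beta, eta, Pc, r, rl;
};

inline double draw_division_factor(double mu, double sigma, double lo,
                                   double hi) {
  for (int it = 0; it < 100000; ++it) {
    double d = R::rnorm(mu, sigma);
    if (d > lo && d < hi) return d;
  }
  stop("division factor sampling failed (bounds too tight?)");
  return mu; // unreached
}

} // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List tissue, List cfg) {
  // --- unpack state -------------------------------------------------------
  DataFrame cells = as<DataFrame>(tissue["cells"]);
  NumericVector li0v = cells["li"];
  NumericVector l0v = cells["l"];
  NumericVector lr0v = cells["lr"];
  NumericVector lii0v = cells["li0"];
  NumericVector t0v = cells["t0"];
  NumericVector tswv = cells["t_switch"];
  CharacterVector zonev = cells["zone"];
  IntegerVector filev = cells["file"];
  NumericVector lam0 = tissue["lambda"];
  IntegerMatrix memb0 = tissue["membership"];
  const int N = as<int>(tissue["n_files"]);
  const double clock0 = as<double>(tissue["clock"]);

  List pl = tissue["params"];
  Params P;
  P.Lw = as<double>(pl["Lw"]); P.alpha = as<double>(pl["alpha"]);
  P.beta = as<double>(pl["beta"]); P.eta = as<double>(pl["eta"]);
  P.Pc = as<double>(pl["Pc"]); P.r = as<double>(pl["r"]);
  P.rl = P.r * P.Lw;

  List sch = tissue["schedule"];
  const double a1 = as<double>(sch["a1"]);
  const double a2 = as<double>(sch["a2"]);
  const double li_max = as<double>(sch["li_max"]);
  const double t_elong = as<double>(sch["t_elong"]);

  List dv = tissue["division"];
  const double d_mu = as<double>(dv["mu_d"]);
  const double d_sd = as<double>(dv["sigma_d"]);
  NumericVector d_b = dv["bounds"];

  const double dt = as<double>(cfg["dt"]);
  const double L_DZ_um = as<double>(cfg["L_DZ_um"]);
  const double L_GZ_um = as<double>(cfg["L_GZ_um"]);
  const double stop_um = as<double>(cfg["stop_um"]);
  const double max_time = as<double>(cfg["max_time"]);
  const int record = as<int>(cfg["record"]); // 0 none, 1 pressures, 2 +lengths
  const int horizon = as<int>(cfg["horizon"]); // recorded hours per cell
  const bool do_divide = as<bool>(cfg["divide"]);
  const bool verbose = cfg.containsElementNamed("verbose") ?
    as<bool>(cfg["verbose"]) : false;
  const long log_every = std::max(1L, (long)std::lround(10.0 / dt));

  const int n_init = li0v.size();

  // --- working arrays -----------------------------------------------------
  std::vector<double> li(li0v.begin(), li0v.end());
  std::vector<double> l(l0v.begin(), l0v.end());
  std::vector<double> lr(lr0v.begin(), lr0v.end());
  std::vector<double> cli0(lii0v.begin(), lii0v.end());
  std::vector<double> t0(t0v.begin(), t0v.end());
  std::vector<double> tsw(n_init), t_end(n_init, -1.0);
  std::vector<int> zone(n_init), cfile(n_init), parent(n_init, 0);
  std::vector<char> alive(n_init, 1), divided(n_init, 0);
  for (int i = 0; i < n_init; ++i) {
    tsw[i] = NumericVector::is_na(tswv[i]) ? -1.0 : tswv[i];
    cfile[i] = filev[i]; // 1-based
    std::string z = as<std::string>(zonev[i]);
    zone[i] = (z == "DZ") ? 0 : (z == "TZ") ? 1 : (z == "EZ") ? 2 : 3;
  }
  std::vector<std::vector<int> > forder(N);
  for (int i = 0; i < n_init; ++i) forder[cfile[i] - 1].push_back(i);

  int K = lam0.size();
  std::vector<double> lam(lam0.begin(), lam0.end());
  std::vector<int> memb; memb.reserve((size_t)K * N * 2);
  for (int k = 0; k < K; ++k)
    for (int n = 0; n < N; ++n) memb.push_back(memb0(k, n) - 1);
  std::vector<int> nxt(K), prv(K);
  for (int k = 0; k < K; ++k) { nxt[k] = k + 1; prv[k] = k - 1; }
  nxt[K - 1] = -1;
  int frag_head = 0;

  std::vector<double> g(n_init), gam(n_init), lsum(n_init);
  std::vector<double> posm(n_init), ptur(n_init);
  std::vector<int> next_rec(n_init, 1);

  std::vector<double> pres;   // n_cells x (2*horizon), row-major
  std::vector<double> lrec, lirec; // n_cells x horizon
  if (record >= 1) pres.assign((size_t)n_init * 2 * horizon, 0.0);
  if (record >= 2) {
    lrec.assign((size_t)n_init * horizon, 0.0);
    lirec.assign((size_t)n_init * horizon, 0.0);
  }

  double max_turg = as<double>(tissue["max_turgor"]);
  double clock = clock0;
  int stopped = 0; // 1 length, 2 time
  double leaf_len = 0.0;
  for (int k = 0; k < K; ++k) leaf_len += lam[k];
  if (leaf_len >= stop_um) stopped = 1;

  std::vector<int> due;
  // --- main loop ----------------------------------------------------------
  for (long step = 0; stopped == 0; ++step) {
    const double t_new = clock0 + (step + 1) * dt;
    // 1. advance li, lr; free rates from the frozen state
    for (int n = 0; n < N; ++n) {
      const std::vector<int>& ord = forder[n];
      for (size_t q = 0; q < ord.size(); ++q) {
        const int c = ord[q];
        const double li_dot = (zone[c] <= 1) ? a1 : (zone[c] == 2 ? a2 : 0.0);
        const double pt = P.beta * (l[c] - lr[c]) / lr[c];
        li[c] += dt * li_dot;
        double ex = pt - P.Pc;
        if (ex > 0) lr[c] += dt * P.eta * li_dot * ex * ex * ex;
        g[c] = P.rl * (P.alpha * (li[c] - l[c]) / l[c]
                       - P.beta * (l[c] - lr[c]) / lr[c]);
        gam[c] = P.rl * (P.alpha * li[c] / l[c] + P.beta * l[c] / lr[c]);
        lsum[c] = 0.0;
      }
    }
    // 2. fragment update (id order; order-independent averages)
    leaf_len = 0.0;
    for (int k = 0; k < K; ++k) {
      const int* row = &memb[(size_t)k * N];
      double sg = 0.0, sG = 0.0;
      for (int n = 0; n < N; ++n) { sg += g[row[n]]; sG += gam[row[n]]; }
      const double nl = lam[k] * (1.0 + dt * (sg / N) / (1.0 + dt * (sG / N)));
      if (!(nl > 0.0))
        stop("fragment length became non-positive at t = %f; reduce dt",
             t_new);
      lam[k] = nl;
      leaf_len += nl;
      for (int n = 0; n < N; ++n) lsum[row[n]] += nl;
    }
    // 3. commit lengths; positions, zones, post-step pressures
    for (int n = 0; n < N; ++n) {
      const std::vector<int>& ord = forder[n];
      double cum = 0.0;
      for (size_t q = 0; q < ord.size(); ++q) {
        const int c = ord[q];
        l[c] = lsum[c];
        const double mid = cum + 0.5 * l[c];
        cum += l[c];
        if (zone[c] == 0 && mid >= L_DZ_um) zone[c] = 1;
        if (zone[c] == 1 && li[c] >= li_max - 1e-9) {
          zone[c] = 2; tsw[c] = t_new;
        }
        if (zone[c] == 2 &&
            (t_new - tsw[c] >= t_elong - 1e-9 || mid >= L_GZ_um)) zone[c] = 3;
        if (zone[c] == 1 && mid >= L_GZ_um) zone[c] = 3;
        posm[c] = P.alpha * (li[c] - l[c]) / l[c];
        ptur[c] = P.beta * (l[c] - lr[c]) / lr[c];
        if (ptur[c] > max_turg) max_turg = ptur[c];
      }
    }
    // 4. divisions
    if (do_divide) {
      due.clear();
      for (int n = 0; n < N; ++n) {
        const std::vector<int>& ord = forder[n];
        for (size_t q = 0; q < ord.size(); ++q) {
          const int c = ord[q];
          if (zone[c] == 0 && li[c] >= li_max - 1e-9) due.push_back(c);
        }
      }
      for (size_t di = 0; di < due.size(); ++di) {
        const int m = due[di];
        const int fn = cfile[m] - 1;
        const double d = draw_division_factor(d_mu, d_sd, d_b[0], d_b[1]);
        // collect the mother's fragments in spatial order via the chain
        int any = -1;
        for (int k = 0; k < K; ++k)
          if (memb[(size_t)k * N + fn] == m) { any = k; break; }
        if (any < 0) stop("internal error: dividing cell has no fragments");
        int first = any;
        while (prv[first] >= 0 && memb[(size_t)prv[first] * N + fn] == m)
          first = prv[first];
        std::vector<int> mf;
        for (int k = first; k >= 0 && memb[(size_t)k * N + fn] == m;
             k = nxt[k]) mf.push_back(k);
        const double target = d * l[m];
        double cum = 0.0;
        size_t j_loc = mf.size() - 1;
        double cum_before = 0.0;
        for (size_t q = 0; q < mf.size(); ++q) {
          const double nc = cum + lam[mf[q]];
          if (nc >= target - 1e-12) { j_loc = q; cum_before = cum; break; }
          cum = nc;
          if (q == mf.size() - 1) cum_before = cum - lam[mf[q]];
        }
        const int j = mf[j_loc];
        const double lamA = target - cum_before;
        std::vector<int> below, above;
        if (lamA > 1e-12 && lamA < lam[j] - 1e-12) {
          const double lamB = lam[j] - lamA;
          lam[j] = lamA;
          const int j2 = K++;
          lam.push_back(lamB);
          for (int n = 0; n < N; ++n)
            memb.push_back(memb[(size_t)j * N + n]);
          nxt.push_back(nxt[j]); prv.push_back(j);
          if (nxt[j] >= 0) prv[nxt[j]] = j2;
          nxt[j] = j2;
          for (size_t q = 0; q <= j_loc; ++q) below.push_back(mf[q]);
          above.push_back(j2);
          for (size_t q = j_loc + 1; q < mf.size(); ++q)
            above.push_back(mf[q]);
        } else if (lamA <= 1e-12) {
          for (size_t q = 0; q < j_loc; ++q) below.push_back(mf[q]);
          for (size_t q = j_loc; q < mf.size(); ++q) above.push_back(mf[q]);
        } else {
          for (size_t q = 0; q <= j_loc; ++q) below.push_back(mf[q]);
          for (size_t q = j_loc + 1; q < mf.size(); ++q)
            above.push_back(mf[q]);
        }
        if (below.empty() || above.empty())
          stop("degenerate division split at t = %f", t_new);
        // daughters
        const int c1 = (int)li.size(), c2 = c1 + 1;
        double lb = 0.0, la = 0.0;
        for (size_t q = 0; q < below.size(); ++q) lb += lam[below[q]];
        for (size_t q = 0; q < above.size(); ++q) la += lam[above[q]];
        const double dli = d * li[m], dlr = d * lr[m];
        li.push_back(dli);        li.push_back(li[m] - dli);
        lr.push_back(dlr);        lr.push_back(lr[m] - dlr);
        l.push_back(lb);          l.push_back(la);
        cli0.push_back(d * li_max); cli0.push_back((1.0 - d) * li_max);
        t0.push_back(t_new);      t0.push_back(t_new);
        tsw.push_back(-1.0);      tsw.push_back(-1.0);
        t_end.push_back(-1.0);    t_end.push_back(-1.0);
        zone.push_back(0);        zone.push_back(0);
        cfile.push_back(fn + 1);  cfile.push_back(fn + 1);
        parent.push_back(m + 1);  parent.push_back(m + 1);
        alive.push_back(1);       alive.push_back(1);
        divided.push_back(0);     divided.push_back(0);
        g.push_back(0); g.push_back(0);
        gam.push_back(0); gam.push_back(0);
        lsum.push_back(0); lsum.push_back(0);
        posm.push_back(0); posm.push_back(0);
        ptur.push_back(0); ptur.push_back(0);
        next_rec.push_back(1); next_rec.push_back(1);
        if (record >= 1) pres.resize(pres.size() + 4 * (size_t)horizon, 0.0);
        if (record >= 2) {
          lrec.resize(lrec.size() + 2 * (size_t)horizon, 0.0);
          lirec.resize(lirec.size() + 2 * (size_t)horizon, 0.0);
        }
        alive[m] = 0; divided[m] = 1; t_end[m] = t_new;
        for (size_t q = 0; q < below.size(); ++q)
          memb[(size_t)below[q] * N + fn] = c1;
        for (size_t q = 0; q < above.size(); ++q)
          memb[(size_t)above[q] * N + fn] = c2;
        std::vector<int>& ord = forder[fn];
        for (size_t q = 0; q < ord.size(); ++q)
          if (ord[q] == m) {
            ord[q] = c1;
            ord.insert(ord.begin() + q + 1, c2);
            break;
          }
      }
    }
    // 5. recording at whole hours of each cell's life
    if (record >= 1) {
      for (int n = 0; n < N; ++n) {
        const std::vector<int>& ord = forder[n];
        for (size_t q = 0; q < ord.size(); ++q) {
          const int c = ord[q];
          const double age = t_new - t0[c];
          while (next_rec[c] <= horizon &&
                 age >= next_rec[c] - 1e-9) {
            const size_t base = (size_t)c * 2 * horizon;
            pres[base + next_rec[c] - 1] =
              P.alpha * (li[c] - l[c]) / l[c];
            pres[base + horizon + next_rec[c] - 1] =
              P.beta * (l[c] - lr[c]) / lr[c];
            if (record >= 2) {
              lrec[(size_t)c * horizon + next_rec[c] - 1] = l[c];
              lirec[(size_t)c * horizon + next_rec[c] - 1] = li[c];
            }
            ++next_rec[c];
          }
        }
      }
    }
    clock = t_new;
    if (verbose && ((step + 1) % log_every == 0)) {
      int na = 0;
      for (int n = 0; n < N; ++n) na += (int)forder[n].size();
      Rprintf("t=%8.2f h  leaf=%8.3f mm  cells=%7d (%d created)  "
              "max_turgor=%6.2f bar\n",
              t_new, leaf_len / 1000.0, na, (int)li.size(), max_turg);
    }
    if (leaf_len >= stop_um) { stopped = 1; break; }
    if (t_new >= max_time - 1e-9) { stopped = 2; break; }
    if ((step & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  // --- assemble outputs ---------------------------------------------------
  const int ncells = (int)li.size();
  // alive cells, file-major spatial order
  std::vector<int> out_row(ncells, -1);
  int n_alive = 0;
  for (int n = 0; n < N; ++n)
    for (size_t q = 0; q < forder[n].size(); ++q)
      out_row[forder[n][q]] = n_alive++;
  IntegerVector o_id(n_alive), o_file(n_alive);
  NumericVector o_li(n_alive), o_l(n_alive), o_lr(n_alive),
      o_li0(n_alive), o_t0(n_alive), o_tsw(n_alive), o_pos(n_alive);
  CharacterVector o_zone(n_alive);
  const char* zl[4] = {"DZ", "TZ", "EZ", "MATURE"};
  for (int n = 0; n < N; ++n) {
    double cum = 0.0;
    for (size_t q = 0; q < forder[n].size(); ++q) {
      const int c = forder[n][q];
      const int rr = out_row[c];
      o_id[rr] = c + 1; o_file[rr] = n + 1;
      o_li[rr] = li[c]; o_l[rr] = l[c]; o_lr[rr] = lr[c];
      o_li0[rr] = cli0[c]; o_t0[rr] = t0[c];
      o_tsw[rr] = tsw[c] < 0 ? NA_REAL : tsw[c];
      o_zone[rr] = zl[zone[c]];
      o_pos[rr] = cum + 0.5 * l[c];
      cum += l[c];
    }
  }
  DataFrame out_cells = DataFrame::create(
      _["id"] = o_id, _["file"] = o_file, _["li"] = o_li, _["l"] = o_l,
      _["lr"] = o_lr, _["li0"] = o_li0, _["t0"] = o_t0,
      _["t_switch"] = o_tsw, _["zone"] = o_zone,
      _["position_um"] = o_pos, _["stringsAsFactors"] = false);

  IntegerVector g_id(ncells), g_file(ncells), g_parent(ncells);
  NumericVector g_t0(ncells), g_li0(ncells), g_tend(ncells);
  LogicalVector g_div(ncells);
  for (int c = 0; c < ncells; ++c) {
    g_id[c] = c + 1; g_file[c] = cfile[c]; g_t0[c] = t0[c];
    g_li0[c] = cli0[c];
    g_tend[c] = t_end[c] < 0 ? clock : t_end[c];
    g_div[c] = divided[c] != 0;
    g_parent[c] = parent[c] == 0 ? NA_INTEGER : parent[c];
  }
  DataFrame out_log = DataFrame::create(
      _["id"] = g_id, _["file"] = g_file, _["t0"] = g_t0,
      _["li0"] = g_li0, _["t_end"] = g_tend, _["divided"] = g_div,
      _["parent"] = g_parent);

  // fragments in spatial order, membership as rows of out_cells (1-based)
  NumericVector o_lam(K);
  IntegerMatrix o_memb(K, N);
  int kk = 0;
  for (int k = frag_head; k >= 0; k = nxt[k], ++kk) {
    o_lam[kk] = lam[k];
    for (int n = 0; n < N; ++n)
      o_memb(kk, n) = out_row[memb[(size_t)k * N + n]] + 1;
  }

  List out = List::create(
      _["cells"] = out_cells, _["log"] = out_log, _["lambda"] = o_lam,
      _["membership"] = o_memb, _["clock"] = clock,
      _["n_created"] = ncells, _["max_turgor"] = max_turg,
      _["stopped_by"] = stopped == 1 ? "length" : "time");
  if (record >= 1) {
    NumericMatrix pm(ncells, 2 * horizon);
    for (int c = 0; c < ncells; ++c)
      for (int k2 = 0; k2 < 2 * horizon; ++k2)
        pm(c, k2) = pres[(size_t)c * 2 * horizon + k2];
    out["pressures"] = pm;
  }
  if (record >= 2) {
    NumericMatrix lm(ncells, horizon), lim(ncells, horizon);
    for (int c = 0; c < ncells; ++c)
      for (int k2 = 0; k2 < horizon; ++k2) {
        lm(c, k2) = lrec[(size_t)c * horizon + k2];
        lim(c, k2) = lirec[(size_t)c * horizon + k2];
      }
    out["l_rec"] = lm;
    out["li_rec"] = lim;
  }
  return out;
}
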