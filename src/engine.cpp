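// Vectorized Izhikevich network engine for the MOB-PCx model.
//
// One trial = `n_steps` forward-Euler ms-steps of every cell, with
// jump-and-decay synaptic channels (tau = syn_tau ms), per-synapse delayed
// MC->GC delivery through a ring buffer, step glomerular input with shared +
// independent Gaussian noise, and per-cell background white noise.  All
// randomness comes from R's RNG so R-level seeds fully determine a trial.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct CSC {
  IntegerVector p, i;
  NumericVector x;
  int nrow, ncol;
  explicit CSC(S4 m)
      : p(as<IntegerVector>(m.slot("p"))),
        i(as<IntegerVector>(m.slot("i"))),
        x(as<NumericVector>(m.slot("x"))) {
    IntegerVector d = m.slot("Dim");
    nrow = d[0];
    ncol = d[1];
  }
};

// add column `col` of W into channel array `ch` with row offset
inline void deliver(const CSC& W, int col, std::vector<double>& ch, int off) {
  for (int k = W.p[col]; k < W.p[col + 1]; ++k) ch[off + W.i[k]] += W.x[k];
}

}  // namespace

// [[Rcpp::export]]
List sim_trial_cpp(List eng, IntegerMatrix glom_act, double osn_amp,
                   double osn_sd_shared, double osn_sd_indiv,
                   IntegerVector record_cells) {
  const int n_mt = eng["n_mt"], n_gc = eng["n_gc"], n_pc = eng["n_pc"],
            n_ffi = eng["n_ffi"], n_fbi = eng["n_fbi"];
  const int off_gc = n_mt, off_pc = n_mt + n_gc, off_ffi = off_pc + n_pc,
            off_fbi = off_ffi + n_ffi;
  const int N = off_fbi + n_fbi;
  const int n_steps = eng["n_steps"];
  const int n_sub = eng["n_substeps"];
  const double dt = eng["dt_ms"];
  const double tau = eng["syn_tau_ms"];
  const bool fb_on = eng["feedback_on"];
  const double dec = std::exp(-dt / tau);

  NumericVector a_ = eng["a"], b_ = eng["b"], c_ = eng["c"], d_ = eng["d"],
                sigma_ = eng["sigma"];
  IntegerVector mt_glom_ = eng["mt_glom"];  // 1-based
  IntegerVector delay_ = eng["delay_mtgc"]; // aligned with mtgc@x, ms >= 1
  // raw pointers: keeps the hot loop free of SEXP proxy / aliasing overhead
  const double *a = REAL(a_), *b = REAL(b_), *c = REAL(c_), *d = REAL(d_),
               *sigma = REAL(sigma_);
  const int *mt_glom = INTEGER(mt_glom_), *delay = INTEGER(delay_);

  CSC mtmt(as<S4>(eng["mtmt"])), mtgc(as<S4>(eng["mtgc"])),
      gcmc(as<S4>(eng["gcmc"])), gcgc(as<S4>(eng["gcgc"])),
      mtpc(as<S4>(eng["mtpc"])), mtffi(as<S4>(eng["mtffi"])),
      pcpc(as<S4>(eng["pcpc"])), ffipc(as<S4>(eng["ffipc"])),
      fbipc(as<S4>(eng["fbipc"])), ffiffi(as<S4>(eng["ffiffi"])),
      pcfbi(as<S4>(eng["pcfbi"])), fbifbi(as<S4>(eng["fbifbi"])),
      fb(as<S4>(eng["fb"]));

  int max_delay = 1;
  for (int k = 0; k < delay_.size(); ++k)
    if (delay[k] > max_delay) max_delay = delay[k];
  const int nslots = max_delay + 1;
  std::vector<std::vector<double>> buf(nslots, std::vector<double>(n_gc, 0.0));

  // state
  std::vector<double> v(N), u(N);
  for (int i = 0; i < N; ++i) {
    v[i] = c[i];
    u[i] = b[i] * v[i];
  }
  // synaptic channels (global indexing; each cell class reads its own)
  std::vector<double> ex_mob(N, 0.0), in_mob(N, 0.0), fb_gc(N, 0.0),
      mob_pcx(N, 0.0), ex_pcx(N, 0.0), in_pcx(N, 0.0);

  const int n_glom = glom_act.nrow();
  const int* gact = INTEGER(glom_act);
  std::vector<double> osn(n_mt, 0.0), shared(n_glom, 0.0);

  IntegerMatrix counts(N, n_steps + 1);
  int* cnt = INTEGER(counts);
  std::vector<int> sp_cell, sp_time;
  sp_cell.reserve(4096);
  sp_time.reserve(4096);

  const int n_rec = record_cells.size();
  NumericMatrix rec_ex_mob, rec_in_mob, rec_fb, rec_mob, rec_ex_pcx, rec_in_pcx;
  if (n_rec > 0) {
    rec_ex_mob = NumericMatrix(n_rec, n_steps + 1);
    rec_in_mob = NumericMatrix(n_rec, n_steps + 1);
    rec_fb = NumericMatrix(n_rec, n_steps + 1);
    rec_mob = NumericMatrix(n_rec, n_steps + 1);
    rec_ex_pcx = NumericMatrix(n_rec, n_steps + 1);
    rec_in_pcx = NumericMatrix(n_rec, n_steps + 1);
  }

  std::vector<int> spiking;
  spiking.reserve(N);

  for (int t = 1; t <= n_steps; ++t) {
    // 1. exponential decay of every synaptic channel
    for (int i = 0; i < N; ++i) {
      ex_mob[i] *= dec; in_mob[i] *= dec; fb_gc[i] *= dec;
      mob_pcx[i] *= dec; ex_pcx[i] *= dec; in_pcx[i] *= dec;
    }
    // 2. delayed MC->GC deliveries arriving now
    {
      std::vector<double>& slot = buf[t % nslots];
      for (int g = 0; g < n_gc; ++g) {
        ex_mob[off_gc + g] += slot[g];
        slot[g] = 0.0;
      }
    }
    // 3. glomerular step input with shared + independent noise
    const int* act_t = gact + (std::size_t)n_glom * (t - 1);
    for (int g = 0; g < n_glom; ++g)
      if (act_t[g])
        shared[g] = (osn_sd_shared > 0) ? osn_sd_shared * norm_rand() : 0.0;
    for (int m = 0; m < n_mt; ++m) {
      int g = mt_glom[m] - 1;
      if (act_t[g]) {
        double e = (osn_sd_indiv > 0) ? osn_sd_indiv * norm_rand() : 0.0;
        osn[m] = osn_amp + shared[g] + e;
      } else {
        osn[m] = 0.0;
      }
    }
    // 4. integrate all cells
    spiking.clear();
    const double h = dt / n_sub;
    double* vv = v.data();
    double* uu = u.data();
    const double *p_exm = ex_mob.data(), *p_inm = in_mob.data(),
                 *p_fb = fb_gc.data(), *p_mob = mob_pcx.data(),
                 *p_exp = ex_pcx.data(), *p_inp = in_pcx.data();
    int bad_cell = -1;
    for (int i = 0; i < N; ++i) {
      double I;
      if (i < off_gc) {                       // M/T
        I = p_exm[i] + p_inm[i] + osn[i];
      } else if (i < off_pc) {                // GC
        I = p_exm[i] + p_inm[i] + (fb_on ? p_fb[i] : 0.0);
      } else if (i < off_ffi) {               // PC
        I = p_mob[i] + p_exp[i] + p_inp[i];
      } else if (i < off_fbi) {               // FFI
        I = p_mob[i] + p_inp[i];
      } else {                                // FBI
        I = p_exp[i] + p_inp[i];
      }
      if (sigma[i] > 0) I += sigma[i] * norm_rand();
      double vi = vv[i], ui = uu[i];
      const double v0 = vi;
      for (int s = 0; s < n_sub; ++s)
        vi += h * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I);
      ui += dt * a[i] * (b[i] * v0 - ui);
      if (!(vi > -1e6 && vi < 1e6) || !(ui > -1e6 && ui < 1e6)) bad_cell = i;
      if (vi >= 30.0) {
        cnt[i + (std::size_t)N * t] = 1;
        sp_cell.push_back(i + 1);
        sp_time.push_back(t);
        spiking.push_back(i);
        vi = c[i];
        ui += d[i];
      }
      vv[i] = vi;
      uu[i] = ui;
    }
    if (bad_cell >= 0)
      stop("simulation diverged at t=%d ms for cell %d", t, bad_cell + 1);
    // 5. synaptic delivery from this step's spikes
    for (int idx : spiking) {
      if (idx < off_gc) {                     // M/T spike
        int m = idx;
        deliver(mtmt, m, ex_mob, 0);
        for (int k = mtgc.p[m]; k < mtgc.p[m + 1]; ++k)
          buf[(t + delay[k]) % nslots][mtgc.i[k]] += mtgc.x[k];
        deliver(mtpc, m, mob_pcx, off_pc);
        deliver(mtffi, m, mob_pcx, off_ffi);
      } else if (idx < off_pc) {              // GC spike
        int g = idx - off_gc;
        deliver(gcmc, g, in_mob, 0);
        deliver(gcgc, g, in_mob, off_gc);
      } else if (idx < off_ffi) {             // PC spike
        int p = idx - off_pc;
        deliver(pcpc, p, ex_pcx, off_pc);
        deliver(pcfbi, p, ex_pcx, off_fbi);
        if (fb_on) deliver(fb, p, fb_gc, off_gc);
      } else if (idx < off_fbi) {             // FFI spike
        int f = idx - off_ffi;
        deliver(ffipc, f, in_pcx, off_pc);
        deliver(ffiffi, f, in_pcx, off_ffi);
      } else {                                // FBI spike
        int f = idx - off_fbi;
        deliver(fbipc, f, in_pcx, off_pc);
        deliver(fbifbi, f, in_pcx, off_fbi);
      }
    }
    // 6. channel recording (value at end of step, jumps included)
    if (n_rec > 0) {
      for (int r = 0; r < n_rec; ++r) {
        int i = record_cells[r] - 1;
        rec_ex_mob(r, t) = ex_mob[i];
        rec_in_mob(r, t) = in_mob[i];
        rec_fb(r, t) = fb_gc[i];
        rec_mob(r, t) = mob_pcx[i];
        rec_ex_pcx(r, t) = ex_pcx[i];
        rec_in_pcx(r, t) = in_pcx[i];
      }
    }
  }

  List out = List::create(
      _["counts"] = counts,
      _["spike_cell"] = IntegerVector(sp_cell.begin(), sp_cell.end()),
      _["spike_time"] = IntegerVector(sp_time.begin(), sp_time.end()));
  if (n_rec > 0)
    out["channels"] = List::create(
        _["mc_ex"] = rec_ex_mob, _["gc_in"] = rec_in_mob,
        _["feedback"] = rec_fb, _["mob"] = rec_mob,
        _["pc_ex"] = rec_ex_pcx, _["pcx_in"] = rec_in_pcx);
  return out;
}

// Suppression-model STDP for one weight block.
//
// For every nonzero synapse whose pre or post cell is flagged plastic, sums
// eps_pre * eps_post * F(t_post - t_pre) over all spike pairs of the trial
// and applies the additive update with sign-preserving clipping.  Spike
// trains are passed CSR-style per cell (offsets into time/efficacy arrays).
// Per-synapse STDP parameters are aligned with W@x.  Returns the updated
// value vector (structure unchanged).
// [[Rcpp::export]]
NumericVector stdp_block_cpp(S4 W, NumericVector Ap, NumericVector Am,
                             NumericVector Tp, NumericVector Tm,
                             LogicalVector plastic_pre,
                             LogicalVector plastic_post,
                             IntegerVector pre_off, IntegerVector pre_t,
                             NumericVector pre_e, IntegerVector post_off,
                             IntegerVector post_t, NumericVector post_e,
                             double lr, double wcap, int update_mode,
                             bool in_place) {
  // update_mode: 0 = excitatory, clip [0, wcap];
  //              1 = inhibitory, update acts on the magnitude;
  //              2 = inhibitory, signed additive update, clip [-wcap, 0]
  CSC w(W);
  // in_place mutates W@x directly (caller must own the vector exclusively,
  // as the experiment drivers do between reshuffles); otherwise work on a
  // copy and leave W untouched
  NumericVector xout = in_place ? w.x : clone(w.x);
  for (int j = 0; j < w.ncol; ++j) {
    const int p0 = pre_off[j], p1 = pre_off[j + 1];
    if (p0 == p1) continue;  // silent presynaptic cell: no pairs
    const bool pre_pl = plastic_pre[j];
    for (int k = w.p[j]; k < w.p[j + 1]; ++k) {
      const int row = w.i[k];
      if (!pre_pl && !plastic_post[row]) continue;
      const int q0 = post_off[row], q1 = post_off[row + 1];
      if (q0 == q1) continue;
      double s = 0.0;
      for (int ip = p0; ip < p1; ++ip) {
        const double tp = pre_t[ip], ep = pre_e[ip];
        for (int iq = q0; iq < q1; ++iq) {
          const double dtij = post_t[iq] - tp;
          double F;
          if (dtij > 0)
            F = Ap[k] * std::exp(-dtij / Tp[k]);
          else if (dtij < 0)
            F = Am[k] * std::exp(dtij / Tm[k]);
          else
            F = 0.0;  // simultaneous spikes: no contribution
          s += ep * post_e[iq] * F;
        }
      }
      if (s == 0.0) continue;
      if (update_mode == 0) {
        double wn = xout[k] + lr * s;
        xout[k] = std::min(std::max(wn, 0.0), wcap);
      } else if (update_mode == 1) {
        // potentiation strengthens inhibition: update acts on the magnitude
        double m = -xout[k] + lr * s;
        xout[k] = -std::min(std::max(m, 0.0), wcap);
      } else {
        double wn = xout[k] + lr * s;
        xout[k] = std::min(std::max(wn, -wcap), 0.0);
      }
    }
  }
  return xout;
}
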