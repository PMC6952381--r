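#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Coupled Monte-Carlo / molecular-dynamics engine.
//
// All nuclei/ions and delocalized electrons are propagated classically
// (velocity Verlet, softened Coulomb forces, default 10-as steps) while
// per-atom electronic configurations evolve stochastically through the
// photoionization, resonant-excitation, Auger, fluorescence,
// electron-impact-ionization and recombination channels. Lengths/times in
// Hartree atomic units inside the engine; channel cross sections arrive
// in nm^2 and the pulse flux is evaluated in photons/nm^2/fs.
//
// The engine runs until t_end or until an atom lands in a configuration
// whose channel tables have not been built yet, in which case it returns
// control to R (status = 1) with the list of needed configuration
// indices; R builds the tables and re-enters.

static const double AU_EV = 27.211386245988;
static const double FS_AU = 41.341373335;
static const double BOHR_NM = 0.052917721067;

struct EventLog {
  std::vector<double> t_fs;
  std::vector<int> atom, type, from, to;
  void add(double t, int a, int ty, int fr, int toi) {
    t_fs.push_back(t); atom.push_back(a); type.push_back(ty);
    from.push_back(fr); to.push_back(toi);
  }
};

static inline double lotz_sigma_nm2(const double* bind, const int* occ,
                                    int nsub, double ke_ev) {
  double s = 0.0;
  for (int i = 0; i < nsub; ++i) {
    if (occ[i] > 0 && bind[i] > 0 && ke_ev > bind[i]) {
      s += 4.5 * occ[i] * std::log(ke_ev / bind[i]) / (ke_ev * bind[i]);
    }
  }
  return s;
}

// [[Rcpp::export]]
List cpp_run_dynamics(NumericMatrix apos_in, NumericMatrix avel_in,
                      NumericVector amass, IntegerVector acfg_in,
                      NumericMatrix epos_in, NumericMatrix evel_in,
                      double t_now, double t_end, double dt,
                      List tables, List pulse, List ctrl,
                      int escaped_in, double injected_in,
                      double removed_in, double next_snap_in,
                      IntegerVector last_ei_in) {
  const int N = apos_in.nrow();
  std::vector<double> ax(N), ay(N), az(N), avx(N), avy(N), avz(N);
  std::vector<int> cfg(N);
  for (int i = 0; i < N; ++i) {
    ax[i] = apos_in(i, 0); ay[i] = apos_in(i, 1); az[i] = apos_in(i, 2);
    avx[i] = avel_in(i, 0); avy[i] = avel_in(i, 1); avz[i] = avel_in(i, 2);
    cfg[i] = acfg_in[i] - 1;
  }
  int M = epos_in.nrow();
  std::vector<double> ex, ey, ez, evx, evy, evz;
  for (int i = 0; i < M; ++i) {
    ex.push_back(epos_in(i, 0)); ey.push_back(epos_in(i, 1));
    ez.push_back(epos_in(i, 2));
    evx.push_back(evel_in(i, 0)); evy.push_back(evel_in(i, 1));
    evz.push_back(evel_in(i, 2));
  }

  // tables
  LogicalVector ready = tables["ready"];
  IntegerVector qcfg = tables["charge"];
  NumericMatrix photo_sig = tables["photo_sig"];
  NumericMatrix photo_ke = tables["photo_ke"];
  IntegerMatrix photo_tgt = tables["photo_tgt"];
  NumericMatrix res_sig = tables["res_sig"];
  IntegerMatrix res_tgt = tables["res_tgt"];
  NumericVector aug_rate = tables["aug_rate"];
  NumericVector aug_ke = tables["aug_ke"];
  IntegerVector aug_tgt = tables["aug_tgt"];
  NumericVector fl_rate = tables["fl_rate"];
  IntegerVector fl_tgt = tables["fl_tgt"];
  IntegerVector ei_tgt = tables["ei_tgt"];
  IntegerVector rc_tgt = tables["rc_tgt"];
  NumericVector ei_bind = tables["ei_bind"];
  NumericMatrix bind_ev = tables["bind_ev"];
  IntegerMatrix occm = tables["occ"];
  const int NPH = photo_sig.ncol(), NRES = res_sig.ncol(),
            NSUB = bind_ev.ncol();

  // pulse
  const double F_ph_nm2 = pulse["fluence_photons_nm2"];
  const double tau_fs = pulse["fwhm_fs"];

  // control
  const double soft2 = ctrl["soft2"];       // bohr^2
  const double r_int = ctrl["r_int"];       // bohr
  const double r_cap = ctrl["r_cap"];       // bohr
  const bool do_ei = ctrl["ei"];
  const bool do_rc = ctrl["rc"];
  const bool motion = ctrl["motion"];
  const bool damage = ctrl["damage"];
  const double snap_every = ctrl["snap_every"];  // a.u.

  const double dt_fs = dt / FS_AU;
  double next_snap = next_snap_in;
  int escaped = escaped_in;
  double injected = injected_in, removed = removed_in;

  EventLog log;
  std::vector<double> snap_t; std::vector<int> snap_ne, snap_esc;
  std::vector<double> snap_pos; std::vector<int> snap_cfg;

  // forces (recomputed fresh at both Verlet stages) and per-electron
  // potential energy in the full cluster field
  std::vector<double> fax(N, 0), fay(N, 0), faz(N, 0);
  std::vector<double> fex, fey, fez, pee;

  std::vector<double> px(64), py(64), pz(64); // electron prev positions
  // per-electron EI hysteresis partner (0-based; persisted across
  // chunk re-entries so the event stream is independent of table builds)
  std::vector<int> last_ei(last_ei_in.begin(), last_ei_in.end());
  if ((int)last_ei.size() < std::max(64, M)) last_ei.resize(std::max(64, M), -1);
  // at most one configuration transition per atom per step: every channel
  // lookup then references the gate-checked start-of-step configuration,
  // making the event stream independent of table-build history
  std::vector<char> moved(N, 0);

  auto compute_forces = [&]() {
    std::fill(fax.begin(), fax.end(), 0.0);
    std::fill(fay.begin(), fay.end(), 0.0);
    std::fill(faz.begin(), faz.end(), 0.0);
    int m = ex.size();
    fex.assign(m, 0.0); fey.assign(m, 0.0); fez.assign(m, 0.0);
    pee.assign(m, 0.0);
    // ion-ion
    for (int i = 0; i < N; ++i) {
      double qi = qcfg[cfg[i]];
      if (qi == 0) continue;
      for (int j = i + 1; j < N; ++j) {
        double qj = qcfg[cfg[j]];
        if (qj == 0) continue;
        double dx = ax[i] - ax[j], dy = ay[i] - ay[j], dz = az[i] - az[j];
        double r2 = dx * dx + dy * dy + dz * dz + soft2;
        double f = qi * qj / (r2 * std::sqrt(r2));
        fax[i] += f * dx; fay[i] += f * dy; faz[i] += f * dz;
        fax[j] -= f * dx; fay[j] -= f * dy; faz[j] -= f * dz;
      }
    }
    // electron-ion and electron-electron
    for (int i = 0; i < m; ++i) {
      for (int j = 0; j < N; ++j) {
        double qj = qcfg[cfg[j]];
        if (qj == 0) continue;
        double dx = ex[i] - ax[j], dy = ey[i] - ay[j], dz = ez[i] - az[j];
        double r2 = dx * dx + dy * dy + dz * dz + soft2;
        double rr = std::sqrt(r2);
        double f = -qj / (r2 * rr);
        fex[i] += f * dx; fey[i] += f * dy; fez[i] += f * dz;
        fax[j] -= f * dx; fay[j] -= f * dy; faz[j] -= f * dz;
        pee[i] += -qj / rr;
      }
      for (int k = i + 1; k < m; ++k) {
        double dx = ex[i] - ex[k], dy = ey[i] - ey[k], dz = ez[i] - ez[k];
        double r2 = dx * dx + dy * dy + dz * dz + soft2;
        double rr = std::sqrt(r2);
        double f = 1.0 / (r2 * rr);
        fex[i] += f * dx; fey[i] += f * dy; fez[i] += f * dz;
        fex[k] -= f * dx; fey[k] -= f * dy; fez[k] -= f * dz;
        pee[i] += 1.0 / rr; pee[k] += 1.0 / rr;
      }
    }
  };

  // pair potential energy of particle (kind 0 = electron idx, 1 = atom idx)
  auto particle_pe = [&](bool is_electron, int idx) {
    double q0 = is_electron ? -1.0 : (double)qcfg[cfg[idx]];
    if (q0 == 0) return 0.0;
    double x0 = is_electron ? ex[idx] : ax[idx];
    double y0 = is_electron ? ey[idx] : ay[idx];
    double z0 = is_electron ? ez[idx] : az[idx];
    double pe = 0.0;
    for (int j = 0; j < N; ++j) {
      if (!is_electron && j == idx) continue;
      double qj = qcfg[cfg[j]];
      if (qj == 0) continue;
      double dx = x0 - ax[j], dy = y0 - ay[j], dz = z0 - az[j];
      pe += q0 * qj / std::sqrt(dx * dx + dy * dy + dz * dz + soft2);
    }
    int m = ex.size();
    for (int k = 0; k < m; ++k) {
      if (is_electron && k == idx) continue;
      double dx = x0 - ex[k], dy = y0 - ey[k], dz = z0 - ez[k];
      pe += q0 * -1.0 / std::sqrt(dx * dx + dy * dy + dz * dz + soft2);
    }
    return pe;
  };

  // electrostatic potential at an atom site (for the energy audit of
  // charge-changing events)
  auto site_potential = [&](int j) {
    double phi = 0.0;
    for (int k = 0; k < N; ++k) {
      if (k == j) continue;
      double qk = qcfg[cfg[k]];
      if (qk == 0) continue;
      double dx = ax[j] - ax[k], dy = ay[j] - ay[k], dz = az[j] - az[k];
      phi += qk / std::sqrt(dx * dx + dy * dy + dz * dz + soft2);
    }
    int m = ex.size();
    for (int k = 0; k < m; ++k) {
      double dx = ax[j] - ex[k], dy = ay[j] - ey[k], dz = az[j] - ez[k];
      phi += -1.0 / std::sqrt(dx * dx + dy * dy + dz * dz + soft2);
    }
    return phi;
  };

  auto spawn_electron = [&](int atom, double ke_ev) {
    double u1 = unif_rand(), u2 = unif_rand();
    double ct = 2.0 * u1 - 1.0, st = std::sqrt(1.0 - ct * ct);
    double ph = 2.0 * M_PI * u2;
    double dxu = st * std::cos(ph), dyu = st * std::sin(ph), dzu = ct;
    double off = 0.2; // bohr birth offset
    // ke_ev is the asymptotic energy (the binding energy already accounts
    // for the ion's attraction); compensate the classical local well at
    // the birth point and launch outward so the electron leaves with the
    // nominal energy instead of being spuriously re-bound
    double q_here = qcfg[cfg[atom]];
    double ke_local = std::max(ke_ev, 0.0) +
      AU_EV * std::max(q_here, 0.0) / std::sqrt(off * off + soft2);
    double v = std::sqrt(2.0 * ke_local / AU_EV);
    ex.push_back(ax[atom] + off * dxu);
    ey.push_back(ay[atom] + off * dyu);
    ez.push_back(az[atom] + off * dzu);
    evx.push_back(avx[atom] + v * dxu);
    evy.push_back(avy[atom] + v * dyu);
    evz.push_back(avz[atom] + v * dzu);
    int i = ex.size() - 1;
    if ((int)last_ei.size() < i + 1) last_ei.resize(i + 1, -1);
    last_ei[i] = -1;
    injected += 0.5 * v * v + particle_pe(true, i);
  };

  auto remove_electron = [&](int i) {
    double v2 = evx[i] * evx[i] + evy[i] * evy[i] + evz[i] * evz[i];
    removed += 0.5 * v2 + particle_pe(true, i);
    int m = ex.size() - 1;
    ex[i] = ex[m]; ey[i] = ey[m]; ez[i] = ez[m];
    evx[i] = evx[m]; evy[i] = evy[m]; evz[i] = evz[m];
    ex.pop_back(); ey.pop_back(); ez.pop_back();
    evx.pop_back(); evy.pop_back(); evz.pop_back();
    if (i < (int)last_ei.size() && m < (int)last_ei.size()) {
      last_ei[i] = last_ei[m];
    }
  };

  int status = 0;
  std::vector<int> need;

  while (t_now < t_end - 1e-9) {
    // all present configurations must have built tables
    for (int i = 0; i < N; ++i) {
      if (!ready[cfg[i]]) need.push_back(cfg[i] + 1);
    }
    if (!need.empty()) { status = 1; break; }

    double t_fs_now = t_now / FS_AU;
    double flux = 0.0;
    if (F_ph_nm2 > 0) {
      double arg = t_fs_now / tau_fs;
      flux = F_ph_nm2 * (2.0 / tau_fs) * std::sqrt(M_LN2 / M_PI) *
        std::exp(-4.0 * M_LN2 * arg * arg);
    }

    std::fill(moved.begin(), moved.end(), 0);
    int m = ex.size();
    // --- MD step: position (Stoermer) Verlet, one fresh force
    // evaluation per step; symplectic and independent of chunk history ---
    if (motion) {
      px.assign(ex.begin(), ex.end());
      py.assign(ey.begin(), ey.end());
      pz.assign(ez.begin(), ez.end());
      for (int i = 0; i < N; ++i) {
        ax[i] += avx[i] * 0.5 * dt; ay[i] += avy[i] * 0.5 * dt;
        az[i] += avz[i] * 0.5 * dt;
      }
      for (int i = 0; i < m; ++i) {
        ex[i] += evx[i] * 0.5 * dt; ey[i] += evy[i] * 0.5 * dt;
        ez[i] += evz[i] * 0.5 * dt;
      }
      compute_forces();
      for (int i = 0; i < N; ++i) {
        double im = dt / amass[i];
        avx[i] += im * fax[i]; avy[i] += im * fay[i]; avz[i] += im * faz[i];
        ax[i] += avx[i] * 0.5 * dt; ay[i] += avy[i] * 0.5 * dt;
        az[i] += avz[i] * 0.5 * dt;
        if (!R_finite(ax[i]) || !R_finite(avx[i]))
          stop("NaN position/velocity for atom %d at t = %f fs", i + 1, t_fs_now);
      }
      for (int i = 0; i < m; ++i) {
        evx[i] += dt * fex[i]; evy[i] += dt * fey[i]; evz[i] += dt * fez[i];
        ex[i] += evx[i] * 0.5 * dt; ey[i] += evy[i] * 0.5 * dt;
        ez[i] += evz[i] * 0.5 * dt;
      }
    }

    t_now += dt;
    t_fs_now = t_now / FS_AU;

    // --- Monte-Carlo electronic transitions ---
    if (damage) {
      for (int i = 0; i < N; ++i) {
        int c = cfg[i];
        double rtot = aug_rate[c] + fl_rate[c];
        if (flux > 0) {
          for (int k = 0; k < NPH; ++k) rtot += photo_sig(c, k) * flux;
          for (int k = 0; k < NRES; ++k) rtot += res_sig(c, k) * flux;
        }
        if (rtot <= 0) continue;
        double p = rtot * dt_fs;
        if (p > 0.25)
          stop("per-step transition probability %f too large; reduce dt", p);
        if (unif_rand() >= p) continue;
        // pick channel
        double u = unif_rand() * rtot;
        double accum = 0.0;
        int done = 0;
        if (flux > 0) {
          for (int k = 0; k < NPH && !done; ++k) {
            accum += photo_sig(c, k) * flux;
            if (u < accum) {
              int tg = photo_tgt(c, k) - 1;
              log.add(t_fs_now, i + 1, 1, c + 1, tg + 1);
              cfg[i] = tg;
              moved[i] = 1;
              injected += (qcfg[tg] - qcfg[c]) * site_potential(i);
              spawn_electron(i, photo_ke(c, k));
              done = 1;
            }
          }
          for (int k = 0; k < NRES && !done; ++k) {
            accum += res_sig(c, k) * flux;
            if (u < accum) {
              int tg = res_tgt(c, k) - 1;
              log.add(t_fs_now, i + 1, 4, c + 1, tg + 1);
              cfg[i] = tg;
              moved[i] = 1;
              done = 1;
            }
          }
        }
        if (!done && aug_rate[c] > 0) {
          accum += aug_rate[c];
          if (u < accum) {
            int tg = aug_tgt[c] - 1;
            log.add(t_fs_now, i + 1, 2, c + 1, tg + 1);
            cfg[i] = tg;
            moved[i] = 1;
            injected += (qcfg[tg] - qcfg[c]) * site_potential(i);
            spawn_electron(i, aug_ke[c]);
            done = 1;
          }
        }
        if (!done && fl_rate[c] > 0) {
          int tg = fl_tgt[c] - 1;
          log.add(t_fs_now, i + 1, 3, c + 1, tg + 1);
          cfg[i] = tg;
          moved[i] = 1;
          done = 1;
        }
      }
    }

    // --- electron-impact ionization (closest-approach criterion) ---
    if (damage && do_ei && motion) {
      int mm = ex.size();
      int m0 = std::min<int>(mm, px.size());
      for (int i = 0; i < m0; ++i) {
        double vx = ex[i] - px[i], vy = ey[i] - py[i], vz = ez[i] - pz[i];
        double seg2 = vx * vx + vy * vy + vz * vz;
        if (seg2 <= 0) continue;
        double ke_ev = 0.5 * (evx[i] * evx[i] + evy[i] * evy[i] +
                              evz[i] * evz[i]) * AU_EV;
        // spare energy: only net-unbound electrons ionize - the energy a
        // trapped electron carries locally is owed to the cluster well
        double e_avail = ke_ev +
          ((i < (int)pee.size()) ? pee[i] * AU_EV : 0.0);
        if (e_avail < 10.0) continue;  // below every ionization threshold
        double reach = std::sqrt(seg2) + 3.0;  // segment + impact margin
        for (int j = 0; j < N; ++j) {
          if (moved[j]) continue;
          int c = cfg[j];
          if (ei_tgt[c] <= 0) continue;
          if (e_avail <= ei_bind[c]) continue;
          double wx = ax[j] - px[i], wy = ay[j] - py[i], wz = az[j] - pz[i];
          if (std::fabs(wx) > reach || std::fabs(wy) > reach ||
              std::fabs(wz) > reach) continue;
          double s = (wx * vx + wy * vy + wz * vz) / seg2;
          if (s < 0) s = 0; if (s > 1) s = 1;
          double dx = wx - s * vx, dy = wy - s * vy, dz = wz - s * vz;
          double d2 = dx * dx + dy * dy + dz * dz;
          double bb[8]; int oo[8];
          for (int q = 0; q < NSUB; ++q) { bb[q] = bind_ev(c, q); oo[q] = occm(c, q); }
          double sig = lotz_sigma_nm2(bb, oo, NSUB, e_avail);
          double b2max = (sig / M_PI) / (BOHR_NM * BOHR_NM);
          if (i < (int)last_ei.size() && last_ei[i] == j) {
            // one collision, one chance: re-arm only after leaving the
            // interaction disc of this atom
            if (d2 > 9.0 * b2max) last_ei[i] = -1; else continue;
          }
          if (d2 < b2max) {
            int tg = ei_tgt[c] - 1;
            log.add(t_fs_now, j + 1, 5, c + 1, tg + 1);
            cfg[j] = tg;
            moved[j] = 1;
            injected += (qcfg[tg] - qcfg[c]) * site_potential(j);
            // projectile loses the binding energy
            double ke_new = std::max(ke_ev - ei_bind[c], 0.1);
            double scale = std::sqrt(ke_new / ke_ev);
            removed += (ke_ev - ke_new) / AU_EV;  // audit: energy to binding
            evx[i] *= scale; evy[i] *= scale; evz[i] *= scale;
            if (i < (int)last_ei.size()) last_ei[i] = j;
            spawn_electron(j, 0.05);
            break;
          }
        }
      }
    }

    // --- recombination (classical capture into an available vacancy) ---
    if (damage && do_rc && motion) {
      for (int i = (int)ex.size() - 1; i >= 0; --i) {
        for (int j = 0; j < N; ++j) {
          if (moved[j]) continue;
          int c = cfg[j];
          double qj = qcfg[c];
          if (qj <= 0) continue;
          if (rc_tgt[c] <= 0) continue;
          double dx = ex[i] - ax[j];
          if (std::fabs(dx) > r_cap) continue;
          double dy = ey[i] - ay[j], dz = ez[i] - az[j];
          if (std::fabs(dy) > r_cap || std::fabs(dz) > r_cap) continue;
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 > r_cap * r_cap) continue;
          double rvx = evx[i] - avx[j], rvy = evy[i] - avy[j],
                 rvz = evz[i] - avz[j];
          double erel = 0.5 * (rvx * rvx + rvy * rvy + rvz * rvz) -
            qj / std::sqrt(d2 + soft2);
          if (erel >= 0) continue;
          log.add(t_fs_now, j + 1, 6, c + 1, rc_tgt[c]);
          remove_electron(i);
          cfg[j] = rc_tgt[c] - 1;
          moved[j] = 1;
          injected += (qcfg[cfg[j]] - qcfg[c]) * site_potential(j);
          break;
        }
      }
    }

    // --- electron escape from the interaction region ---
    if (motion) {
      double Qtot = 0.0;
      for (int i = 0; i < N; ++i) Qtot += qcfg[cfg[i]];
      Qtot -= (double)ex.size();
      for (int i = (int)ex.size() - 1; i >= 0; --i) {
        double r2 = ex[i] * ex[i] + ey[i] * ey[i] + ez[i] * ez[i];
        if (r2 < r_int * r_int) continue;
        double ke = 0.5 * (evx[i] * evx[i] + evy[i] * evy[i] +
                           evz[i] * evz[i]);
        double pot = (Qtot + 1.0) > 0 ? -(Qtot + 1.0) / std::sqrt(r2) : 0.0;
        if (ke + pot > 0) {
          log.add(t_fs_now, 0, 7, 0, 0);
          remove_electron(i);
          ++escaped;
        }
      }
    }

    // --- snapshot ---
    if (t_now >= next_snap - 1e-9) {
      snap_t.push_back(t_fs_now);
      snap_ne.push_back(ex.size());
      snap_esc.push_back(escaped);
      for (int i = 0; i < N; ++i) {
        snap_pos.push_back(ax[i]); snap_pos.push_back(ay[i]);
        snap_pos.push_back(az[i]);
        snap_cfg.push_back(cfg[i] + 1);
      }
      next_snap += snap_every;
    }
  }

  // repackage state
  NumericMatrix apos(N, 3), avel(N, 3);
  IntegerVector acfg(N);
  for (int i = 0; i < N; ++i) {
    apos(i, 0) = ax[i]; apos(i, 1) = ay[i]; apos(i, 2) = az[i];
    avel(i, 0) = avx[i]; avel(i, 1) = avy[i]; avel(i, 2) = avz[i];
    acfg[i] = cfg[i] + 1;
  }
  int mf = ex.size();
  NumericMatrix epos(mf, 3), evel(mf, 3);
  for (int i = 0; i < mf; ++i) {
    epos(i, 0) = ex[i]; epos(i, 1) = ey[i]; epos(i, 2) = ez[i];
    evel(i, 0) = evx[i]; evel(i, 1) = evy[i]; evel(i, 2) = evz[i];
  }
  int ns = snap_t.size();
  NumericMatrix spos(ns * N, 3);
  IntegerVector scfg(ns * N);
  for (int k = 0; k < ns * N; ++k) {
    spos(k, 0) = snap_pos[3 * k]; spos(k, 1) = snap_pos[3 * k + 1];
    spos(k, 2) = snap_pos[3 * k + 2];
    scfg[k] = snap_cfg[k];
  }
  return List::create(
    _["status"] = status,
    _["need"] = IntegerVector(need.begin(), need.end()),
    _["t_now"] = t_now, _["next_snap"] = next_snap,
    _["apos"] = apos, _["avel"] = avel, _["acfg"] = acfg,
    _["epos"] = epos, _["evel"] = evel,
    _["escaped"] = escaped,
    _["injected"] = injected, _["removed"] = removed,
    _["snap_t"] = NumericVector(snap_t.begin(), snap_t.end()),
    _["snap_ne"] = IntegerVector(snap_ne.begin(), snap_ne.end()),
    _["snap_esc"] = IntegerVector(snap_esc.begin(), snap_esc.end()),
    _["snap_pos"] = spos, _["snap_cfg"] = scfg,
    _["last_ei"] = IntegerVector(last_ei.begin(),
                                 last_ei.begin() + ex.size()),
    _["ev_t"] = NumericVector(log.t_fs.begin(), log.t_fs.end()),
    _["ev_atom"] = IntegerVector(log.atom.begin(), log.atom.end()),
    _["ev_type"] = IntegerVector(log.type.begin(), log.type.end()),
    _["ev_from"] = IntegerVector(log.from.begin(), log.from.end()),
    _["ev_to"] = IntegerVector(log.to.begin(), log.to.end()));
}

// Total kinetic + pair potential energy of a state (audit helper).
// [[Rcpp::export]]
List cpp_state_energy(NumericMatrix apos, NumericMatrix avel,
                      NumericVector amass, IntegerVector charge,
                      NumericMatrix epos, NumericMatrix evel,
                      double soft2) {
  int N = apos.nrow(), M = epos.nrow();
  double ke = 0, pe = 0;
  for (int i = 0; i < N; ++i) {
    ke += 0.5 * amass[i] * (avel(i, 0) * avel(i, 0) +
                            avel(i, 1) * avel(i, 1) +
                            avel(i, 2) * avel(i, 2));
    for (int j = i + 1; j < N; ++j) {
      if (charge[i] == 0 || charge[j] == 0) continue;
      double dx = apos(i, 0) - apos(j, 0), dy = apos(i, 1) - apos(j, 1),
             dz = apos(i, 2) - apos(j, 2);
      pe += charge[i] * charge[j] /
        std::sqrt(dx * dx + dy * dy + dz * dz + soft2);
    }
  }
  for (int i = 0; i < M; ++i) {
    ke += 0.5 * (evel(i, 0) * evel(i, 0) + evel(i, 1) * evel(i, 1) +
                 evel(i, 2) * evel(i, 2));
    for (int j = 0; j < N; ++j) {
      if (charge[j] == 0) continue;
      double dx = epos(i, 0) - apos(j, 0), dy = epos(i, 1) - apos(j, 1),
             dz = epos(i, 2) - apos(j, 2);
      pe += -charge[j] / std::sqrt(dx * dx + dy * dy + dz * dz + soft2);
    }
    for (int k = i + 1; k < M; ++k) {
      double dx = epos(i, 0) - epos(k, 0), dy = epos(i, 1) - epos(k, 1),
             dz = epos(i, 2) - epos(k, 2);
      pe += 1.0 / std::sqrt(dx * dx + dy * dy + dz * dz + soft2);
    }
  }
  return List::create(_["kinetic"] = ke, _["potential"] = pe,
                      _["total"] = ke + pe);
}
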