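// Leave-one-out cross-validation for the linear soft-margin C-SVM.
//
// Solves the standard C-SVC dual (equality constraint sum alpha_i y_i = 0,
// box 0 <= alpha <= C) by SMO with maximal-violating-pair working-set
// selection and LIBSVM's stopping rule (max violation < eps) and bias
// computation, so the fitted machine is the same model e1071/LIBSVM fits.
// What makes it fast for swarm search workloads:
//   * the full kernel matrix over all samples is computed once per mask;
//   * each leave-one-out fold warm-starts from the full-data solution
//     with the held-out point's weight redistributed, so folds converge
//     in a handful of iterations;
//   * one-versus-one machines not involving the held-out sample's class
//     are reused unchanged (their training set does not contain it).
// Route equivalence with e1071 is pinned by the package's tests.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct PairProblem {
  std::vector<int> idx;   // sample indices (0-based, into the full data)
  std::vector<int> ylab;  // +1 for the first class of the pair, -1 for the second
  std::vector<double> alpha;
  double rho;
  bool hard;              // SMO hit its iteration cap; use the IPM directly
};

// LIBSVM's calculate_rho on a gradient vector.
double rho_from_gradient(const std::vector<double>& G,
                         const std::vector<int>& y,
                         const std::vector<double>& alpha, double C) {
  const int l = (int) G.size();
  double ub = HUGE_VAL, lb = -HUGE_VAL, sum_free = 0.0;
  int n_free = 0;
  for (int t = 0; t < l; ++t) {
    const double yG = y[t] * G[t];
    if (alpha[t] >= C) {
      if (y[t] < 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 0) {
      if (y[t] > 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      ++n_free;
      sum_free += yG;
    }
  }
  return n_free > 0 ? sum_free / n_free : (ub + lb) / 2.0;
}

// Primal-dual interior-point solver for the same C-SVC dual:
//   min 1/2 a' Q a - 1'a,  y'a = 0,  0 <= a <= C,  Q = Z Z' low rank.
// Mehrotra predictor-corrector; the normal matrix (Q + D) is inverted
// through the Woodbury identity on the k x k core, so each iteration is
// O(l k^2). Iteration counts are small and insensitive to C, which makes
// this the robust fallback when SMO zigzags on heavily overlapping data.
// Z holds y_i * x_i rows for the active samples (l x k, row-major).
double ipm_solve(const std::vector<double>& Z, int l, int k,
                 const std::vector<int>& y, double C,
                 std::vector<double>& alpha) {
  std::vector<double> a(l, 0.5 * C), z(l, 1.0), w(l, 1.0);
  double nu = 0.0;
  std::vector<double> q(l), r1(l), dinv(l), t1(l), t2(l), da(l), dz(l), dw(l);
  std::vector<double> core((size_t) k * k), zty(k), ztr(k), sol(k);
  std::vector<double> v1(l), v2(l), rza(l), rwu(l);

  const int max_ipm = 80;
  for (int iter = 0; iter < max_ipm; ++iter) {
    // Qa = Z (Z' a)
    std::vector<double> zta(k, 0.0);
    for (int i = 0; i < l; ++i) {
      const double* Zi = &Z[(size_t) i * k];
      for (int d = 0; d < k; ++d) zta[d] += Zi[d] * a[i];
    }
    double mu = 0.0, rp = 0.0, rd_norm = 0.0;
    for (int i = 0; i < l; ++i) {
      const double* Zi = &Z[(size_t) i * k];
      double Qa = 0.0;
      for (int d = 0; d < k; ++d) Qa += Zi[d] * zta[d];
      q[i] = Qa;
      mu += a[i] * z[i] + (C - a[i]) * w[i];
    }
    mu /= 2.0 * l;
    for (int i = 0; i < l; ++i) rp += y[i] * a[i];
    // dual residual: Qa - 1 + nu*y - z + w
    for (int i = 0; i < l; ++i) {
      const double rd = q[i] - 1.0 + nu * y[i] - z[i] + w[i];
      r1[i] = -rd;
      rd_norm = std::max(rd_norm, std::fabs(rd));
    }
    const double scale = 1.0 + C;
    if (mu < 1e-9 * scale && std::fabs(rp) < 1e-9 * scale &&
        rd_norm < 1e-7 * scale) {
      break;
    }

    // two passes: affine predictor, then corrector with centering
    double sigma_mu = 0.0;
    for (int pass = 0; pass < 2; ++pass) {
      for (int i = 0; i < l; ++i) {
        if (pass == 0) {
          rza[i] = -a[i] * z[i];
          rwu[i] = -(C - a[i]) * w[i];
        } else {
          rza[i] = -a[i] * z[i] + sigma_mu - da[i] * dz[i];
          rwu[i] = -(C - a[i]) * w[i] + sigma_mu + da[i] * dw[i];
        }
        dinv[i] = 1.0 / (z[i] / a[i] + w[i] / (C - a[i]));
        // rhs for the reduced system in da
        t1[i] = r1[i] + rza[i] / a[i] - rwu[i] / (C - a[i]);
      }
      // solve (Q + D) da + y dnu = t1,  y'da = -rp via Woodbury
      // core = I_k + Z' Dinv Z
      std::fill(core.begin(), core.end(), 0.0);
      std::fill(zty.begin(), zty.end(), 0.0);
      std::fill(ztr.begin(), ztr.end(), 0.0);
      for (int i = 0; i < l; ++i) {
        const double* Zi = &Z[(size_t) i * k];
        const double di = dinv[i];
        for (int d = 0; d < k; ++d) {
          const double zd = Zi[d] * di;
          ztr[d] += zd * t1[i];
          zty[d] += zd * y[i];
          for (int e = d; e < k; ++e) core[(size_t) d * k + e] += zd * Zi[e];
        }
      }
      for (int d = 0; d < k; ++d) core[(size_t) d * k + d] += 1.0;
      // Cholesky of core (upper triangle filled)
      for (int d = 0; d < k; ++d) {
        for (int e = d; e < k; ++e) {
          double s = core[(size_t) d * k + e];
          for (int p = 0; p < d; ++p) {
            s -= core[(size_t) p * k + d] * core[(size_t) p * k + e];
          }
          if (e == d) {
            core[(size_t) d * k + d] = std::sqrt(std::max(s, 1e-300));
          } else {
            core[(size_t) d * k + e] = s / core[(size_t) d * k + d];
          }
        }
      }
      // Minv * v = Dinv v - Dinv Z core^-1 Z' Dinv v, for v = t1 and y
      // (chol solve on the k-vector)
      // helper lambda-free: compute for rhs in kvec -> sol
      // first for t1
      for (int rhs = 0; rhs < 2; ++rhs) {
        std::vector<double>& kv = rhs == 0 ? ztr : zty;
        for (int d = 0; d < k; ++d) {
          double s = kv[d];
          for (int p = 0; p < d; ++p) s -= core[(size_t) p * k + d] * sol[p];
          sol[d] = s / core[(size_t) d * k + d];
        }
        for (int d = k - 1; d >= 0; --d) {
          double s = sol[d];
          for (int p = d + 1; p < k; ++p) s -= core[(size_t) d * k + p] * sol[p];
          sol[d] = s / core[(size_t) d * k + d];
        }
        for (int i = 0; i < l; ++i) {
          const double* Zi = &Z[(size_t) i * k];
          double zz = 0.0;
          for (int d = 0; d < k; ++d) zz += Zi[d] * sol[d];
          const double base = rhs == 0 ? t1[i] : y[i];
          (rhs == 0 ? v1 : v2)[i] = dinv[i] * (base - zz);
        }
      }
      double yv1 = 0.0, yv2 = 0.0;
      for (int i = 0; i < l; ++i) {
        yv1 += y[i] * v1[i];
        yv2 += y[i] * v2[i];
      }
      const double dnu = (yv1 + rp) / std::max(yv2, 1e-300);
      double ap = 1.0, ad = 1.0;
      for (int i = 0; i < l; ++i) {
        da[i] = v1[i] - dnu * v2[i];
        dz[i] = (rza[i] - z[i] * da[i]) / a[i];
        dw[i] = (rwu[i] + w[i] * da[i]) / (C - a[i]);
        if (da[i] < 0) ap = std::min(ap, -a[i] / da[i]);
        if (da[i] > 0) ap = std::min(ap, (C - a[i]) / da[i]);
        if (dz[i] < 0) ad = std::min(ad, -z[i] / dz[i]);
        if (dw[i] < 0) ad = std::min(ad, -w[i] / dw[i]);
      }
      if (pass == 0) {
        // Mehrotra centering from the affine step
        double mu_aff = 0.0;
        const double tp = std::min(1.0, 0.995 * ap);
        const double td = std::min(1.0, 0.995 * ad);
        for (int i = 0; i < l; ++i) {
          mu_aff += (a[i] + tp * da[i]) * (z[i] + td * dz[i]) +
                    (C - a[i] - tp * da[i]) * (w[i] + td * dw[i]);
        }
        mu_aff /= 2.0 * l;
        const double ratio = mu_aff / std::max(mu, 1e-300);
        sigma_mu = ratio * ratio * ratio * mu;
      } else {
        const double tp = std::min(1.0, 0.995 * ap);
        const double td = std::min(1.0, 0.995 * ad);
        for (int i = 0; i < l; ++i) {
          a[i] += tp * da[i];
          z[i] += td * dz[i];
          w[i] += td * dw[i];
        }
        nu += td * dnu;
      }
    }
  }
  alpha = a;
  // clean tiny residuals so downstream bound tests see exact 0 / C
  for (int i = 0; i < l; ++i) {
    if (alpha[i] < 1e-7 * C) alpha[i] = 0.0;
    if (alpha[i] > C * (1.0 - 1e-7)) alpha[i] = C;
  }
  return nu;  // caller recomputes rho with the LIBSVM rule
}

// SMO on an active subset. K is the full N x N kernel, row-major.
// alpha enters as a feasible warm start and leaves optimal. Returns rho.
double smo_solve(const std::vector<double>& K, int n_all,
                 const std::vector<int>& idx, const std::vector<int>& y,
                 double C, double eps, int max_iter,
                 std::vector<double>& alpha, bool* converged) {
  const int l = (int) idx.size();
  std::vector<double> G(l, -1.0);
  for (int i = 0; i < l; ++i) {
    double g = -1.0;
    const double* Ki = &K[(size_t) idx[i] * n_all];
    for (int j = 0; j < l; ++j) {
      if (alpha[j] != 0.0) {
        g += y[i] * y[j] * Ki[idx[j]] * alpha[j];
      }
    }
    G[i] = g;
  }
  *converged = false;
  for (int iter = 0; iter < max_iter; ++iter) {
    // second-order working-set selection as in LIBSVM: i maximizes the
    // violation over I_up, j minimizes the quadratic objective gain
    // among violating members of I_low
    double gmax = -HUGE_VAL, gmax2 = -HUGE_VAL;
    int ii = -1;
    for (int t = 0; t < l; ++t) {
      const double v = -y[t] * G[t];
      if (((y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0)) &&
          v > gmax) {
        gmax = v; ii = t;
      }
    }
    int jj = -1;
    double obj_min = HUGE_VAL;
    if (ii >= 0) {
      const double* Kii_row = &K[(size_t) idx[ii] * n_all];
      const double Kii_d = Kii_row[idx[ii]];
      for (int t = 0; t < l; ++t) {
        if ((y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C)) {
          const double yG = y[t] * G[t];
          if (yG > gmax2) gmax2 = yG;
          const double b = gmax + yG;
          if (b > 0) {
            double a = Kii_d + K[(size_t) idx[t] * n_all + idx[t]] -
              2.0 * y[ii] * y[t] * Kii_row[idx[t]];
            if (a <= 0) a = 1e-12;
            const double obj = -(b * b) / a;
            if (obj < obj_min) { obj_min = obj; jj = t; }
          }
        }
      }
    }
    if (ii < 0 || jj < 0 || gmax + gmax2 < eps) {
      *converged = true;
      break;
    }

    const int i = ii, j = jj;
    const double Kii = K[(size_t) idx[i] * n_all + idx[i]];
    const double Kjj = K[(size_t) idx[j] * n_all + idx[j]];
    const double Kij = K[(size_t) idx[i] * n_all + idx[j]];
    const double old_ai = alpha[i], old_aj = alpha[j];

    if (y[i] != y[j]) {
      double quad = Kii + Kjj + 2.0 * Kij;
      if (quad <= 0) quad = 1e-12;
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = Kii + Kjj - 2.0 * Kij;
      if (quad <= 0) quad = 1e-12;
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    const double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai == 0.0 && daj == 0.0) { *converged = true; break; }  // stuck
    const double* Ki = &K[(size_t) idx[i] * n_all];
    const double* Kj = &K[(size_t) idx[j] * n_all];
    for (int t = 0; t < l; ++t) {
      G[t] += y[t] * (y[i] * Ki[idx[t]] * dai + y[j] * Kj[idx[t]] * daj);
    }
  }

  return rho_from_gradient(G, y, alpha, C);
}

// Solve one pair machine: SMO first (capped), interior point as the
// fallback for SMO-pathological problems; both solve the same QP, so the
// switch is purely about speed. `direct_ipm` skips the SMO attempt for
// machines already known to be pathological.
const int SMO_CAP = 6000;
double solve_machine(const std::vector<double>& K, const NumericMatrix& x,
                     int n_all, const std::vector<int>& idx,
                     const std::vector<int>& y, double C, double eps,
                     bool direct_ipm, bool* used_ipm,
                     std::vector<double>& alpha) {
  if (!direct_ipm) {
    bool conv = false;
    const double rho = smo_solve(K, n_all, idx, y, C, eps, SMO_CAP, alpha,
                                 &conv);
    if (conv) {
      *used_ipm = false;
      return rho;
    }
  }
  *used_ipm = true;
  const int l = (int) idx.size(), k = x.ncol();
  std::vector<double> Z((size_t) l * k);
  for (int i = 0; i < l; ++i) {
    for (int d = 0; d < k; ++d) {
      Z[(size_t) i * k + d] = y[i] * x(idx[i], d);
    }
  }
  ipm_solve(Z, l, k, y, C, alpha);
  std::vector<double> zta(k, 0.0), G(l);
  for (int i = 0; i < l; ++i) {
    for (int d = 0; d < k; ++d) zta[d] += Z[(size_t) i * k + d] * alpha[i];
  }
  for (int i = 0; i < l; ++i) {
    double g = -1.0;
    for (int d = 0; d < k; ++d) g += Z[(size_t) i * k + d] * zta[d];
    G[i] = g;
  }
  return rho_from_gradient(G, y, alpha, C);
}

double decision_value(const std::vector<double>& K, int n_all,
                      const PairProblem& p, int sample) {
  double f = 0.0;
  for (size_t t = 0; t < p.idx.size(); ++t) {
    if (p.alpha[t] != 0.0) {
      f += p.alpha[t] * p.ylab[t] * K[(size_t) p.idx[t] * n_all + sample];
    }
  }
  return f - p.rho;
}

}  // namespace

//' @name loocv_linear_svm_cpp
//' @title Compiled leave-one-out evaluation of a linear C-SVM
//' @description Internal workhorse behind the default evaluation route of
//'   [loocv_accuracy()]; see that function for the user-facing contract.
//' @param x numeric matrix (samples x selected genes)
//' @param y integer class codes 1..n_classes, ordered by first appearance
//' @param n_classes number of classes
//' @param cost SVM penalty parameter C
//' @param eps SMO stopping tolerance
//' @param max_iter iteration cap per solve
//' @return leave-one-out accuracy as a fraction
//' @keywords internal
// [[Rcpp::export]]
double loocv_linear_svm_cpp(NumericMatrix x, IntegerVector y, int n_classes,
                            double cost, double eps, int max_iter) {
  const int N = x.nrow(), k = x.ncol();
  if (N < 2) stop("need at least two samples");

  // full linear kernel, row-major
  std::vector<double> K((size_t) N * N);
  for (int i = 0; i < N; ++i) {
    for (int j = i; j < N; ++j) {
      double s = 0.0;
      for (int d = 0; d < k; ++d) s += x(i, d) * x(j, d);
      K[(size_t) i * N + j] = s;
      K[(size_t) j * N + i] = s;
    }
  }

  // one-versus-one machines on the full data
  std::vector<PairProblem> pairs;
  std::vector<std::pair<int, int> > pair_classes;
  for (int a = 1; a <= n_classes; ++a) {
    for (int b = a + 1; b <= n_classes; ++b) {
      PairProblem p;
      for (int i = 0; i < N; ++i) {
        if (y[i] == a || y[i] == b) {
          p.idx.push_back(i);
          p.ylab.push_back(y[i] == a ? 1 : -1);
        }
      }
      p.alpha.assign(p.idx.size(), 0.0);
      bool used_ipm = false;
      p.rho = solve_machine(K, x, N, p.idx, p.ylab, cost, eps, false,
                            &used_ipm, p.alpha);
      p.hard = used_ipm;
      pairs.push_back(p);
      pair_classes.push_back(std::make_pair(a, b));
    }
  }

  int correct = 0;
  std::vector<int> votes(n_classes + 1);
  for (int h = 0; h < N; ++h) {
    std::fill(votes.begin(), votes.end(), 0);
    for (size_t pi = 0; pi < pairs.size(); ++pi) {
      const int a = pair_classes[pi].first, b = pair_classes[pi].second;
      double f;
      if (y[h] != a && y[h] != b) {
        // machine never sees sample h: full solution applies unchanged
        f = decision_value(K, N, pairs[pi], h);
      } else {
        const PairProblem& full = pairs[pi];
        PairProblem sub;
        double removed = 0.0;
        int removed_y = 0;
        bool in_training = false;
        for (size_t t = 0; t < full.idx.size(); ++t) {
          if (full.idx[t] == h) {
            removed = full.alpha[t];
            removed_y = full.ylab[t];
            in_training = true;
          } else {
            sub.idx.push_back(full.idx[t]);
            sub.ylab.push_back(full.ylab[t]);
            sub.alpha.push_back(full.alpha[t]);
          }
        }
        if (in_training && removed == 0.0) {
          // held-out point has zero dual weight: the fold solution equals
          // the full solution and the point sits outside the margin on
          // its own side, so this machine classifies it correctly
          ++votes[removed_y > 0 ? a : b];
          continue;
        }
        bool has_pos = false, has_neg = false;
        for (size_t t = 0; t < sub.idx.size(); ++t) {
          if (sub.ylab[t] > 0) has_pos = true; else has_neg = true;
        }
        if (!has_pos || !has_neg) {
          // training fold has one class: predict it
          ++votes[has_pos ? a : b];
          continue;
        }
        if (removed > 0.0) {
          // restore the equality constraint by shrinking weights on the
          // opposite side of the removed point (total mass suffices:
          // both sides sum to the same value)
          double need = removed;
          for (size_t t = 0; t < sub.idx.size() && need > 0.0; ++t) {
            if (sub.ylab[t] != removed_y && sub.alpha[t] > 0.0) {
              const double take = std::min(sub.alpha[t], need);
              sub.alpha[t] -= take;
              need -= take;
            }
          }
        }
        bool used_ipm = false;
        sub.rho = solve_machine(K, x, N, sub.idx, sub.ylab, cost, eps,
                                full.hard, &used_ipm, sub.alpha);
        f = decision_value(K, N, sub, h);
      }
      ++votes[f > 0 ? a : b];
    }
    int best = 1;
    for (int c = 2; c <= n_classes; ++c) {
      if (votes[c] > votes[best]) best = c;  // ties keep the smaller code
    }
    if (best == y[h]) ++correct;
  }
  return (double) correct / N;
}
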