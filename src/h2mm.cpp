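// Photon-by-photon hidden Markov machinery with arrival-time-dependent
// transition operators.  The hidden chain steps once per clock tick; between
// consecutive photons separated by d ticks the transition operator is A^d.
// A^d and the segment eigen-sums are built from one eigendecomposition of A
// per EM iteration and cached per distinct gap d, which keeps the per-photon
// cost at O(K^2).

#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct EigOp {
  cx_mat V, Vinv;
  cx_vec lam;
  mat A;
  bool ok = false;

  void init(const mat& A_) {
    A = A_;
    cx_vec eigval;
    cx_mat eigvec;
    ok = eig_gen(eigval, eigvec, A);
    if (ok) {
      lam = eigval;
      V = eigvec;
      cx_mat Vi;
      ok = inv(Vi, V);
      if (ok) {
        Vinv = Vi;
        // reject near-defective decompositions
        double rc = rcond(conv_to<mat>::from(abs(V)));
        if (!(rc > 1e-12)) ok = false;
      }
    }
  }

  // A^d by eigendecomposition, or by binary powering as a fallback
  mat power(double d) const {
    if (ok) {
      cx_vec lp(lam.n_elem);
      for (uword i = 0; i < lam.n_elem; ++i) lp(i) = std::pow(lam(i), d);
      return real(V * diagmat(lp) * Vinv);
    }
    mat result = eye<mat>(A.n_rows, A.n_cols);
    mat base = A;
    long long n = (long long)d;
    while (n > 0) {
      if (n & 1) result = result * base;
      base = base * base;
      n >>= 1;
    }
    return result;
  }

  // F(a,b) = sum_{m=0}^{d-1} lam_a^m lam_b^{d-1-m}
  cx_mat fsum(double d) const {
    uword K = lam.n_elem;
    cx_mat F(K, K);
    cx_vec lp(K);
    for (uword i = 0; i < K; ++i) lp(i) = std::pow(lam(i), d);
    for (uword a = 0; a < K; ++a) {
      for (uword b = 0; b < K; ++b) {
        std::complex<double> da = lam(a) - lam(b);
        if (std::abs(da) < 1e-10) {
          std::complex<double> lm = 0.5 * (lam(a) + lam(b));
          F(a, b) = d * std::pow(lm, d - 1.0);
        } else {
          F(a, b) = (lp(a) - lp(b)) / da;
        }
      }
    }
    return F;
  }
};

struct OpCache {
  const EigOp* op;
  std::unordered_map<long long, mat> pow_cache;
  std::unordered_map<long long, cx_mat> fsum_cache;

  explicit OpCache(const EigOp* o) : op(o) {}

  const mat& power(double d) {
    long long key = (long long)d;
    auto it = pow_cache.find(key);
    if (it != pow_cache.end()) return it->second;
    return pow_cache.emplace(key, op->power(d)).first->second;
  }
  const cx_mat& fsum(double d) {
    long long key = (long long)d;
    auto it = fsum_cache.find(key);
    if (it != fsum_cache.end()) return it->second;
    return fsum_cache.emplace(key, op->fsum(d)).first->second;
  }
};

inline double clamp_dt(double d) { return d < 1.0 ? 1.0 : d; }

}  // namespace

// Forward-algorithm log-likelihood, summed over bursts.
// colors: 0-based color per photon; dt: tick gap to previous photon in the
// same burst (ignored for the first photon); ptr: 0-based burst offsets,
// length nb+1.
// [[Rcpp::export]]
double h2mm_loglik_cpp(const arma::vec& pi, const arma::mat& A,
                       const arma::mat& B, const arma::ivec& colors,
                       const arma::vec& dt, const arma::ivec& ptr) {
  EigOp op;
  op.init(A);
  OpCache cache(&op);
  double ll = 0.0;
  for (uword b = 0; b + 1 < ptr.n_elem; ++b) {
    long long lo = ptr(b), hi = ptr(b + 1);
    if (lo >= hi) continue;
    rowvec alpha = pi.t() % B.col(colors(lo)).t();
    double c = accu(alpha);
    if (c <= 0) return -datum::inf;
    alpha /= c;
    ll += std::log(c);
    for (long long k = lo + 1; k < hi; ++k) {
      const mat& T = cache.power(clamp_dt(dt(k)));
      alpha = (alpha * T) % B.col(colors(k)).t();
      c = accu(alpha);
      if (c <= 0) return -datum::inf;
      alpha /= c;
      ll += std::log(c);
    }
  }
  return ll;
}

// One full Baum-Welch EM run.  Returns the fitted model, the log-likelihood
// trace, and per-photon posteriors' summaries.
// [[Rcpp::export]]
Rcpp::List h2mm_em_cpp(const arma::vec& pi0, const arma::mat& A0,
                       const arma::mat& B0, const arma::ivec& colors,
                       const arma::vec& dt, const arma::ivec& ptr,
                       int max_iter, double tol) {
  const uword K = A0.n_rows;
  const uword C = B0.n_cols;
  const uword n = colors.n_elem;
  vec pi = pi0;
  mat A = A0, B = B0;
  std::vector<double> ll_trace;
  double ll_prev = -datum::inf;
  bool converged = false;
  int iter = 0;

  mat alpha_all(n, K, fill::zeros);
  vec cvec(n, fill::zeros);

  for (iter = 0; iter < max_iter; ++iter) {
    EigOp op;
    op.init(A);
    OpCache cache(&op);

    double ll = 0.0;
    // ---- forward pass (store scaled alpha and scales) ----
    for (uword b = 0; b + 1 < ptr.n_elem; ++b) {
      long long lo = ptr(b), hi = ptr(b + 1);
      if (lo >= hi) continue;
      rowvec alpha = pi.t() % B.col(colors(lo)).t();
      double c = accu(alpha);
      if (c <= 0) Rcpp::stop("zero forward probability (invalid model)");
      alpha /= c;
      alpha_all.row(lo) = alpha;
      cvec(lo) = c;
      ll += std::log(c);
      for (long long k = lo + 1; k < hi; ++k) {
        const mat& T = cache.power(clamp_dt(dt(k)));
        alpha = (alpha * T) % B.col(colors(k)).t();
        c = accu(alpha);
        if (c <= 0) Rcpp::stop("zero forward probability (invalid model)");
        alpha /= c;
        alpha_all.row(k) = alpha;
        cvec(k) = c;
        ll += std::log(c);
      }
    }
    ll_trace.push_back(ll);

    // ---- backward pass with accumulation ----
    vec pi_acc(K, fill::zeros);
    mat B_num(K, C, fill::zeros);
    cx_mat Y(K, K, fill::zeros);  // eigen-basis accumulated transition counts
    bool use_eig = op.ok;
    mat Xi_direct(K, K, fill::zeros);  // fallback accumulation

    for (uword b = 0; b + 1 < ptr.n_elem; ++b) {
      long long lo = ptr(b), hi = ptr(b + 1);
      if (lo >= hi) continue;
      vec bhat(K, fill::ones);
      for (long long k = hi - 1; k > lo; --k) {
        // gamma at photon k
        vec gam = alpha_all.row(k).t() % bhat;
        B_num.col(colors(k)) += gam;
        double d = clamp_dt(dt(k));
        vec w = B.col(colors(k)) % bhat;
        rowvec u = alpha_all.row(k - 1);
        double ck = cvec(k);
        if (use_eig) {
          cx_rowvec uV = conv_to<cx_rowvec>::from(u) * op.V;
          cx_vec Vw = op.Vinv * conv_to<cx_vec>::from(w);
          const cx_mat& F = cache.fsum(d);
          // Y += outer(uV, Vw) % F / ck
          for (uword a = 0; a < K; ++a)
            for (uword bb = 0; bb < K; ++bb)
              Y(a, bb) += uV(a) * Vw(bb) * F(a, bb) / ck;
        } else {
          // O(d) exact two-pass accumulation (rare: defective A)
          long long dd = (long long)d;
          std::vector<vec> right((size_t)dd);
          vec r = w;
          for (long long m = dd - 1; m >= 0; --m) {
            right[(size_t)m] = r;
            if (m > 0) r = A * r;
          }
          rowvec left = u;
          for (long long m = 0; m < dd; ++m) {
            for (uword i = 0; i < K; ++i)
              for (uword j = 0; j < K; ++j)
                Xi_direct(i, j) += left(i) * A(i, j) * right[(size_t)m](j) / ck;
            left = left * A;
          }
        }
        // update bhat to photon k-1
        const mat& T = cache.power(d);
        bhat = (T * w) / ck;
      }
      vec gam0 = alpha_all.row(lo).t() % bhat;
      B_num.col(colors(lo)) += gam0;
      pi_acc += gam0;
    }

    // ---- M-step ----
    mat Xi;
    if (use_eig) {
      Xi = A % real(op.Vinv.st() * Y * op.V.st());
    } else {
      Xi = Xi_direct;  // already A_ij-weighted in the fallback
    }
    Xi.transform([](double x) { return x < 0 ? 0.0 : x; });
    vec rs = sum(Xi, 1);
    mat A_new = A;
    for (uword i = 0; i < K; ++i) {
      if (rs(i) > 0) A_new.row(i) = Xi.row(i) / rs(i);
    }
    vec Brs = sum(B_num, 1);
    mat B_new = B;
    for (uword i = 0; i < K; ++i) {
      if (Brs(i) > 0) B_new.row(i) = B_num.row(i) / Brs(i);
    }
    double ps = accu(pi_acc);
    vec pi_new = ps > 0 ? vec(pi_acc / ps) : pi;

    bool done = std::isfinite(ll_prev) &&
                (ll - ll_prev) / (double)n < tol &&
                (ll - ll_prev) >= -1e-6 * std::abs(ll);
    ll_prev = ll;
    if (done) { converged = true; break; }
    if (iter == max_iter - 1) break;  // keep model consistent with loglik
    pi = pi_new;
    A = A_new;
    B = B_new;
  }

  return Rcpp::List::create(
      Rcpp::Named("pi") = pi, Rcpp::Named("A") = A, Rcpp::Named("B") = B,
      Rcpp::Named("loglik") = ll_prev,
      Rcpp::Named("ll_trace") = ll_trace,
      Rcpp::Named("iterations") = iter + 1,
      Rcpp::Named("converged") = converged);
}

// Most probable state path (Viterbi) with A^dt transition operators.
// Returns 0-based states per photon.
// [[Rcpp::export]]
Rcpp::IntegerVector h2mm_viterbi_cpp(const arma::vec& pi, const arma::mat& A,
                                     const arma::mat& B,
                                     const arma::ivec& colors,
                                     const arma::vec& dt,
                                     const arma::ivec& ptr) {
  EigOp op;
  op.init(A);
  const uword K = A.n_rows;
  const uword n = colors.n_elem;
  std::unordered_map<long long, mat> logT_cache;
  auto logT = [&](double d) -> const mat& {
    long long key = (long long)d;
    auto it = logT_cache.find(key);
    if (it != logT_cache.end()) return it->second;
    mat T = op.power(d);
    T.transform([](double x) { return std::log(x < 1e-300 ? 1e-300 : x); });
    return logT_cache.emplace(key, std::move(T)).first->second;
  };
  mat logB = B;
  logB.transform([](double x) { return std::log(x < 1e-300 ? 1e-300 : x); });
  vec logpi = pi;
  logpi.transform([](double x) { return std::log(x < 1e-300 ? 1e-300 : x); });

  Rcpp::IntegerVector path(n);
  for (uword b = 0; b + 1 < ptr.n_elem; ++b) {
    long long lo = ptr(b), hi = ptr(b + 1);
    if (lo >= hi) continue;
    long long len = hi - lo;
    mat delta(len, K);
    imat psi(len, K, fill::zeros);
    delta.row(0) = logpi.t() + logB.col(colors(lo)).t();
    for (long long k = 1; k < len; ++k) {
      const mat& lT = logT(clamp_dt(dt(lo + k)));
      for (uword j = 0; j < K; ++j) {
        double best = -datum::inf;
        uword arg = 0;
        for (uword i = 0; i < K; ++i) {
          double v = delta(k - 1, i) + lT(i, j);
          if (v > best) { best = v; arg = i; }
        }
        delta(k, j) = best + logB(j, colors(lo + k));
        psi(k, j) = arg;
      }
    }
    uword s = index_max(delta.row(len - 1));
    path[hi - 1] = (int)s;
    for (long long k = len - 1; k > 0; --k) {
      s = psi(k, s);
      path[lo + k - 1] = (int)s;
    }
  }
  return path;
}

// Complete-data log-likelihood of a given state path (for ICL).
// [[Rcpp::export]]
double h2mm_path_loglik_cpp(const arma::vec& pi, const arma::mat& A,
                            const arma::mat& B, const arma::ivec& colors,
                            const arma::vec& dt, const arma::ivec& ptr,
                            const arma::ivec& states) {
  EigOp op;
  op.init(A);
  std::unordered_map<long long, mat> cache;
  auto power = [&](double d) -> const mat& {
    long long key = (long long)d;
    auto it = cache.find(key);
    if (it != cache.end()) return it->second;
    return cache.emplace(key, op.power(d)).first->second;
  };
  auto slog = [](double x) { return std::log(x < 1e-300 ? 1e-300 : x); };
  double ll = 0.0;
  for (uword b = 0; b + 1 < ptr.n_elem; ++b) {
    long long lo = ptr(b), hi = ptr(b + 1);
    if (lo >= hi) continue;
    ll += slog(pi(states(lo))) + slog(B(states(lo), colors(lo)));
    for (long long k = lo + 1; k < hi; ++k) {
      const mat& T = power(clamp_dt(dt(k)));
      ll += slog(T(states(k - 1), states(k))) +
            slog(B(states(k), colors(k)));
    }
  }
  return ll;
}
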