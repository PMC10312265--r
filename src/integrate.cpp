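// Fixed-step Heun integration of the shunting rate network.
//
// State is an N x P matrix (array neurons x populations). Away from the
// array edges every Gaussian weight matrix is Toeplitz, so each projection
// is applied as a 1-D convolution of the presynaptic column with its
// (gain-scaled, center-shifted) kernel vector, truncated at the edges with
// zero padding -- exactly the edge policy of the dense weight matrices.
// The resulting drive is routed into the excitatory / inhibitory
// conductance of the postsynaptic population according to the projection
// sign and the transfer rule: signed routing sends the negative part of
// the drive to the opposite conductance (disinhibitory rebound drive);
// half-wave rectification transmits [v]+ only.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Projection {
  arma::vec kv;      // kernel weights for index lags -K..K
  int K;             // half-support
  int offset;        // center shift (eta)
  int pre, post, sgn;
  bool rectified;    // half-wave rectify the presynaptic signal
};

struct Network {
  std::vector<Projection> proj;
  std::vector<arma::mat> stim;       // signed drive, N x (nsteps + 1)
  std::vector<int> stimTarget;
  arma::rowvec A;                    // leak rate per population
  double eExt, eInh;
};

// d[i] = sum_m kv[m + K] * v[i + offset + m], zero outside [0, N)
static void applyKernel(const Projection& p, const double* v, int N,
                        double* d) {
  for (int i = 0; i < N; ++i) {
    const int lo = std::max(-p.K, -(i + p.offset));
    const int hi = std::min(p.K, N - 1 - (i + p.offset));
    double acc = 0.0;
    const double* kv = p.kv.memptr() + p.K;
    const double* vv = v + i + p.offset;
    for (int m = lo; m <= hi; ++m) acc += kv[m] * vv[m];
    d[i] = acc;
  }
}

static void derivative(const Network& net, const arma::mat& V, int s,
                       arma::mat& dV, arma::mat& Iext, arma::mat& Iinh,
                       arma::vec& d, arma::vec& vrect) {
  const int N = V.n_rows;
  Iext.zeros();
  Iinh.zeros();
  for (size_t k = 0; k < net.proj.size(); ++k) {
    const Projection& p = net.proj[k];
    const double* v;
    if (!p.rectified) {
      v = V.colptr(p.pre);
    } else {
      vrect = arma::clamp(V.col(p.pre), 0.0, arma::datum::inf);
      v = vrect.memptr();
    }
    applyKernel(p, v, N, d.memptr());
    double* ie = Iext.colptr(p.post);
    double* ii = Iinh.colptr(p.post);
    if (p.sgn > 0) {
      for (int i = 0; i < N; ++i) {
        if (d[i] >= 0) ie[i] += d[i];
        else if (!p.rectified) ii[i] -= d[i];
      }
    } else {
      for (int i = 0; i < N; ++i) {
        if (d[i] >= 0) ii[i] += d[i];
        else if (!p.rectified) ie[i] -= d[i];
      }
    }
  }
  for (size_t k = 0; k < net.stim.size(); ++k) {
    const double* sd = net.stim[k].colptr(s);
    double* ie = Iext.colptr(net.stimTarget[k]);
    double* ii = Iinh.colptr(net.stimTarget[k]);
    for (int i = 0; i < N; ++i) {
      if (sd[i] >= 0) ie[i] += sd[i];
      else ii[i] -= sd[i];
    }
  }
  dV = -(V.each_row() % net.A) - (V - net.eExt) % Iext -
       (V - net.eInh) % Iinh;
}

// [[Rcpp::export]]
arma::cube integrate_heun_cpp(List kernelVecs, IntegerVector offsets,
                              IntegerVector pre, IntegerVector post,
                              IntegerVector sgn, LogicalVector rectified,
                              arma::rowvec A, double eExt,
                              double eInh,
                              List stimDrive, IntegerVector stimTarget,
                              int N, int P, int nsteps, double dt) {
  Network net;
  net.A = A;
  net.eExt = eExt;
  net.eInh = eInh;
  for (int k = 0; k < kernelVecs.size(); ++k) {
    Projection p;
    p.kv = as<arma::vec>(kernelVecs[k]);
    p.K = (static_cast<int>(p.kv.n_elem) - 1) / 2;
    p.offset = offsets[k];
    p.pre = pre[k];
    p.post = post[k];
    p.sgn = sgn[k];
    p.rectified = rectified[k];
    net.proj.push_back(p);
  }
  for (int k = 0; k < stimDrive.size(); ++k) {
    net.stim.push_back(as<arma::mat>(stimDrive[k]));
    net.stimTarget.push_back(stimTarget[k]);
  }

  arma::cube out(N, P, nsteps + 1, arma::fill::zeros);
  arma::mat V(N, P, arma::fill::zeros);
  arma::mat k1(N, P), k2(N, P), Vp(N, P);
  arma::mat Iext(N, P), Iinh(N, P);
  arma::vec d(N), vrect(N);

  const double bound = std::max(std::abs(eExt), std::abs(eInh)) + 1e-6;
  for (int s = 0; s < nsteps; ++s) {
    derivative(net, V, s, k1, Iext, Iinh, d, vrect);
    Vp = V + dt * k1;
    derivative(net, Vp, s + 1, k2, Iext, Iinh, d, vrect);
    V += (dt / 2.0) * (k1 + k2);
    if (arma::abs(V).max() > bound)
      stop("integration error: trajectory left the reversal-potential "
           "bounds at t = %g s (dt = %g s); reduce dt or the gains",
           (s + 1) * dt, dt);
    out.slice(s + 1) = V;
  }
  return out;
}
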