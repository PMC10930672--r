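// Dense statevector kernels for the quantum depth-infused (QDI) layer.
//
// Conventions (fixed; unit tests depend on them):
//   * little-endian qubit order: qubit 0 is the least significant bit of
//     the amplitude index;
//   * R_A(phi) = exp(-i * phi * A / 2) for A in {X, Y, Z};
//   * entangler: CNOT chain (q, q+1) for q = 0..n-2, optionally closed
//     into a ring with CNOT(n-1, 0);
//   * readout: CNOT(control = q, target = 0) for q = 1..n-1 ascending,
//     then <Y> on every qubit.
//
// Gradients use the two-point parameter-shift rule, which is exact for
// single-qubit rotation generators: df/dt = [f(t + pi/2) - f(t - pi/2)] / 2.

#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;
typedef std::complex<double> cd;

static inline void check_qubit(int q, int n) {
  if (q < 0 || q >= n) stop("qubit index out of range");
}

static void rx_inplace(std::vector<cd>& a, int n, int q, double th) {
  const double c = std::cos(th / 2.0), s = std::sin(th / 2.0);
  const cd mis(0.0, -s);
  const size_t bit = size_t(1) << q, dim = a.size();
  for (size_t i = 0; i < dim; ++i) {
    if (i & bit) continue;
    const size_t j = i | bit;
    const cd a0 = a[i], a1 = a[j];
    a[i] = c * a0 + mis * a1;
    a[j] = mis * a0 + c * a1;
  }
  (void)n;
}

static void ry_inplace(std::vector<cd>& a, int n, int q, double th) {
  const double c = std::cos(th / 2.0), s = std::sin(th / 2.0);
  const size_t bit = size_t(1) << q, dim = a.size();
  for (size_t i = 0; i < dim; ++i) {
    if (i & bit) continue;
    const size_t j = i | bit;
    const cd a0 = a[i], a1 = a[j];
    a[i] = c * a0 - s * a1;
    a[j] = s * a0 + c * a1;
  }
  (void)n;
}

static void rz_inplace(std::vector<cd>& a, int n, int q, double th) {
  const cd p0 = std::polar(1.0, -th / 2.0), p1 = std::polar(1.0, th / 2.0);
  const size_t bit = size_t(1) << q, dim = a.size();
  for (size_t i = 0; i < dim; ++i) a[i] *= (i & bit) ? p1 : p0;
  (void)n;
}

static void cnot_inplace(std::vector<cd>& a, int n, int control, int target) {
  const size_t cb = size_t(1) << control, tb = size_t(1) << target;
  const size_t dim = a.size();
  for (size_t i = 0; i < dim; ++i) {
    if ((i & cb) && !(i & tb)) std::swap(a[i], a[i | tb]);
  }
  (void)n;
}

// <P_q> for P in {X, Y, Z}; the state is assumed normalized.
static double expect_inplace(const std::vector<cd>& a, int q, char pauli) {
  const size_t bit = size_t(1) << q, dim = a.size();
  double e = 0.0;
  if (pauli == 'Z') {
    for (size_t i = 0; i < dim; ++i)
      e += ((i & bit) ? -1.0 : 1.0) * std::norm(a[i]);
  } else if (pauli == 'X') {
    for (size_t i = 0; i < dim; ++i)
      if (!(i & bit)) e += 2.0 * std::real(std::conj(a[i]) * a[i | bit]);
  } else { // Y
    for (size_t i = 0; i < dim; ++i)
      if (!(i & bit)) e += 2.0 * std::imag(std::conj(a[i]) * a[i | bit]);
  }
  return e;
}

static std::vector<cd> as_state(const ComplexVector& amps) {
  std::vector<cd> a(amps.size());
  for (int i = 0; i < amps.size(); ++i) a[i] = cd(amps[i].r, amps[i].i);
  return a;
}

static ComplexVector as_rvec(const std::vector<cd>& a) {
  ComplexVector out(a.size());
  for (size_t i = 0; i < a.size(); ++i) {
    out[i].r = a[i].real();
    out[i].i = a[i].imag();
  }
  return out;
}

// [[Rcpp::export]]
ComplexVector cpp_apply_rotation(ComplexVector amps, int n_qubits, int qubit,
                                 std::string axis, double angle) {
  check_qubit(qubit, n_qubits);
  std::vector<cd> a = as_state(amps);
  if (axis == "X") rx_inplace(a, n_qubits, qubit, angle);
  else if (axis == "Y") ry_inplace(a, n_qubits, qubit, angle);
  else if (axis == "Z") rz_inplace(a, n_qubits, qubit, angle);
  else stop("axis must be one of 'X', 'Y', 'Z'");
  return as_rvec(a);
}

// [[Rcpp::export]]
ComplexVector cpp_apply_cnot(ComplexVector amps, int n_qubits, int control,
                             int target) {
  check_qubit(control, n_qubits);
  check_qubit(target, n_qubits);
  if (control == target) stop("control and target must differ");
  std::vector<cd> a = as_state(amps);
  cnot_inplace(a, n_qubits, control, target);
  return as_rvec(a);
}

// [[Rcpp::export]]
double cpp_expectation_pauli(ComplexVector amps, int n_qubits, int qubit,
                             std::string pauli) {
  check_qubit(qubit, n_qubits);
  if (pauli != "X" && pauli != "Y" && pauli != "Z")
    stop("pauli must be one of 'X', 'Y', 'Z'");
  std::vector<cd> a = as_state(amps);
  return expect_inplace(a, qubit, pauli[0]);
}

// Readout basis change: CNOT(q -> 0) for q = 1..n-1 in ascending order.
// [[Rcpp::export]]
ComplexVector cpp_readout_transform(ComplexVector amps, int n_qubits) {
  std::vector<cd> a = as_state(amps);
  for (int q = 1; q < n_qubits; ++q) cnot_inplace(a, n_qubits, q, 0);
  return as_rvec(a);
}

static void entangle(std::vector<cd>& a, int n, bool ring) {
  for (int q = 0; q + 1 < n; ++q) cnot_inplace(a, n, q, q + 1);
  if (ring && n > 2) cnot_inplace(a, n, n - 1, 0);
}

// Full circuit: |0..0>, variational row 0, then per re-uploading block b:
// RZ feature encodings followed by variational row b; finally the readout
// transform and <Y> on every qubit.
static void qdi_expectations(const double* feat, const double* theta,
                             int n, int nblk, bool ring, double* out) {
  const size_t dim = size_t(1) << n;
  std::vector<cd> a(dim, cd(0.0, 0.0));
  a[0] = cd(1.0, 0.0);
  // theta is column-major (nblk + 1) x n: theta[row + (nblk + 1) * q]
  for (int q = 0; q < n; ++q) rx_inplace(a, n, q, theta[0 + (nblk + 1) * q]);
  entangle(a, n, ring);
  for (int b = 1; b <= nblk; ++b) {
    for (int q = 0; q < n; ++q) rz_inplace(a, n, q, feat[(b - 1) * n + q]);
    for (int q = 0; q < n; ++q) rx_inplace(a, n, q, theta[b + (nblk + 1) * q]);
    entangle(a, n, ring);
  }
  for (int q = 1; q < n; ++q) cnot_inplace(a, n, q, 0);
  for (int q = 0; q < n; ++q) out[q] = expect_inplace(a, q, 'Y');
}

// [[Rcpp::export]]
NumericVector cpp_qdi_forward(NumericVector features, NumericMatrix theta,
                              int n_qubits, int n_blocks, bool ring) {
  if (features.size() != n_qubits * n_blocks)
    stop("feature vector length must equal n_qubits * n_reupload_blocks");
  if (theta.nrow() != n_blocks + 1 || theta.ncol() != n_qubits)
    stop("theta must have shape (n_reupload_blocks + 1) x n_qubits");
  NumericVector out(n_qubits);
  qdi_expectations(features.begin(), theta.begin(), n_qubits, n_blocks, ring,
                   out.begin());
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_qdi_forward_batch(NumericMatrix features, NumericMatrix theta,
                                    int n_qubits, int n_blocks, bool ring) {
  const int ns = features.nrow();
  if (features.ncol() != n_qubits * n_blocks)
    stop("feature matrix must have n_qubits * n_reupload_blocks columns");
  NumericMatrix out(ns, n_qubits);
  std::vector<double> f(features.ncol()), o(n_qubits);
  for (int s = 0; s < ns; ++s) {
    for (int j = 0; j < features.ncol(); ++j) f[j] = features(s, j);
    qdi_expectations(f.data(), theta.begin(), n_qubits, n_blocks, ring,
                     o.data());
    for (int q = 0; q < n_qubits; ++q) out(s, q) = o[q];
  }
  return out;
}

// Parameter-shift Jacobians of the n_qubits outputs with respect to every
// theta entry and every input feature, for one sample.
static void qdi_jacobians(const double* feat, const double* theta, int n,
                          int nblk, bool ring, double* jac_th, double* jac_ft) {
  const int npar = (nblk + 1) * n, nfeat = n * nblk;
  const double half = M_PI / 2.0;
  std::vector<double> th(theta, theta + npar), ft(feat, feat + nfeat);
  std::vector<double> plus(n), minus(n);
  for (int p = 0; p < npar; ++p) {
    th[p] = theta[p] + half;
    qdi_expectations(ft.data(), th.data(), n, nblk, ring, plus.data());
    th[p] = theta[p] - half;
    qdi_expectations(ft.data(), th.data(), n, nblk, ring, minus.data());
    th[p] = theta[p];
    for (int q = 0; q < n; ++q)
      jac_th[p + npar * q] = (plus[q] - minus[q]) / 2.0;
  }
  for (int j = 0; j < nfeat; ++j) {
    ft[j] = feat[j] + half;
    qdi_expectations(ft.data(), th.data(), n, nblk, ring, plus.data());
    ft[j] = feat[j] - half;
    qdi_expectations(ft.data(), th.data(), n, nblk, ring, minus.data());
    ft[j] = feat[j];
    for (int q = 0; q < n; ++q)
      jac_ft[j + nfeat * q] = (plus[q] - minus[q]) / 2.0;
  }
}

// [[Rcpp::export]]
List cpp_qdi_jacobians(NumericVector features, NumericMatrix theta,
                       int n_qubits, int n_blocks, bool ring) {
  if (features.size() != n_qubits * n_blocks)
    stop("feature vector length must equal n_qubits * n_reupload_blocks");
  const int npar = (n_blocks + 1) * n_qubits, nfeat = n_qubits * n_blocks;
  NumericMatrix jt(npar, n_qubits), jf(nfeat, n_qubits);
  qdi_jacobians(features.begin(), theta.begin(), n_qubits, n_blocks, ring,
                jt.begin(), jf.begin());
  return List::create(_["theta"] = jt, _["features"] = jf);
}

// ---- adjoint reverse pass for training -------------------------------------
//
// For the batched backward pass the upstream gradient g contracts the
// outputs into one scalar E = sum_q g_q <Y_q>, so a single adjoint sweep
// (Jones & Gacon style) yields every dE/dtheta and dE/dfeature exactly, at
// the cost of about three circuit evaluations instead of two per parameter.
// The values are identical to the parameter-shift rule (both are exact);
// the test suite checks the two routes against each other.

struct GateRef {
  char kind;  // 'X' (RX, theta), 'Z' (RZ, feature), 'C' (CNOT)
  int a;      // qubit (rotations) / control (CNOT)
  int b;      // CNOT target, else unused
  double angle;
  int slot;   // index into theta (kind X) or features (kind Z)
};

static std::vector<GateRef> qdi_gate_list(const double* feat,
                                          const double* theta, int n,
                                          int nblk, bool ring) {
  std::vector<GateRef> gates;
  auto add_entangler = [&]() {
    for (int q = 0; q + 1 < n; ++q)
      gates.push_back({'C', q, q + 1, 0.0, -1});
    if (ring && n > 2) gates.push_back({'C', n - 1, 0, 0.0, -1});
  };
  for (int q = 0; q < n; ++q)
    gates.push_back({'X', q, -1, theta[0 + (nblk + 1) * q],
                     0 + (nblk + 1) * q});
  add_entangler();
  for (int b = 1; b <= nblk; ++b) {
    for (int q = 0; q < n; ++q) {
      const int j = (b - 1) * n + q;
      gates.push_back({'Z', q, -1, feat[j], j});
    }
    for (int q = 0; q < n; ++q)
      gates.push_back({'X', q, -1, theta[b + (nblk + 1) * q],
                       b + (nblk + 1) * q});
    add_entangler();
  }
  for (int q = 1; q < n; ++q) gates.push_back({'C', q, 0, 0.0, -1});
  return gates;
}

static void apply_gate(std::vector<cd>& a, int n, const GateRef& g,
                       bool inverse) {
  const double sgn = inverse ? -1.0 : 1.0;
  if (g.kind == 'X') rx_inplace(a, n, g.a, sgn * g.angle);
  else if (g.kind == 'Z') rz_inplace(a, n, g.a, sgn * g.angle);
  else cnot_inplace(a, n, g.a, g.b);
}

// Im(<phi| P_qubit |psi>) for P in {X, Z}
static double adj_im_bracket(const std::vector<cd>& phi,
                             const std::vector<cd>& psi, int q, char pauli) {
  const size_t bit = size_t(1) << q, dim = psi.size();
  cd acc(0.0, 0.0);
  if (pauli == 'Z') {
    for (size_t i = 0; i < dim; ++i)
      acc += std::conj(phi[i]) * (((i & bit) ? -1.0 : 1.0) * psi[i]);
  } else { // X
    for (size_t i = 0; i < dim; ++i)
      if (!(i & bit)) {
        acc += std::conj(phi[i]) * psi[i | bit] +
               std::conj(phi[i | bit]) * psi[i];
      }
  }
  return acc.imag();
}

// phi = (sum_q g_q Y_q) psi
static void apply_weighted_y(const std::vector<cd>& psi, const double* g,
                             int n, std::vector<cd>& phi) {
  const size_t dim = psi.size();
  phi.assign(dim, cd(0.0, 0.0));
  for (int q = 0; q < n; ++q) {
    if (g[q] == 0.0) continue;
    const size_t bit = size_t(1) << q;
    for (size_t i = 0; i < dim; ++i) {
      if (i & bit) continue;
      const size_t j = i | bit;
      phi[i] += g[q] * cd(0.0, -1.0) * psi[j];
      phi[j] += g[q] * cd(0.0, 1.0) * psi[i];
    }
  }
}

// Batched reverse pass: gradient of sum_q grad_out[s, q] * y[s, q] with
// respect to the feature matrix (per sample) and theta (summed over the
// batch).  grad_out is n_samples x n_qubits.
// [[Rcpp::export]]
List cpp_qdi_backward_batch(NumericMatrix features, NumericMatrix theta,
                            NumericMatrix grad_out, int n_qubits, int n_blocks,
                            bool ring) {
  const int ns = features.nrow();
  const int nfeat = n_qubits * n_blocks;
  if (features.ncol() != nfeat)
    stop("feature matrix must have n_qubits * n_reupload_blocks columns");
  if (grad_out.nrow() != ns || grad_out.ncol() != n_qubits)
    stop("grad_out must be n_samples x n_qubits");
  NumericMatrix gfeat(ns, nfeat);
  NumericMatrix gtheta(n_blocks + 1, n_qubits);
  const size_t dim = size_t(1) << n_qubits;
  std::vector<double> f(nfeat), g(n_qubits);
  std::vector<cd> psi, phi;
  for (int s = 0; s < ns; ++s) {
    for (int j = 0; j < nfeat; ++j) f[j] = features(s, j);
    for (int q = 0; q < n_qubits; ++q) g[q] = grad_out(s, q);
    std::vector<GateRef> gates =
        qdi_gate_list(f.data(), theta.begin(), n_qubits, n_blocks, ring);
    psi.assign(dim, cd(0.0, 0.0));
    psi[0] = cd(1.0, 0.0);
    for (const GateRef& gt : gates) apply_gate(psi, n_qubits, gt, false);
    apply_weighted_y(psi, g.data(), n_qubits, phi);
    for (int k = int(gates.size()) - 1; k >= 0; --k) {
      const GateRef& gt = gates[k];
      if (gt.kind == 'X') {
        gtheta[gt.slot] += adj_im_bracket(phi, psi, gt.a, 'X');
      } else if (gt.kind == 'Z') {
        gfeat(s, gt.slot) += adj_im_bracket(phi, psi, gt.a, 'Z');
      }
      apply_gate(psi, n_qubits, gt, true);
      apply_gate(phi, n_qubits, gt, true);
    }
  }
  return List::create(_["features"] = gfeat, _["theta"] = gtheta);
}
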