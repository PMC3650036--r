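#include <Rcpp.h>
using namespace Rcpp;

// Full-epoch sweep of the recurrent network with optional RTRL sensitivity
// accumulation.
//
// W is Nr x (p + Nr): external-input columns first, then one-step feedback
// columns. At step n the input is u(n) = [x_ext(n), y(n-1)] and neuron i
// emits y_i(n) = tanh(gain_i * (W u(n))_i + bias_i). The RTRL recursion
//   P_i(n) = gain_i (1 - y_i(n)^2) * (delta_{ik} u_l(n) + sum_j W[i, p+j] P_j(n-1))
// propagates dy_i(n)/dw_{kl} forward in time from a zero initial state;
// only the first neuron's slice (the network output) is stored per step,
// flattened in R column-major order of W.
//
// [[Rcpp::export]]
List rnn_sweep_cpp(NumericMatrix W, NumericVector gain, NumericVector bias,
                   NumericMatrix x_ext, NumericVector y_init,
                   bool sensitivities) {
  const int nr = W.nrow();
  const int pc = W.ncol();
  const int p = pc - nr;
  const int n = x_ext.nrow();
  const int nw = nr * pc;

  if (p < 1 || x_ext.ncol() != p)
    stop("external input width inconsistent with the weight matrix");
  if (gain.size() != nr || bias.size() != nr || y_init.size() != nr)
    stop("gain, bias and initial state must have one entry per neuron");

  std::vector<double> y(nr), ynew(nr), u(pc);
  for (int i = 0; i < nr; ++i) y[i] = y_init[i];

  NumericMatrix net_in(n, nr), out(n, nr);
  NumericMatrix s1(sensitivities ? n : 1, sensitivities ? nw : 1);
  std::vector<double> pold(nr * nw, 0.0), pnew(nr * nw, 0.0);

  for (int t = 0; t < n; ++t) {
    for (int j = 0; j < p; ++j) u[j] = x_ext(t, j);
    for (int j = 0; j < nr; ++j) u[p + j] = y[j];
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int l = 0; l < pc; ++l) s += W(i, l) * u[l];
      net_in(t, i) = s;
      ynew[i] = std::tanh(gain[i] * s + bias[i]);
    }
    if (sensitivities) {
      for (int i = 0; i < nr; ++i) {
        const double slope = gain[i] * (1.0 - ynew[i] * ynew[i]);
        for (int wi = 0; wi < nw; ++wi) {
          const int k = wi % nr;          // row of W, column-major flattening
          const int l = wi / nr;          // column of W
          double acc = (i == k) ? u[l] : 0.0;
          for (int j = 0; j < nr; ++j) acc += W(i, p + j) * pold[j + nr * wi];
          pnew[i + nr * wi] = slope * acc;
        }
      }
      std::swap(pold, pnew);
      for (int wi = 0; wi < nw; ++wi) s1(t, wi) = pold[0 + nr * wi];
    }
    for (int i = 0; i < nr; ++i) {
      y[i] = ynew[i];
      out(t, i) = y[i];
    }
  }
  return List::create(_["net_input"] = net_in, _["outputs"] = out,
                      _["s1"] = s1);
}
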