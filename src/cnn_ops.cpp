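#include <Rcpp.h>
using namespace Rcpp;

// 1-D convolution (kernel width 3, stride 1) and max-pooling primitives.
// Arrays are stored as R arrays with dim (batch, positions, filters).

// [[Rcpp::export]]
NumericVector conv1d_forward_cpp(NumericMatrix X, NumericMatrix W, NumericVector b) {
  int B = X.nrow(), P = X.ncol(), K = W.nrow(), F = W.ncol();
  int T = P - K + 1;
  NumericVector Z((R_xlen_t)B * T * F);
  // Z[b, t, f] = sum_k W[k, f] * X[b, t + k] + b[f]
  for (int f = 0; f < F; ++f) {
    R_xlen_t off = (R_xlen_t)f * B * T;
    for (int t = 0; t < T; ++t) {
      R_xlen_t col = off + (R_xlen_t)t * B;
      for (int i = 0; i < B; ++i) Z[col + i] = b[f];
      for (int k = 0; k < K; ++k) {
        double w = W(k, f);
        if (w == 0.0) continue;
        for (int i = 0; i < B; ++i) Z[col + i] += w * X(i, t + k);
      }
    }
  }
  Z.attr("dim") = IntegerVector::create(B, T, F);
  return Z;
}

// [[Rcpp::export]]
List conv1d_backward_cpp(NumericMatrix X, NumericMatrix W, NumericVector dZ) {
  IntegerVector d = dZ.attr("dim");
  int B = d[0], T = d[1], F = d[2], K = W.nrow();
  NumericMatrix dW(K, F);
  NumericVector db(F);
  for (int f = 0; f < F; ++f) {
    R_xlen_t off = (R_xlen_t)f * B * T;
    double dbf = 0.0;
    for (int t = 0; t < T; ++t) {
      R_xlen_t col = off + (R_xlen_t)t * B;
      for (int i = 0; i < B; ++i) dbf += dZ[col + i];
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int i = 0; i < B; ++i) s += dZ[col + i] * X(i, t + k);
        dW(k, f) += s;
      }
    }
    db[f] = dbf;
  }
  return List::create(_["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool_forward_cpp(NumericVector Z, int pool) {
  IntegerVector d = Z.attr("dim");
  int B = d[0], T = d[1], F = d[2];
  int T2 = T / pool;  // non-overlapping windows, trailing remainder dropped
  NumericVector out((R_xlen_t)B * T2 * F);
  IntegerVector arg((R_xlen_t)B * T2 * F);  // index of max within window (0-based, absolute t)
  for (int f = 0; f < F; ++f) {
    R_xlen_t offZ = (R_xlen_t)f * B * T;
    R_xlen_t offO = (R_xlen_t)f * B * T2;
    for (int t2 = 0; t2 < T2; ++t2) {
      R_xlen_t colO = offO + (R_xlen_t)t2 * B;
      for (int i = 0; i < B; ++i) {
        double best = R_NegInf;
        int bestt = t2 * pool;
        for (int k = 0; k < pool; ++k) {
          int t = t2 * pool + k;
          double v = Z[offZ + (R_xlen_t)t * B + i];
          if (v > best) { best = v; bestt = t; }
        }
        out[colO + i] = best;
        arg[colO + i] = bestt;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(B, T2, F);
  arg.attr("dim") = IntegerVector::create(B, T2, F);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(NumericVector dOut, IntegerVector argmax, int T) {
  IntegerVector d = dOut.attr("dim");
  int B = d[0], T2 = d[1], F = d[2];
  NumericVector dZ((R_xlen_t)B * T * F);
  for (int f = 0; f < F; ++f) {
    R_xlen_t offO = (R_xlen_t)f * B * T2;
    R_xlen_t offZ = (R_xlen_t)f * B * T;
    for (int t2 = 0; t2 < T2; ++t2) {
      R_xlen_t colO = offO + (R_xlen_t)t2 * B;
      for (int i = 0; i < B; ++i) {
        int t = argmax[colO + i];
        dZ[offZ + (R_xlen_t)t * B + i] += dOut[colO + i];
      }
    }
  }
  dZ.attr("dim") = IntegerVector::create(B, T, F);
  return dZ;
}

// gradient w.r.t. the conv input is not needed (input layer), so it is omitted.
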