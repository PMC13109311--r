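// Compute kernels for the LPCNet stack. The parameter handling, Adam
// optimizer and training loop live in R; these kernels run the
// numerical forward/backward passes. Two paths exist: per-layer
// exported kernels (used by the R layer wrappers, whose caches are R
// objects — convenient for inspection and gradient tests), and a fused
// whole-network step (`.lpcnetStepCpp`) that keeps every activation
// cache on the C++ side, which is what the training loop uses.
// Inter-layer activations are (batch, channel, position) cubes; the
// attention core uses (position, channel, batch) so each sample's token
// matrix is a contiguous slice.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// ---- fused convolution block: conv1d -> ReLU -> max-pool(2) ----
// X: (n, Cin, L) cube; W: (K*Cin) x Cout, tap-major columns (tap j,
// channel ch at row j*Cin + ch); b: Cout. Row i + n*t of the im2col
// matrix holds the receptive field of sample i at position t. Stride 1,
// zero 'same' padding, odd kernel; pooling drops a trailing odd
// position.

struct ConvCache {
  mat cols;
  umat M, P;
  int n = 0, Cin = 0, L = 0;
};

static mat im2col(const cube& X, int K) {
  const int n = X.n_rows, Cin = X.n_cols, L = X.n_slices;
  const int h = (K - 1) / 2;
  mat cols(n * (size_t)L, K * (size_t)Cin, fill::zeros);
  for (int j = 0; j < K; ++j) {
    for (int ch = 0; ch < Cin; ++ch) {
      double* dst = cols.colptr(j * (size_t)Cin + ch);
      for (int t = 0; t < L; ++t) {
        const int srcT = t + j - h;
        if (srcT < 0 || srcT >= L) continue;
        std::memcpy(dst + (size_t)n * t,
                    X.slice(srcT).colptr(ch), n * sizeof(double));
      }
    }
  }
  return cols;
}

static cube convBlockFwd(const cube& X, const mat& W, const vec& b,
                         ConvCache& cc) {
  const int n = X.n_rows, Cin = X.n_cols;
  const int L = X.n_slices;
  const int Cout = W.n_cols;
  const int L2 = L / 2;
  cc.n = n; cc.Cin = Cin; cc.L = L;
  cc.cols = im2col(X, W.n_rows / Cin);
  mat Z = cc.cols * W;
  Z.each_row() += b.t();
  cc.M = Z > 0;                       // ReLU mask
  Z %= conv_to<mat>::from(cc.M);
  cube Y(n, Cout, L2);
  cc.P.set_size(n * (size_t)L2, Cout); // 1 where the earlier slot won
  for (int t2 = 0; t2 < L2; ++t2) {
    const mat a = Z.rows(2 * n * (size_t)t2, 2 * n * (size_t)t2 + n - 1);
    const mat c = Z.rows(n * (2 * (size_t)t2 + 1),
                         n * (2 * (size_t)t2 + 1) + n - 1);
    const umat first = a >= c;
    cc.P.rows(n * (size_t)t2, n * (size_t)t2 + n - 1) = first;
    Y.slice(t2) = arma::max(a, c);
  }
  return Y;
}

static cube convBlockBwd(const cube& gY, const mat& W, const ConvCache& cc,
                         mat& gW, vec& gb) {
  const int n = cc.n, Cin = cc.Cin, L = cc.L;
  const int K = W.n_rows / Cin, Cout = W.n_cols;
  const int L2 = gY.n_slices;
  mat gZ(n * (size_t)L, Cout, fill::zeros);
  for (int t2 = 0; t2 < L2; ++t2) {
    const mat& g = gY.slice(t2);
    const umat first = cc.P.rows(n * (size_t)t2, n * (size_t)t2 + n - 1);
    gZ.rows(2 * n * (size_t)t2, 2 * n * (size_t)t2 + n - 1) =
        g % conv_to<mat>::from(first);
    gZ.rows(n * (2 * (size_t)t2 + 1), n * (2 * (size_t)t2 + 1) + n - 1) =
        g % conv_to<mat>::from(1 - first);
  }
  gZ %= conv_to<mat>::from(cc.M);
  gW = cc.cols.t() * gZ;
  gb = sum(gZ, 0).t();
  mat gcols = gZ * W.t();
  cube gX(n, Cin, L, fill::zeros);
  const int h = (K - 1) / 2;
  for (int j = 0; j < K; ++j) {
    for (int ch = 0; ch < Cin; ++ch) {
      const double* src = gcols.colptr(j * (size_t)Cin + ch);
      for (int t = 0; t < L; ++t) {
        const int srcT = t + j - h;
        if (srcT < 0 || srcT >= L) continue;
        double* dst = gX.slice(srcT).colptr(ch);
        const double* s = src + (size_t)n * t;
        for (int i = 0; i < n; ++i) dst[i] += s[i];
      }
    }
  }
  return gX;
}

// ---- LSTM ----
// X: (n, C, T) cube; Wx: C x 4H; Wh: H x 4H; b: 4H. Gate order along
// columns: input, forget, candidate, output. `reverse` runs the
// recurrence from the last time step to the first (the backward
// direction of a bidirectional layer); caches and outputs stay indexed
// by actual time.

struct LstmCache {
  cube I, F, G, O, Tc, Cprev, Hprev;
  bool reverse = false;
};

static cube lstmFwd(const cube& X, const mat& Wx, const mat& Wh,
                    const vec& b, bool reverse, LstmCache& lc) {
  const int n = X.n_rows, T = X.n_slices;
  const int H = Wx.n_cols / 4;
  lc.reverse = reverse;
  mat h(n, H, fill::zeros), c(n, H, fill::zeros);
  cube Hs(n, H, T);
  lc.I.set_size(n, H, T); lc.F.set_size(n, H, T); lc.G.set_size(n, H, T);
  lc.O.set_size(n, H, T); lc.Tc.set_size(n, H, T);
  lc.Cprev.set_size(n, H, T); lc.Hprev.set_size(n, H, T);
  const rowvec br = b.t();
  for (int k = 0; k < T; ++k) {
    const int t = reverse ? T - 1 - k : k;
    mat z = X.slice(t) * Wx + h * Wh;
    z.each_row() += br;
    mat i_ = sigm(z.cols(0, H - 1));
    mat f_ = sigm(z.cols(H, 2 * H - 1));
    mat g_ = tanh(z.cols(2 * H, 3 * H - 1));
    mat o_ = sigm(z.cols(3 * H, 4 * H - 1));
    lc.Cprev.slice(t) = c;
    lc.Hprev.slice(t) = h;
    c = f_ % c + i_ % g_;
    mat tc = tanh(c);
    h = o_ % tc;
    lc.I.slice(t) = i_; lc.F.slice(t) = f_; lc.G.slice(t) = g_;
    lc.O.slice(t) = o_; lc.Tc.slice(t) = tc;
    Hs.slice(t) = h;
  }
  return Hs;
}

static cube lstmBwd(const cube& X, const mat& Wx, const mat& Wh,
                    const LstmCache& lc, const cube& gY, mat& gWx,
                    mat& gWh, vec& gbOut) {
  const int n = X.n_rows, C = X.n_cols, T = X.n_slices;
  const int H = Wx.n_cols / 4;
  gWx.zeros(C, 4 * H);
  gWh.zeros(H, 4 * H);
  rowvec gb(4 * H, fill::zeros);
  cube gX(n, C, T);
  mat gh(n, H, fill::zeros), gc(n, H, fill::zeros);
  for (int k = T - 1; k >= 0; --k) {
    const int t = lc.reverse ? T - 1 - k : k;
    mat ghT = gh + gY.slice(t);
    mat go = ghT % lc.Tc.slice(t);
    mat gcT = gc + ghT % lc.O.slice(t) %
                       (1.0 - lc.Tc.slice(t) % lc.Tc.slice(t));
    mat gi = gcT % lc.G.slice(t);
    mat gf = gcT % lc.Cprev.slice(t);
    mat gg = gcT % lc.I.slice(t);
    gc = gcT % lc.F.slice(t);
    mat gz(n, 4 * H);
    gz.cols(0, H - 1) = gi % lc.I.slice(t) % (1.0 - lc.I.slice(t));
    gz.cols(H, 2 * H - 1) = gf % lc.F.slice(t) % (1.0 - lc.F.slice(t));
    gz.cols(2 * H, 3 * H - 1) = gg % (1.0 - lc.G.slice(t) % lc.G.slice(t));
    gz.cols(3 * H, 4 * H - 1) = go % lc.O.slice(t) % (1.0 - lc.O.slice(t));
    gWx += X.slice(t).t() * gz;
    gWh += lc.Hprev.slice(t).t() * gz;
    gb += sum(gz, 0);
    gX.slice(t) = gz * Wx.t();
    gh = gz * Wh.t();
  }
  gbOut = gb.t();
  return gX;
}

// ---- multi-head self-attention ----
// Xc: (T, D, n) cube; heads: list of lists with Wq/Wk/Wv (D x dh);
// Wo: (nh*dh) x D. Scores scaled by 1/sqrt(dh) when scale is true.
// Q/K/V/A caches stacked as (.., .., h*n + i) slices.

struct MhsaCache {
  cube Q, K, V, A, concat;
  double rowSumDev = 0.0;
};

static cube mhsaFwd(const cube& Xc, const List& heads, const mat& Wo,
                    bool scale, MhsaCache& mc) {
  const int T = Xc.n_rows, D = Xc.n_cols, n = Xc.n_slices;
  const int nh = heads.size();
  const mat Wq0 = as<List>(heads[0])["Wq"];
  const int dh = Wq0.n_cols;
  const double sc = scale ? 1.0 / std::sqrt((double)dh) : 1.0;
  mc.Q.set_size(T, dh, n * nh); mc.K.set_size(T, dh, n * nh);
  mc.V.set_size(T, dh, n * nh); mc.A.set_size(T, T, n * nh);
  mc.concat.set_size(T, nh * dh, n);
  mc.rowSumDev = 0.0;
  for (int h = 0; h < nh; ++h) {
    const List ph = heads[h];
    const mat Wq = ph["Wq"], Wk = ph["Wk"], Wv = ph["Wv"];
    for (int i = 0; i < n; ++i) {
      const mat& Xi = Xc.slice(i);
      mat Qi = Xi * Wq, Ki = Xi * Wk, Vi = Xi * Wv;
      mat S = (Qi * Ki.t()) * sc;
      S.each_col() -= max(S, 1);        // numerically stable softmax
      mat E = exp(S);
      mat Ai = E.each_col() / sum(E, 1);
      mc.rowSumDev = std::max(mc.rowSumDev, abs(sum(Ai, 1) - 1.0).max());
      const int s = h * n + i;
      mc.Q.slice(s) = Qi; mc.K.slice(s) = Ki; mc.V.slice(s) = Vi;
      mc.A.slice(s) = Ai;
      mc.concat.slice(i).cols(h * dh, (h + 1) * dh - 1) = Ai * Vi;
    }
  }
  cube Y(T, D, n);
  for (int i = 0; i < n; ++i) Y.slice(i) = mc.concat.slice(i) * Wo;
  return Y;
}

static cube mhsaBwd(const cube& Xc, const cube& gY, const List& heads,
                    const mat& Wo, const MhsaCache& mc, bool scale,
                    List& gheadsOut, mat& gWo) {
  const int T = Xc.n_rows, D = Xc.n_cols, n = Xc.n_slices;
  const int nh = heads.size();
  const mat Wq0 = as<List>(heads[0])["Wq"];
  const int dh = Wq0.n_cols;
  const double sc = scale ? 1.0 / std::sqrt((double)dh) : 1.0;
  gWo.zeros(nh * dh, D);
  cube gX(T, D, n, fill::zeros);
  cube gconcat(T, nh * dh, n);
  for (int i = 0; i < n; ++i) {
    gWo += mc.concat.slice(i).t() * gY.slice(i);
    gconcat.slice(i) = gY.slice(i) * Wo.t();
  }
  List gheads(nh);
  for (int h = 0; h < nh; ++h) {
    const List ph = heads[h];
    const mat Wq = ph["Wq"], Wk = ph["Wk"], Wv = ph["Wv"];
    mat gWq(D, dh, fill::zeros), gWk(D, dh, fill::zeros),
        gWv(D, dh, fill::zeros);
    for (int i = 0; i < n; ++i) {
      const int s = h * n + i;
      const mat gO = gconcat.slice(i).cols(h * dh, (h + 1) * dh - 1);
      const mat& Ai = mc.A.slice(s);
      mat gA = gO * mc.V.slice(s).t();
      mat gV = Ai.t() * gO;
      // softmax backward per row: gS = A % (gA - rowSums(gA % A))
      vec r = sum(gA % Ai, 1);
      mat gS = Ai % (gA.each_col() - r);
      mat gQ = (gS * mc.K.slice(s)) * sc;
      mat gK = (gS.t() * mc.Q.slice(s)) * sc;
      const mat& Xi = Xc.slice(i);
      gWq += Xi.t() * gQ;
      gWk += Xi.t() * gK;
      gWv += Xi.t() * gV;
      gX.slice(i) += gQ * Wq.t() + gK * Wk.t() + gV * Wv.t();
    }
    gheads[h] = List::create(_["Wq"] = gWq, _["Wk"] = gWk, _["Wv"] = gWv);
  }
  gheadsOut = gheads;
  return gX;
}

// (n, D, T) <-> (T, D, n) layout transposes
static cube toTDN(const cube& A) {
  const int n = A.n_rows, D = A.n_cols, T = A.n_slices;
  cube Xc(T, D, n);
  for (int t = 0; t < T; ++t)
    for (int d = 0; d < D; ++d) {
      const double* src = A.slice(t).colptr(d);
      for (int i = 0; i < n; ++i) Xc.at(t, d, i) = src[i];
    }
  return Xc;
}
static cube toNDT(const cube& Xc) {
  const int T = Xc.n_rows, D = Xc.n_cols, n = Xc.n_slices;
  cube A(n, D, T);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < D; ++d) {
      const double* src = Xc.slice(i).colptr(d);
      for (int t = 0; t < T; ++t) A.at(i, d, t) = src[t];
    }
  return A;
}

// ---- per-layer exports (R layer wrappers) ----

// [[Rcpp::export(name = ".convBlockFwdCpp")]]
List convBlockFwdCpp(const arma::cube& X, const arma::mat& W,
                     const arma::vec& b) {
  ConvCache cc;
  cube Y = convBlockFwd(X, W, b, cc);
  return List::create(_["Y"] = Y, _["cols"] = cc.cols, _["M"] = cc.M,
                      _["P"] = cc.P);
}

// [[Rcpp::export(name = ".convBlockBwdCpp")]]
List convBlockBwdCpp(const arma::cube& gY, const arma::mat& W,
                     const arma::mat& cols, const arma::umat& M,
                     const arma::umat& P, int n, int Cin, int L) {
  ConvCache cc;
  cc.cols = cols; cc.M = M; cc.P = P; cc.n = n; cc.Cin = Cin; cc.L = L;
  mat gW; vec gb;
  cube gX = convBlockBwd(gY, W, cc, gW, gb);
  return List::create(_["gX"] = gX,
                      _["grads"] = List::create(_["W"] = gW, _["b"] = gb));
}

// [[Rcpp::export(name = ".lstmFwdCpp")]]
List lstmFwdCpp(const arma::cube& X, const arma::mat& Wx,
                const arma::mat& Wh, const arma::vec& b, bool reverse) {
  LstmCache lc;
  cube Hs = lstmFwd(X, Wx, Wh, b, reverse, lc);
  return List::create(_["H"] = Hs, _["I"] = lc.I, _["F"] = lc.F,
                      _["G"] = lc.G, _["O"] = lc.O, _["Tc"] = lc.Tc,
                      _["Cprev"] = lc.Cprev, _["Hprev"] = lc.Hprev);
}

// [[Rcpp::export(name = ".lstmBwdCpp")]]
List lstmBwdCpp(const arma::cube& X, const arma::mat& Wx,
                const arma::mat& Wh, const List& cache,
                const arma::cube& gY, bool reverse) {
  LstmCache lc;
  lc.I = as<cube>(cache["I"]); lc.F = as<cube>(cache["F"]);
  lc.G = as<cube>(cache["G"]); lc.O = as<cube>(cache["O"]);
  lc.Tc = as<cube>(cache["Tc"]); lc.Cprev = as<cube>(cache["Cprev"]);
  lc.Hprev = as<cube>(cache["Hprev"]); lc.reverse = reverse;
  mat gWx, gWh; vec gb;
  cube gX = lstmBwd(X, Wx, Wh, lc, gY, gWx, gWh, gb);
  return List::create(
      _["gX"] = gX,
      _["grads"] = List::create(_["Wx"] = gWx, _["Wh"] = gWh,
                                _["b"] = gb));
}

// [[Rcpp::export(name = ".mhsaFwdCpp")]]
List mhsaFwdCpp(const arma::cube& X, const List& heads,
                const arma::mat& Wo, bool scale) {
  MhsaCache mc;
  cube Y = mhsaFwd(X, heads, Wo, scale, mc);
  return List::create(_["Y"] = Y, _["Q"] = mc.Q, _["K"] = mc.K,
                      _["V"] = mc.V, _["A"] = mc.A,
                      _["concat"] = mc.concat,
                      _["rowSumDev"] = mc.rowSumDev);
}

// [[Rcpp::export(name = ".mhsaBwdCpp")]]
List mhsaBwdCpp(const arma::cube& X, const arma::cube& gY,
                const List& heads, const arma::mat& Wo,
                const arma::cube& Q, const arma::cube& K,
                const arma::cube& V, const arma::cube& A,
                const arma::cube& concat, bool scale) {
  MhsaCache mc;
  mc.Q = Q; mc.K = K; mc.V = V; mc.A = A; mc.concat = concat;
  List gheads; mat gWo;
  cube gX = mhsaBwd(X, gY, heads, Wo, mc, scale, gheads, gWo);
  return List::create(
      _["gX"] = gX,
      _["grads"] = List::create(_["heads"] = gheads, _["Wo"] = gWo));
}

// ---- fused whole-network step ----
// params: list with conv1..convN (W, b), optional bilstm (fwd/bwd with
// Wx, Wh, b), optional mhsa (heads, Wo), head (W, b). X: n x B matrix.

struct NetCaches {
  std::vector<ConvCache> conv;
  std::vector<cube> convIn;
  LstmCache lstmF, lstmB;
  cube lstmIn;
  MhsaCache mhsa;
  cube mhsaIn;             // (T, D, n)
  mat headIn;
  int T = 0, D = 0;
};

static mat netForward(const mat& X, const List& params, bool scale,
                      NetCaches& nc, int& nConv) {
  const int n = X.n_rows, B = X.n_cols;
  CharacterVector nm = params.names();
  nConv = 0;
  for (int i = 0; i < nm.size(); ++i)
    if (std::string(nm[i]).rfind("conv", 0) == 0) ++nConv;
  cube A(n, 1, B);
  for (int t = 0; t < B; ++t)
    A.slice(t) = X.col(t);
  nc.conv.resize(nConv);
  nc.convIn.resize(nConv);
  for (int i = 0; i < nConv; ++i) {
    const List p = params[std::string("conv") + std::to_string(i + 1)];
    nc.convIn[i] = A;
    A = convBlockFwd(A, as<mat>(p["W"]), as<vec>(p["b"]), nc.conv[i]);
  }
  if (params.containsElementNamed("bilstm")) {
    const List pb = params["bilstm"];
    const List pf = pb["fwd"], pr = pb["bwd"];
    nc.lstmIn = A;
    cube Hf = lstmFwd(A, as<mat>(pf["Wx"]), as<mat>(pf["Wh"]),
                      as<vec>(pf["b"]), false, nc.lstmF);
    cube Hb = lstmFwd(A, as<mat>(pr["Wx"]), as<mat>(pr["Wh"]),
                      as<vec>(pr["b"]), true, nc.lstmB);
    const int H = Hf.n_cols;
    cube A2(A.n_rows, 2 * H, A.n_slices);
    A2.cols(0, H - 1) = Hf;
    A2.cols(H, 2 * H - 1) = Hb;
    A = A2;
  }
  if (params.containsElementNamed("mhsa")) {
    const List pm = params["mhsa"];
    nc.mhsaIn = toTDN(A);
    cube Y = mhsaFwd(nc.mhsaIn, pm["heads"], as<mat>(pm["Wo"]), scale,
                     nc.mhsa);
    A = toNDT(Y);
  }
  nc.T = A.n_slices;
  nc.D = A.n_cols;
  nc.headIn = sum(A, 2) / (double)A.n_slices;   // mean pool over positions
  const List ph = params["head"];
  mat out = nc.headIn * as<mat>(ph["W"]);
  out.each_row() += as<vec>(ph["b"]).t();
  return out;
}

// [[Rcpp::export(name = ".lpcnetPredictCpp")]]
arma::vec lpcnetPredictCpp(const arma::mat& X, const List& params,
                           bool scale) {
  NetCaches nc;
  int nConv = 0;
  return vec(netForward(X, params, scale, nc, nConv));
}

// [[Rcpp::export(name = ".lpcnetStepCpp")]]
List lpcnetStepCpp(const arma::mat& X, const arma::vec& y,
                   const List& params, bool scale) {
  NetCaches nc;
  int nConv = 0;
  mat out = netForward(X, params, scale, nc, nConv);
  const int n = X.n_rows;
  vec res = out.col(0) - y;
  const double loss = dot(res, res) / n;
  mat gOut(res * (2.0 / n));

  List grads(params.size());
  grads.names() = params.names();
  const List ph = params["head"];
  mat headW = ph["W"];
  grads["head"] = List::create(_["W"] = mat(nc.headIn.t() * gOut),
                               _["b"] = vec(sum(gOut, 0).t()));
  mat gPool = gOut * headW.t();               // n x D
  cube gA(n, nc.D, nc.T);
  for (int t = 0; t < nc.T; ++t) gA.slice(t) = gPool / (double)nc.T;

  if (params.containsElementNamed("mhsa")) {
    const List pm = params["mhsa"];
    List gheads; mat gWo;
    cube gXc = mhsaBwd(nc.mhsaIn, toTDN(gA), pm["heads"],
                       as<mat>(pm["Wo"]), nc.mhsa, scale, gheads, gWo);
    grads["mhsa"] = List::create(_["heads"] = gheads, _["Wo"] = gWo);
    gA = toNDT(gXc);
  }
  if (params.containsElementNamed("bilstm")) {
    const List pb = params["bilstm"];
    const List pf = pb["fwd"], pr = pb["bwd"];
    const int H = gA.n_cols / 2;
    mat gWxF, gWhF, gWxB, gWhB; vec gbF, gbB;
    cube gXf = lstmBwd(nc.lstmIn, as<mat>(pf["Wx"]), as<mat>(pf["Wh"]),
                       nc.lstmF, gA.cols(0, H - 1), gWxF, gWhF, gbF);
    cube gXb = lstmBwd(nc.lstmIn, as<mat>(pr["Wx"]), as<mat>(pr["Wh"]),
                       nc.lstmB, gA.cols(H, 2 * H - 1), gWxB, gWhB, gbB);
    grads["bilstm"] = List::create(
        _["fwd"] = List::create(_["Wx"] = gWxF, _["Wh"] = gWhF,
                                _["b"] = gbF),
        _["bwd"] = List::create(_["Wx"] = gWxB, _["Wh"] = gWhB,
                                _["b"] = gbB));
    gA = gXf + gXb;
  }
  for (int i = nConv - 1; i >= 0; --i) {
    const std::string key = std::string("conv") + std::to_string(i + 1);
    const List p = params[key];
    mat gW; vec gb;
    gA = convBlockBwd(gA, as<mat>(p["W"]), nc.conv[i], gW, gb);
    grads[key] = List::create(_["W"] = gW, _["b"] = gb);
  }
  return List::create(_["loss"] = loss, _["out"] = vec(out.col(0)),
                      _["grads"] = grads,
                      _["rowSumDev"] = nc.mhsa.rowSumDev);
}
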