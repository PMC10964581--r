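// Low-level kernels for the CPU training engine and instance labelling.
// Array layout follows R column-major conventions:
//   2D feature maps: dim (H, W, C),  index (i,j,c) -> i + H*(j + W*c)
//   3D feature maps: dim (D, H, W, C), index (d,i,j,c) -> d + D*(i + H*(j + W*c))
// Convolutions are "same" padded, stride 1, odd kernel size k.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---- 2D im2col / col2im ---------------------------------------------------

// [[Rcpp::export]]
arma::mat cpp_im2col2(const arma::vec& x, int H, int W, int C, int k) {
  const int p = (k - 1) / 2;
  arma::mat out(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int js = j + dj - p;
          if (js < 0 || js >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int is = i + di - p;
            if (is < 0 || is >= H) continue;
            out(i + H * j, col) = x[is + H * (js + W * c)];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_col2im2(const arma::mat& cols, int H, int W, int C, int k) {
  const int p = (k - 1) / 2;
  arma::vec out(H * W * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = c * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int js = j + dj - p;
          if (js < 0 || js >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int is = i + di - p;
            if (is < 0 || is >= H) continue;
            out[is + H * (js + W * c)] += cols(i + H * j, col);
          }
        }
      }
    }
  }
  return out;
}

// ---- 3D im2col / col2im ---------------------------------------------------

// [[Rcpp::export]]
arma::mat cpp_im2col3(const arma::vec& x, int D, int H, int W, int C, int k) {
  const int p = (k - 1) / 2;
  arma::mat out(D * H * W, k * k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        for (int dd = 0; dd < k; ++dd) {
          const int col = c * k * k * k + dj * k * k + di * k + dd;
          for (int j = 0; j < W; ++j) {
            const int js = j + dj - p;
            if (js < 0 || js >= W) continue;
            for (int i = 0; i < H; ++i) {
              const int is = i + di - p;
              if (is < 0 || is >= H) continue;
              for (int d = 0; d < D; ++d) {
                const int ds = d + dd - p;
                if (ds < 0 || ds >= D) continue;
                out(d + D * (i + H * j), col) = x[ds + D * (is + H * (js + W * c))];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_col2im3(const arma::mat& cols, int D, int H, int W, int C, int k) {
  const int p = (k - 1) / 2;
  arma::vec out(D * H * W * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        for (int dd = 0; dd < k; ++dd) {
          const int col = c * k * k * k + dj * k * k + di * k + dd;
          for (int j = 0; j < W; ++j) {
            const int js = j + dj - p;
            if (js < 0 || js >= W) continue;
            for (int i = 0; i < H; ++i) {
              const int is = i + di - p;
              if (is < 0 || is >= H) continue;
              for (int d = 0; d < D; ++d) {
                const int ds = d + dd - p;
                if (ds < 0 || ds >= D) continue;
                out[ds + D * (is + H * (js + W * c))] += cols(d + D * (i + H * j), col);
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// ---- pooling (2x2 / 2x2x2 max) -------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool2(const arma::vec& x, int H, int W, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(Ho * Wo * C);
  IntegerVector idx(Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -1e300; int bestk = 0;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const int src = (2 * i + di) + H * ((2 * j + dj) + W * c);
            if (x[src] > best) { best = x[src]; bestk = src; }
          }
        }
        const int o = i + Ho * (j + Wo * c);
        y[o] = best; idx[o] = bestk;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::vec cpp_maxpool2_bwd(const arma::vec& dy, const IntegerVector& idx,
                           int H, int W, int C) {
  arma::vec dx(H * W * C, arma::fill::zeros);
  for (int o = 0; o < dy.n_elem; ++o) dx[idx[o]] += dy[o];
  return dx;
}

// [[Rcpp::export]]
List cpp_maxpool3(const arma::vec& x, int D, int H, int W, int C) {
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  NumericVector y(Do * Ho * Wo * C);
  IntegerVector idx(Do * Ho * Wo * C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        for (int d = 0; d < Do; ++d) {
          double best = -1e300; int bestk = 0;
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di)
              for (int dd = 0; dd < 2; ++dd) {
                const int src = (2 * d + dd) + D * ((2 * i + di) + H * ((2 * j + dj) + W * c));
                if (x[src] > best) { best = x[src]; bestk = src; }
              }
          const int o = d + Do * (i + Ho * (j + Wo * c));
          y[o] = best; idx[o] = bestk;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::vec cpp_maxpool3_bwd(const arma::vec& dy, const IntegerVector& idx,
                           int D, int H, int W, int C) {
  arma::vec dx(D * H * W * C, arma::fill::zeros);
  for (int o = 0; o < dy.n_elem; ++o) dx[idx[o]] += dy[o];
  return dx;
}

// ---- nearest-neighbour upsampling (x2) ------------------------------------

// [[Rcpp::export]]
arma::vec cpp_upsample2(const arma::vec& x, int H, int W, int C) {
  const int Ho = 2 * H, Wo = 2 * W;
  arma::vec y(Ho * Wo * C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        y[i + Ho * (j + Wo * c)] = x[(i / 2) + H * ((j / 2) + W * c)];
  return y;
}

// [[Rcpp::export]]
arma::vec cpp_upsample2_bwd(const arma::vec& dy, int H, int W, int C) {
  // H, W are the *input* (small) dims; dy has dims (2H, 2W, C)
  const int Ho = 2 * H, Wo = 2 * W;
  arma::vec dx(H * W * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        dx[(i / 2) + H * ((j / 2) + W * c)] += dy[i + Ho * (j + Wo * c)];
  return dx;
}

// [[Rcpp::export]]
arma::vec cpp_upsample3(const arma::vec& x, int D, int H, int W, int C) {
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  arma::vec y(Do * Ho * Wo * C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        for (int d = 0; d < Do; ++d)
          y[d + Do * (i + Ho * (j + Wo * c))] =
            x[(d / 2) + D * ((i / 2) + H * ((j / 2) + W * c))];
  return y;
}

// [[Rcpp::export]]
arma::vec cpp_upsample3_bwd(const arma::vec& dy, int D, int H, int W, int C) {
  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  arma::vec dx(D * H * W * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        for (int d = 0; d < Do; ++d)
          dx[(d / 2) + D * ((i / 2) + H * ((j / 2) + W * c))] +=
            dy[d + Do * (i + Ho * (j + Wo * c))];
  return dx;
}

// ---- connected components --------------------------------------------------
// 2D: 8-connectivity on an (H, W) binary mask.
// 3D: 26-connectivity on a (D, H, W) binary mask.
// Labels assigned in raster-scan discovery order, 1..n.

// [[Rcpp::export]]
IntegerVector cpp_label2(const IntegerVector& mask, int H, int W) {
  IntegerVector lab(H * W, 0);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const int v = i + H * j;
      if (mask[v] == 0 || lab[v] != 0) continue;
      ++next;
      lab[v] = next;
      stack.push_back(v);
      while (!stack.empty()) {
        const int u = stack.back(); stack.pop_back();
        const int ui = u % H, uj = u / H;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int ni = ui + di, nj = uj + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            const int n = ni + H * nj;
            if (mask[n] != 0 && lab[n] == 0) { lab[n] = next; stack.push_back(n); }
          }
        }
      }
    }
  }
  return lab;
}

// [[Rcpp::export]]
IntegerVector cpp_label3(const IntegerVector& mask, int D, int H, int W) {
  IntegerVector lab(D * H * W, 0);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      for (int d = 0; d < D; ++d) {
        const int v = d + D * (i + H * j);
        if (mask[v] == 0 || lab[v] != 0) continue;
        ++next;
        lab[v] = next;
        stack.push_back(v);
        while (!stack.empty()) {
          const int u = stack.back(); stack.pop_back();
          const int ud = u % D, ui = (u / D) % H, uj = u / (D * H);
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di)
              for (int dd = -1; dd <= 1; ++dd) {
                if (dd == 0 && di == 0 && dj == 0) continue;
                const int nd = ud + dd, ni = ui + di, nj = uj + dj;
                if (nd < 0 || nd >= D || ni < 0 || ni >= H || nj < 0 || nj >= W)
                  continue;
                const int n = nd + D * (ni + H * nj);
                if (mask[n] != 0 && lab[n] == 0) { lab[n] = next; stack.push_back(n); }
              }
        }
      }
    }
  }
  return lab;
}
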