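#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Convolution (im2col + GEMM). Tensors are arma::cube with (row, col, channel)
// = (y, x, c); weights are a (k*k*Cin) x Cout matrix whose row ordering matches
// the column-major flattening of an R array of dim (k, k, Cin, Cout):
// row = ky + k*kx + k*k*c.
// ---------------------------------------------------------------------------

static arma::mat im2col(const arma::cube &x, int k, int stride, int pad,
                        int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat out(static_cast<size_t>(Ho) * Wo, static_cast<size_t>(k) * k * C);
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const size_t col = ky + k * kx + static_cast<size_t>(k) * k * c;
        for (int ox = 0; ox < Wo; ++ox) {
          const int ix = ox * stride + kx - pad;
          for (int oy = 0; oy < Ho; ++oy) {
            const int iy = oy * stride + ky - pad;
            double v = 0.0;
            if (iy >= 0 && iy < H && ix >= 0 && ix < W) v = x(iy, ix, c);
            out(oy + static_cast<size_t>(Ho) * ox, col) = v;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube &x, const arma::mat &w, int k,
                      int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int Cout = w.n_cols;
  arma::mat cols = im2col(x, k, stride, pad, Ho, Wo);
  arma::mat y = cols * w; // (Ho*Wo) x Cout
  arma::cube out(Ho, Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = arma::reshape(y.col(c), Ho, Wo);
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd(const arma::cube &x, const arma::mat &w, const arma::cube &dy,
                int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  arma::mat dymat(static_cast<size_t>(Ho) * Wo, Cout);
  for (int c = 0; c < Cout; ++c)
    dymat.col(c) = arma::vectorise(dy.slice(c));
  arma::mat cols = im2col(x, k, stride, pad, Ho, Wo);
  arma::mat dw = cols.t() * dymat;
  arma::mat dcols = dymat * w.t(); // (Ho*Wo) x (k*k*C)
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const size_t col = ky + k * kx + static_cast<size_t>(k) * k * c;
        for (int ox = 0; ox < Wo; ++ox) {
          const int ix = ox * stride + kx - pad;
          if (ix < 0 || ix >= W) continue;
          for (int oy = 0; oy < Ho; ++oy) {
            const int iy = oy * stride + ky - pad;
            if (iy < 0 || iy >= H) continue;
            dx(iy, ix, c) += dcols(oy + static_cast<size_t>(Ho) * ox, col);
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// ---------------------------------------------------------------------------
// Factor-2 bilinear upsampling (half-pixel centers, i.e. align_corners=false).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::cube upsample2_fwd(const arma::cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = 2 * H, Wo = 2 * W;
  arma::cube out(Ho, Wo, C);
  for (int ox = 0; ox < Wo; ++ox) {
    double sx = (ox + 0.5) / 2.0 - 0.5;
    int x0 = (int)std::floor(sx);
    double fx = sx - x0;
    int x0c = std::min(std::max(x0, 0), W - 1);
    int x1c = std::min(std::max(x0 + 1, 0), W - 1);
    for (int oy = 0; oy < Ho; ++oy) {
      double sy = (oy + 0.5) / 2.0 - 0.5;
      int y0 = (int)std::floor(sy);
      double fy = sy - y0;
      int y0c = std::min(std::max(y0, 0), H - 1);
      int y1c = std::min(std::max(y0 + 1, 0), H - 1);
      for (int c = 0; c < C; ++c) {
        out(oy, ox, c) = (1 - fy) * ((1 - fx) * x(y0c, x0c, c) + fx * x(y0c, x1c, c)) +
                         fy * ((1 - fx) * x(y1c, x0c, c) + fx * x(y1c, x1c, c));
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube upsample2_bwd(const arma::cube &dy, int H, int W) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int ox = 0; ox < Wo; ++ox) {
    double sx = (ox + 0.5) / 2.0 - 0.5;
    int x0 = (int)std::floor(sx);
    double fx = sx - x0;
    int x0c = std::min(std::max(x0, 0), W - 1);
    int x1c = std::min(std::max(x0 + 1, 0), W - 1);
    for (int oy = 0; oy < Ho; ++oy) {
      double sy = (oy + 0.5) / 2.0 - 0.5;
      int y0 = (int)std::floor(sy);
      double fy = sy - y0;
      int y0c = std::min(std::max(y0, 0), H - 1);
      int y1c = std::min(std::max(y0 + 1, 0), H - 1);
      for (int c = 0; c < C; ++c) {
        const double g = dy(oy, ox, c);
        dx(y0c, x0c, c) += g * (1 - fy) * (1 - fx);
        dx(y0c, x1c, c) += g * (1 - fy) * fx;
        dx(y1c, x0c, c) += g * fy * (1 - fx);
        dx(y1c, x1c, c) += g * fy * fx;
      }
    }
  }
  return dx;
}

// ---------------------------------------------------------------------------
// Projective warp. hmat maps OUTPUT pixel coords (x, y, 1) (0-based, x = col)
// to input coords. mode: 0 = nearest, 1 = bilinear. Out-of-range -> fill.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::cube warp_perspective(const arma::cube &img, const arma::mat &hmat,
                            int out_h, int out_w, int mode, double fill) {
  const int H = img.n_rows, W = img.n_cols, C = img.n_slices;
  arma::cube out(out_h, out_w, C);
  out.fill(fill);
  for (int ox = 0; ox < out_w; ++ox) {
    for (int oy = 0; oy < out_h; ++oy) {
      double d = hmat(2, 0) * ox + hmat(2, 1) * oy + hmat(2, 2);
      if (std::abs(d) < 1e-12) continue;
      double sx = (hmat(0, 0) * ox + hmat(0, 1) * oy + hmat(0, 2)) / d;
      double sy = (hmat(1, 0) * ox + hmat(1, 1) * oy + hmat(1, 2)) / d;
      if (mode == 0) {
        int ix = (int)std::lround(sx), iy = (int)std::lround(sy);
        if (ix >= 0 && ix < W && iy >= 0 && iy < H)
          for (int c = 0; c < C; ++c) out(oy, ox, c) = img(iy, ix, c);
      } else {
        if (sx < -1 || sx > W || sy < -1 || sy > H) continue;
        int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
        double fx = sx - x0, fy = sy - y0;
        for (int c = 0; c < C; ++c) {
          double acc = 0.0;
          for (int dy2 = 0; dy2 <= 1; ++dy2) {
            for (int dx2 = 0; dx2 <= 1; ++dx2) {
              int xx = x0 + dx2, yy = y0 + dy2;
              double v = (xx >= 0 && xx < W && yy >= 0 && yy < H)
                             ? img(yy, xx, c)
                             : fill;
              acc += v * (dx2 ? fx : 1 - fx) * (dy2 ? fy : 1 - fy);
            }
          }
          out(oy, ox, c) = acc;
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Hough accumulation: each pixel votes its probability mass into
// (theta, rho = x cos theta + y sin theta), with linear splitting between the
// two neighbouring rho bins. x = 0-based column, y = 0-based row.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat hough_accum(const arma::mat &map, const arma::vec &thetas,
                      double rho_min, double rho_step, int n_rho) {
  const int H = map.n_rows, W = map.n_cols, T = thetas.n_elem;
  arma::vec ct(T), st(T);
  for (int t = 0; t < T; ++t) {
    ct[t] = std::cos(thetas[t]);
    st[t] = std::sin(thetas[t]);
  }
  arma::mat acc(T, n_rho, arma::fill::zeros);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      const double v = map(y, x);
      if (v <= 0) continue;
      for (int t = 0; t < T; ++t) {
        double rho = x * ct[t] + y * st[t];
        double f = (rho - rho_min) / rho_step;
        int i0 = (int)std::floor(f);
        double w1 = f - i0;
        if (i0 >= 0 && i0 < n_rho) acc(t, i0) += v * (1 - w1);
        if (i0 + 1 >= 0 && i0 + 1 < n_rho) acc(t, i0 + 1) += v * w1;
      }
    }
  }
  return acc;
}

// ---------------------------------------------------------------------------
// Angle-angle transform: value at (i, j) is the variance of accumulator
// samples along the segment from (theta_i, rho_min) to (theta_j, rho_max),
// one (theta-interpolated) sample per rho bin.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat angle_angle(const arma::mat &acc) {
  const int T = acc.n_rows, R = acc.n_cols;
  arma::mat out(T, T, arma::fill::zeros);
  if (R < 2) return out;
  for (int j = 0; j < T; ++j) {
    for (int i = 0; i < T; ++i) {
      double s = 0.0, s2 = 0.0;
      for (int kk = 0; kk < R; ++kk) {
        double t = i + (double)(j - i) * kk / (R - 1);
        int t0 = (int)std::floor(t);
        double ft = t - t0;
        int t0c = std::min(std::max(t0, 0), T - 1);
        int t1c = std::min(std::max(t0 + 1, 0), T - 1);
        double v = (1 - ft) * acc(t0c, kk) + ft * acc(t1c, kk);
        s += v;
        s2 += v * v;
      }
      double mu = s / R;
      out(i, j) = std::max(0.0, s2 / R - mu * mu);
    }
  }
  return out;
}

// Windowed variant: restrict (i, j) to the 0-based inclusive index ranges
// [i0, i1] x [j0, j1] (used for the fine zoom around a coarse peak).
// [[Rcpp::export]]
arma::mat angle_angle_sub(const arma::mat &acc, int i0, int i1, int j0, int j1) {
  const int T = acc.n_rows, R = acc.n_cols;
  arma::mat out(i1 - i0 + 1, j1 - j0 + 1, arma::fill::zeros);
  if (R < 2) return out;
  for (int j = j0; j <= j1; ++j) {
    for (int i = i0; i <= i1; ++i) {
      double s = 0.0, s2 = 0.0;
      for (int kk = 0; kk < R; ++kk) {
        double t = i + (double)(j - i) * kk / (R - 1);
        int t0 = (int)std::floor(t);
        double ft = t - t0;
        int t0c = std::min(std::max(t0, 0), T - 1);
        int t1c = std::min(std::max(t0 + 1, 0), T - 1);
        double v = (1 - ft) * acc(t0c, kk) + ft * acc(t1c, kk);
        s += v;
        s2 += v * v;
      }
      double mu = s / R;
      out(i - i0, j - j0) = std::max(0.0, s2 / R - mu * mu);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 8-connected component labelling of a binary mask (BFS, labels 1..n).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix label_components8(const LogicalMatrix &mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      if (!mask(y, x) || lab(y, x)) continue;
      ++next;
      stack.push_back(y + H * x);
      lab(y, x) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int py = p % H, px = p / H;
        for (int dx = -1; dx <= 1; ++dx) {
          for (int dy = -1; dy <= 1; ++dy) {
            int ny = py + dy, nx = px + dx;
            if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
            if (mask(ny, nx) && !lab(ny, nx)) {
              lab(ny, nx) = next;
              stack.push_back(ny + H * nx);
            }
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Dense linear sum assignment, Jonker-Volgenant style shortest augmenting
// paths with dual potentials. Returns, for each row, the assigned column
// (1-based). Square cost matrix.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector jv_assign(const arma::mat &cost) {
  const int n = cost.n_rows;
  if ((int)cost.n_cols != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  // potentials for rows (u) and columns (v); way[j] = previous column on path
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0); // p[j] = row matched to col j
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) {
          minv[j] = cur;
          way[j] = j0;
        }
        if (minv[j] < delta) {
          delta = minv[j];
          j1 = j;
        }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) {
          u[p[j]] += delta;
          v[j] -= delta;
        } else {
          minv[j] -= delta;
        }
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  IntegerVector rowsol(n);
  for (int j = 1; j <= n; ++j)
    if (p[j] > 0) rowsol[p[j] - 1] = j;
  return rowsol;
}

// ---------------------------------------------------------------------------
// Block max-pooling by an integer factor (used to shrink grid maps pre-Hough).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat maxpool_factor(const arma::mat &x, int f) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = (H + f - 1) / f, Wo = (W + f - 1) / f;
  arma::mat out(Ho, Wo, arma::fill::zeros);
  for (int xx = 0; xx < W; ++xx)
    for (int yy = 0; yy < H; ++yy) {
      double v = x(yy, xx);
      int oy = yy / f, ox = xx / f;
      if (v > out(oy, ox)) out(oy, ox) = v;
    }
  return out;
}

// [[Rcpp::export]]
arma::vec autocorr_raw(const arma::vec &x, int m_max) {
  const int n = x.n_elem;
  arma::vec r(m_max + 1, arma::fill::zeros);
  for (int m = 0; m <= m_max; ++m) {
    double s = 0.0;
    for (int i = 0; i + m < n; ++i) s += x[i] * x[i + m];
    r[m] = s;
  }
  return r;
}
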