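// Fast radial symmetry transform (bright-symmetry voting) and 8-connected
// component labelling. The transform follows the classic gradient-voting
// formulation: for each radius n, every pixel whose gradient magnitude
// exceeds the gradient threshold casts one vote at the positively affected
// pixel p + round(n * ghat), incrementing an orientation image O_n and
// adding |g| to a magnitude image M_n; F_n = (min(|O_n|, kappa)/kappa)^alpha
// * (M_n / kappa), smoothed with an isotropic Gaussian of sigma =
// sigma_factor * n; the response is the mean of F_n over radii.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

inline int round_half_up(double x) { return (int)std::floor(x + 0.5); }

// separable Gaussian blur with zero padding outside the image
void gauss_blur(std::vector<double>& m, int H, int W, double sigma) {
  if (sigma <= 0) return;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int j = -r; j <= r; ++j) {
    k[j + r] = std::exp(-0.5 * (double)j * j / (sigma * sigma));
    s += k[j + r];
  }
  for (double& v : k) v /= s;
  std::vector<double> tmp((std::size_t)H * W, 0.0);
  // along rows (y direction)
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      double acc = 0.0;
      for (int j = -r; j <= r; ++j) {
        const int yy = y + j;
        if (yy >= 0 && yy < H) acc += k[j + r] * m[yy + (std::size_t)x * H];
      }
      tmp[y + (std::size_t)x * H] = acc;
    }
  }
  // along columns (x direction)
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      double acc = 0.0;
      for (int j = -r; j <= r; ++j) {
        const int xx = x + j;
        if (xx >= 0 && xx < W) acc += k[j + r] * tmp[y + (std::size_t)xx * H];
      }
      m[y + (std::size_t)x * H] = acc;
    }
  }
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_frst(NumericMatrix map, IntegerVector radii, double alpha,
                       double beta, bool beta_absolute, double kappa_small,
                       double kappa_large, double sigma_factor) {
  const int H = map.nrow(), W = map.ncol();
  if (radii.size() == 0) stop("empty radius set");
  std::vector<double> gx((std::size_t)H * W, 0.0), gy((std::size_t)H * W, 0.0),
      gmag((std::size_t)H * W, 0.0);
  double maxg = 0.0;
  for (int x = 1; x < W - 1; ++x) {
    for (int y = 1; y < H - 1; ++y) {
      const std::size_t i = y + (std::size_t)x * H;
      const double dx = (map(y, x + 1) - map(y, x - 1)) / 2.0;
      const double dy = (map(y + 1, x) - map(y - 1, x)) / 2.0;
      gx[i] = dx;
      gy[i] = dy;
      gmag[i] = std::sqrt(dx * dx + dy * dy);
      if (gmag[i] > maxg) maxg = gmag[i];
    }
  }
  NumericMatrix S(H, W);
  if (maxg == 0.0) return S;  // flat map: no gradients, no votes
  const double thr = beta_absolute ? beta : beta * maxg;

  std::vector<double> O((std::size_t)H * W), M((std::size_t)H * W),
      F((std::size_t)H * W);
  for (int ri = 0; ri < radii.size(); ++ri) {
    const int n = radii[ri];
    if (n < 1) stop("radii must be >= 1 px");
    std::fill(O.begin(), O.end(), 0.0);
    std::fill(M.begin(), M.end(), 0.0);
    for (int x = 1; x < W - 1; ++x) {
      for (int y = 1; y < H - 1; ++y) {
        const std::size_t i = y + (std::size_t)x * H;
        if (gmag[i] <= thr) continue;
        const int qx = x + round_half_up(n * gx[i] / gmag[i]);
        const int qy = y + round_half_up(n * gy[i] / gmag[i]);
        if (qx < 0 || qx >= W || qy < 0 || qy >= H) continue;
        const std::size_t q = qy + (std::size_t)qx * H;
        O[q] += 1.0;
        M[q] += gmag[i];
      }
    }
    const double kappa = (n == 1) ? kappa_small : kappa_large;
    for (std::size_t i = 0; i < O.size(); ++i) {
      const double o = std::min(std::abs(O[i]), kappa);
      F[i] = std::pow(o / kappa, alpha) * (M[i] / kappa);
    }
    gauss_blur(F, H, W, sigma_factor * n);
    for (std::size_t i = 0; i < F.size(); ++i) S[i] += F[i];
  }
  const double nr = (double)radii.size();
  for (std::size_t i = 0; i < (std::size_t)H * W; ++i) S[i] /= nr;
  return S;
}

// 8-connected component labelling of a logical mask; labels 1..n in
// first-encounter (column-major scan) order, 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::size_t> stack;
  for (std::size_t i = 0; i < (std::size_t)H * W; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      const std::size_t cur = stack.back();
      stack.pop_back();
      const int y = cur % H, x = cur / H;
      for (int ddx = -1; ddx <= 1; ++ddx) {
        for (int ddy = -1; ddy <= 1; ++ddy) {
          if (ddx == 0 && ddy == 0) continue;
          const int ny = y + ddy, nx = x + ddx;
          if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
          const std::size_t ni = ny + (std::size_t)nx * H;
          if (mask[ni] && lab[ni] == 0) {
            lab[ni] = next;
            stack.push_back(ni);
          }
        }
      }
    }
  }
  return lab;
}
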