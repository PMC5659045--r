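#include <Rcpp.h>
using namespace Rcpp;

// Coupled anisotropic diffusion, explicit Euler with replicated borders.
// u moves by edge-gated mean-curvature flow plus fidelity toward M; v by
// curvature flow weighted by the schedule a[n-1] (its per-iteration update
// is magnitude-limited for stability under the large early weights) with
// coupling b toward u. Both fields are clamped to [0,1]; pixels where
// fov == 0 stay frozen at M.
// [[Rcpp::export(name = ".diffuse_cpp")]]
NumericMatrix diffuse_cpp(NumericMatrix M, NumericVector a_sched, double b,
                          double l, double dt, LogicalMatrix fov) {
  const int H = M.nrow(), W = M.ncol();
  const int iterations = a_sched.size();
  NumericMatrix u(clone(M)), v(clone(M)), un(H, W), vn(H, W);
  const double eps_g = 1e-6, cap = 0.05;
  auto clampi = [](int i, int n) { return i < 0 ? 0 : (i >= n ? n - 1 : i); };
  for (int n = 0; n < iterations; ++n) {
    const double a_n = a_sched[n];
    for (int j = 0; j < W; ++j) {
      const int jm = clampi(j - 1, W), jp = clampi(j + 1, W);
      for (int i = 0; i < H; ++i) {
        if (!fov(i, j)) { un(i, j) = M(i, j); vn(i, j) = M(i, j); continue; }
        const int im = clampi(i - 1, H), ip = clampi(i + 1, H);
        // gradients of v (central differences)
        const double vx = (v(i, jp) - v(i, jm)) / 2.0;
        const double vy = (v(ip, j) - v(im, j)) / 2.0;
        const double g = 1.0 / (1.0 + l * (vx * vx + vy * vy));
        // |grad u| * curvature(u)
        const double ux = (u(i, jp) - u(i, jm)) / 2.0;
        const double uy = (u(ip, j) - u(im, j)) / 2.0;
        const double uxx = u(i, jp) - 2.0 * u(i, j) + u(i, jm);
        const double uyy = u(ip, j) - 2.0 * u(i, j) + u(im, j);
        const double uxy = (u(ip, jp) - u(ip, jm) - u(im, jp) + u(im, jm)) / 4.0;
        const double ug2 = ux * ux + uy * uy;
        const double ucurv = (uxx * uy * uy - 2.0 * ux * uy * uxy +
                              uyy * ux * ux) / (ug2 + eps_g);
        const double du = g * ucurv - (1.0 - g) * (u(i, j) - M(i, j));
        // curvature(v)
        const double vxx = v(i, jp) - 2.0 * v(i, j) + v(i, jm);
        const double vyy = v(ip, j) - 2.0 * v(i, j) + v(im, j);
        const double vxy = (v(ip, jp) - v(ip, jm) - v(im, jp) + v(im, jm)) / 4.0;
        const double vg2 = vx * vx + vy * vy;
        const double vcurv = (vxx * vy * vy - 2.0 * vx * vy * vxy +
                              vyy * vx * vx) / std::pow(vg2 + eps_g, 1.5);
        double dvc = dt * a_n * vcurv;
        if (dvc > cap) dvc = cap; else if (dvc < -cap) dvc = -cap;
        double uu = u(i, j) + dt * du;
        double vv = v(i, j) + dvc - dt * b * (v(i, j) - u(i, j));
        if (!std::isfinite(uu) || !std::isfinite(vv))
          stop("non-finite values in diffusion at iteration %d", n + 1);
        un(i, j) = uu < 0.0 ? 0.0 : (uu > 1.0 ? 1.0 : uu);
        vn(i, j) = vv < 0.0 ? 0.0 : (vv > 1.0 ? 1.0 : vv);
      }
    }
    std::swap(u, un);
    std::swap(v, vn);
  }
  return u;
}
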