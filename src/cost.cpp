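#include <Rcpp.h>
using namespace Rcpp;

// Weighted squared-nearest-neighbor cost between centroids and a
// transformed template:
//   C = sqrt(D + 1) / n * sum_i (|A_i - B_i| * P_i * S_i)^2
// B_i is the transformed template site nearest to centroid A_i (ties ->
// lowest site index), P_i = W_O when B_i is a filled orientation marker,
// D = number of filled markers that are nearest site to no centroid.

static double cost2d_core(const NumericMatrix& A, const NumericVector& S,
                          const std::vector<double>& tx,
                          const std::vector<double>& ty,
                          const LogicalVector& marker, double WO,
                          IntegerVector* assign_out) {
  const int n = A.nrow(), m = tx.size();
  std::vector<bool> hit(m, false);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bj = 0;
    const double ax = A(i, 0), ay = A(i, 1);
    for (int j = 0; j < m; ++j) {
      const double dx = ax - tx[j], dy = ay - ty[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; bj = j; }
    }
    hit[bj] = true;
    const double w = (marker[bj] ? WO : 1.0) * S[i];
    acc += best * w * w;
    if (assign_out) (*assign_out)[i] = bj + 1;
  }
  int D = 0;
  for (int j = 0; j < m; ++j)
    if (marker[j] && !hit[j]) ++D;
  if (assign_out) assign_out->attr("D") = D;
  return std::sqrt((double)(D + 1)) / n * acc;
}

// [[Rcpp::export]]
List cost_2d_cpp(NumericMatrix A, NumericVector S, NumericMatrix T,
                 LogicalVector marker, double WO) {
  const int m = T.nrow();
  std::vector<double> tx(m), ty(m);
  for (int j = 0; j < m; ++j) { tx[j] = T(j, 0); ty[j] = T(j, 1); }
  IntegerVector assign(A.nrow());
  double C = cost2d_core(A, S, tx, ty, marker, WO, &assign);
  int D = assign.attr("D");
  assign.attr("D") = R_NilValue;
  return List::create(_["cost"] = C, _["assignment"] = assign, _["D"] = D);
}

// Coarse grid search over rotation x translation (scales fixed at 1):
// the template is rotated about its centroid, then shifted so its centroid
// lands on `center` plus each translation offset.
// [[Rcpp::export]]
List coarse_align_2d_cpp(NumericMatrix A, NumericVector S, NumericMatrix T,
                         LogicalVector marker, double WO,
                         NumericVector thetas, NumericVector dxs,
                         NumericVector dys, NumericVector center) {
  const int n = A.nrow(), m = T.nrow();
  double cx = 0.0, cy = 0.0;
  for (int j = 0; j < m; ++j) { cx += T(j, 0); cy += T(j, 1); }
  cx /= m; cy /= m;
  double best = R_PosInf, bt = 0, bx = 0, by = 0;
  std::vector<double> rx(m), ry(m), tx(m), ty(m);
  for (int it = 0; it < thetas.size(); ++it) {
    const double th = thetas[it] * M_PI / 180.0;
    const double c = std::cos(th), s = std::sin(th);
    for (int j = 0; j < m; ++j) {
      const double x0 = T(j, 0) - cx, y0 = T(j, 1) - cy;
      rx[j] = c * x0 - s * y0;
      ry[j] = s * x0 + c * y0;
    }
    for (int ix = 0; ix < dxs.size(); ++ix) {
      for (int iy = 0; iy < dys.size(); ++iy) {
        const double ox = center[0] + dxs[ix], oy = center[1] + dys[iy];
        for (int j = 0; j < m; ++j) { tx[j] = rx[j] + ox; ty[j] = ry[j] + oy; }
        const double C = cost2d_core(A, S, tx, ty, marker, WO, nullptr);
        if (C < best) { best = C; bt = thetas[it]; bx = ox; by = oy; }
      }
    }
  }
  return List::create(_["cost"] = best, _["theta"] = bt,
                      _["ox"] = bx, _["oy"] = by);
}

// Unweighted squared-nearest-neighbor cost in 3D: C = sum_i |A_i - B_i|^2
// [[Rcpp::export]]
List cost_3d_cpp(NumericMatrix A, NumericMatrix T) {
  const int n = A.nrow(), m = T.nrow();
  IntegerVector assign(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < m; ++j) {
      const double dx = A(i, 0) - T(j, 0);
      const double dy = A(i, 1) - T(j, 1);
      const double dz = A(i, 2) - T(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    acc += best;
    assign[i] = bj + 1;
  }
  return List::create(_["cost"] = acc, _["assignment"] = assign);
}

// 3D grid search: the template z is divided by each candidate z_scale
// (modelling the axial compression of the imaged structure relative to the
// design), the template is rotated about z through its centroid and shifted
// so its centroid lands on the centroids' COM plus an (x, y, z) offset.
// Returns the minimal-cost grid node.
// [[Rcpp::export]]
List grid_align_3d_cpp(NumericMatrix A, NumericMatrix T,
                       NumericVector z_scales, NumericVector phis,
                       NumericVector dxs, NumericVector dys,
                       NumericVector dzs) {
  const int n = A.nrow(), m = T.nrow();
  double tcx = 0, tcy = 0, tcz = 0;
  for (int j = 0; j < m; ++j) { tcx += T(j, 0); tcy += T(j, 1); tcz += T(j, 2); }
  tcx /= m; tcy /= m; tcz /= m;

  double acx = 0, acy = 0, acz = 0;
  for (int i = 0; i < n; ++i) {
    acx += A(i, 0); acy += A(i, 1); acz += A(i, 2);
  }
  acx /= n; acy /= n; acz /= n;

  const int np = phis.size();
  NumericVector bcost(np, R_PosInf), bzs(np), bx(np), by(np), bz(np);
  std::vector<double> ax(n), ay(n), az(n);
  for (int i = 0; i < n; ++i) { ax[i] = A(i, 0); ay[i] = A(i, 1); az[i] = A(i, 2); }
  std::vector<double> rx(m), ry(m), rz(m);
  for (int is = 0; is < z_scales.size(); ++is) {
    const double zs = z_scales[is];
    for (int ip = 0; ip < np; ++ip) {
      const double ph = phis[ip] * M_PI / 180.0;
      const double c = std::cos(ph), s = std::sin(ph);
      for (int j = 0; j < m; ++j) {
        const double x0 = T(j, 0) - tcx, y0 = T(j, 1) - tcy;
        rx[j] = c * x0 - s * y0;
        ry[j] = s * x0 + c * y0;
        rz[j] = (T(j, 2) - tcz) / zs;
      }
      for (int ix = 0; ix < dxs.size(); ++ix) {
        for (int iy = 0; iy < dys.size(); ++iy) {
          for (int iz = 0; iz < dzs.size(); ++iz) {
            const double ox = acx + dxs[ix], oy = acy + dys[iy];
            const double oz = acz + dzs[iz];
            double acc = 0.0;
            for (int i = 0; i < n; ++i) {
              double bd = R_PosInf;
              for (int j = 0; j < m; ++j) {
                const double dx = ax[i] - (rx[j] + ox);
                const double dy = ay[i] - (ry[j] + oy);
                const double dz = az[i] - (rz[j] + oz);
                const double d2 = dx * dx + dy * dy + dz * dz;
                if (d2 < bd) bd = d2;
              }
              acc += bd;
              if (acc >= bcost[ip]) break;
            }
            if (acc < bcost[ip]) {
              bcost[ip] = acc; bzs[ip] = zs;
              bx[ip] = ox; by[ip] = oy; bz[ip] = oz;
            }
          }
        }
      }
    }
  }
  // best grid node per candidate rotation: rotationally degenerate layouts
  // produce near-tied minima that the caller disambiguates by marker roles
  return List::create(_["phi"] = phis, _["cost"] = bcost, _["z_scale"] = bzs,
                      _["ox"] = bx, _["oy"] = by, _["oz"] = bz);
}
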