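#include <Rcpp.h>
using namespace Rcpp;

// Tissue label coding shared with the R layer:
// 0 = outside, 1 = white matter, 2 = cortex, 3 = pial/CSF.

// Gauss-Seidel relaxation of the discrete Laplace equation on the cortical
// ribbon. Dirichlet conditions sit on the tissue interfaces (the faces
// between a cortex voxel and a white-matter or pial/CSF neighbour): 0 on the
// white-matter side, 1 on the pial side. Boundary neighbours are folded in
// as ghost values 2*phi_D - phi_i, which places the condition half a voxel
// from the cortex voxel centre and keeps the stencil second-order at the
// boundary. Outside voxels carry no condition (zero flux at the volume
// edge). Sweeps stop when the largest in-sweep update falls below `tol`.
// [[Rcpp::export]]
List laplace_gauss_seidel(IntegerVector labels, double tol, int max_iter) {
  IntegerVector dim = labels.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = labels.size();

  NumericVector phi(n, NA_REAL);
  std::vector<R_xlen_t> cortex;
  cortex.reserve(n / 4);
  for (R_xlen_t i = 0; i < n; ++i)
    if (labels[i] == 2) { phi[i] = 0.5; cortex.push_back(i); }

  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  LogicalVector isolated(n, false);

  double max_update = R_PosInf;
  int iter = 0;
  while (iter < max_iter && max_update >= tol) {
    max_update = 0.0;
    for (size_t c = 0; c < cortex.size(); ++c) {
      const R_xlen_t i = cortex[c];
      const int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / sz);
      double sum = 0.0;      // cortex neighbours + 2 * sum of face values
      int n_used = 0;        // neighbours carrying any condition
      int n_bound = 0;       // of which boundary (ghost) neighbours
      const R_xlen_t nb[6] = {
        (x > 0)      ? i - sx : (R_xlen_t)-1,
        (x < nx - 1) ? i + sx : (R_xlen_t)-1,
        (y > 0)      ? i - sy : (R_xlen_t)-1,
        (y < ny - 1) ? i + sy : (R_xlen_t)-1,
        (z > 0)      ? i - sz : (R_xlen_t)-1,
        (z < nz - 1) ? i + sz : (R_xlen_t)-1 };
      for (int k = 0; k < 6; ++k) {
        if (nb[k] < 0) continue;
        const int lab = labels[nb[k]];
        if (lab == 2) { sum += phi[nb[k]]; ++n_used; }
        else if (lab == 1) { ++n_used; ++n_bound; }            // face value 0
        else if (lab == 3) { sum += 2.0; ++n_used; ++n_bound; } // face value 1
      }
      if (n_used == 0) { isolated[i] = true; continue; }
      const double next = sum / (n_used + n_bound);
      const double d = std::abs(next - phi[i]);
      if (d > max_update) max_update = d;
      phi[i] = next;
    }
    ++iter;
  }

  phi.attr("dim") = dim;
  isolated.attr("dim") = dim;
  return List::create(_["potential"] = phi,
                      _["iterations"] = iter,
                      _["residual"] = max_update,
                      _["converged"] = (max_update < tol),
                      _["isolated"] = isolated);
}
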