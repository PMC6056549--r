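// d-dimensional convex hull volume by the incremental beneath-beyond
// method. Volume is accumulated as points are added: each exterior point
// contributes the union of cones from itself over the facets it sees.
// Inputs of affine rank < d have zero d-volume by contract.
#include <RcppArmadillo.h>
#include <map>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::mat;
using arma::vec;
using arma::uvec;

namespace {

struct Facet {
  std::vector<arma::uword> verts;  // d vertex row indices, sorted
  vec normal;                      // outward unit normal
  double offset;                   // normal . x = offset on the facet plane
};

// outward-oriented facet; interior is any strictly interior point
bool make_facet(const mat& X, const std::vector<arma::uword>& verts,
                const vec& interior, double tol, Facet& out) {
  const arma::uword d = X.n_cols;
  mat A(d - 1, d);
  for (arma::uword i = 1; i < d; ++i)
    A.row(i - 1) = X.row(verts[i]) - X.row(verts[0]);
  mat N = arma::null(A.n_rows ? A : mat(1, d, arma::fill::zeros));
  if (N.n_cols == 0) return false;
  vec n = N.col(0);
  double off = arma::dot(n, X.row(verts[0]).t());
  double side = arma::dot(n, interior) - off;
  if (std::abs(side) < tol && N.n_cols > 1) return false;  // degenerate
  if (side > 0) { n = -n; off = -off; }
  out.verts = verts;
  std::sort(out.verts.begin(), out.verts.end());
  out.normal = n;
  out.offset = off;
  return true;
}

// verts holds d rows (apex supplied) or d+1 rows (apex = last vertex)
double simplex_volume(const mat& X, const std::vector<arma::uword>& verts,
                      const vec* apex) {
  const arma::uword d = X.n_cols;
  mat M(d, d);
  const vec base = apex ? *apex : vec(X.row(verts[d]).t());
  for (arma::uword i = 0; i < d; ++i)
    M.col(i) = X.row(verts[i]).t() - base;
  double v = std::abs(arma::det(M));
  for (arma::uword i = 2; i <= d; ++i) v /= static_cast<double>(i);
  return v;
}

}  // namespace

// [[Rcpp::export]]
double hull_volume_cpp(const arma::mat& X) {
  const arma::uword n = X.n_rows, d = X.n_cols;
  if (d == 0 || n == 0) return 0.0;
  if (d == 1) return X.col(0).max() - X.col(0).min();
  if (n <= d) return 0.0;

  double spread = 0.0;
  for (arma::uword j = 0; j < d; ++j)
    spread = std::max(spread, X.col(j).max() - X.col(j).min());
  if (spread <= 0.0) return 0.0;
  const double tol = 1e-9 * spread;

  // seed simplex: d+1 affinely independent rows found greedily
  std::vector<arma::uword> seed;
  seed.push_back(0);
  mat B(d, 0);  // orthonormalized directions from X.row(seed[0])
  for (arma::uword i = 1; i < n && seed.size() < d + 1; ++i) {
    vec v = (X.row(i) - X.row(seed[0])).t();
    vec r = v - B * (B.t() * v);
    if (arma::norm(r) > tol) {
      B.insert_cols(B.n_cols, r / arma::norm(r));
      seed.push_back(i);
    }
  }
  if (seed.size() < d + 1) return 0.0;  // affinely degenerate input

  vec interior(d, arma::fill::zeros);
  for (arma::uword i = 0; i <= d; ++i) interior += X.row(seed[i]).t();
  interior /= static_cast<double>(d + 1);

  std::vector<Facet> facets;
  for (arma::uword skip = 0; skip <= d; ++skip) {
    std::vector<arma::uword> verts;
    for (arma::uword i = 0; i <= d; ++i)
      if (i != skip) verts.push_back(seed[i]);
    Facet f;
    if (make_facet(X, verts, interior, tol, f)) facets.push_back(f);
  }

  double volume = simplex_volume(X, seed, nullptr);

  std::vector<bool> used(n, false);
  for (arma::uword i = 0; i < seed.size(); ++i) used[seed[i]] = true;

  for (arma::uword p = 0; p < n; ++p) {
    if (used[p]) continue;
    const vec xp = X.row(p).t();
    std::vector<size_t> visible;
    for (size_t f = 0; f < facets.size(); ++f)
      if (arma::dot(facets[f].normal, xp) - facets[f].offset > tol)
        visible.push_back(f);
    if (visible.empty()) continue;

    // horizon ridges: (d-1)-subsets seen by exactly one visible facet
    std::map<std::vector<arma::uword>, int> ridge_count;
    for (size_t vi : visible) {
      for (arma::uword drop = 0; drop < d; ++drop) {
        std::vector<arma::uword> ridge;
        for (arma::uword i = 0; i < d; ++i)
          if (i != drop) ridge.push_back(facets[vi].verts[i]);
        ++ridge_count[ridge];
      }
    }

    for (size_t vi : visible)
      volume += simplex_volume(X, facets[vi].verts, &xp);

    std::vector<Facet> next;
    std::vector<bool> is_visible(facets.size(), false);
    for (size_t vi : visible) is_visible[vi] = true;
    for (size_t f = 0; f < facets.size(); ++f)
      if (!is_visible[f]) next.push_back(facets[f]);
    for (std::map<std::vector<arma::uword>, int>::const_iterator it =
             ridge_count.begin();
         it != ridge_count.end(); ++it) {
      if (it->second != 1) continue;
      std::vector<arma::uword> verts = it->first;
      verts.push_back(p);
      Facet f;
      if (make_facet(X, verts, interior, tol, f)) next.push_back(f);
    }
    facets.swap(next);
  }
  return volume;
}
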