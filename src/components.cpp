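#include <Rcpp.h>
using namespace Rcpp;

// 26-connectivity connected-component labeling on a 3-D logical grid via
// union-find over the selected voxels.  Input is the vector of selected
// 1-based linear indices (column-major, x fastest) plus the grid dims;
// output is a component label (1..n_components) per selected voxel, with
// components numbered by their smallest contained linear index.

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// [[Rcpp::export]]
IntegerVector label_components_26(const IntegerVector& idx,
                                  const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int m = idx.size();
  IntegerVector labels(m);
  if (m == 0) return labels;

  // map linear index -> position in idx (idx is sorted ascending by caller)
  std::unordered_map<int, int> pos;
  pos.reserve(m * 2);
  for (int k = 0; k < m; ++k) pos[idx[k]] = k;

  std::vector<int> parent(m);
  for (int k = 0; k < m; ++k) parent[k] = k;

  for (int k = 0; k < m; ++k) {
    int lin = idx[k] - 1;
    int x = lin % nx, y = (lin / nx) % ny, z = lin / (nx * ny);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          int nlin = xx + nx * (yy + ny * zz) + 1;
          auto it = pos.find(nlin);
          if (it == pos.end()) continue;
          int ra = uf_find(parent, k), rb = uf_find(parent, it->second);
          if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
        }
  }

  // number components by smallest contained linear index; since idx is
  // sorted and roots are minimal positions, first occurrence order works
  std::unordered_map<int, int> comp_id;
  int next = 0;
  for (int k = 0; k < m; ++k) {
    int r = uf_find(parent, k);
    auto it = comp_id.find(r);
    if (it == comp_id.end()) { comp_id[r] = ++next; labels[k] = next; }
    else labels[k] = it->second;
  }
  return labels;
}
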