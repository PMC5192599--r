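#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Seeded priority-flood watershed on a scalar surface, 4-connected.
// Lower surface values flood first; ties resolve in insertion (FIFO) order,
// which on a flat surface reduces to multi-source breadth-first growth.
// seeds: matrix with columns (id, row, col), 1-based coordinates.
// mask: optional logical matrix; pixels outside it stay 0.
// [[Rcpp::export]]
IntegerMatrix watershed_cpp(NumericMatrix grad, IntegerMatrix seeds,
                            Nullable<LogicalMatrix> mask_) {
  const int H = grad.nrow(), W = grad.ncol();
  IntegerMatrix labels(H, W);
  std::vector<char> inmask((size_t)H * W, 1);
  if (mask_.isNotNull()) {
    LogicalMatrix mask(mask_);
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        inmask[(size_t)j * H + i] = mask(i, j) ? 1 : 0;
  }

  struct Node {
    double value;
    unsigned long order;
    int y, x, label;
  };
  struct Cmp {
    bool operator()(const Node& a, const Node& b) const {
      if (a.value != b.value) return a.value > b.value;  // min-heap on value
      return a.order > b.order;                          // FIFO on ties
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  unsigned long counter = 0;

  const int ns = seeds.nrow();
  for (int s = 0; s < ns; ++s) {
    int id = seeds(s, 0), y = seeds(s, 1) - 1, x = seeds(s, 2) - 1;
    if (y < 0 || y >= H || x < 0 || x >= W)
      stop("seed %d at (%d, %d) lies outside the image", id, y + 1, x + 1);
    pq.push(Node{grad(y, x), counter++, y, x, id});
  }

  const int dy[4] = {-1, 1, 0, 0};
  const int dx[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    if (labels(nd.y, nd.x) != 0) continue;
    if (!inmask[(size_t)nd.x * H + nd.y]) continue;
    labels(nd.y, nd.x) = nd.label;
    for (int k = 0; k < 4; ++k) {
      int yy = nd.y + dy[k], xx = nd.x + dx[k];
      if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
      if (labels(yy, xx) != 0) continue;
      if (!inmask[(size_t)xx * H + yy]) continue;
      pq.push(Node{grad(yy, xx), counter++, yy, xx, nd.label});
    }
  }
  return labels;
}
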