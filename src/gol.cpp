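#include <Rcpp.h>
using namespace Rcpp;

// Conway B3/S23 rule, synchronous update, toroidal (wrap-around) boundary.
// [[Rcpp::export]]
IntegerMatrix gol_evolve_cpp(IntegerMatrix grid, int steps) {
  int H = grid.nrow(), W = grid.ncol();
  IntegerMatrix cur = clone(grid), nxt(H, W);
  for (int s = 0; s < steps; ++s) {
    for (int i = 0; i < H; ++i) {
      int im = (i + H - 1) % H, ip = (i + 1) % H;
      for (int j = 0; j < W; ++j) {
        int jm = (j + W - 1) % W, jp = (j + 1) % W;
        int nb = cur(im, jm) + cur(im, j) + cur(im, jp)
               + cur(i, jm) + cur(i, jp)
               + cur(ip, jm) + cur(ip, j) + cur(ip, jp);
        nxt(i, j) = (nb == 3 || (nb == 2 && cur(i, j))) ? 1 : 0;
      }
    }
    IntegerMatrix tmp = cur; cur = nxt; nxt = tmp;
  }
  return cur;
}
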