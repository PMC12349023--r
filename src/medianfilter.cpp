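#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Square median filter with reflected borders for 8-bit-scale images.
// Direct nth_element per window: O(H * W * k^2), ample for the small odd
// kernels (3-7 px) used to suppress salt-and-pepper sensor noise.

// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int k) {
  const int H = img.nrow(), W = img.ncol(), r = k / 2;
  NumericMatrix out(H, W);
  std::vector<double> win;
  win.reserve((size_t) k * k);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      win.clear();
      for (int dy = -r; dy <= r; ++dy) {
        int yy = y + dy;
        if (yy < 0) yy = -yy - 1;            // reflect
        if (yy >= H) yy = 2 * H - yy - 1;
        for (int dx = -r; dx <= r; ++dx) {
          int xx = x + dx;
          if (xx < 0) xx = -xx - 1;
          if (xx >= W) xx = 2 * W - xx - 1;
          win.push_back(img(yy, xx));
        }
      }
      std::nth_element(win.begin(), win.begin() + win.size() / 2, win.end());
      out(y, x) = win[win.size() / 2];
    }
  }
  return out;
}
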