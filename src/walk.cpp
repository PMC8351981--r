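#include <Rcpp.h>
using namespace Rcpp;

// Sample an index in [0, len) from cumulative weights cum[off .. off+len-1]
// (last entry equals the total). Linear scan: neighbourhoods and layer
// counts are small.
static inline int sample_cum(const double *cum, int off, int len, double total) {
  double u = unif_rand() * total;
  for (int m = 0; m < len - 1; ++m) {
    if (u < cum[off + m]) return m;
  }
  return len - 1;
}

// Biased random walk with random restart over a multilayer network.
//
// State arrays are flattened per (layer, node): segment s = l * n + i of
// nbr_idx/nbr_cum (delimited by nbr_ptr, 0-based offsets) holds node i's
// neighbour indices in layer l and the cumulative unnormalized move scores.
// inter is an n * k * k array of layer-switch scores, node-major then
// source-layer row: inter[(i * k + ls) * k + lt].
//
// Each iteration: move to a neighbour sampled from the rescaled scores
// (scoring it); with probability jump_prob return to the seed (scoring it);
// with probability change_prob resample the layer from the inter row of the
// current node. A walker stuck without in-layer neighbours first forces a
// layer change restricted to layers where it has neighbours, and if
// isolated everywhere moves to the seed instead. Uses R's RNG.
// [[Rcpp::export(name = ".walk_cpp")]]
List walk_cpp(int n, int k, int seed0, double t_steps, double jump_prob,
              double change_prob, IntegerVector nbr_ptr, IntegerVector nbr_idx,
              NumericVector nbr_cum, NumericVector inter) {
  RNGScope scope;
  std::vector<double> counts(n, 0.0);
  double jumps = 0.0;

  int cur = seed0;
  counts[cur] += 1.0;
  int layer = (int)(unif_rand() * k);
  if (layer >= k) layer = k - 1;

  std::vector<double> lw(k);

  for (double step = 0; step < t_steps; ++step) {
    int seg = layer * n + cur;
    int off = nbr_ptr[seg], len = nbr_ptr[seg + 1] - off;

    if (len == 0) {
      // stuck: force a layer change towards layers with neighbours
      double tot = 0.0;
      for (int lt = 0; lt < k; ++lt) {
        int s2 = lt * n + cur;
        lw[lt] = (nbr_ptr[s2 + 1] > nbr_ptr[s2])
                     ? inter[(cur * k + layer) * k + lt]
                     : 0.0;
        tot += lw[lt];
      }
      if (tot > 0.0) {
        double u = unif_rand() * tot, acc = 0.0;
        int pick = k - 1;
        for (int lt = 0; lt < k; ++lt) {
          acc += lw[lt];
          if (u < acc) { pick = lt; break; }
        }
        layer = pick;
        seg = layer * n + cur;
        off = nbr_ptr[seg];
        len = nbr_ptr[seg + 1] - off;
      } else {
        // isolated in every layer: the move lands on the seed
        cur = seed0;
        counts[cur] += 1.0;
        goto after_move;
      }
    }

    {
      double total = nbr_cum[off + len - 1];
      int m = sample_cum(REAL(nbr_cum), off, len, total);
      cur = nbr_idx[off + m];
      counts[cur] += 1.0;
    }

  after_move:
    if (unif_rand() < jump_prob) {
      cur = seed0;
      counts[cur] += 1.0;
      jumps += 1.0;
    }
    if (change_prob > 0.0 && k > 1 && unif_rand() < change_prob) {
      double tot = 0.0;
      for (int lt = 0; lt < k; ++lt) {
        lw[lt] = inter[(cur * k + layer) * k + lt];
        tot += lw[lt];
      }
      double u = unif_rand() * tot, acc = 0.0;
      int pick = k - 1;
      for (int lt = 0; lt < k; ++lt) {
        acc += lw[lt];
        if (u < acc) { pick = lt; break; }
      }
      layer = pick;
    }
  }

  return List::create(_["counts"] = NumericVector(counts.begin(), counts.end()),
                      _["jumps"] = jumps);
}
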