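#include <Rcpp.h>
using namespace Rcpp;

// Generalized (Sankoff) parsimony on one character.
//
// edge: postorder edge matrix (parent, child), ape node numbering
//       (tips 1..n_tip, internal nodes from n_tip+1, root last parent).
// tip_state: per tip, 1-based index into the character's state set, or 0
//            when the taxon is missing from the gene (all-zero leaf vector,
//            i.e. standard missing data).
// cost: k x k symmetric step matrix.
//
// Internal nodes range over the observed states only, matching PAUP
// step-matrix (USERTYPE) semantics: no hypothetical intermediate states.
static double sankoff_one(const IntegerMatrix &edge, int n_tip,
                          const int *tip_state, const NumericMatrix &cost,
                          std::vector<double> &buf) {
  const int k = cost.nrow();
  const int n_edge = edge.nrow();
  const int root = edge(n_edge - 1, 0);
  int max_node = root;
  for (int e = 0; e < n_edge; ++e) {
    if (edge(e, 0) > max_node) max_node = edge(e, 0);
    if (edge(e, 1) > max_node) max_node = edge(e, 1);
  }
  const double INF = std::numeric_limits<double>::infinity();
  buf.assign((size_t)max_node * k, 0.0);
  // leaves
  for (int t = 0; t < n_tip; ++t) {
    double *v = &buf[(size_t)t * k];
    int s = tip_state[t];
    if (s > 0) {
      for (int j = 0; j < k; ++j) v[j] = INF;
      v[s - 1] = 0.0;
    } // s == 0: missing taxon, all-zero vector
  }
  // postorder accumulation
  for (int e = 0; e < n_edge; ++e) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    double *vp = &buf[(size_t)p * k];
    const double *vc = &buf[(size_t)c * k];
    for (int s = 0; s < k; ++s) {
      double m = INF;
      for (int t = 0; t < k; ++t) {
        const double w = vc[t] + cost(s, t);
        if (w < m) m = w;
      }
      vp[s] += m;
    }
  }
  const double *vr = &buf[(size_t)(root - 1) * k];
  double best = INF;
  for (int s = 0; s < k; ++s)
    if (vr[s] < best) best = vr[s];
  return best;
}

// [[Rcpp::export]]
double sankoff_char_cpp(IntegerMatrix edge, int n_tip, IntegerVector tip_state,
                        NumericMatrix cost) {
  std::vector<double> buf;
  return sankoff_one(edge, n_tip, INTEGER(tip_state), cost, buf);
}

// Score a whole character matrix on one topology.
// tip_states: integer matrix, n_tip x n_char (column = one character).
// costs: list of k_i x k_i step matrices; weights: per-character weight.
// [[Rcpp::export]]
double sankoff_matrix_cpp(IntegerMatrix edge, int n_tip,
                          IntegerMatrix tip_states, List costs,
                          NumericVector weights) {
  const int n_char = tip_states.ncol();
  std::vector<double> buf;
  double total = 0.0;
  for (int i = 0; i < n_char; ++i) {
    if (weights[i] == 0.0) continue; // bootstrap zero-weight characters
    NumericMatrix cost = costs[i];
    total += weights[i] *
             sankoff_one(edge, n_tip, &tip_states(0, i), cost, buf);
  }
  return total;
}

// Per-character lengths on one topology (unweighted).
// [[Rcpp::export]]
NumericVector sankoff_lengths_cpp(IntegerMatrix edge, int n_tip,
                                  IntegerMatrix tip_states, List costs) {
  const int n_char = tip_states.ncol();
  std::vector<double> buf;
  NumericVector out(n_char);
  for (int i = 0; i < n_char; ++i) {
    NumericMatrix cost = costs[i];
    out[i] = sankoff_one(edge, n_tip, &tip_states(0, i), cost, buf);
  }
  return out;
}
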