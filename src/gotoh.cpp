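#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap alignment (Gotoh three-state DP) over a precomputed cell-score
// matrix C, where C(i, j) is the score of aligning position i of sequence a
// (rows) with position j of sequence b (columns).  Working on cell scores
// lets the same kernel serve residue-residue alignment (C = S[a, b]) and
// profile-profile alignment in the progressive MSA (C = t(Fa) %*% S %*% Fb).
//
// Gap cost: a run of k gapped positions costs gap_open + (k - 1) * gap_extend.
// Tie-breaks are fixed so output is platform-deterministic: diagonal beats
// up (gap in b) beats left (gap in a), both for state choice during traceback
// and for the predecessor within a state.

static const double NEG_INF = -1e300;

static inline int argmax3(double m, double x, double y) {
  // 0 = diagonal/M, 1 = up/X, 2 = left/Y; earliest wins ties
  if (m >= x && m >= y) return 0;
  if (x >= y) return 1;
  return 2;
}

// [[Rcpp::export]]
List gotoh_align_cells(NumericMatrix C, double gap_open, double gap_extend,
                       bool local) {
  const int n = C.nrow(), m = C.ncol();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);

  M(0, 0) = 0.0;
  X(0, 0) = Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = local ? 0.0 : NEG_INF; // SW alignments may start anywhere
    Y(i, 0) = NEG_INF;
    X(i, 0) = local ? NEG_INF : -(gap_open + (i - 1) * gap_extend);
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = local ? 0.0 : NEG_INF;
    X(0, j) = NEG_INF;
    Y(0, j) = local ? NEG_INF : -(gap_open + (j - 1) * gap_extend);
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = std::max(M(i - 1, j - 1),
                             std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      double mv = diag + C(i - 1, j - 1);
      if (local && mv < 0.0) mv = 0.0;
      M(i, j) = mv;
      X(i, j) = std::max(M(i - 1, j) - gap_open,
                         std::max(X(i - 1, j) - gap_extend,
                                  Y(i - 1, j) - gap_open));
      Y(i, j) = std::max(M(i, j - 1) - gap_open,
                         std::max(X(i, j - 1) - gap_open,
                                  Y(i, j - 1) - gap_extend));
    }
  }

  double score;
  int ei, ej, state; // traceback start
  if (local) {
    score = 0.0; ei = 0; ej = 0; state = 0;
    for (int i = 1; i <= n; ++i)
      for (int j = 1; j <= m; ++j)
        if (M(i, j) > score) { score = M(i, j); ei = i; ej = j; }
    // earliest (row-major) maximal cell wins because of strict '>' above
  } else {
    state = argmax3(M(n, m), X(n, m), Y(n, m));
    score = state == 0 ? M(n, m) : (state == 1 ? X(n, m) : Y(n, m));
    ei = n; ej = m;
  }

  // traceback; ops recorded 0 = diag, 1 = up (consume a), 2 = left (consume b)
  std::vector<int> ops;
  int i = ei, j = ej, st = state;
  while (i > 0 || j > 0) {
    if (local && st == 0 && M(i, j) == 0.0) break;
    if (st == 0) {
      if (i == 0 || j == 0) break; // cannot happen for finite M off the origin
      ops.push_back(0);
      st = argmax3(M(i - 1, j - 1), X(i - 1, j - 1), Y(i - 1, j - 1));
      --i; --j;
    } else if (st == 1) {
      if (i == 0) break;
      ops.push_back(1);
      double fromM = M(i - 1, j) - gap_open;
      double fromX = X(i - 1, j) - gap_extend;
      double fromY = Y(i - 1, j) - gap_open;
      st = argmax3(fromM, fromX, fromY);
      --i;
    } else {
      if (j == 0) break;
      ops.push_back(2);
      double fromM = M(i, j - 1) - gap_open;
      double fromX = X(i, j - 1) - gap_open;
      double fromY = Y(i, j - 1) - gap_extend;
      st = argmax3(fromM, fromX, fromY);
      --j;
    }
    if (local && i > 0 && j > 0 && st == 0 && M(i, j) == 0.0) break;
    if (local && (i == 0 || j == 0)) break;
  }
  const int si = i, sj = j; // 1-based starts are si + 1, sj + 1

  const int L = (int) ops.size();
  IntegerVector pa(L), pb(L);
  int ca = si, cb = sj;
  for (int k = L - 1, c = 0; k >= 0; --k, ++c) {
    int op = ops[k];
    if (op == 0)      { pa[c] = ++ca; pb[c] = ++cb; }
    else if (op == 1) { pa[c] = ++ca; pb[c] = 0; }
    else              { pa[c] = 0;    pb[c] = ++cb; }
  }

  return List::create(_["score"] = score, _["path_a"] = pa, _["path_b"] = pb,
                      _["start_a"] = si + 1, _["start_b"] = sj + 1);
}
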