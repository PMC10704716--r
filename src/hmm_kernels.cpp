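#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Profile HMM with per-node states M/I/D.  Transition matrix `trans` has
// M+1 rows (node 0 = begin through node M) and 9 columns in the order
// MM, MI, MD, IM, II, ID, DM, DI, DD (log probabilities; at node M the
// *M column is the transition into the end state and *D is -Inf; row 0's
// D* entries are -Inf).  Queries are passed as 0-based letter indices
// into the match-emission columns, with -1 meaning "outside alphabet"
// (emitted at the background value `unk`, identical under the null, so
// such letters contribute nothing to the bitscore).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse3(double a, double b, double c) {
  double m = a > b ? a : b;
  if (c > m) m = c;
  if (m == NEG_INF) return NEG_INF;
  return m + std::log(std::exp(a - m) + std::exp(b - m) + std::exp(c - m));
}

static inline double max3(double a, double b, double c) {
  double m = a > b ? a : b;
  return c > m ? c : m;
}

// [[Rcpp::export]]
double forward_logprob_cpp(NumericMatrix match_emis, NumericVector ins_emis,
                           NumericMatrix trans, IntegerVector query,
                           double unk) {
  int M = match_emis.nrow();
  int n = query.size();
  // dp matrices over nodes 0..M and emitted-letter counts 0..n
  NumericMatrix Vm(M + 1, n + 1), Vi(M + 1, n + 1), Vd(M + 1, n + 1);
  std::fill(Vm.begin(), Vm.end(), NEG_INF);
  std::fill(Vi.begin(), Vi.end(), NEG_INF);
  std::fill(Vd.begin(), Vd.end(), NEG_INF);
  Vm(0, 0) = 0.0;  // begin state acts as M_0

  for (int k = 0; k <= M; ++k) {
    for (int i = 0; i <= n; ++i) {
      if (k > 0) {
        if (i > 0) {
          int x = query[i - 1];
          double em = (x >= 0) ? match_emis(k - 1, x) : unk;
          Vm(k, i) = em + lse3(Vm(k - 1, i - 1) + trans(k - 1, 0),
                               Vi(k - 1, i - 1) + trans(k - 1, 3),
                               Vd(k - 1, i - 1) + trans(k - 1, 6));
        }
        Vd(k, i) = lse3(Vm(k - 1, i) + trans(k - 1, 2),
                        Vi(k - 1, i) + trans(k - 1, 5),
                        Vd(k - 1, i) + trans(k - 1, 8));
      }
      if (i > 0) {
        int x = query[i - 1];
        double em = (x >= 0) ? ins_emis[x] : unk;
        Vi(k, i) = em + lse3(Vm(k, i - 1) + trans(k, 1),
                             Vi(k, i - 1) + trans(k, 4),
                             Vd(k, i - 1) + trans(k, 7));
      }
    }
  }
  return lse3(Vm(M, n) + trans(M, 0), Vi(M, n) + trans(M, 3),
              Vd(M, n) + trans(M, 6));
}

// Viterbi over the same state space; returns the best path as a matrix
// with one row per state visited: column 1 the state (0=M, 1=I, 2=D) and
// column 2 the node index (M/D at node k in 1..M, I at node k in 0..M).
// [[Rcpp::export]]
List viterbi_path_cpp(NumericMatrix match_emis, NumericVector ins_emis,
                      NumericMatrix trans, IntegerVector query, double unk) {
  int M = match_emis.nrow();
  int n = query.size();
  NumericMatrix Vm(M + 1, n + 1), Vi(M + 1, n + 1), Vd(M + 1, n + 1);
  IntegerMatrix Pm(M + 1, n + 1), Pi(M + 1, n + 1), Pd(M + 1, n + 1);
  std::fill(Vm.begin(), Vm.end(), NEG_INF);
  std::fill(Vi.begin(), Vi.end(), NEG_INF);
  std::fill(Vd.begin(), Vd.end(), NEG_INF);
  Vm(0, 0) = 0.0;

  // predecessor codes: 0 = from M, 1 = from I, 2 = from D, -1 = start
  auto argbest = [](double a, double b, double c, double &best) {
    best = max3(a, b, c);
    if (best == a) return 0;
    if (best == b) return 1;
    return 2;
  };

  for (int k = 0; k <= M; ++k) {
    for (int i = 0; i <= n; ++i) {
      if (k > 0) {
        if (i > 0) {
          int x = query[i - 1];
          double em = (x >= 0) ? match_emis(k - 1, x) : unk;
          double best;
          Pm(k, i) = argbest(Vm(k - 1, i - 1) + trans(k - 1, 0),
                             Vi(k - 1, i - 1) + trans(k - 1, 3),
                             Vd(k - 1, i - 1) + trans(k - 1, 6), best);
          Vm(k, i) = em + best;
        }
        {
          double best;
          Pd(k, i) = argbest(Vm(k - 1, i) + trans(k - 1, 2),
                             Vi(k - 1, i) + trans(k - 1, 5),
                             Vd(k - 1, i) + trans(k - 1, 8), best);
          Vd(k, i) = best;
        }
      }
      if (i > 0) {
        int x = query[i - 1];
        double em = (x >= 0) ? ins_emis[x] : unk;
        double best;
        Pi(k, i) = argbest(Vm(k, i - 1) + trans(k, 1),
                           Vi(k, i - 1) + trans(k, 4),
                           Vd(k, i - 1) + trans(k, 7), best);
        Vi(k, i) = em + best;
      }
    }
  }

  double endM = Vm(M, n) + trans(M, 0);
  double endI = Vi(M, n) + trans(M, 3);
  double endD = Vd(M, n) + trans(M, 6);
  double best;
  int state = argbest(endM, endI, endD, best);

  // trace back
  std::vector<int> states, nodes;
  int k = M, i = n;
  while (!(state == 0 && k == 0)) {
    states.push_back(state);
    nodes.push_back(k);
    int prev;
    if (state == 0) { prev = Pm(k, i); --k; --i; }
    else if (state == 1) { prev = Pi(k, i); --i; }
    else { prev = Pd(k, i); --k; }
    state = prev;
  }
  int len = states.size();
  IntegerMatrix path(len, 2);
  for (int j = 0; j < len; ++j) {
    path(j, 0) = states[len - 1 - j];
    path(j, 1) = nodes[len - 1 - j];
  }
  return List::create(_["logprob"] = best, _["path"] = path);
}
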