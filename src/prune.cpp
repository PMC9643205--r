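// Felsenstein pruning over fixed topologies, vectorized across sites.
//
// Conventions shared with the R side:
//  - states: ntip x nsites integer matrix, 1..20 observed, 0 missing.
//    Row i corresponds to tip node id i (1-based, ape numbering).
//  - edge: (parent, child) rows in postorder (children before parents);
//    the root is the parent of the last edge.
//  - One "cg" slot per mixture component x rate category.  For each slot
//    the caller supplies the symmetrized eigendecomposition of the
//    generator (U, lambda, V with Q = U diag(lambda) V), with the rate
//    multiplier already folded into lambda, plus the root profile.
//  - Missing tips are marginalized: the tip partial is a vector of ones,
//    realized as an extra all-ones column appended to each transition
//    matrix so tip contributions are a single column gather.
//  - Underflow is handled by column rescaling with log-scale
//    accumulators, applied lazily (every few tree levels).
#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat ptrans(const arma::mat& U, const arma::vec& lam,
                        const arma::mat& V, double t) {
  arma::mat P = U * arma::diagmat(arma::exp(lam * t)) * V;
  P.clamp(0.0, arma::datum::inf);
  return P;
}

// transition matrix with an appended ones column for missing states
static arma::mat ptrans_aug(const arma::mat& U, const arma::vec& lam,
                            const arma::mat& V, double t) {
  arma::mat P(20, 21);
  P.cols(0, 19) = ptrans(U, lam, V, t);
  P.col(20).ones();
  return P;
}

// contribution of edge e to the parent partial: 20 x nsites.
// For a tip child the columns are gathered from the augmented P.
static arma::mat edge_contrib(const arma::mat& Paug, int child, int ntip,
                              const arma::umat& tipidx,
                              const arma::mat* Dchild) {
  if (child <= ntip) return Paug.cols(tipidx.row(child - 1).t());
  return Paug.cols(0, 19) * (*Dchild);
}

static void rescale(arma::mat& M, arma::rowvec& logs) {
  arma::rowvec m = arma::max(M, 0);
  m.transform([](double v) { return v > 0 ? v : 1.0; });
  M.each_row() /= m;
  logs += arma::log(m);
}

// rescale roughly every `LAZY` accumulated tree levels
static const int LAZY = 5;

// 0-based augmented-column index per tip per site (20 = missing)
static arma::umat tip_index(const arma::imat& states) {
  arma::umat idx(states.n_rows, states.n_cols);
  for (arma::uword j = 0; j < states.n_cols; ++j) {
    for (arma::uword i = 0; i < states.n_rows; ++i) {
      int s = states(i, j);
      idx(i, j) = (s == 0) ? 20u : (arma::uword)(s - 1);
    }
  }
  return idx;
}

// per-site mixture log-likelihood from per-slot site logs (ncg x N):
// marginal mode mixes all slots with logw; allocated mode mixes the G
// slots of the site's component with equal weight.
static arma::rowvec mix_sites(const arma::mat& slotlog,
                              const arma::rowvec& logw,
                              const arma::ivec& alloc, int G) {
  const int N = slotlog.n_cols;
  if (alloc.n_elem == 0) {
    arma::mat Y = slotlog.each_col() + logw.t();
    arma::rowvec m = arma::max(Y, 0);
    return m + arma::log(arma::sum(arma::exp(Y.each_row() - m), 0));
  }
  arma::mat Y(G, N);
  for (int g = 0; g < G; ++g) {
    for (int i = 0; i < N; ++i) Y(g, i) = slotlog((alloc(i) - 1) * G + g, i);
  }
  Y -= std::log((double)G);
  arma::rowvec m = arma::max(Y, 0);
  return m + arma::log(arma::sum(arma::exp(Y.each_row() - m), 0));
}

// [[Rcpp::export]]
arma::rowvec cpp_prune_one(const arma::imat& states, const arma::imat& edge,
                           int ntip, const arma::mat& U, const arma::vec& lam,
                           const arma::mat& V, const arma::vec& tvec,
                           const arma::vec& pi) {
  const int N = states.n_cols, E = edge.n_rows;
  const int nnode = edge.max();
  const arma::umat tipidx = tip_index(states);
  std::vector<arma::mat> D(nnode + 1);
  std::vector<arma::rowvec> ls(nnode + 1);
  std::vector<int> depth(nnode + 1, 0);
  for (int e = 0; e < E; ++e) {
    int p = edge(e, 0), c = edge(e, 1);
    arma::mat Paug = ptrans_aug(U, lam, V, tvec(e));
    arma::mat C = edge_contrib(Paug, c, ntip, tipidx,
                               c > ntip ? &D[c] : nullptr);
    int d = (c > ntip) ? depth[c] + 1 : 1;
    if (D[p].n_elem == 0) {
      D[p] = std::move(C);
      ls[p] = (c > ntip) ? ls[c] : arma::rowvec(N, arma::fill::zeros);
      depth[p] = d;
    } else {
      D[p] %= C;
      if (c > ntip) ls[p] += ls[c];
      depth[p] = std::max(depth[p], d);
    }
    if (depth[p] >= LAZY) {
      rescale(D[p], ls[p]);
      depth[p] = 0;
    }
  }
  int root = edge(E - 1, 0);
  arma::rowvec out = arma::log(pi.t() * D[root]) + ls[root];
  return out;
}

// One depth-first branch-length sweep: every edge receives one
// multiplicative Metropolis-Hastings update against the full mixture
// likelihood, using cached upward/downward partials so the whole sweep
// costs a small constant number of tree passes.  `curslot` carries the
// per-slot site log-likelihoods of the current state in and out, so only
// proposals are evaluated.  Branch lengths have an exponential prior
// with rate prior_rate.  Uses R's RNG.
// [[Rcpp::export]]
List cpp_bl_sweep(const arma::imat& states, const arma::imat& edge, int ntip,
                  List Ul, List laml, List Vl, const arma::mat& piMat,
                  const arma::rowvec& logw, const arma::ivec& alloc, int G,
                  arma::vec tvec, arma::mat curslot, double prior_rate,
                  double window) {
  const int N = states.n_cols, E = edge.n_rows, K = Ul.size();
  const int nnode = edge.max();
  const arma::umat tipidx = tip_index(states);
  std::vector<arma::mat> U(K), V(K);
  std::vector<arma::vec> lam(K);
  for (int k = 0; k < K; ++k) {
    U[k] = as<arma::mat>(Ul[k]);
    V[k] = as<arma::mat>(Vl[k]);
    lam[k] = as<arma::vec>(laml[k]);
  }
  // downward partials per slot per internal node, and per-edge current
  // contributions PD[k][e] (with log-scales)
  std::vector<std::vector<arma::mat>> D(K), PD(K);
  std::vector<std::vector<arma::rowvec>> lsD(K), lsPD(K);
  std::vector<std::vector<int>> childEdges(nnode + 1);
  for (int e = 0; e < E; ++e) childEdges[edge(e, 0)].push_back(e);
  const int root = edge(E - 1, 0);
  for (int k = 0; k < K; ++k) {
    D[k].resize(nnode + 1);
    lsD[k].resize(nnode + 1);
    PD[k].resize(E);
    lsPD[k].resize(E);
    std::vector<int> depth(nnode + 1, 0);
    for (int e = 0; e < E; ++e) {
      int p = edge(e, 0), c = edge(e, 1);
      arma::mat Paug = ptrans_aug(U[k], lam[k], V[k], tvec(e));
      PD[k][e] = edge_contrib(Paug, c, ntip, tipidx,
                              c > ntip ? &D[k][c] : nullptr);
      lsPD[k][e] = (c > ntip) ? lsD[k][c] : arma::rowvec(N, arma::fill::zeros);
      int d = (c > ntip) ? depth[c] + 1 : 1;
      if (D[k][p].n_elem == 0) {
        D[k][p] = PD[k][e];
        lsD[k][p] = lsPD[k][e];
        depth[p] = d;
      } else {
        D[k][p] %= PD[k][e];
        lsD[k][p] += lsPD[k][e];
        depth[p] = std::max(depth[p], d);
      }
      if (depth[p] >= LAZY) {
        rescale(D[k][p], lsD[k][p]);
        depth[p] = 0;
      }
    }
  }
  int accepts = 0;
  double lcur = arma::accu(mix_sites(curslot, logw, alloc, G));
  // recursive DFS; T/lsT are the top partials at the current node
  std::function<void(int, std::vector<arma::mat>&, std::vector<arma::rowvec>&)>
  visit = [&](int p, std::vector<arma::mat>& T, std::vector<arma::rowvec>& lsT) {
    for (int ei : childEdges[p]) {
      int c = edge(ei, 1);
      // A = T * product of the other children's current contributions
      std::vector<arma::mat> A(K);
      std::vector<arma::rowvec> lsA(K);
      for (int k = 0; k < K; ++k) {
        A[k] = T[k];
        lsA[k] = lsT[k];
        for (int ej : childEdges[p]) {
          if (ej == ei) continue;
          A[k] %= PD[k][ej];
          lsA[k] += lsPD[k][ej];
        }
      }
      // MH on this edge length; only the proposal needs evaluating
      double t0 = tvec(ei);
      double t1 = t0 * std::exp(window * (unif_rand() - 0.5));
      arma::mat prop(K, N);
      std::vector<arma::mat> PDnew(K);
      for (int k = 0; k < K; ++k) {
        arma::mat Paug1 = ptrans_aug(U[k], lam[k], V[k], t1);
        PDnew[k] = edge_contrib(Paug1, c, ntip, tipidx,
                                c > ntip ? &D[k][c] : nullptr);
        prop.row(k) = arma::log(arma::sum(A[k] % PDnew[k], 0)) +
                      lsA[k] + lsPD[k][ei];
      }
      double lprop = arma::accu(mix_sites(prop, logw, alloc, G));
      double logacc = (lprop - lcur) - prior_rate * (t1 - t0) +
                      std::log(t1 / t0);
      if (std::log(unif_rand()) < logacc) {
        tvec(ei) = t1;
        for (int k = 0; k < K; ++k) PD[k][ei] = std::move(PDnew[k]);
        curslot = std::move(prop);
        lcur = lprop;
        ++accepts;
      }
      if (c > ntip) {
        // descend with the top partial for the child
        std::vector<arma::mat> Tc(K);
        std::vector<arma::rowvec> lsTc(K);
        for (int k = 0; k < K; ++k) {
          arma::mat P = ptrans(U[k], lam[k], V[k], tvec(ei));
          Tc[k] = P.t() * A[k];
          lsTc[k] = lsA[k];
          rescale(Tc[k], lsTc[k]);
        }
        visit(c, Tc, lsTc);
        // child's downward partial changed below; refresh this edge
        for (int k = 0; k < K; ++k) {
          arma::mat P = ptrans(U[k], lam[k], V[k], tvec(ei));
          PD[k][ei] = P * D[k][c];
          lsPD[k][ei] = lsD[k][c];
        }
      }
    }
    // rebuild this node's downward partial from refreshed contributions
    for (int k = 0; k < K; ++k) {
      bool first = true;
      for (int ei : childEdges[p]) {
        if (first) {
          D[k][p] = PD[k][ei];
          lsD[k][p] = lsPD[k][ei];
          first = false;
        } else {
          D[k][p] %= PD[k][ei];
          lsD[k][p] += lsPD[k][ei];
        }
      }
      rescale(D[k][p], lsD[k][p]);
    }
  };
  std::vector<arma::mat> Troot(K);
  std::vector<arma::rowvec> lsroot(K);
  for (int k = 0; k < K; ++k) {
    Troot[k] = arma::repmat(piMat.col(k), 1, N);
    lsroot[k] = arma::rowvec(N, arma::fill::zeros);
  }
  visit(root, Troot, lsroot);
  return List::create(_["t"] = tvec, _["accepts"] = accepts,
                      _["log_likelihood"] = lcur, _["slots"] = curslot);
}
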