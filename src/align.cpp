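#include <Rcpp.h>
using namespace Rcpp;

// Gotoh affine-gap local alignment with traceback.
// q, t: 0-based residue codes indexing into S. Gap of length L costs
// gap_open + L * gap_extend (BLAST convention). Ties between co-optimal end
// cells are broken by the alignment with the smallest query start, then the
// smallest target start; within a traceback the move preference is
// diagonal > vertical (consume query) > horizontal (consume target).

static const int NEG = -1000000000;

struct Traceback {
  int qstart, qend, tstart, tend;
  std::vector<int> qpos, tpos; // 1-based matched columns
};

static Traceback trace_one(int i, int j,
                           const std::vector<int> &H,
                           const std::vector<int> &E,
                           const std::vector<int> &F,
                           const IntegerVector &q, const IntegerVector &t,
                           const IntegerMatrix &S,
                           int go, int ge, int m1) {
  Traceback tb;
  tb.qend = i; tb.tend = j;
  int state = 0; // 0=H, 1=E (gap consuming target), 2=F (gap consuming query)
  std::vector<int> qp, tp;
  while (i > 0 && j > 0) {
    int idx = i * m1 + j;
    if (state == 0) {
      if (H[idx] == 0) break;
      int s = S(q[i - 1], t[j - 1]);
      if (H[idx] == H[(i - 1) * m1 + (j - 1)] + s) {
        qp.push_back(i); tp.push_back(j); --i; --j;
      } else if (H[idx] == F[idx]) {
        state = 2;
      } else {
        state = 1;
      }
    } else if (state == 1) { // E: gap in query, consume target char j
      if (E[idx] == E[i * m1 + (j - 1)] - ge) { --j; }
      else { --j; state = 0; }
    } else { // F: consume query char i
      if (F[idx] == F[(i - 1) * m1 + j] - ge) { --i; }
      else { --i; state = 0; }
    }
  }
  std::reverse(qp.begin(), qp.end());
  std::reverse(tp.begin(), tp.end());
  tb.qpos = qp; tb.tpos = tp;
  tb.qstart = qp.empty() ? 0 : qp.front();
  tb.tstart = tp.empty() ? 0 : tp.front();
  return tb;
}

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector t, IntegerMatrix S,
                  int gap_open, int gap_extend) {
  int n = q.size(), m = t.size();
  int m1 = m + 1;
  std::vector<int> H((n + 1) * m1, 0), E((n + 1) * m1, NEG),
      F((n + 1) * m1, NEG);
  int best = 0;
  std::vector<std::pair<int, int> > best_cells;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int idx = i * m1 + j;
      int e = std::max(H[i * m1 + (j - 1)] - gap_open - gap_extend,
                       E[i * m1 + (j - 1)] - gap_extend);
      int f = std::max(H[(i - 1) * m1 + j] - gap_open - gap_extend,
                       F[(i - 1) * m1 + j] - gap_extend);
      E[idx] = e; F[idx] = f;
      int h = H[(i - 1) * m1 + (j - 1)] + S(q[i - 1], t[j - 1]);
      h = std::max(h, std::max(e, f));
      h = std::max(h, 0);
      H[idx] = h;
      if (h > best) { best = h; best_cells.clear(); }
      if (h == best && best > 0) best_cells.push_back(std::make_pair(i, j));
    }
  }
  if (best == 0) {
    return List::create(_["score"] = 0,
                        _["qstart"] = NA_INTEGER, _["qend"] = NA_INTEGER,
                        _["tstart"] = NA_INTEGER, _["tend"] = NA_INTEGER,
                        _["qpos"] = IntegerVector(0),
                        _["tpos"] = IntegerVector(0));
  }
  Traceback bestTb;
  bool have = false;
  for (size_t k = 0; k < best_cells.size(); ++k) {
    Traceback tb = trace_one(best_cells[k].first, best_cells[k].second,
                             H, E, F, q, t, S, gap_open, gap_extend, m1);
    if (!have || tb.qstart < bestTb.qstart ||
        (tb.qstart == bestTb.qstart && tb.tstart < bestTb.tstart)) {
      bestTb = tb; have = true;
    }
  }
  return List::create(_["score"] = best,
                      _["qstart"] = bestTb.qstart, _["qend"] = bestTb.qend,
                      _["tstart"] = bestTb.tstart, _["tend"] = bestTb.tend,
                      _["qpos"] = wrap(bestTb.qpos),
                      _["tpos"] = wrap(bestTb.tpos));
}

// Best gapless placement of a PSSM against a residue window.
// res: 0-based codes into the PSSM columns, -1 for unknown residues (scored
// as -1 per position). pssm: L x A integer matrix (model positions x
// alphabet). Partial-model prefix/suffix truncation is allowed only where
// the model overhangs the window edges; ties are broken by the smallest
// window start.

// [[Rcpp::export]]
List pssm_best_cpp(IntegerVector res, IntegerMatrix pssm) {
  int W = res.size(), L = pssm.nrow();
  bool have = false;
  double best = 0; int b_ws = 0, b_we = 0, b_ms = 0, b_me = 0;
  for (int d = 1 - L; d <= W - 1; ++d) {
    // model position i aligns to window position i + d (1-based)
    int i0 = std::max(1, 1 - d), i1 = std::min(L, W - d);
    if (i1 < i0) continue;
    double s = 0;
    for (int i = i0; i <= i1; ++i) {
      int r = res[i + d - 1];
      s += (r < 0) ? -1.0 : pssm(i - 1, r);
    }
    int ws = i0 + d;
    if (!have || s > best || (s == best && ws < b_ws)) {
      have = true; best = s; b_ws = ws; b_we = i1 + d; b_ms = i0; b_me = i1;
    }
  }
  return List::create(_["score"] = best, _["win_start"] = b_ws,
                      _["win_end"] = b_we, _["model_start"] = b_ms,
                      _["model_end"] = b_me);
}
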