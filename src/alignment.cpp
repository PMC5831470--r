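#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh). Gap of length L costs
// open + extend * L. Traceback preference: diagonal > up > left.
// States: 0 = M (diagonal), 1 = Ix (gap in b, consume a: "up"),
// 2 = Iy (gap in a, consume b: "left").

static const double NEG = -1e30;

// [[Rcpp::export(name = ".cpp_pair_align")]]
List cpp_pair_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
                    double open, double extend, bool local) {
  int n = a.size(), m = b.size();
  double g1 = open + extend; // cost of a length-1 gap / opening move
  NumericMatrix M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);
  IntegerMatrix tM(n + 1, m + 1), tIx(n + 1, m + 1), tIy(n + 1, m + 1);
  M(0, 0) = 0.0;
  Ix(0, 0) = Iy(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG;
    Iy(i, 0) = NEG;
    Ix(i, 0) = local ? NEG : -(open + extend * i);
    tIx(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG;
    Ix(0, j) = NEG;
    Iy(0, j) = local ? NEG : -(open + extend * j);
    tIy(0, j) = 2;
  }
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sub(a[i - 1] - 1, b[j - 1] - 1);
      // M state: predecessor preference diag-M > diag-Ix > diag-Iy;
      // in local mode an alignment may start fresh at this cell (-1) and a
      // negative cell is dead (-2)
      double vM = M(i - 1, j - 1), vIx = Ix(i - 1, j - 1), vIy = Iy(i - 1, j - 1);
      double pm = vM; int tm = 0;
      if (vIx > pm) { pm = vIx; tm = 1; }
      if (vIy > pm) { pm = vIy; tm = 2; }
      if (local && pm < 0.0) { pm = 0.0; tm = -1; }
      double mm = pm + s;
      if (local && mm < 0.0) { mm = 0.0; tm = -2; }
      M(i, j) = mm; tM(i, j) = tm;
      // Ix: gap in b (up): from M (open) or Ix (extend) or Iy (open)
      double x1 = M(i - 1, j) - g1, x2 = Ix(i - 1, j) - extend,
             x3 = Iy(i - 1, j) - g1;
      double px = x1; int tx = 0;
      if (x2 > px) { px = x2; tx = 1; }
      if (x3 > px) { px = x3; tx = 2; }
      Ix(i, j) = px; tIx(i, j) = tx;
      // Iy: gap in a (left)
      double y1 = M(i, j - 1) - g1, y2 = Iy(i, j - 1) - extend,
             y3 = Ix(i, j - 1) - g1;
      double py = y1; int ty = 0;
      if (y2 > py) { py = y2; ty = 2; }
      if (y3 > py) { py = y3; ty = 1; }
      Iy(i, j) = py; tIy(i, j) = ty;
      if (local && M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }
  int ei, ej, state;
  double score;
  if (local) {
    score = best; ei = bi; ej = bj; state = 0;
    if (best <= 0.0) { // empty local alignment
      return List::create(_["score"] = 0.0, _["a_aln"] = IntegerVector(0),
                          _["b_aln"] = IntegerVector(0),
                          _["a_start"] = 0, _["a_end"] = 0,
                          _["b_start"] = 0, _["b_end"] = 0);
    }
  } else {
    // final state preference M > Ix > Iy
    double fM = M(n, m), fX = Ix(n, m), fY = Iy(n, m);
    score = fM; state = 0;
    if (fX > score) { score = fX; state = 1; }
    if (fY > score) { score = fY; state = 2; }
    ei = n; ej = m;
  }
  std::vector<int> aa, bb; // 0 = gap, else 1-based residue code
  int i = ei, j = ej, st = state;
  while (true) {
    if (i == 0 && j == 0) break;
    if (st == 0) {
      int prev = tM(i, j);
      if (local && prev == -2) break;  // dead cell: nothing to emit
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]);
      --i; --j;
      if (local && prev == -1) break;  // alignment started at this cell
      st = prev;
    } else if (st == 1) {
      int prev = tIx(i, j);
      aa.push_back(a[i - 1]); bb.push_back(0);
      --i;
      st = prev;
    } else {
      int prev = tIy(i, j);
      aa.push_back(0); bb.push_back(b[j - 1]);
      --j;
      st = prev;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(_["score"] = score,
                      _["a_aln"] = wrap(aa), _["b_aln"] = wrap(bb),
                      _["a_start"] = i + 1, _["a_end"] = ei,
                      _["b_start"] = j + 1, _["b_end"] = ej);
}

// Plain score-only Smith-Waterman used in bulk homology scans.
// [[Rcpp::export(name = ".cpp_sw_score")]]
double cpp_sw_score(IntegerVector a, IntegerVector b, NumericMatrix sub,
                    double open, double extend) {
  int n = a.size(), m = b.size();
  double g1 = open + extend;
  std::vector<double> M(m + 1, 0.0), Ix(m + 1, NEG), Iy(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diagM = M[0], diagIx = Ix[0], diagIy = Iy[0];
    M[0] = 0.0; Ix[0] = NEG; Iy[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      double sM = M[j], sIx = Ix[j], sIy = Iy[j];
      double s = sub(a[i - 1] - 1, b[j - 1] - 1);
      double pm = std::max(diagM, std::max(diagIx, diagIy));
      double mm = std::max(0.0, pm + s);
      double px = std::max(sM - g1, std::max(sIx - extend, sIy - g1));
      double prevM = M[j - 1], prevIx = Ix[j - 1], prevIy = Iy[j - 1];
      double py = std::max(prevM - g1, std::max(prevIy - extend, prevIx - g1));
      M[j] = mm; Ix[j] = px; Iy[j] = py;
      if (mm > best) best = mm;
      diagM = sM; diagIx = sIx; diagIy = sIy;
    }
  }
  return best;
}
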