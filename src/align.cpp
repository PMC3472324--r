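#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh).
// A gap of length L costs gap_open + L * gap_extend, matching the BLAST
// convention for its -11/-1 defaults.
//
// q, s: 1-based integer codes into the substitution matrix.
// Returns the optimal score plus traceback spans and identity counts.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector q, IntegerVector s, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  const int m = q.size(), n = s.size();
  const double gfirst = gap_open + gap_extend;  // cost of the first gap column

  NumericMatrix H(m + 1, n + 1), E(m + 1, n + 1), F(m + 1, n + 1);
  // traceback: 0 stop, 1 diagonal, 2 gap in subject (up, consumes query),
  // 3 gap in query (left, consumes subject)
  IntegerMatrix TB(m + 1, n + 1);
  IntegerMatrix TE(m + 1, n + 1), TF(m + 1, n + 1);  // 1 if gap was extended

  const double NEG = -1e30;
  double best = 0.0;
  int bi = 0, bj = 0;

  for (int j = 0; j <= n; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= m; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double e_open = H(i, j - 1) - gfirst;
      double e_ext  = E(i, j - 1) - gap_extend;
      E(i, j) = std::max(e_open, e_ext);
      TE(i, j) = (e_ext > e_open) ? 1 : 0;

      double f_open = H(i - 1, j) - gfirst;
      double f_ext  = F(i - 1, j) - gap_extend;
      F(i, j) = std::max(f_open, f_ext);
      TF(i, j) = (f_ext > f_open) ? 1 : 0;

      double diag = H(i - 1, j - 1) + sub(q[i - 1] - 1, s[j - 1] - 1);
      double h = 0.0; int tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (F(i, j) > h) { h = F(i, j); tb = 2; }
      if (E(i, j) > h) { h = E(i, j); tb = 3; }
      H(i, j) = h; TB(i, j) = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  int qstart = 0, qend = 0, sstart = 0, send = 0;
  int n_ident = 0, align_len = 0;
  if (best > 0.0) {
    int i = bi, j = bj;
    qend = bi; send = bj;
    int state = 0;  // 0 = in H, 2 = in F (up), 3 = in E (left)
    while (i > 0 && j > 0) {
      if (state == 0) {
        int tb = TB(i, j);
        if (tb == 0) break;
        if (tb == 1) {
          ++align_len;
          if (q[i - 1] == s[j - 1]) ++n_ident;
          --i; --j;
        } else {
          state = tb;
        }
      } else if (state == 2) {
        ++align_len;
        int ext = TF(i, j);
        --i;
        if (!ext) state = 0;
      } else {
        ++align_len;
        int ext = TE(i, j);
        --j;
        if (!ext) state = 0;
      }
    }
    qstart = i + 1; sstart = j + 1;
  }

  return List::create(_["score"] = best, _["qstart"] = qstart,
                      _["qend"] = qend, _["sstart"] = sstart,
                      _["send"] = send, _["n_ident"] = n_ident,
                      _["align_len"] = align_len);
}
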