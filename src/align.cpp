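#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Index lookup for the rows/columns of the substitution matrix.
// Characters absent from the matrix (e.g. 'X') score 0 against everything.
static std::vector<int> char_index(const CharacterVector &alphabet) {
  std::vector<int> idx(256, -1);
  for (int k = 0; k < alphabet.size(); ++k) {
    std::string a = as<std::string>(alphabet[k]);
    if (a.size() == 1) idx[(unsigned char)a[0]] = k;
  }
  return idx;
}

// Smith-Waterman local alignment with affine gaps (Gotoh).
// A gap of length L costs gap_open + L * gap_extend.
// Traceback tie-break: prefer diagonal, then up (gap in subject),
// then left (gap in query). Best cell: highest score, then smallest
// query index, then smallest subject index.
// Intervals are 0-based half-open; a score of 0 yields empty intervals.
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string query, std::string subject,
              NumericMatrix submat, double gap_open, double gap_extend) {
  const int m = query.size(), n = subject.size();
  CharacterVector alpha = rownames(submat);
  std::vector<int> idx = char_index(alpha);
  const double gi = gap_open + gap_extend; // cost of first gapped residue

  std::vector<double> H(n + 1, 0.0), E(n + 1, R_NegInf);
  std::vector<double> Hprev(n + 1, 0.0);
  std::vector<double> Fcol(n + 1, R_NegInf);
  // traceback matrices: 0 stop, 1 diag, 2 up, 3 left
  std::vector<signed char> tbH((m + 1) * (n + 1), 0);
  std::vector<signed char> tbE((m + 1) * (n + 1), 0); // 1 = opened here
  std::vector<signed char> tbF((m + 1) * (n + 1), 0);

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    std::swap(Hprev, H);
    H[0] = 0.0; E[0] = R_NegInf;
    int qi = idx[(unsigned char)query[i - 1]];
    for (int j = 1; j <= n; ++j) {
      int sj = idx[(unsigned char)subject[j - 1]];
      double s = (qi >= 0 && sj >= 0) ? submat(qi, sj) : 0.0;
      // E: gap in query (move left)
      double e_open = H[j - 1] - gi, e_ext = E[j - 1] - gap_extend;
      double e = (e_open >= e_ext) ? e_open : e_ext;
      tbE[i * (n + 1) + j] = (e_open >= e_ext) ? 1 : 0;
      E[j] = e;
      // F: gap in subject (move up)
      double f_open = Hprev[j] - gi, f_ext = Fcol[j] - gap_extend;
      double f = (f_open >= f_ext) ? f_open : f_ext;
      tbF[i * (n + 1) + j] = (f_open >= f_ext) ? 1 : 0;
      Fcol[j] = f;
      double diag = Hprev[j - 1] + s;
      // preference on equal scores: diagonal, then up, then left, then stop
      double h = 0.0; signed char dir = 0;
      if (diag >= h) { h = diag; dir = 1; }
      if (f > h) { h = f; dir = 2; }
      if (e > h) { h = e; dir = 3; }
      if (h <= 0.0) { h = 0.0; dir = 0; }
      H[j] = h;
      tbH[i * (n + 1) + j] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  int qs = 0, qe = 0, ss = 0, se = 0;
  if (best > 0.0) {
    qe = bi; se = bj;
    int i = bi, j = bj;
    // state 0 = in H, 1 = in E (left), 2 = in F (up)
    int state = 0;
    while (i > 0 && j > 0) {
      if (state == 0) {
        signed char d = tbH[i * (n + 1) + j];
        if (d == 0) break;
        if (d == 1) { --i; --j; }
        else if (d == 2) state = 2;
        else state = 1;
      } else if (state == 1) {
        signed char opened = tbE[i * (n + 1) + j];
        --j;
        if (opened) state = 0;
      } else {
        signed char opened = tbF[i * (n + 1) + j];
        --i;
        if (opened) state = 0;
      }
    }
    qs = i; ss = j;
  }
  return List::create(_["score"] = best,
                      _["query_start"] = qs, _["query_end"] = qe,
                      _["subject_start"] = ss, _["subject_end"] = se);
}

// Needleman-Wunsch global alignment with affine gaps, used by the
// non-authoritative progressive MSA helper. Returns the two aligned
// strings (gap character '-'). Tie-break: diagonal, then up, then left.
// [[Rcpp::export(name = ".nw_align")]]
List nw_align(std::string query, std::string subject,
              NumericMatrix submat, double gap_open, double gap_extend) {
  const int m = query.size(), n = subject.size();
  CharacterVector alpha = rownames(submat);
  std::vector<int> idx = char_index(alpha);
  const double gi = gap_open + gap_extend;
  const double NEG = -1e30;

  std::vector<double> H((m + 1) * (n + 1), NEG), E((m + 1) * (n + 1), NEG),
      F((m + 1) * (n + 1), NEG);
  std::vector<signed char> tbH((m + 1) * (n + 1), 0), tbE((m + 1) * (n + 1), 0),
      tbF((m + 1) * (n + 1), 0);
  H[0] = 0.0;
  for (int j = 1; j <= n; ++j) {
    E[j] = -(gap_open + j * gap_extend);
    H[j] = E[j];
    tbH[j] = 3; tbE[j] = (j == 1) ? 1 : 0;
  }
  for (int i = 1; i <= m; ++i) {
    F[i * (n + 1)] = -(gap_open + i * gap_extend);
    H[i * (n + 1)] = F[i * (n + 1)];
    tbH[i * (n + 1)] = 2; tbF[i * (n + 1)] = (i == 1) ? 1 : 0;
  }
  for (int i = 1; i <= m; ++i) {
    int qi = idx[(unsigned char)query[i - 1]];
    for (int j = 1; j <= n; ++j) {
      int sj = idx[(unsigned char)subject[j - 1]];
      double s = (qi >= 0 && sj >= 0) ? submat(qi, sj) : 0.0;
      size_t c = i * (n + 1) + j, l = c - 1, u = (i - 1) * (n + 1) + j,
             d = u - 1;
      double e_open = H[l] - gi, e_ext = E[l] - gap_extend;
      E[c] = (e_open >= e_ext) ? e_open : e_ext;
      tbE[c] = (e_open >= e_ext) ? 1 : 0;
      double f_open = H[u] - gi, f_ext = F[u] - gap_extend;
      F[c] = (f_open >= f_ext) ? f_open : f_ext;
      tbF[c] = (f_open >= f_ext) ? 1 : 0;
      double diag = H[d] + s;
      double h = diag; signed char dir = 1;
      if (F[c] > h) { h = F[c]; dir = 2; }
      if (E[c] > h) { h = E[c]; dir = 3; }
      H[c] = h; tbH[c] = dir;
    }
  }

  std::string aq, as;
  int i = m, j = n, state = 0;
  while (i > 0 || j > 0) {
    size_t c = i * (n + 1) + j;
    if (state == 0) {
      signed char d = tbH[c];
      if (d == 1) { aq.push_back(query[i - 1]); as.push_back(subject[j - 1]); --i; --j; }
      else if (d == 2) state = 2;
      else state = 1;
    } else if (state == 1) {
      aq.push_back('-'); as.push_back(subject[j - 1]);
      if (tbE[c]) state = 0;
      --j;
    } else {
      aq.push_back(query[i - 1]); as.push_back('-');
      if (tbF[c]) state = 0;
      --i;
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(as.begin(), as.end());
  return List::create(_["score"] = H[m * (n + 1) + n],
                      _["aligned_query"] = aq, _["aligned_subject"] = as);
}
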