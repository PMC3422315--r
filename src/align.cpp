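#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Gapless sliding alignment of reads against a panel of amplicon references.
//
// For each read, every ungapped placement on every amplicon is scored.
// Amplicon positions listed in `masks` (0-based; the declared editing sites)
// are excluded from mismatch counting so that a read's editing status can
// never change its assignment. Identity is computed over the unmasked
// overlap; a placement with no unmasked overlap has identity 1 by
// convention (vacuously consistent).
//
// Placement search, per amplicon: keep the placement maximizing
// (overlap, identity, -offset) among placements with identity >=
// min_identity. Across amplicons the best candidate wins on
// (overlap, identity); an exact tie between two distinct amplicons is
// reported as ambiguous. Status codes: 0 assigned, 1 short (best passing
// overlap < min_match), 2 low identity (no placement passes), 3 ambiguous.

// [[Rcpp::export]]
DataFrame assign_reads_cpp(CharacterVector seqs, CharacterVector amp_seqs,
                           List masks, int min_match, double min_identity) {
  const int n_amp = amp_seqs.size();
  std::vector<std::string> amps(n_amp);
  std::vector<std::vector<bool> > masked(n_amp);
  for (int a = 0; a < n_amp; ++a) {
    amps[a] = as<std::string>(amp_seqs[a]);
    masked[a].assign(amps[a].size(), false);
    IntegerVector m = masks[a];
    for (int j = 0; j < m.size(); ++j) {
      int pos = m[j];
      if (pos >= 0 && pos < (int)amps[a].size()) masked[a][pos] = true;
    }
  }

  const int n = seqs.size();
  IntegerVector out_target(n), out_offset(n), out_len(n), out_status(n);
  NumericVector out_ident(n);

  for (int r = 0; r < n; ++r) {
    std::string read = as<std::string>(seqs[r]);
    const int lr = read.size();

    int best_amp = -1, best_len = -1, best_off = 0;
    double best_ident = -1.0;
    bool tie = false;
    // fallback: best placement regardless of identity threshold, for reporting
    int fb_len = 0, fb_off = 0;
    double fb_ident = 0.0;

    for (int a = 0; a < n_amp; ++a) {
      const std::string &amp = amps[a];
      const std::vector<bool> &msk = masked[a];
      const int la = amp.size();
      int a_best_len = -1, a_best_off = 0;
      double a_best_ident = -1.0;

      for (int off = -(lr - 1); off <= la - 1; ++off) {
        int lo = off < 0 ? -off : 0;            // first read index aligned
        int hi = (la - 1 - off < lr - 1) ? la - 1 - off : lr - 1;
        int overlap = hi - lo + 1;
        if (overlap < 1) continue;
        int unmasked = 0, match = 0;
        for (int i = lo; i <= hi; ++i) {
          if (msk[off + i]) continue;
          ++unmasked;
          if (read[i] == amp[off + i]) ++match;
        }
        double ident = unmasked > 0 ? (double)match / unmasked : 1.0;
        if (overlap > fb_len || (overlap == fb_len && ident > fb_ident)) {
          fb_len = overlap; fb_ident = ident; fb_off = off;
        }
        if (ident + 1e-12 < min_identity) continue;
        if (overlap > a_best_len ||
            (overlap == a_best_len && ident > a_best_ident + 1e-12)) {
          a_best_len = overlap; a_best_ident = ident; a_best_off = off;
        }
      }

      if (a_best_len < 0) continue;
      if (a_best_len > best_len ||
          (a_best_len == best_len && a_best_ident > best_ident + 1e-12)) {
        best_amp = a; best_len = a_best_len; best_ident = a_best_ident;
        best_off = a_best_off; tie = false;
      } else if (a_best_len == best_len &&
                 std::abs(a_best_ident - best_ident) <= 1e-12) {
        tie = true;
      }
    }

    if (best_amp < 0) {                       // nothing passes identity
      out_target[r] = NA_INTEGER;
      out_offset[r] = fb_off; out_len[r] = fb_len; out_ident[r] = fb_ident;
      out_status[r] = 2;
    } else if (best_len < min_match) {        // matching sequence too short
      out_target[r] = NA_INTEGER;
      out_offset[r] = best_off; out_len[r] = best_len; out_ident[r] = best_ident;
      out_status[r] = 1;
    } else if (tie) {                         // distinct amplicons tie exactly
      out_target[r] = NA_INTEGER;
      out_offset[r] = best_off; out_len[r] = best_len; out_ident[r] = best_ident;
      out_status[r] = 3;
    } else {
      out_target[r] = best_amp + 1;
      out_offset[r] = best_off; out_len[r] = best_len; out_ident[r] = best_ident;
      out_status[r] = 0;
    }
  }

  return DataFrame::create(
    _["target"] = out_target, _["offset"] = out_offset,
    _["matched_length"] = out_len, _["identity"] = out_ident,
    _["status"] = out_status);
}
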