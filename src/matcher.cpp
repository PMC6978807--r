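#include <Rcpp.h>
using namespace Rcpp;

// Ungapped placement of (unique) reads on hairpin references.
//
// A read may start anywhere within +/- start_slack of a mature 5' start.
// Placements with more than max_mm mismatches are rejected; among acceptable
// placements the fewest-mismatch one wins.  Ties at the minimal mismatch
// count across *different* genes leave the read unassigned ("ambiguous");
// ties within one gene are broken towards the placement closest to the
// annotated mature start (then the leftmost).
//
// Returns, per read: 1-based reference row (NA if unassigned), 0-based
// hairpin offset of the read 5' end, mismatch count, and an ambiguity flag.
// [[Rcpp::export]]
List match_reads_cpp(CharacterVector reads,
                     CharacterVector hairpins,
                     IntegerVector mature_start,
                     IntegerVector gene_idx,
                     int max_mm,
                     int start_slack,
                     int min_read_length) {
  const int n_reads = reads.size();
  const int n_refs = hairpins.size();

  std::vector<std::string> hp(n_refs);
  for (int j = 0; j < n_refs; ++j) hp[j] = as<std::string>(hairpins[j]);

  IntegerVector ref_row(n_reads, NA_INTEGER);
  IntegerVector offset(n_reads, NA_INTEGER);
  IntegerVector n_mismatch(n_reads, NA_INTEGER);
  LogicalVector ambiguous(n_reads, false);
  LogicalVector too_short(n_reads, false);

  for (int i = 0; i < n_reads; ++i) {
    const std::string rd = as<std::string>(reads[i]);
    const int L = rd.size();
    if (L < min_read_length) { too_short[i] = true; continue; }

    int best_mm = max_mm + 1;
    int best_ref = -1, best_off = -1, best_gene = -1;
    int best_dist = INT_MAX;
    bool tie_other_gene = false;

    for (int j = 0; j < n_refs; ++j) {
      const int hl = hp[j].size();
      const int anchor = mature_start[j] - 1;  // 0-based
      for (int off = anchor - start_slack; off <= anchor + start_slack; ++off) {
        if (off < 0 || off + L > hl) continue;
        int mm = 0;
        for (int k = 0; k < L && mm <= max_mm; ++k)
          if (rd[k] != hp[j][off + k]) ++mm;
        if (mm > max_mm) continue;
        const int dist = off > anchor ? off - anchor : anchor - off;
        if (mm < best_mm) {
          best_mm = mm; best_ref = j; best_off = off;
          best_gene = gene_idx[j]; best_dist = dist;
          tie_other_gene = false;
        } else if (mm == best_mm) {
          if (gene_idx[j] != best_gene) {
            tie_other_gene = true;
          } else if (dist < best_dist || (dist == best_dist && off < best_off)) {
            best_off = off; best_ref = j; best_dist = dist;
          }
        }
      }
    }

    if (best_ref >= 0 && !tie_other_gene) {
      ref_row[i] = best_ref + 1;
      offset[i] = best_off;
      n_mismatch[i] = best_mm;
    } else if (best_ref >= 0) {
      ambiguous[i] = true;
    }
  }

  return List::create(_["ref_row"] = ref_row,
                      _["offset"] = offset,
                      _["n_mismatch"] = n_mismatch,
                      _["ambiguous"] = ambiguous,
                      _["too_short"] = too_short);
}

// Mismatch positions (1-based on the read) of read i against hairpin
// hp starting at 0-based offset off.  Small helper so tallying internal
// modifications never rescans reads in R.
// [[Rcpp::export]]
List mismatch_positions_cpp(CharacterVector reads,
                            CharacterVector hairpins,
                            IntegerVector ref_row,
                            IntegerVector offset) {
  const int n = reads.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    if (ref_row[i] == NA_INTEGER) { out[i] = IntegerVector(0); continue; }
    const std::string rd = as<std::string>(reads[i]);
    const std::string hp = as<std::string>(hairpins[ref_row[i] - 1]);
    const int off = offset[i];
    std::vector<int> pos;
    for (int k = 0; k < (int)rd.size(); ++k)
      if (rd[k] != hp[off + k]) pos.push_back(k + 1);
    out[i] = wrap(pos);
  }
  return out;
}

// In-place style single-base substitutions: reads[idx[i]] gets base[i] at
// position pos[i] (1-based).  Used by the simulator to plant edits and
// sequencing miscalls sampled in R.
// [[Rcpp::export]]
CharacterVector substitute_bases_cpp(CharacterVector reads,
                                     IntegerVector idx,
                                     IntegerVector pos,
                                     CharacterVector base) {
  CharacterVector out = clone(reads);
  for (int i = 0; i < idx.size(); ++i) {
    std::string s = as<std::string>(out[idx[i] - 1]);
    s[pos[i] - 1] = as<std::string>(base[i])[0];
    out[idx[i] - 1] = s;
  }
  return out;
}
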