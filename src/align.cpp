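#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Glocal (read-global, reference-local) affine-gap alignment.
//
// A gap of length L costs gapOpen + L * gapExtend, so a long cut-site
// deletion stays one gap instead of being broken into mismatches. Reference
// overhangs on both sides are free. Traceback is deterministic: diagonal
// moves are preferred over gap extension over gap opening, and the smallest
// reference end offset wins ties; indels are then canonicalized by maximal
// left-shifting within repeats (same convention as the exported R helper
// leftAlignCigar).

static const int NEG = INT_MIN / 4;  // safe sentinel under further subtraction

struct AlnResult {
  int score;
  int ref_start;       // 0-based
  std::string cigar;   // ops M, I (read insertion), D (ref deletion)
};

// per-cell traceback byte: bits 0-1 = M predecessor layer,
// bits 2-3 = I predecessor, bits 4-5 = D predecessor (0=M, 1=I, 2=D)
static inline unsigned char pack(unsigned char tm, unsigned char ti,
                                 unsigned char td) {
  return tm | (ti << 2) | (td << 4);
}

// maximally left-shift every indel block without changing the score
static void left_align(std::vector<std::pair<int, char>>& blocks,
                       int& ref_start, const std::string& read,
                       const std::string& ref) {
  bool changed = true;
  while (changed) {
    changed = false;
    // merge adjacent equal ops / drop empties
    std::vector<std::pair<int, char>> mb;
    for (auto& b : blocks) {
      if (b.first == 0) continue;
      if (!mb.empty() && mb.back().second == b.second) mb.back().first += b.first;
      else mb.push_back(b);
    }
    blocks = mb;
    int rpos = ref_start, qpos = 0;
    for (size_t k = 0; k < blocks.size(); ++k) {
      int L = blocks[k].first;
      char op = blocks[k].second;
      if ((op == 'I' || op == 'D') && k > 0 && blocks[k - 1].second == 'M') {
        int prevM = blocks[k - 1].first, s = 0;
        if (op == 'D') {
          while (s < prevM && rpos - s - 1 >= 0 &&
                 ref[rpos - s - 1] == ref[rpos + L - s - 1]) ++s;
        } else {
          while (s < prevM && qpos - s - 1 >= 0 &&
                 read[qpos - s - 1] == read[qpos + L - s - 1]) ++s;
        }
        if (s > 0) {
          blocks[k - 1].first -= s;
          if (k + 1 < blocks.size() && blocks[k + 1].second == 'M')
            blocks[k + 1].first += s;
          else
            blocks.insert(blocks.begin() + k + 1, {s, 'M'});
          changed = true;
          break;  // re-scan after any shift
        }
      }
      if (op != 'I') rpos += L;
      if (op != 'D') qpos += L;
    }
  }
  // a deletion shifted to the alignment start is a free reference overhang
  while (!blocks.empty() && blocks.front().second == 'D') {
    ref_start += blocks.front().first;
    blocks.erase(blocks.begin());
  }
  while (!blocks.empty() && blocks.back().second == 'D') blocks.pop_back();
}

static AlnResult align_one(const std::string& read, const std::string& ref,
                           int ma, int mi, int go, int ge,
                           std::vector<int>& Mp, std::vector<int>& Ip,
                           std::vector<int>& Dp, std::vector<int>& Mc,
                           std::vector<int>& Ic, std::vector<int>& Dc,
                           std::vector<unsigned char>& tb) {
  const int m = (int)read.size(), n = (int)ref.size();
  const int W = n + 1;
  Mp.assign(W, 0); Ip.assign(W, NEG); Dp.assign(W, NEG);  // row 0
  Mc.resize(W); Ic.resize(W); Dc.resize(W);
  tb.assign((size_t)(m + 1) * W, 0);

  const int openc = go + ge;
  for (int i = 1; i <= m; ++i) {
    unsigned char* tbrow = &tb[(size_t)i * W];
    const char ri = read[i - 1];
    // j = 0 column: only I reachable
    {
      int fromI = Ip[0] - ge, fromM = Mp[0] - openc, fromD = Dp[0] - openc;
      int best = fromI; unsigned char t = 1;
      if (fromM > best) { best = fromM; t = 0; }
      if (fromD > best) { best = fromD; t = 2; }
      Mc[0] = NEG; Ic[0] = best; Dc[0] = NEG;
      tbrow[0] = pack(0, t, 0);
    }
    for (int j = 1; j <= n; ++j) {
      // I: consume read base against a gap in the reference (prefer extend)
      int fromI = Ip[j] - ge, fromMo = Mp[j] - openc, fromDo = Dp[j] - openc;
      int bi = fromI; unsigned char ti = 1;
      if (fromMo > bi) { bi = fromMo; ti = 0; }
      if (fromDo > bi) { bi = fromDo; ti = 2; }
      // M: diagonal (prefer M > D > I chains)
      int s = (ri == ref[j - 1]) ? ma : -mi;
      int dM = Mp[j - 1], dI = Ip[j - 1], dD = Dp[j - 1];
      int bm = dM; unsigned char tm = 0;
      if (dD > bm) { bm = dD; tm = 2; }
      if (dI > bm) { bm = dI; tm = 1; }
      bm += s;
      // D: consume reference base against a gap in the read (prefer extend)
      int fromD = Dc[j - 1] - ge, fromMo2 = Mc[j - 1] - openc,
          fromIo = Ic[j - 1] - openc;
      int bd = fromD; unsigned char td = 2;
      if (fromMo2 > bd) { bd = fromMo2; td = 0; }
      if (fromIo > bd) { bd = fromIo; td = 1; }
      Mc[j] = bm; Ic[j] = bi; Dc[j] = bd;
      tbrow[j] = pack(tm, ti, td);
    }
    Mp.swap(Mc); Ip.swap(Ic); Dp.swap(Dc);
  }

  // free reference suffix: best score over all end columns, all layers
  int best = NEG, bj = 0; unsigned char bl = 0;
  for (int j = 0; j <= n; ++j) {
    if (Mp[j] > best) { best = Mp[j]; bj = j; bl = 0; }
    if (Dp[j] > best) { best = Dp[j]; bj = j; bl = 2; }
    if (Ip[j] > best) { best = Ip[j]; bj = j; bl = 1; }
  }

  // traceback over the packed byte matrix
  std::vector<std::pair<int, char>> blocks;
  int i = m, j = bj; unsigned char layer = bl;
  auto push = [&blocks](char op) {
    if (!blocks.empty() && blocks.back().second == op) blocks.back().first++;
    else blocks.push_back({1, op});
  };
  while (i > 0) {
    unsigned char t = tb[(size_t)i * W + j];
    if (layer == 0) { push('M'); layer = t & 3; --i; --j; }
    else if (layer == 1) { push('I'); layer = (t >> 2) & 3; --i; }
    else { push('D'); layer = (t >> 4) & 3; --j; }
  }
  std::reverse(blocks.begin(), blocks.end());
  int ref_start = j;
  left_align(blocks, ref_start, read, ref);

  std::string cig;
  for (auto& b : blocks) { cig += std::to_string(b.first); cig.push_back(b.second); }
  AlnResult res; res.score = best; res.ref_start = ref_start; res.cigar = cig;
  return res;
}

// [[Rcpp::export]]
DataFrame cpp_align_glocal(CharacterVector reads, std::string ref,
                           int match, int mismatch, int gapOpen, int gapExtend) {
  const int nr = reads.size();
  IntegerVector score(nr), ref_start(nr);
  CharacterVector cigar(nr);
  std::vector<int> Mp, Ip, Dp, Mc, Ic, Dc;
  std::vector<unsigned char> tb;
  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    if (rd.empty()) stop("empty read at index %d", r + 1);
    AlnResult a = align_one(rd, ref, match, mismatch, gapOpen, gapExtend,
                            Mp, Ip, Dp, Mc, Ic, Dc, tb);
    score[r] = a.score; ref_start[r] = a.ref_start; cigar[r] = a.cigar;
  }
  return DataFrame::create(_["score"] = score, _["ref_start"] = ref_start,
                           _["cigar"] = cigar, _["stringsAsFactors"] = false);
}

// Hamming distance between target and the substring of each read starting at
// starts[i] (0-based). NA when the window falls outside the read.
// [[Rcpp::export]]
IntegerVector cpp_hamming_at(CharacterVector reads, std::string target,
                             IntegerVector starts) {
  const int nr = reads.size(), L = (int)target.size();
  if (starts.size() != nr) stop("starts must match reads length");
  IntegerVector out(nr);
  for (int r = 0; r < nr; ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int len = (int)LENGTH(STRING_ELT(reads, r));
    int st = starts[r];
    if (st == NA_INTEGER || st < 0 || st + L > len) { out[r] = NA_INTEGER; continue; }
    int d = 0;
    for (int k = 0; k < L; ++k) if (s[st + k] != target[k]) ++d;
    out[r] = d;
  }
  return out;
}

// Variant extraction from one alignment: returns kinds (1=sub, 2=del, 3=ins),
// 0-based positions, lengths and alt strings, walking the CIGAR blocks.
// [[Rcpp::export]]
List cpp_alignment_variants(std::string read, std::string ref, int ref_start,
                            std::string cigar) {
  std::vector<int> kind, pos, len;
  std::vector<std::string> alt;
  int rpos = ref_start, qpos = 0;
  size_t c = 0;
  while (c < cigar.size()) {
    int L = 0;
    while (c < cigar.size() && isdigit(cigar[c])) L = L * 10 + (cigar[c++] - '0');
    char op = cigar[c++];
    if (op == 'M') {
      for (int k = 0; k < L; ++k) {
        if (read[qpos + k] != ref[rpos + k]) {
          kind.push_back(1); pos.push_back(rpos + k); len.push_back(1);
          alt.push_back(std::string(1, read[qpos + k]));
        }
      }
      rpos += L; qpos += L;
    } else if (op == 'D') {
      kind.push_back(2); pos.push_back(rpos); len.push_back(L);
      alt.push_back("");
      rpos += L;
    } else if (op == 'I') {
      kind.push_back(3); pos.push_back(rpos); len.push_back(L);
      alt.push_back(read.substr(qpos, L));
      qpos += L;
    } else {
      stop("unsupported CIGAR op '%c'", op);
    }
  }
  return List::create(_["kind"] = wrap(kind), _["position"] = wrap(pos),
                      _["length"] = wrap(len), _["alt"] = wrap(alt));
}
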