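#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Reference-consuming length implied by a CIGAR string, or -1 if malformed.
static long cigar_ref_len(const std::string& cig) {
    if (cig == "*") return -1;
    long reflen = 0, num = 0;
    bool have_num = false;
    for (char c : cig) {
        if (c >= '0' && c <= '9') {
            num = num * 10 + (c - '0');
            have_num = true;
        } else {
            if (!have_num || num <= 0) return -1;
            switch (c) {
            case 'M': case '=': case 'X': case 'D': case 'N':
                reflen += num; break;
            case 'I': case 'S': case 'H': case 'P':
                break;
            default:
                return -1;
            }
            num = 0; have_num = false;
        }
    }
    if (have_num) return -1;
    return reflen;
}

// Accumulate per-base coverage and error counters for one contig.
//
// Conventions: a read base aligned under M/=/X adds 1 to coverage at its
// reference base and 1 to the mismatch counter when it differs from the
// reference; each reference base skipped by a D operator adds 1 to the
// deletion counter; an insertion of length L adds L to the insertion counter
// of the reference base immediately after the inserted sequence (a trailing
// insertion is charged to the last preceding aligned base, a leading one to
// the first aligned base). The aligned-span counter covers M/=/X/D bases and
// is used for sliding-window error masking of contig alignments.
// [[Rcpp::export]]
List walk_alignments_cpp(IntegerVector pos1, CharacterVector cigar,
                         CharacterVector seq, std::string ref,
                         bool count_errors) {
    const long L = (long)ref.size();
    IntegerVector cov(L), mm(L), del(L), ins(L), span(L);
    int n_malformed = 0, n_noseq = 0;
    const int n = pos1.size();

    for (int r = 0; r < n; ++r) {
        std::string cig = as<std::string>(cigar[r]);
        long reflen = cigar_ref_len(cig);
        long rpos = (long)pos1[r] - 1;
        if (reflen < 0 || rpos < 0 || rpos + reflen > L) {
            ++n_malformed;
            continue;
        }
        std::string sq = as<std::string>(seq[r]);
        bool have_seq = !(sq.empty() || sq == "*");
        if (count_errors && !have_seq) {
            ++n_noseq;
            continue;
        }
        long qpos = 0, pending_ins = 0, last_aligned = -1;
        long num = 0;
        bool bad = false;
        for (size_t k = 0; k < cig.size() && !bad; ++k) {
            char c = cig[k];
            if (c >= '0' && c <= '9') {
                num = num * 10 + (c - '0');
                continue;
            }
            switch (c) {
            case 'M': case '=': case 'X':
                if (have_seq && qpos + num > (long)sq.size()) { bad = true; break; }
                for (long j = 0; j < num; ++j) {
                    if (pending_ins > 0) {
                        ins[rpos] += (int)pending_ins;
                        pending_ins = 0;
                    }
                    cov[rpos] += 1;
                    span[rpos] += 1;
                    if (count_errors && sq[qpos] != ref[rpos]) mm[rpos] += 1;
                    ++rpos;
                    ++qpos;
                }
                last_aligned = rpos - 1;
                break;
            case 'D':
                for (long j = 0; j < num; ++j) {
                    del[rpos] += 1;
                    span[rpos] += 1;
                    ++rpos;
                }
                break;
            case 'N':
                rpos += num;
                break;
            case 'I':
                pending_ins += num;
                qpos += num;
                break;
            case 'S':
                qpos += num;
                break;
            case 'H': case 'P':
                break;
            }
            num = 0;
        }
        if (bad) { ++n_malformed; continue; }
        if (pending_ins > 0 && last_aligned >= 0)
            ins[last_aligned] += (int)pending_ins;
    }
    return List::create(_["cov"] = cov, _["mm"] = mm, _["del"] = del,
                        _["ins"] = ins, _["span"] = span,
                        _["n_malformed"] = n_malformed,
                        _["n_noseq"] = n_noseq);
}

static inline char random_base() {
    static const char B[4] = {'A', 'C', 'G', 'T'};
    int k = (int)(unif_rand() * 4.0);
    if (k > 3) k = 3;
    return B[k];
}

static inline char random_other_base(char refc) {
    static const char B[4] = {'A', 'C', 'G', 'T'};
    char c;
    do { c = B[(int)(unif_rand() * 4.0) % 4]; } while (c == refc);
    return c;
}

// Simulate aligned reads with per-base error rates and an exact event log.
//
// Each read spans read_len reference bases starting at starts[r] (0-based).
// Interior reference bases may be deleted (probability delr), aligned bases
// may mismatch (mmr), and a single base may be inserted before an interior
// aligned base (insr, charged to that base). Events never occur at the first
// or last spanned base, so edge attribution is never ambiguous in simulated
// data. Uses R's RNG; seed with set.seed() in the caller.
// [[Rcpp::export]]
List simulate_reads_cpp(IntegerVector starts, int read_len, std::string ref,
                        NumericVector mmr, NumericVector delr,
                        NumericVector insr) {
    const int n = starts.size();
    const long L = (long)ref.size();
    CharacterVector out_cigar(n), out_seq(n);
    std::vector<int> ev_read, ev_type, ev_pos, ev_len;
    std::string seq, cig;
    seq.reserve(read_len + 8);

    for (int r = 0; r < n; ++r) {
        long pos = starts[r];
        if (pos < 0 || pos + read_len > L) stop("read start out of range");
        seq.clear();
        // op-level run-length encoding of the alignment
        std::vector<std::pair<char, int> > ops;
        bool any_aligned = false;
        for (long i = pos; i < pos + read_len; ++i) {
            bool interior = (i > pos) && (i < pos + read_len - 1);
            if (interior && unif_rand() < delr[i]) {
                ev_read.push_back(r + 1);
                ev_type.push_back(2);
                ev_pos.push_back((int)i);
                ev_len.push_back(1);
                if (!ops.empty() && ops.back().first == 'D') ops.back().second++;
                else ops.push_back(std::make_pair('D', 1));
                continue;
            }
            if (interior && any_aligned && unif_rand() < insr[i]) {
                ev_read.push_back(r + 1);
                ev_type.push_back(3);
                ev_pos.push_back((int)i);
                ev_len.push_back(1);
                seq.push_back(random_base());
                if (!ops.empty() && ops.back().first == 'I') ops.back().second++;
                else ops.push_back(std::make_pair('I', 1));
            }
            char refc = ref[i];
            char base = refc;
            if (unif_rand() < mmr[i]) {
                base = random_other_base(refc);
                ev_read.push_back(r + 1);
                ev_type.push_back(1);
                ev_pos.push_back((int)i);
                ev_len.push_back(1);
            }
            seq.push_back(base);
            any_aligned = true;
            if (!ops.empty() && ops.back().first == 'M') ops.back().second++;
            else ops.push_back(std::make_pair('M', 1));
        }
        cig.clear();
        for (size_t k = 0; k < ops.size(); ++k) {
            cig += std::to_string(ops[k].second);
            cig.push_back(ops[k].first);
        }
        out_cigar[r] = cig;
        out_seq[r] = seq;
    }
    return List::create(_["cigar"] = out_cigar, _["seq"] = out_seq,
                        _["ev_read"] = ev_read, _["ev_type"] = ev_type,
                        _["ev_pos"] = ev_pos, _["ev_len"] = ev_len);
}
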