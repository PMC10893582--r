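// Low-level zlib primitives backing the compression checks and the
// BGZF/ZIP fixture writers: per-member gzip walking (CRC32 + ISIZE verified
// by zlib itself), raw-deflate compression/inflation, and CRC32.

#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <vector>

using namespace Rcpp;

static const size_t CHUNK = 65536;

// Walk a (possibly multi-member) gzip stream member by member.
// zlib verifies each member's CRC32 and ISIZE trailer; we track byte offsets
// so a failure can be localised. Returns ok, member count/offsets, the
// inflated bytes (if keep_data), and on failure a message + offset.
// [[Rcpp::export(name = ".gzipWalk")]]
List gzip_walk(std::string path, bool keep_data) {
    FILE* fp = std::fopen(path.c_str(), "rb");
    if (!fp)
        return List::create(_["ok"] = false, _["n_members"] = 0,
                            _["member_offsets"] = NumericVector(0),
                            _["error"] = "cannot open file",
                            _["error_offset"] = 0.0,
                            _["data"] = RawVector(0));

    z_stream strm;
    std::memset(&strm, 0, sizeof(strm));
    // 15 + 16: gzip-wrapped deflate only
    int ret = inflateInit2(&strm, 15 + 16);
    if (ret != Z_OK) {
        std::fclose(fp);
        stop("inflateInit2 failed");
    }

    std::vector<unsigned char> in(CHUNK), out(CHUNK);
    std::vector<unsigned char> data;
    std::vector<double> offsets;            // start offset of each member
    double consumed = 0;                    // bytes handed to zlib and used
    double member_start = 0;
    int n_members = 0;
    bool ok = true;
    std::string err;
    double err_off = 0;
    bool in_member = false;
    bool input_done = false;

    strm.avail_in = 0;
    strm.next_in = in.data();

    for (;;) {
        if (strm.avail_in == 0 && !input_done) {
            size_t got = std::fread(in.data(), 1, CHUNK, fp);
            if (got == 0) {
                if (std::ferror(fp)) {
                    ok = false; err = "read error"; err_off = consumed;
                    break;
                }
                input_done = true;
            }
            strm.avail_in = (uInt)got;
            strm.next_in = in.data();
        }
        if (strm.avail_in == 0 && input_done) {
            if (in_member) {
                ok = false;
                err = "truncated stream";
                err_off = consumed;
            } else if (n_members == 0) {
                ok = false;
                err = "not a gzip stream";
                err_off = 0;
            }
            break;
        }

        if (!in_member) { member_start = consumed; in_member = true; }

        strm.avail_out = (uInt)CHUNK;
        strm.next_out = out.data();
        uInt avail_before = strm.avail_in;
        ret = inflate(&strm, Z_NO_FLUSH);
        consumed += (double)(avail_before - strm.avail_in);
        size_t produced = CHUNK - strm.avail_out;
        if (keep_data && produced > 0)
            data.insert(data.end(), out.data(), out.data() + produced);

        if (ret == Z_STREAM_END) {
            offsets.push_back(member_start);
            ++n_members;
            in_member = false;
            inflateReset(&strm);
        } else if (ret != Z_OK && ret != Z_BUF_ERROR) {
            ok = false;
            err = (ret == Z_DATA_ERROR && strm.msg)
                      ? std::string(strm.msg)
                      : std::string("corrupt gzip stream");
            err_off = member_start;
            break;
        }
    }

    inflateEnd(&strm);
    std::fclose(fp);

    RawVector rdata(keep_data ? data.size() : 0);
    if (keep_data && !data.empty())
        std::memcpy(RAW(rdata), data.data(), data.size());

    return List::create(_["ok"] = ok, _["n_members"] = n_members,
                        _["member_offsets"] = wrap(offsets),
                        _["error"] = err, _["error_offset"] = err_off,
                        _["data"] = rdata);
}

// [[Rcpp::export(name = ".deflateRaw")]]
RawVector deflate_raw(RawVector input, int level) {
    z_stream strm;
    std::memset(&strm, 0, sizeof(strm));
    // windowBits -15: headerless deflate (BGZF payloads, ZIP entries)
    if (deflateInit2(&strm, level, Z_DEFLATED, -15, 8,
                     Z_DEFAULT_STRATEGY) != Z_OK)
        stop("deflateInit2 failed");

    uLong bound = deflateBound(&strm, (uLong)input.size());
    std::vector<unsigned char> out(bound);
    strm.next_in = (Bytef*)RAW(input);
    strm.avail_in = (uInt)input.size();
    strm.next_out = out.data();
    strm.avail_out = (uInt)bound;
    int ret = deflate(&strm, Z_FINISH);
    if (ret != Z_STREAM_END) { deflateEnd(&strm); stop("deflate failed"); }
    size_t n = bound - strm.avail_out;
    deflateEnd(&strm);

    RawVector res(n);
    std::memcpy(RAW(res), out.data(), n);
    return res;
}

// [[Rcpp::export(name = ".inflateRaw")]]
List inflate_raw(RawVector input) {
    z_stream strm;
    std::memset(&strm, 0, sizeof(strm));
    if (inflateInit2(&strm, -15) != Z_OK)
        stop("inflateInit2 failed");

    std::vector<unsigned char> out;
    std::vector<unsigned char> buf(CHUNK);
    strm.next_in = (Bytef*)RAW(input);
    strm.avail_in = (uInt)input.size();
    bool ok = true;
    std::string err;
    for (;;) {
        strm.next_out = buf.data();
        strm.avail_out = (uInt)CHUNK;
        int ret = inflate(&strm, Z_FINISH);
        size_t produced = CHUNK - strm.avail_out;
        if (produced > 0)
            out.insert(out.end(), buf.data(), buf.data() + produced);
        if (ret == Z_STREAM_END) break;
        if (ret == Z_OK || ret == Z_BUF_ERROR) {
            if (strm.avail_in == 0 && produced == 0) {
                ok = false; err = "truncated deflate stream"; break;
            }
            continue;
        }
        ok = false;
        err = strm.msg ? std::string(strm.msg) : "corrupt deflate stream";
        break;
    }
    inflateEnd(&strm);

    RawVector rdata(ok ? out.size() : 0);
    if (ok && !out.empty())
        std::memcpy(RAW(rdata), out.data(), out.size());
    return List::create(_["ok"] = ok, _["data"] = rdata, _["error"] = err);
}

// CRC32 as a double (fits uint32 exactly)
// [[Rcpp::export(name = ".crc32Raw")]]
double crc32_raw(RawVector input) {
    uLong crc = crc32(0L, Z_NULL, 0);
    crc = crc32(crc, (const Bytef*)RAW(input), (uInt)input.size());
    return (double)crc;
}
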