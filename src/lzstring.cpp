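// LZ-string compression (Lempel-Ziv-Welch variant with incremental code
// widening and literal-character escape codes), producing compressed words
// that remain valid JavaScript strings: a 15-bits-per-character variant for
// payloads embedded in script files, and a 6-bits-per-character variant over
// a URL-safe alphabet for share links.  The bit stream layout follows the
// de-facto lz-string wire format: codes are emitted LSB-first, packed into
// output characters MSB-first; codes 0/1 escape a fresh 8/16-bit literal,
// code 2 terminates the stream; the code width starts at 2 bits (3 at
// decompression) and grows by one whenever the dictionary fills the current
// width.
#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static const std::string kUriAlphabet =
    "ABCDEFGHIJKLMNOPQRSTUVWXYZabcdefghijklmnopqrstuvwxyz0123456789+-$";

// ---- UTF-8 <-> UTF-16 code units -------------------------------------------

static std::vector<uint16_t> utf8_to_utf16(const char* s) {
  std::vector<uint16_t> out;
  const unsigned char* p = reinterpret_cast<const unsigned char*>(s);
  while (*p) {
    uint32_t cp = 0;
    if (*p < 0x80) {
      cp = *p++;
    } else if ((*p >> 5) == 0x6) {
      cp = (*p++ & 0x1F) << 6;
      cp |= (*p++ & 0x3F);
    } else if ((*p >> 4) == 0xE) {
      cp = (*p++ & 0x0F) << 12;
      cp |= (*p++ & 0x3F) << 6;
      cp |= (*p++ & 0x3F);
    } else if ((*p >> 3) == 0x1E) {
      cp = (*p++ & 0x07) << 18;
      cp |= (*p++ & 0x3F) << 12;
      cp |= (*p++ & 0x3F) << 6;
      cp |= (*p++ & 0x3F);
    } else {
      ++p;  // skip invalid byte
      continue;
    }
    if (cp <= 0xFFFF) {
      out.push_back(static_cast<uint16_t>(cp));
    } else {
      cp -= 0x10000;
      out.push_back(static_cast<uint16_t>(0xD800 + (cp >> 10)));
      out.push_back(static_cast<uint16_t>(0xDC00 + (cp & 0x3FF)));
    }
  }
  return out;
}

static std::string utf16_to_utf8(const std::vector<uint16_t>& units) {
  std::string out;
  out.reserve(units.size() * 3);
  size_t i = 0;
  while (i < units.size()) {
    uint32_t cp = units[i];
    if (cp >= 0xD800 && cp <= 0xDBFF && i + 1 < units.size() &&
        units[i + 1] >= 0xDC00 && units[i + 1] <= 0xDFFF) {
      cp = 0x10000 + ((cp - 0xD800) << 10) + (units[i + 1] - 0xDC00);
      i += 2;
    } else {
      i += 1;
    }
    if (cp < 0x80) {
      out.push_back(static_cast<char>(cp));
    } else if (cp < 0x800) {
      out.push_back(static_cast<char>(0xC0 | (cp >> 6)));
      out.push_back(static_cast<char>(0x80 | (cp & 0x3F)));
    } else if (cp < 0x10000) {
      out.push_back(static_cast<char>(0xE0 | (cp >> 12)));
      out.push_back(static_cast<char>(0x80 | ((cp >> 6) & 0x3F)));
      out.push_back(static_cast<char>(0x80 | (cp & 0x3F)));
    } else {
      out.push_back(static_cast<char>(0xF0 | (cp >> 18)));
      out.push_back(static_cast<char>(0x80 | ((cp >> 12) & 0x3F)));
      out.push_back(static_cast<char>(0x80 | ((cp >> 6) & 0x3F)));
      out.push_back(static_cast<char>(0x80 | (cp & 0x3F)));
    }
  }
  return out;
}

// ---- bit packing ------------------------------------------------------------

struct BitWriter {
  int bits_per_char;
  int val = 0;
  int position = 0;
  std::vector<uint16_t> data;

  explicit BitWriter(int bpc) : bits_per_char(bpc) {}

  void write_bits(int value, int n) {
    for (int i = 0; i < n; ++i) {
      val = (val << 1) | (value & 1);
      if (position == bits_per_char - 1) {
        position = 0;
        data.push_back(static_cast<uint16_t>(val));
        val = 0;
      } else {
        ++position;
      }
      value >>= 1;
    }
  }

  void flush() {
    while (true) {
      val <<= 1;
      if (position == bits_per_char - 1) {
        data.push_back(static_cast<uint16_t>(val));
        break;
      }
      ++position;
    }
  }
};

struct BitReader {
  const std::vector<uint16_t>& data;
  int reset_value;   // bitmask of the MSB of one packed character
  int val;
  int position;
  size_t index;

  BitReader(const std::vector<uint16_t>& d, int reset)
      : data(d), reset_value(reset),
        val(d.empty() ? 0 : d[0]), position(reset), index(1) {}

  bool exhausted() const { return index > data.size(); }

  int read_bits(int n) {
    int bits = 0, power = 1;
    for (int i = 0; i < n; ++i) {
      int resb = val & position;
      position >>= 1;
      if (position == 0) {
        position = reset_value;
        val = index < data.size() ? data[index] : 0;
        ++index;
      }
      bits |= (resb > 0 ? 1 : 0) * power;
      power <<= 1;
    }
    return bits;
  }
};

// ---- core compress / decompress ---------------------------------------------

struct U16Hash {
  size_t operator()(const std::u16string& s) const {
    size_t h = 1469598103934665603ULL;
    for (char16_t c : s) { h ^= c; h *= 1099511628211ULL; }
    return h;
  }
};

static std::vector<uint16_t> lz_compress_core(const std::vector<uint16_t>& input,
                                              int bits_per_char) {
  BitWriter out(bits_per_char);
  if (!input.empty()) {
    std::unordered_map<std::u16string, int, U16Hash> dictionary;
    std::unordered_map<std::u16string, bool, U16Hash> to_create;
    std::u16string w, wc, c;
    int enlarge_in = 2, dict_size = 3, num_bits = 2;

    auto emit_w = [&]() {
      auto it_create = to_create.find(w);
      if (it_create != to_create.end()) {
        uint16_t ch = static_cast<uint16_t>(w[0]);
        if (ch < 256) {
          out.write_bits(0, num_bits);
          out.write_bits(ch, 8);
        } else {
          out.write_bits(1, num_bits);
          out.write_bits(ch, 16);
        }
        if (--enlarge_in == 0) { enlarge_in = 1 << num_bits; ++num_bits; }
        to_create.erase(it_create);
      } else {
        out.write_bits(dictionary[w], num_bits);
      }
      if (--enlarge_in == 0) { enlarge_in = 1 << num_bits; ++num_bits; }
    };

    for (uint16_t unit : input) {
      c.assign(1, static_cast<char16_t>(unit));
      if (dictionary.find(c) == dictionary.end()) {
        dictionary[c] = dict_size++;
        to_create[c] = true;
      }
      wc = w + c;
      if (dictionary.find(wc) != dictionary.end()) {
        w = wc;
      } else {
        emit_w();
        dictionary[wc] = dict_size++;
        w = c;
      }
    }
    if (!w.empty()) emit_w();
    out.write_bits(2, num_bits);
  } else {
    out.write_bits(2, 2);
  }
  out.flush();
  return out.data;
}

// Returns false on a corrupt stream.
static bool lz_decompress_core(const std::vector<uint16_t>& input,
                               int reset_value,
                               std::vector<uint16_t>& result) {
  result.clear();
  if (input.empty()) return true;
  std::vector<std::u16string> dictionary;
  for (int i = 0; i < 3; ++i) dictionary.push_back(std::u16string());
  BitReader in(input, reset_value);
  int enlarge_in = 4, dict_size = 4, num_bits = 3;

  int next = in.read_bits(2);
  std::u16string c;
  switch (next) {
    case 0: c.assign(1, static_cast<char16_t>(in.read_bits(8))); break;
    case 1: c.assign(1, static_cast<char16_t>(in.read_bits(16))); break;
    case 2: return true;  // empty stream
    default: return false;
  }
  dictionary.push_back(c);
  std::u16string w = c, entry;
  result.insert(result.end(), c.begin(), c.end());

  while (true) {
    if (in.exhausted()) return false;
    int bits = in.read_bits(num_bits);
    int code = bits;
    switch (bits) {
      case 0:
        dictionary.push_back(std::u16string(1, static_cast<char16_t>(in.read_bits(8))));
        ++dict_size;
        code = dict_size - 1;
        --enlarge_in;
        break;
      case 1:
        dictionary.push_back(std::u16string(1, static_cast<char16_t>(in.read_bits(16))));
        ++dict_size;
        code = dict_size - 1;
        --enlarge_in;
        break;
      case 2:
        return true;
    }
    if (enlarge_in == 0) { enlarge_in = 1 << num_bits; ++num_bits; }
    if (code < static_cast<int>(dictionary.size()) && !dictionary[code].empty()) {
      entry = dictionary[code];
    } else if (code == dict_size) {
      entry = w + w.substr(0, 1);
    } else {
      return false;
    }
    result.insert(result.end(), entry.begin(), entry.end());
    dictionary.push_back(w + entry.substr(0, 1));
    ++dict_size;
    --enlarge_in;
    w = entry;
    if (enlarge_in == 0) { enlarge_in = 1 << num_bits; ++num_bits; }
  }
}

// ---- R interface ------------------------------------------------------------

static const char* as_utf8(const String& s) { return String(s).get_cstring(); }

// [[Rcpp::export(name = ".lz_compress_utf16_cpp")]]
String lz_compress_utf16_cpp(String text) {
  text.set_encoding(CE_UTF8);
  std::vector<uint16_t> input = utf8_to_utf16(text.get_cstring());
  std::vector<uint16_t> packed = lz_compress_core(input, 15);
  std::vector<uint16_t> units;
  units.reserve(packed.size() + 1);
  for (uint16_t v : packed) units.push_back(static_cast<uint16_t>(v + 32));
  units.push_back(32);  // trailing space, per the reference wire format
  String out(utf16_to_utf8(units));
  out.set_encoding(CE_UTF8);
  return out;
}

// [[Rcpp::export(name = ".lz_decompress_utf16_cpp")]]
SEXP lz_decompress_utf16_cpp(String text) {
  text.set_encoding(CE_UTF8);
  std::vector<uint16_t> units = utf8_to_utf16(text.get_cstring());
  for (uint16_t& v : units) {
    if (v < 32) return R_NilValue;
    v = static_cast<uint16_t>(v - 32);
  }
  std::vector<uint16_t> result;
  if (!lz_decompress_core(units, 16384, result)) return R_NilValue;
  String out(utf16_to_utf8(result));
  out.set_encoding(CE_UTF8);
  return wrap(out);
}

// [[Rcpp::export(name = ".lz_compress_uri_cpp")]]
String lz_compress_uri_cpp(String text) {
  text.set_encoding(CE_UTF8);
  std::vector<uint16_t> input = utf8_to_utf16(text.get_cstring());
  std::vector<uint16_t> packed = lz_compress_core(input, 6);
  std::string out;
  out.reserve(packed.size());
  for (uint16_t v : packed) out.push_back(kUriAlphabet[v]);
  String res(out);
  res.set_encoding(CE_UTF8);
  return res;
}

// [[Rcpp::export(name = ".lz_decompress_uri_cpp")]]
SEXP lz_decompress_uri_cpp(String text) {
  text.set_encoding(CE_UTF8);
  const char* s = text.get_cstring();
  static int lookup[256];
  static bool ready = false;
  if (!ready) {
    for (int i = 0; i < 256; ++i) lookup[i] = -1;
    for (size_t i = 0; i < kUriAlphabet.size(); ++i)
      lookup[static_cast<unsigned char>(kUriAlphabet[i])] = static_cast<int>(i);
    ready = true;
  }
  std::vector<uint16_t> units;
  for (const char* p = s; *p; ++p) {
    unsigned char ch = static_cast<unsigned char>(*p);
    if (ch == ' ') ch = '+';  // '+' may arrive as ' ' after URL decoding
    int v = lookup[ch];
    if (v < 0) return R_NilValue;
    units.push_back(static_cast<uint16_t>(v));
  }
  std::vector<uint16_t> result;
  if (!lz_decompress_core(units, 32, result)) return R_NilValue;
  String out(utf16_to_utf8(result));
  out.set_encoding(CE_UTF8);
  return wrap(out);
}

// ---- CRC-32 (for the zip container of the XLSX export) ----------------------

// [[Rcpp::export(name = ".crc32_cpp")]]
double crc32_cpp(RawVector data) {
  static uint32_t table[256];
  static bool ready = false;
  if (!ready) {
    for (uint32_t n = 0; n < 256; ++n) {
      uint32_t c = n;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? (0xEDB88320u ^ (c >> 1)) : (c >> 1);
      table[n] = c;
    }
    ready = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return static_cast<double>(crc ^ 0xFFFFFFFFu);
}
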