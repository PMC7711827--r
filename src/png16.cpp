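// Minimal 16-bit grayscale PNG writer/reader.  Scintigraphic count images
// need the full 16-bit sample depth, which the png package's writer does not
// expose; this codec covers exactly the subset the package emits: color type
// 0 (grayscale), bit depth 8 or 16, no interlace.  Compression is zlib level
// 6 with fixed settings, so identical pixel data yields byte-identical files.

#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <vector>

using namespace Rcpp;

namespace {

void put_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

void write_chunk(FILE* f, const char type[4], const std::vector<unsigned char>& data) {
  std::vector<unsigned char> hdr;
  put_u32(hdr, (uint32_t)data.size());
  fwrite(hdr.data(), 1, 4, f);
  unsigned char t[4] = {(unsigned char)type[0], (unsigned char)type[1],
                        (unsigned char)type[2], (unsigned char)type[3]};
  fwrite(t, 1, 4, f);
  if (!data.empty()) fwrite(data.data(), 1, data.size(), f);
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, t, 4);
  if (!data.empty()) crc = crc32(crc, data.data(), (uInt)data.size());
  std::vector<unsigned char> c;
  put_u32(c, (uint32_t)crc);
  fwrite(c.data(), 1, 4, f);
}

uint32_t get_u32(const unsigned char* p) {
  return ((uint32_t)p[0] << 24) | ((uint32_t)p[1] << 16) | ((uint32_t)p[2] << 8) | p[3];
}

inline int paeth(int a, int b, int c) {
  int p = a + b - c, pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

}  // namespace

// [[Rcpp::export]]
void cpp_write_png16(std::string path, IntegerMatrix img) {
  int H = img.nrow(), W = img.ncol();
  std::vector<unsigned char> raw((size_t)H * (1 + 2 * (size_t)W));
  size_t p = 0;
  for (int i = 0; i < H; ++i) {
    raw[p++] = 0;  // filter type 0
    for (int j = 0; j < W; ++j) {
      int v = img(i, j);
      if (v < 0) v = 0;
      if (v > 65535) v = 65535;
      raw[p++] = (v >> 8) & 0xff;
      raw[p++] = v & 0xff;
    }
  }
  uLongf comp_len = compressBound((uLong)raw.size());
  std::vector<unsigned char> comp(comp_len);
  if (compress2(comp.data(), &comp_len, raw.data(), (uLong)raw.size(), 6) != Z_OK)
    stop("PNG compression failed");
  comp.resize(comp_len);

  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  fwrite(sig, 1, 8, f);
  std::vector<unsigned char> ihdr;
  put_u32(ihdr, (uint32_t)W);
  put_u32(ihdr, (uint32_t)H);
  ihdr.push_back(16);  // bit depth
  ihdr.push_back(0);   // color type: grayscale
  ihdr.push_back(0); ihdr.push_back(0); ihdr.push_back(0);
  write_chunk(f, "IHDR", ihdr);
  write_chunk(f, "IDAT", comp);
  write_chunk(f, "IEND", std::vector<unsigned char>());
  std::fclose(f);
}

// [[Rcpp::export]]
IntegerMatrix cpp_read_png16(std::string path) {
  FILE* f = std::fopen(path.c_str(), "rb");
  if (!f) stop("cannot open '%s'", path.c_str());
  std::fseek(f, 0, SEEK_END);
  long sz = std::ftell(f);
  std::fseek(f, 0, SEEK_SET);
  std::vector<unsigned char> buf(sz);
  if (std::fread(buf.data(), 1, sz, f) != (size_t)sz) { std::fclose(f); stop("short read on '%s'", path.c_str()); }
  std::fclose(f);
  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  if (sz < 8 || !std::equal(sig, sig + 8, buf.data())) stop("'%s' is not a PNG file", path.c_str());

  uint32_t W = 0, H = 0;
  int depth = 0, color = -1;
  std::vector<unsigned char> idat;
  size_t pos = 8;
  while (pos + 8 <= (size_t)sz) {
    uint32_t len = get_u32(&buf[pos]);
    std::string type((char*)&buf[pos + 4], 4);
    const unsigned char* data = &buf[pos + 8];
    if (type == "IHDR") {
      W = get_u32(data); H = get_u32(data + 4);
      depth = data[8]; color = data[9];
      if (color != 0 || (depth != 8 && depth != 16) || data[12] != 0)
        stop("unsupported PNG variant in '%s' (need non-interlaced grayscale 8/16-bit)", path.c_str());
    } else if (type == "IDAT") {
      idat.insert(idat.end(), data, data + len);
    } else if (type == "IEND") {
      break;
    }
    pos += 12 + len;
  }
  if (W == 0 || H == 0 || idat.empty()) stop("malformed PNG '%s'", path.c_str());

  int bpp = depth / 8;
  size_t stride = (size_t)W * bpp;
  std::vector<unsigned char> raw(H * (stride + 1));
  uLongf raw_len = (uLongf)raw.size();
  if (uncompress(raw.data(), &raw_len, idat.data(), (uLong)idat.size()) != Z_OK || raw_len != raw.size())
    stop("PNG inflate failed for '%s'", path.c_str());

  // undo scanline filters (byte-wise, per the PNG spec)
  std::vector<unsigned char> prev(stride, 0);
  IntegerMatrix img(H, W);
  std::vector<unsigned char> cur(stride);
  for (uint32_t i = 0; i < H; ++i) {
    const unsigned char* line = &raw[(size_t)i * (stride + 1)];
    int ft = line[0];
    for (size_t b = 0; b < stride; ++b) {
      int x = line[1 + b];
      int a = b >= (size_t)bpp ? cur[b - bpp] : 0;
      int up = prev[b];
      int c = b >= (size_t)bpp ? prev[b - bpp] : 0;
      switch (ft) {
        case 0: break;
        case 1: x += a; break;
        case 2: x += up; break;
        case 3: x += (a + up) / 2; break;
        case 4: x += paeth(a, up, c); break;
        default: stop("bad PNG filter type %d", ft);
      }
      cur[b] = (unsigned char)(x & 0xff);
    }
    for (uint32_t j = 0; j < W; ++j)
      img(i, j) = depth == 16 ? ((int)cur[2 * j] << 8) | cur[2 * j + 1] : cur[j];
    prev = cur;
  }
  return img;
}
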