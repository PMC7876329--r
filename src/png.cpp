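// Minimal PNG codec (8-bit grayscale/RGB/RGBA, zlib, no interlace).
// The R image stack available here has no PNG reader/writer, so the package
// carries its own: enough for the fixture generator and overlay output.

#include <Rcpp.h>
#include <zlib.h>

#include <cstring>
#include <vector>

namespace {

void put_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

uint32_t get_u32(const unsigned char* p) {
  return ((uint32_t)p[0] << 24) | ((uint32_t)p[1] << 16) |
         ((uint32_t)p[2] << 8) | (uint32_t)p[3];
}

void put_chunk(std::vector<unsigned char>& out, const char* type,
               const std::vector<unsigned char>& data) {
  put_u32(out, (uint32_t)data.size());
  size_t start = out.size();
  out.insert(out.end(), type, type + 4);
  out.insert(out.end(), data.begin(), data.end());
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, out.data() + start, (uInt)(4 + data.size()));
  put_u32(out, (uint32_t)crc);
}

}  // namespace

// img: raw vector of interleaved samples, row-major
// (R, G, B[, A] per pixel), length H*W*channels
// [[Rcpp::export(name = ".cpp_png_encode")]]
Rcpp::RawVector cpp_png_encode(Rcpp::RawVector img, int height, int width,
                               int channels) {
  if ((int)img.size() != height * width * channels)
    Rcpp::stop("pixel buffer size mismatch");
  int color_type;
  switch (channels) {
    case 1: color_type = 0; break;
    case 3: color_type = 2; break;
    case 4: color_type = 6; break;
    default: Rcpp::stop("channels must be 1, 3 or 4");
  }
  const size_t stride = (size_t)width * channels;
  std::vector<unsigned char> raw((stride + 1) * height);
  for (int r = 0; r < height; ++r) {
    raw[r * (stride + 1)] = 0;  // filter type None
    std::memcpy(&raw[r * (stride + 1) + 1], &img[r * stride], stride);
  }
  uLongf clen = compressBound((uLong)raw.size());
  std::vector<unsigned char> comp(clen);
  if (compress2(comp.data(), &clen, raw.data(), (uLong)raw.size(), 6) != Z_OK)
    Rcpp::stop("zlib compression failed");
  comp.resize(clen);

  std::vector<unsigned char> out;
  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  out.insert(out.end(), sig, sig + 8);
  std::vector<unsigned char> ihdr;
  put_u32(ihdr, (uint32_t)width);
  put_u32(ihdr, (uint32_t)height);
  ihdr.push_back(8);                       // bit depth
  ihdr.push_back((unsigned char)color_type);
  ihdr.push_back(0); ihdr.push_back(0); ihdr.push_back(0);
  put_chunk(out, "IHDR", ihdr);
  put_chunk(out, "IDAT", comp);
  put_chunk(out, "IEND", {});
  return Rcpp::RawVector(out.begin(), out.end());
}

// returns list(height, width, channels, pixels = raw interleaved row-major)
// [[Rcpp::export(name = ".cpp_png_decode")]]
Rcpp::List cpp_png_decode(Rcpp::RawVector bytes) {
  const unsigned char* p = (const unsigned char*)RAW(bytes);
  const size_t n = bytes.size();
  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  if (n < 8 || std::memcmp(p, sig, 8) != 0) Rcpp::stop("not a PNG file");
  size_t pos = 8;
  int width = 0, height = 0, bit_depth = 0, color_type = 0;
  std::vector<unsigned char> idat;
  while (pos + 8 <= n) {
    uint32_t len = get_u32(p + pos);
    const char* type = (const char*)(p + pos + 4);
    const unsigned char* data = p + pos + 8;
    if (pos + 12 + len > n) Rcpp::stop("truncated PNG chunk");
    if (std::memcmp(type, "IHDR", 4) == 0) {
      width = (int)get_u32(data);
      height = (int)get_u32(data + 4);
      bit_depth = data[8];
      color_type = data[9];
      if (data[12] != 0) Rcpp::stop("interlaced PNG not supported");
    } else if (std::memcmp(type, "IDAT", 4) == 0) {
      idat.insert(idat.end(), data, data + len);
    } else if (std::memcmp(type, "IEND", 4) == 0) {
      break;
    }
    pos += 12 + len;
  }
  if (bit_depth != 8) Rcpp::stop("only 8-bit PNG supported");
  int channels;
  switch (color_type) {
    case 0: channels = 1; break;
    case 2: channels = 3; break;
    case 6: channels = 4; break;
    default: Rcpp::stop("unsupported PNG color type %d", color_type);
  }
  const size_t stride = (size_t)width * channels;
  std::vector<unsigned char> raw((stride + 1) * height);
  uLongf rlen = (uLongf)raw.size();
  if (uncompress(raw.data(), &rlen, idat.data(), (uLong)idat.size()) != Z_OK ||
      rlen != raw.size())
    Rcpp::stop("PNG inflate failed");
  // undo per-row filters
  Rcpp::RawVector px((R_xlen_t)stride * height);
  const int bpp = channels;
  for (int r = 0; r < height; ++r) {
    const unsigned char ft = raw[r * (stride + 1)];
    const unsigned char* src = &raw[r * (stride + 1) + 1];
    unsigned char* cur = (unsigned char*)RAW(px) + r * stride;
    const unsigned char* up =
        r > 0 ? (unsigned char*)RAW(px) + (r - 1) * stride : nullptr;
    for (size_t i = 0; i < stride; ++i) {
      const int a = i >= (size_t)bpp ? cur[i - bpp] : 0;
      const int b = up ? up[i] : 0;
      const int c = (up && i >= (size_t)bpp) ? up[i - bpp] : 0;
      int v = src[i];
      switch (ft) {
        case 0: break;
        case 1: v += a; break;
        case 2: v += b; break;
        case 3: v += (a + b) / 2; break;
        case 4: {
          const int pp = a + b - c, pa = std::abs(pp - a),
                    pb = std::abs(pp - b), pc = std::abs(pp - c);
          v += (pa <= pb && pa <= pc) ? a : (pb <= pc ? b : c);
          break;
        }
        default: Rcpp::stop("unsupported PNG filter %d", ft);
      }
      cur[i] = (unsigned char)(v & 0xff);
    }
  }
  return Rcpp::List::create(Rcpp::Named("height") = height,
                            Rcpp::Named("width") = width,
                            Rcpp::Named("channels") = channels,
                            Rcpp::Named("pixels") = px);
}
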