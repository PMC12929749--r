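// Small compiled helpers: IEEE-754 half-precision rounding (storage contract
// for preprocessed slices/tiles) and 26-connected 3D component labeling.
#include <Rcpp.h>
#include <cstring>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static inline uint16_t f32_to_f16(float f) {
  uint32_t x;
  std::memcpy(&x, &f, 4);
  uint32_t sign = (x >> 16) & 0x8000u;
  int32_t exp = (int32_t)((x >> 23) & 0xFF) - 127 + 15;
  uint32_t mant = x & 0x7FFFFFu;
  if (exp >= 31) return (uint16_t)(sign | 0x7C00u);  // overflow -> inf
  if (exp <= 0) {
    if (exp < -10) return (uint16_t)sign;  // underflow -> zero
    mant |= 0x800000u;                     // implicit leading 1
    int shift = 14 - exp;                  // denormalize
    uint32_t half_mant = mant >> shift;
    uint32_t rem = mant & ((1u << shift) - 1);
    uint32_t halfway = 1u << (shift - 1);
    if (rem > halfway || (rem == halfway && (half_mant & 1u))) half_mant++;
    return (uint16_t)(sign | half_mant);
  }
  uint32_t half_mant = mant >> 13;
  uint32_t rem = mant & 0x1FFFu;
  if (rem > 0x1000u || (rem == 0x1000u && (half_mant & 1u))) {
    half_mant++;
    if (half_mant == 0x400u) { half_mant = 0; exp++; if (exp >= 31) return (uint16_t)(sign | 0x7C00u); }
  }
  return (uint16_t)(sign | ((uint32_t)exp << 10) | half_mant);
}

static inline float f16_to_f32(uint16_t h) {
  uint32_t sign = (uint32_t)(h & 0x8000u) << 16;
  uint32_t exp = (h >> 10) & 0x1Fu;
  uint32_t mant = h & 0x3FFu;
  uint32_t x;
  if (exp == 0) {
    if (mant == 0) { x = sign; }
    else {
      int e = -1;
      do { mant <<= 1; e++; } while (!(mant & 0x400u));
      mant &= 0x3FFu;
      x = sign | ((uint32_t)(127 - 15 - e) << 23) | (mant << 13);
    }
  } else if (exp == 31) {
    x = sign | 0x7F800000u | (mant << 13);
  } else {
    x = sign | ((exp - 15 + 127) << 23) | (mant << 13);
  }
  float f;
  std::memcpy(&f, &x, 4);
  return f;
}

// round each value to the nearest half-precision representable number
// [[Rcpp::export]]
NumericVector cpp_round_half(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = (double)f16_to_f32(f32_to_f16((float)x[i]));
  out.attr("dim") = x.attr("dim");
  return out;
}

// 26-connected component labeling of a 3D {0,1} array (dims d1 x d2 x d3).
// Returns integer labels (0 = background), components numbered by decreasing
// voxel count (label 1 is the largest).
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  size_t n = (size_t)d1 * d2 * d3;
  IntegerVector lab(n);
  std::vector<size_t> stack;
  int next = 0;
  std::vector<size_t> sizes;
  for (size_t start = 0; start < n; ++start) {
    if (mask[start] == 0 || lab[start] != 0) continue;
    ++next;
    size_t count = 0;
    stack.push_back(start);
    lab[start] = next;
    while (!stack.empty()) {
      size_t v = stack.back();
      stack.pop_back();
      ++count;
      int i = (int)(v % d1), j = (int)((v / d1) % d2), k = (int)(v / ((size_t)d1 * d2));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
            size_t w = (size_t)ii + (size_t)d1 * jj + (size_t)d1 * d2 * kk;
            if (mask[w] != 0 && lab[w] == 0) { lab[w] = next; stack.push_back(w); }
          }
    }
    sizes.push_back(count);
  }
  // relabel by decreasing size
  std::vector<int> order(next);
  for (int i = 0; i < next; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return sizes[a] > sizes[b]; });
  std::vector<int> newlab(next + 1, 0);
  for (int r = 0; r < next; ++r) newlab[order[r] + 1] = r + 1;
  for (size_t i = 0; i < n; ++i) lab[i] = newlab[lab[i]];
  lab.attr("dim") = dims;
  return lab;
}
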