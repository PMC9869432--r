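#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Invertible integer mixer over [0, 2^bits): the classic Wang-style sequence
// with the result masked to `bits` after every step so that each step stays a
// bijection on the ring Z/2^bits.  Steps of the form x + (x<<a) + (x<<b) are
// multiplications by an odd constant (invertible mod 2^bits); xor-shift steps
// are involutions recoverable by repeated shifting.

static inline uint64_t mask_bits(int bits) {
  return (bits >= 64) ? ~0ULL : ((1ULL << bits) - 1ULL);
}

// modular inverse of odd a mod 2^64 by Newton iteration; caller masks
static inline uint64_t inv_odd(uint64_t a) {
  uint64_t x = a;             // correct to 3 bits
  for (int i = 0; i < 5; ++i) x *= 2 - a * x;
  return x;
}

static inline uint64_t xorshift_right(uint64_t x, int s, uint64_t m) {
  return (x ^ (x >> s)) & m;
}

static inline uint64_t inv_xorshift_right(uint64_t y, int s, uint64_t m) {
  // invert x ^= x >> s by propagating recovered high bits downwards
  uint64_t x = y;
  for (int i = 0; i < 64 / s + 1; ++i) x = (y ^ (x >> s)) & m;
  return x;
}

static uint64_t hash_one(uint64_t x, int bits) {
  uint64_t m = mask_bits(bits);
  x = ((~x) + (x << 21)) & m;
  x = xorshift_right(x, 24, m);
  x = (x + (x << 3) + (x << 8)) & m;   // * 265
  x = xorshift_right(x, 14, m);
  x = (x + (x << 2) + (x << 4)) & m;   // * 21
  x = xorshift_right(x, 28, m);
  x = (x + (x << 31)) & m;             // * (1 + 2^31)
  return x;
}

static uint64_t unhash_one(uint64_t y, int bits) {
  uint64_t m = mask_bits(bits);
  // step 7: y = x * (1 + 2^31)
  uint64_t c7 = (1ULL + (1ULL << 31)) & m;
  y = (y * (inv_odd(c7 | 1ULL) & m)) & m;  // c7 is odd already; |1 is a no-op
  y = inv_xorshift_right(y, 28, m);
  y = (y * (inv_odd(21ULL) & m)) & m;
  y = inv_xorshift_right(y, 14, m);
  y = (y * (inv_odd(265ULL) & m)) & m;
  y = inv_xorshift_right(y, 24, m);
  // step 1: y = ~x + (x<<21) = x*(2^21 - 1) - 1 (mod 2^bits)
  uint64_t c1 = ((1ULL << 21) - 1ULL) & m;
  if (c1 == 0) c1 = m;  // bits <= 21: multiplier is -1 mod 2^bits
  y = (((y + 1ULL) & m) * (inv_odd(c1) & m)) & m;
  return y;
}

// [[Rcpp::export(name = ".hash_mix_cpp")]]
NumericVector hash_mix_cpp(NumericVector x, int bits, bool invert) {
  if (bits < 4 || bits > 52)
    stop("bit width must be in [4, 52]");
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = x[i];
    if (ISNA(v) || v < 0 || v >= std::ldexp(1.0, bits))
      stop("k-mer code out of range for the given bit width");
    uint64_t u = (uint64_t)v;
    out[i] = (double)(invert ? unhash_one(u, bits) : hash_one(u, bits));
  }
  return out;
}
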