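#ifndef SYNKIN_RNG_H
#define SYNKIN_RNG_H

#include <cstdint>
#include <cmath>

// xoshiro256++ seeded via splitmix64; self-contained so that simulation
// results are bit-reproducible for a given integer seed, independent of
// R's RNG state.
struct Xoshiro {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;

  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on [0, 1)
  inline double unif() {
    return (next() >> 11) * 0x1.0p-53;
  }

  // uniform on (0, 1] (safe for log())
  inline double unif_pos() {
    return ((next() >> 11) + 1) * 0x1.0p-53;
  }

  // standard normal, Box-Muller with cached spare
  inline double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u = unif_pos();
    double v = unif();
    double r = std::sqrt(-2.0 * std::log(u));
    double a = 6.283185307179586476925286766559 * v;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }

  inline double rexp(double rate) {
    return -std::log(unif_pos()) / rate;
  }
};

#endif
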