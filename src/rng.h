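// Compact xoshiro256++ generator with the draw primitives the simulator
// needs. One instance per simulation; all draws consume it in a fixed,
// documented order, so a configuration + seed reproduces a stream exactly.
#ifndef PHOTONFFS_RNG_H
#define PHOTONFFS_RNG_H

#include <cstdint>
#include <cmath>

struct SimRng {
  uint64_t s[4];
  bool has_spare;
  double spare;

  explicit SimRng(uint64_t seed) : has_spare(false), spare(0.0) {
    // splitmix64 expansion of the seed into the state
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
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
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }

  // standard normal (Marsaglia polar method, one spare cached)
  inline double normal() {
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * f;
    has_spare = true;
    return u * f;
  }

  // unit-mean exponential
  inline double expo() {
    double u = unif();
    while (u <= 0.0) u = unif();
    return -std::log(u);
  }

  // Poisson, Knuth multiplication method (means here are O(1))
  inline int pois(double mu) {
    if (mu <= 0.0) return 0;
    const double limit = std::exp(-mu);
    double prod = unif();
    int k = 0;
    while (prod > limit) {
      prod *= unif();
      ++k;
    }
    return k;
  }
};

#endif
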