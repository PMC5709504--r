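#ifndef MULTISTAGE_RNG_H
#define MULTISTAGE_RNG_H

#include <cstdint>
#include <cmath>
#include <random>

// Per-replicate streams: a SplitMix64 mix of (root seed, stream index) seeds an
// independent mt19937_64. Streams are reproducible and order-independent.
struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
};

class StreamRng {
  std::mt19937_64 gen;
public:
  StreamRng(uint64_t root, uint64_t stream) {
    SplitMix64 sm(root ^ (0x9E3779B97F4A7C15ULL * (stream + 1ULL)));
    uint64_t a = sm.next(), b = sm.next();
    gen.seed(a ^ (b << 1));
  }
  // uniform on [0, 1) with 53 random bits; platform-independent given mt19937_64
  double unif() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
  // exponential waiting time; 1 - unif() is in (0, 1] so the log is finite
  double rexp(double rate) { return -std::log(1.0 - unif()) / rate; }
  // integer in {0, ..., n-1}
  int runif_int(int n) {
    int i = (int)(unif() * n);
    return i >= n ? n - 1 : i;
  }
};

#endif
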