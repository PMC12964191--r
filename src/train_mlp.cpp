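// Training core for the genotype MLP classifier.
//
// The hot loop (noise injection, dropout masking, backprop, Adam) lives
// here; everything else (splits, balancing, attribution) is R-side.
// Randomness comes from a self-contained xoshiro256++ stream seeded from
// a single integer, so training is bit-reproducible for a given seed
// independently of R's RNG state.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
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
  double unif() {  // uniform in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  // Marsaglia-Tsang ziggurat tables (shared, computed once)
  struct Zig {
    uint32_t kn[128];
    double wn[128], fn[128];
    Zig() {
      double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
      const double m1 = 2147483648.0;
      double q = vn / std::exp(-0.5 * dn * dn);
      kn[0] = static_cast<uint32_t>((dn / q) * m1);
      kn[1] = 0;
      wn[0] = q / m1;
      wn[127] = dn / m1;
      fn[0] = 1.0;
      fn[127] = std::exp(-0.5 * dn * dn);
      for (int i = 126; i >= 1; --i) {
        dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
        kn[i + 1] = static_cast<uint32_t>((dn / tn) * m1);
        tn = dn;
        fn[i] = std::exp(-0.5 * dn * dn);
        wn[i] = dn / m1;
      }
    }
  };
  static const Zig z;  // shared tables, built at load time
  // ziggurat normal from a pre-drawn 64-bit word (bits 0..38 consumed)
  double normal_from(uint64_t u) {
    const int32_t hz = static_cast<int32_t>(static_cast<uint32_t>(u));
    const uint32_t iz = static_cast<uint32_t>(u >> 32) & 127u;
    if (static_cast<uint32_t>(std::abs(hz)) < z.kn[iz]) return hz * z.wn[iz];
    return normal_slow(hz, iz);
  }
  double normal() { return normal_from(next()); }
  double normal_slow(int32_t hz, uint32_t iz) {
    const double r = 3.442619855899;
    for (;;) {
      if (iz == 0) {  // tail
        double x, y;
        do {
          x = -std::log(1.0 - unif()) / r;
          y = -std::log(1.0 - unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      const double x = hz * z.wn[iz];
      if (z.fn[iz] + unif() * (z.fn[iz - 1] - z.fn[iz]) <
          std::exp(-0.5 * x * x)) {
        return x;
      }
      const uint64_t u = next();
      hz = static_cast<int32_t>(static_cast<uint32_t>(u));
      iz = static_cast<uint32_t>(u >> 32) & 127u;
      if (static_cast<uint32_t>(std::abs(hz)) < z.kn[iz]) return hz * z.wn[iz];
    }
  }
  // Fisher-Yates shuffle of an index vector
  void shuffle(arma::uvec& idx) {
    for (arma::uword i = idx.n_elem - 1; i > 0; --i) {
      arma::uword j = static_cast<arma::uword>(unif() * (i + 1));
      std::swap(idx[i], idx[j]);
    }
  }
};

const Xoshiro::Zig Xoshiro::z;

inline double gelu(double x) {
  return 0.5 * x * (1.0 + std::erf(x * M_SQRT1_2));
}
inline double gelu_grad(double x) {
  const double cdf = 0.5 * (1.0 + std::erf(x * M_SQRT1_2));
  const double pdf = std::exp(-0.5 * x * x) / std::sqrt(2.0 * M_PI);
  return cdf + x * pdf;
}

// act codes: 0 identity, 1 relu, 2 gelu
inline void activate(arma::mat& a, const arma::mat& z, int code) {
  switch (code) {
    case 0: a = z; break;
    case 1: a = arma::clamp(z, 0.0, arma::datum::inf); break;
    default:
      a.set_size(arma::size(z));
      for (arma::uword i = 0; i < z.n_elem; ++i) a[i] = gelu(z[i]);
  }
}
inline void activate_grad(arma::mat& g, const arma::mat& z, int code) {
  switch (code) {
    case 0: g.ones(arma::size(z)); break;
    case 1: g = arma::conv_to<arma::mat>::from(z > 0.0); break;
    default:
      g.set_size(arma::size(z));
      for (arma::uword i = 0; i < z.n_elem; ++i) g[i] = gelu_grad(z[i]);
  }
}

struct Adam {
  arma::mat m, v;
  explicit Adam(arma::uword r, arma::uword c) : m(r, c, arma::fill::zeros),
                                                v(r, c, arma::fill::zeros) {}
  void step(arma::mat& w, const arma::mat& grad, double lr, double wd,
            double b1t, double b2t) {
    arma::mat g = grad;
    if (wd > 0.0) g += wd * w;  // L2 coupled into the gradient
    m = 0.9 * m + 0.1 * g;
    v = 0.999 * v + 0.001 * arma::square(g);
    w -= lr * (m / (1.0 - b1t)) / (arma::sqrt(v / (1.0 - b2t)) + 1e-8);
  }
};

double val_loss(const arma::mat& Xv, const arma::vec& yv,
                const arma::mat& W1, const arma::rowvec& b1,
                const arma::mat& W2, const arma::rowvec& b2,
                const arma::vec& W3, double b3, int act1, int act2) {
  arma::mat Z1 = Xv * W1;
  Z1.each_row() += b1;
  arma::mat A1;
  activate(A1, Z1, act1);
  arma::mat Z2 = A1 * W2;
  Z2.each_row() += b2;
  arma::mat A2;
  activate(A2, Z2, act2);
  arma::vec p = 1.0 / (1.0 + arma::exp(-(A2 * W3 + b3)));
  p = arma::clamp(p, 1e-12, 1.0 - 1e-12);
  return arma::as_scalar(-arma::mean(yv % arma::log(p) +
                                     (1.0 - yv) % arma::log(1.0 - p)));
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_train_mlp(const arma::mat& W1_in, const arma::vec& b1_in,
                         const arma::mat& W2_in, const arma::vec& b2_in,
                         const arma::mat& W3_in, const arma::vec& b3_in,
                         const arma::mat& Xtr, const arma::vec& ytr,
                         const arma::mat& Xval, const arma::vec& yval,
                         double input_mask_p, double hidden_dropout_p,
                         double input_noise_sd, double label_noise_sd,
                         double lr, double weight_decay,
                         int epochs, int batch_size,
                         int act1, int act2, int seed) {
  arma::mat W1 = W1_in, W2 = W2_in;
  arma::vec W3 = W3_in.col(0);
  arma::rowvec b1 = b1_in.t(), b2 = b2_in.t();
  double b3 = b3_in[0];
  const arma::uword n = Xtr.n_rows, L = Xtr.n_cols;
  const arma::uword h1 = W1.n_cols, h2 = W2.n_cols;

  Xoshiro rng(static_cast<uint64_t>(seed) * 2862933555777941757ULL + 3037000493ULL);

  Adam aW1(L, h1), ab1(1, h1), aW2(h1, h2), ab2(1, h2), aW3(h2, 1), ab3(1, 1);
  arma::vec hist_train(epochs), hist_val(epochs);

  const double keep_in = 1.0 - input_mask_p;
  const double scale_in = keep_in > 0.0 ? 1.0 / keep_in : 0.0;
  const double keep_h = 1.0 - hidden_dropout_p;
  const double scale_h = keep_h > 0.0 ? 1.0 / keep_h : 0.0;

  arma::uvec order = arma::regspace<arma::uvec>(0, n - 1);
  double b1t = 1.0, b2t = 1.0;
  arma::mat Xb_full(batch_size, L);  // reused across batches
  arma::mat Xb_tail;                 // sized on first partial batch

  for (int ep = 0; ep < epochs; ++ep) {
    rng.shuffle(order);
    double ep_loss = 0.0;
    arma::uword seen = 0;
    for (arma::uword start = 0; start < n; start += batch_size) {
      const arma::uword end = std::min(n - 1, start + batch_size - 1);
      const arma::uvec idx = order.subvec(start, end);
      const arma::uword B = idx.n_elem;

      // masked + noised input copy (inverted dropout; noise only on kept
      // entries since masked ones are zeroed regardless)
      const bool full = (B == static_cast<arma::uword>(batch_size));
      if (!full && Xb_tail.n_rows != B) Xb_tail.set_size(B, L);
      arma::mat& Xb = full ? Xb_full : Xb_tail;
      // mask decision uses the top 25 bits of the same 64-bit draw whose
      // low bits feed the ziggurat normal, so one RNG step serves both
      const uint64_t mask_thresh =
          static_cast<uint64_t>(input_mask_p * 33554432.0);  // * 2^25
      Xoshiro lrng = rng;  // local copy keeps the state in registers
      const arma::uword* ip2 = idx.memptr();
      for (arma::uword j = 0; j < L; ++j) {
        const double* xcol = Xtr.colptr(j);
        double* out = Xb.colptr(j);
        if (input_mask_p > 0.0 && input_noise_sd > 0.0) {
          for (arma::uword r = 0; r < B; ++r) {
            const uint64_t u = lrng.next();
            // branchless: keep flag multiplies the noised value
            const double keep = ((u >> 39) >= mask_thresh) ? 1.0 : 0.0;
            out[r] = keep * (xcol[ip2[r]] + input_noise_sd * lrng.normal_from(u)) *
                     scale_in;
          }
        } else if (input_mask_p > 0.0) {
          for (arma::uword r = 0; r < B; ++r) {
            out[r] = (lrng.next() >> 39) < mask_thresh
                         ? 0.0 : xcol[ip2[r]] * scale_in;
          }
        } else if (input_noise_sd > 0.0) {
          for (arma::uword r = 0; r < B; ++r) {
            out[r] = xcol[ip2[r]] + input_noise_sd * lrng.normal();
          }
        } else {
          for (arma::uword r = 0; r < B; ++r) out[r] = xcol[ip2[r]];
        }
      }
      rng = lrng;  // write the advanced state back
      arma::vec yb(B);
      for (arma::uword r = 0; r < B; ++r) {
        double y = ytr(idx[r]);
        if (label_noise_sd > 0.0) y += label_noise_sd * rng.normal();
        yb[r] = std::min(1.0, std::max(0.0, y));
      }

      // forward
      arma::mat Z1 = Xb * W1;
      Z1.each_row() += b1;
      arma::mat M1;
      if (hidden_dropout_p > 0.0) {
        M1.set_size(B, h1);
        for (arma::uword i = 0; i < M1.n_elem; ++i) {
          M1[i] = rng.unif() < hidden_dropout_p ? 0.0 : scale_h;
        }
        Z1 %= M1;
      }
      arma::mat A1, G1;
      activate(A1, Z1, act1);
      arma::mat Z2 = A1 * W2;
      Z2.each_row() += b2;
      arma::mat M2;
      if (hidden_dropout_p > 0.0) {
        M2.set_size(B, h2);
        for (arma::uword i = 0; i < M2.n_elem; ++i) {
          M2[i] = rng.unif() < hidden_dropout_p ? 0.0 : scale_h;
        }
        Z2 %= M2;
      }
      arma::mat A2, G2;
      activate(A2, Z2, act2);
      arma::vec z3 = A2 * W3 + b3;
      arma::vec p = 1.0 / (1.0 + arma::exp(-z3));
      arma::vec pc = arma::clamp(p, 1e-12, 1.0 - 1e-12);
      ep_loss += arma::as_scalar(-arma::sum(yb % arma::log(pc) +
                                            (1.0 - yb) % arma::log(1.0 - pc)));
      seen += B;

      // backward (BCE + sigmoid)
      arma::vec dz3 = (p - yb) / static_cast<double>(B);
      arma::vec dW3 = A2.t() * dz3;
      double db3 = arma::accu(dz3);
      arma::mat dA2 = dz3 * W3.t();
      activate_grad(G2, Z2, act2);
      arma::mat dZ2 = dA2 % G2;
      if (hidden_dropout_p > 0.0) dZ2 %= M2;
      arma::mat dW2 = A1.t() * dZ2;
      arma::rowvec db2 = arma::sum(dZ2, 0);
      arma::mat dA1 = dZ2 * W2.t();
      activate_grad(G1, Z1, act1);
      arma::mat dZ1 = dA1 % G1;
      if (hidden_dropout_p > 0.0) dZ1 %= M1;
      arma::mat dW1 = Xb.t() * dZ1;
      arma::rowvec db1 = arma::sum(dZ1, 0);

      b1t *= 0.9;
      b2t *= 0.999;
      aW1.step(W1, dW1, lr, weight_decay, b1t, b2t);
      { arma::mat bw = b1; ab1.step(bw, db1, lr, weight_decay, b1t, b2t); b1 = bw.row(0); }
      aW2.step(W2, dW2, lr, weight_decay, b1t, b2t);
      { arma::mat bw = b2; ab2.step(bw, db2, lr, weight_decay, b1t, b2t); b2 = bw.row(0); }
      { arma::mat w3 = W3; aW3.step(w3, dW3, lr, weight_decay, b1t, b2t); W3 = w3.col(0); }
      { arma::mat bw(1, 1); bw(0, 0) = b3;
        arma::mat gb(1, 1); gb(0, 0) = db3;
        ab3.step(bw, gb, lr, weight_decay, b1t, b2t); b3 = bw(0, 0); }
    }
    hist_train[ep] = ep_loss / static_cast<double>(seen);
    hist_val[ep] = val_loss(Xval, yval, W1, b1, W2, b2, W3, b3, act1, act2);
  }

  return Rcpp::List::create(
      Rcpp::Named("W1") = W1, Rcpp::Named("b1") = b1.t(),
      Rcpp::Named("W2") = W2, Rcpp::Named("b2") = b2.t(),
      Rcpp::Named("W3") = arma::mat(W3), Rcpp::Named("b3") = arma::vec{b3},
      Rcpp::Named("history_train") = hist_train,
      Rcpp::Named("history_val") = hist_val);
}
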