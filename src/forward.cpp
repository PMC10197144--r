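// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Slice-wise angular-spectrum propagation of a prepared pupil field.
//
// P : complex pupil field on the centered frequency lattice: the product of
//     source spectrum, mask transmission, aberration phasor and aperture
//     support (orthonormal scaling: sum(|P|^2) is the total energy).
// K : defocus phase per micron of axial displacement (radians/um), same
//     lattice; zero outside the propagating-wave circle.
// z : axial positions (um) of the simulated slices.
// ls: scattering length (um); non-finite disables the exp(-(z - min z)/ls)
//     intensity decay.
// OTF: optional DC-at-(1,1) transform of the object's intensity pattern;
//     when non-empty each intensity slice is circularly convolved with the
//     object (incoherent image formation). Pass a 0x0 matrix to skip.
//
// Because |ifft2| is invariant to circular shifts of its input, the centered
// lattice can be transformed directly: intensities come out unshifted.
//
// Returns per-slice diagnostics and, optionally, the full intensity stack:
//   profile : per-slice maximum intensity (the on-axis signal proxy)
//   energy  : per-slice total intensity (Parseval check)
//   xz_mip  : max over the y (column) index for each (x, z)
//   stack   : N x N x nz intensity cube when keep_stack is true
// [[Rcpp::export]]
Rcpp::List cpp_propagate(const arma::cx_mat& P, const arma::mat& K,
                         const arma::vec& z, double ls, bool keep_stack,
                         const arma::cx_mat& OTF) {
  const uword N = P.n_rows;
  const uword nz = z.n_elem;
  const double z0 = z.min();
  const bool convolve = OTF.n_elem > 0;
  vec profile(nz), energy(nz);
  mat xz(N, nz);
  cube stack;
  if (keep_stack) stack.set_size(N, N, nz);
  const double scale = static_cast<double>(N); // orthonormal inverse transform
  for (uword i = 0; i < nz; ++i) {
    cx_mat field = ifft2(P % exp(cx_double(0.0, 1.0) * (K * z[i]))) * scale;
    mat I = square(abs(field));
    if (convolve) {
      I = real(ifft2(fft2(cx_mat(I, mat(N, N, fill::zeros))) % OTF));
      I.clamp(0.0, datum::inf);
    }
    if (std::isfinite(ls)) I *= std::exp(-(z[i] - z0) / ls);
    profile[i] = I.max();
    energy[i] = accu(I);
    xz.col(i) = max(I, 1); // max over columns (y) for each row (x)
    if (keep_stack) stack.slice(i) = I;
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("profile") = profile,
      Rcpp::Named("energy") = energy,
      Rcpp::Named("xz_mip") = xz);
  if (keep_stack) out["stack"] = stack;
  return out;
}

// Per-slice counts of voxels at or above `threshold` times the stack's
// global maximum, in single precision; the voxel-mode fitness hot path.
// [[Rcpp::export]]
arma::vec cpp_voxel_counts(const arma::cx_mat& P, const arma::mat& K,
                           const arma::vec& z, double ls,
                           const arma::cx_mat& OTF, double threshold) {
  const uword N = P.n_rows;
  const uword nz = z.n_elem;
  const double z0 = z.min();
  const bool convolve = OTF.n_elem > 0;
  const cx_fmat Pf = conv_to<cx_fmat>::from(P);
  const fmat Kf = conv_to<fmat>::from(K);
  cx_fmat OTFf;
  if (convolve) OTFf = conv_to<cx_fmat>::from(OTF);
  const float scale = static_cast<float>(N);
  fcube stack(N, N, nz);
  cx_fmat cur = exp(cx_fmat(fmat(N, N, fill::zeros),
                            Kf * static_cast<float>(z[0])));
  cx_fmat step;
  if (nz > 1) {
    step = exp(cx_fmat(fmat(N, N, fill::zeros),
                       Kf * static_cast<float>(z[1] - z[0])));
  }
  for (uword i = 0; i < nz; ++i) {
    if (i > 0) cur %= step;
    cx_fmat field = ifft2(Pf % cur) * scale;
    fmat I = square(abs(field));
    if (convolve) {
      I = real(ifft2(fft2(cx_fmat(I, fmat(N, N, fill::zeros))) % OTFf));
    }
    if (std::isfinite(ls)) {
      I *= static_cast<float>(std::exp(-(z[i] - z0) / ls));
    }
    stack.slice(i) = I;
  }
  const float cut = static_cast<float>(threshold) * stack.max();
  vec counts(nz);
  for (uword i = 0; i < nz; ++i) {
    counts[i] = static_cast<double>(accu(stack.slice(i) >= cut));
  }
  return counts;
}

// Per-slice maximum intensity only, in single precision; the depth-mode
// fitness hot path (the cost thresholds at 50% of the profile maximum,
// far above float rounding).
// [[Rcpp::export]]
arma::vec cpp_profile(const arma::cx_mat& P, const arma::mat& K,
                      const arma::vec& z, double ls, const arma::cx_mat& OTF) {
  const uword N = P.n_rows;
  const uword nz = z.n_elem;
  const double z0 = z.min();
  const bool convolve = OTF.n_elem > 0;
  const cx_fmat Pf = conv_to<cx_fmat>::from(P);
  const fmat Kf = conv_to<fmat>::from(K);
  cx_fmat OTFf;
  if (convolve) OTFf = conv_to<cx_fmat>::from(OTF);
  vec out(nz);
  const float scale = static_cast<float>(N);
  // uniform z steps: advance the defocus phasor by one complex multiply per
  // slice instead of a full exp (float drift over ~100 steps is far below
  // the 50% fitness threshold)
  cx_fmat cur = exp(cx_fmat(fmat(N, N, fill::zeros),
                            Kf * static_cast<float>(z[0])));
  cx_fmat step;
  if (nz > 1) {
    step = exp(cx_fmat(fmat(N, N, fill::zeros),
                       Kf * static_cast<float>(z[1] - z[0])));
  }
  for (uword i = 0; i < nz; ++i) {
    if (i > 0) cur %= step;
    cx_fmat field = ifft2(Pf % cur) * scale;
    fmat I = square(abs(field));
    if (convolve) {
      I = real(ifft2(fft2(cx_fmat(I, fmat(N, N, fill::zeros))) % OTFf));
    }
    double m = I.max();
    if (std::isfinite(ls)) m *= std::exp(-(z[i] - z0) / ls);
    out[i] = m;
  }
  return out;
}
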