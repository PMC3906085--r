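# FFT helpers shared by the phantom PSF and Wiener restoration. All
# convolutions reflect-pad the volume by the kernel support before the
# transform so no wraparound ghosts enter the field of view.

reflect_index <- function(n, pad) {
  # indices 1..n extended by `pad` on both sides with mirror boundary
  if (n == 1) return(rep(1L, n + 2 * pad))
  j <- seq.int(-pad, n - 1 + pad)          # 0-based extended positions
  m <- j %% (2 * n - 2)
  ifelse(m < n, m + 1L, 2 * n - 1 - m)
}

pad_reflect <- function(arr, pad) {
  d <- dim(arr)
  arr[reflect_index(d[1], pad[1]),
      reflect_index(d[2], pad[2]),
      reflect_index(d[3], pad[3])]
}

gaussian_kernel_1d <- function(sigma, support) {
  x <- seq(-support, support)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 3D separable Gaussian kernel, sigma in voxels per axis; sums to 1
gaussian_kernel_3d <- function(sigma_vox, support = NULL) {
  if (is.null(support)) support <- pmax(1L, ceiling(4 * sigma_vox))
  kx <- gaussian_kernel_1d(max(sigma_vox[1], 1e-8), support[1])
  ky <- gaussian_kernel_1d(max(sigma_vox[2], 1e-8), support[2])
  kz <- gaussian_kernel_1d(max(sigma_vox[3], 1e-8), support[3])
  outer(outer(kx, ky), kz)
}

# place a (2r+1)^3 kernel into a d-sized array wrapped around the origin
embed_kernel <- function(kernel, d) {
  kd <- dim(kernel)
  r <- (kd - 1) %/% 2
  big <- array(0, dim = d)
  ix <- ((seq_len(kd[1]) - 1 - r[1]) %% d[1]) + 1
  iy <- ((seq_len(kd[2]) - 1 - r[2]) %% d[2]) + 1
  iz <- ((seq_len(kd[3]) - 1 - r[3]) %% d[3]) + 1
  big[ix, iy, iz] <- big[ix, iy, iz] + kernel
  big
}

# convolve with reflect padding; kernel must be odd-sized and centered
fft_convolve <- function(arr, kernel) {
  r <- (dim(kernel) - 1) %/% 2
  ap <- pad_reflect(arr, r)
  d <- dim(ap)
  K <- stats::fft(embed_kernel(kernel, d))
  out <- Re(stats::fft(stats::fft(ap) * K, inverse = TRUE)) / prod(d)
  out[r[1] + seq_len(dim(arr)[1]),
      r[2] + seq_len(dim(arr)[2]),
      r[3] + seq_len(dim(arr)[3]), drop = FALSE]
}

# Wiener restoration: Fhat = conj(H) / (|H|^2 + nsr) * G, reflect-padded
fft_wiener <- function(arr, kernel, nsr) {
  r <- (dim(kernel) - 1) %/% 2
  ap <- pad_reflect(arr, r)
  d <- dim(ap)
  H <- stats::fft(embed_kernel(kernel, d))
  G <- stats::fft(ap)
  W <- Conj(H) / (Mod(H)^2 + nsr)
  out <- Re(stats::fft(W * G, inverse = TRUE)) / prod(d)
  out[r[1] + seq_len(dim(arr)[1]),
      r[2] + seq_len(dim(arr)[2]),
      r[3] + seq_len(dim(arr)[3]), drop = FALSE]
}

# Gaussian blur of a volume, sigma in mm, respecting anisotropic spacing
gaussian_blur <- function(arr, sigma_mm, spacing) {
  if (sigma_mm <= 0) return(arr)
  fft_convolve(arr, gaussian_kernel_3d(sigma_mm / spacing))
}
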