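#' Specification for the multi-domain synthetic generator
#'
#' Describes a benchmark that emulates the cross-subject setting: `K` class
#' prototypes drawn once in a latent space and shared by every domain, a
#' shared linear embedding into `d` observed dimensions, and a per-domain
#' distortion (rotation plus mean shift) standing in for subject-specific
#' differences, plus isotropic Gaussian noise.  Distortion is rotation +
#' translation (not arbitrary affine) so that a subspace alignment of the
#' domains exists by construction.
#'
#' @param n_sources number of source domains.
#' @param n_classes number of classes `K`.
#' @param d observed feature dimension.
#' @param latent_dim latent dimension (`<= d`).
#' @param samples_per_class samples per class per domain.
#' @param rotation per-plane angle (radians) of each domain's random rotation;
#'   0 disables the linear distortion.
#' @param mean_shift Euclidean norm of each domain's random mean offset.
#' @param noise_sd standard deviation of the additive isotropic noise.
#' @param class_separation pairwise Euclidean distance between latent class
#'   prototypes.
#' @param seed RNG seed; the dataset is a deterministic function of the spec.
#' @return object of class `"synth_spec"`.
#' @export
synth_spec <- function(n_sources = 2, n_classes = 3, d = 20, latent_dim = 8,
                       samples_per_class = 40, rotation = 0.3,
                       mean_shift = 1.0, noise_sd = 0.3,
                       class_separation = 1.0, seed = 0) {
  stopifnot(n_sources >= 1, n_classes >= 1, d >= 1, latent_dim >= 1,
            latent_dim <= d, samples_per_class >= 1, noise_sd >= 0,
            mean_shift >= 0, class_separation >= 0)
  structure(list(n_sources = as.integer(n_sources),
                 n_classes = as.integer(n_classes), d = as.integer(d),
                 latent_dim = as.integer(latent_dim),
                 samples_per_class = as.integer(samples_per_class),
                 rotation = rotation, mean_shift = mean_shift,
                 noise_sd = noise_sd, class_separation = class_separation,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

## rotation by angle theta in floor(d/2) random mutually orthogonal 2-planes
random_rotation <- function(d, theta) {
  if (theta == 0 || d < 2) return(diag(d))
  V <- rorth(d, d)
  R <- diag(d)
  ct <- cos(theta); st <- sin(theta)
  for (p in seq_len(floor(d / 2))) {
    u <- V[, 2 * p - 1]; v <- V[, 2 * p]
    R <- R + st * (tcrossprod(v, u) - tcrossprod(u, v)) +
      (ct - 1) * (tcrossprod(u) + tcrossprod(v))
  }
  R
}

#' Generate a synthetic multi-domain dataset
#'
#' @param spec a [synth_spec()].
#' @return a [multidomain_dataset()] with `spec$n_sources` source blocks and
#'   one target block, labels balanced exactly as specified.
#' @examples
#' dat <- generate_domains(synth_spec(seed = 7))
#' dat
#' @export
generate_domains <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  K <- spec$n_classes
  ## latent prototypes at pairwise distance class_separation (orthonormal
  ## directions scaled by sep/sqrt(2); falls back to random directions when
  ## latent_dim < K)
  P <- if (spec$latent_dim >= K) rorth(spec$latent_dim, K)
       else apply(matrix(rnorm(spec$latent_dim * K), ncol = K), 2,
                  function(v) v / sqrt(sum(v^2)))
  proto <- P * spec$class_separation / sqrt(2)
  E <- rorth(spec$d, spec$latent_dim)        # shared isometric embedding
  mu <- E %*% proto                          # d x K class means
  make_block <- function() {
    R <- random_rotation(spec$d, spec$rotation)
    shift <- rnorm(spec$d)
    shift <- shift / sqrt(sum(shift^2)) * spec$mean_shift
    labels <- rep(seq_len(K), each = spec$samples_per_class)
    X <- R %*% mu[, labels, drop = FALSE] + shift +
      matrix(rnorm(spec$d * length(labels), sd = spec$noise_sd),
             spec$d, length(labels))
    list(X = X, labels = labels)
  }
  sources <- lapply(seq_len(spec$n_sources), function(i) make_block())
  target <- make_block()
  multidomain_dataset(sources = sources, target = target, n_classes = K)
}

#' Band-limited Gaussian toy signal
#'
#' Sum of independent band-limited Gaussian processes with requested per-band
#' variances, built by spectral masking of white noise; feeds the
#' differential-entropy extractor in tests and examples.
#'
#' @param channels channel count.
#' @param seconds duration in seconds.
#' @param rate sampling rate in Hz; must exceed twice the highest band edge.
#' @param band_powers numeric vector of variances, one per band.
#' @param bands named list of band edges as in [de_config()].
#' @param seed RNG seed.
#' @return numeric matrix channels x samples.
#' @export
toy_signal <- function(channels, seconds, rate, band_powers,
                       bands = eeg_bands(), seed = 0) {
  stopifnot(length(band_powers) == length(bands))
  hi <- max(vapply(bands, `[`, numeric(1), 2))
  if (rate <= 2 * hi - 1e-9)
    stop("sampling rate must exceed twice the highest band edge")
  n <- floor(seconds * rate)
  if (n < 1) stop("zero-length signal requested")
  set.seed(seed)
  freqs <- (seq_len(n) - 1) / n * rate
  freqs <- pmin(freqs, rate - freqs)     # two-sided frequency axis
  out <- matrix(0, channels, n)
  for (ch in seq_len(channels)) {
    x <- numeric(n)
    for (b in seq_along(bands)) {
      if (band_powers[b] <= 0) next
      w <- rnorm(n)
      W <- fft(w)
      mask <- freqs >= bands[[b]][1] & freqs <= bands[[b]][2]
      comp <- Re(fft(W * mask, inverse = TRUE)) / n
      s <- sd(comp) * sqrt((n - 1) / n)
      if (s > 0) comp <- comp / s * sqrt(band_powers[b])
      x <- x + comp
    }
    out[ch, ] <- x
  }
  out
}
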