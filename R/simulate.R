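#' Contrast transfer function parameters
#'
#' Microscope parameters of the simulated imaging model: defocus (positive =
#' underfocus), acceleration voltage, amplitude contrast fraction, a Gaussian
#' B-factor envelope, spherical aberration and the detector pixel size.
#'
#' @param defocus_um Defocus in micrometers.
#' @param voltage_kv Acceleration voltage in kV.
#' @param amplitude_contrast Amplitude contrast fraction in \[0, 1\].
#' @param b_factor Envelope B-factor in Angstrom^2.
#' @param cs_mm Spherical aberration in mm.
#' @param pixel_size Pixel size in Angstrom per pixel.
#' @return A list of class `ctf_params`.
#' @export
ctf_params <- function(defocus_um = 2.5, voltage_kv = 300,
                       amplitude_contrast = 0.1, b_factor = 200,
                       cs_mm = 2.0, pixel_size = 1.2) {
  if (min(defocus_um, voltage_kv, b_factor, cs_mm, pixel_size) <= 0)
    stop_cfg("CTF parameters must be positive")
  if (amplitude_contrast < 0 || amplitude_contrast > 1)
    stop_cfg("amplitude_contrast must lie in [0, 1]")
  structure(list(defocus_um = defocus_um, voltage_kv = voltage_kv,
                 amplitude_contrast = amplitude_contrast,
                 b_factor = b_factor, cs_mm = cs_mm,
                 pixel_size = pixel_size), class = "ctf_params")
}

#' Relativistically corrected electron wavelength
#'
#' @param voltage_kv Acceleration voltage in kV.
#' @return Wavelength in Angstrom (about 0.0197 A at 300 kV).
#' @export
electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1e3
  12.2639 / sqrt(v * (1 + 0.97845e-6 * v))
}

# 2-D CTF evaluated on the FFT frequency grid of an n x n image:
#   CTF(s) = -[sqrt(1 - A^2) sin(gamma) + A cos(gamma)] * exp(-B s^2 / 4)
#   gamma(s) = pi * lambda * s^2 * dz - (pi/2) * Cs * lambda^3 * s^4
ctf_2d <- function(n, params) {
  lambda <- electron_wavelength(params$voltage_kv)
  dz <- params$defocus_um * 1e4          # Angstrom
  cs <- params$cs_mm * 1e7               # Angstrom
  f1 <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[1:n] / n
  s2 <- outer(f1^2, f1^2, "+") / params$pixel_size^2
  gam <- pi * lambda * s2 * dz - (pi / 2) * cs * lambda^3 * s2^2
  a <- params$amplitude_contrast
  -(sqrt(1 - a^2) * sin(gam) + a * cos(gam)) * exp(-params$b_factor * s2 / 4)
}

#' Apply a contrast transfer function to an image
#'
#' Multiplies the image spectrum by the 2-D CTF and returns the real part of
#' the inverse transform. At zero frequency the CTF equals minus the
#' amplitude contrast, so the DC component of the image is scaled by `-A`.
#'
#' @param img Square numeric matrix.
#' @param params A [ctf_params()] object.
#' @return Filtered matrix of the same shape.
#' @export
apply_ctf <- function(img, params = ctf_params()) {
  if (nrow(img) != ncol(img)) stop_cfg("apply_ctf requires a square image")
  h <- ctf_2d(nrow(img), params)
  Re(fft(fft(img) * h, inverse = TRUE)) / length(img)
}

#' Synthetic particle template
#'
#' A reproducible, soft-edged "lumpy blob": a sum of randomly placed smooth
#' Gaussian bumps inside a circular support with a sigmoid edge, zero outside
#' the support. It stands in for projections of a real macromolecule so the
#' noise/CTF chain of the simulator can be exercised with exactly known
#' ground truth; it is synthetic and is not derived from any density map.
#'
#' @param size Template side length in pixels.
#' @param seed RNG seed; the same seed gives the identical template.
#' @param amplitude Peak intensity of the template (arbitrary units on the
#'   simulated camera scale).
#' @param n_bumps Number of Gaussian bumps composing the blob.
#' @return `size x size` matrix, zero outside the circular support.
#' @export
make_template <- function(size, seed = 1, amplitude = 570, n_bumps = 12) {
  with_seed(child_seed(seed, "template"), {
    g <- seq_len(size) - (size + 1) / 2
    r <- sqrt(outer(g^2, g^2, "+"))
    support <- 1 / (1 + exp((r - 0.40 * size) / (size / 24)))
    support[r > size / 2] <- 0
    acc <- matrix(0, size, size)
    for (i in seq_len(n_bumps)) {
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0, 0.30 * size)
      cx <- rad * cos(ang); cy <- rad * sin(ang)
      bsd <- runif(1, size / 12, size / 6)
      amp <- runif(1, 0.4, 1)
      acc <- acc + amp * exp(-(outer((g - cy)^2, (g - cx)^2, "+")) /
                               (2 * bsd^2))
    }
    tmpl <- acc * support
    tmpl * (amplitude / max(tmpl))
  })
}

#' Rotate a template by an arbitrary angle
#'
#' Bilinear interpolation about the template center with zero fill; the
#' circular support keeps all mass inside the frame for any angle.
#'
#' @param tmpl Template matrix.
#' @param angle_deg Rotation angle in degrees.
#' @return Rotated matrix of the same shape.
#' @export
rotate_template <- function(tmpl, angle_deg) {
  cpp_rotate_bilinear(tmpl, angle_deg)
}

#' Simulation specification
#'
#' Parameterization of the synthetic-micrograph generator. Each micrograph
#' receives `particles_per_micrograph` randomly rotated copies of the
#' template at rejection-sampled positions (pairwise center distance at
#' least `min_center_distance`), then zero-mean Gaussian structural noise
#' with SD `88 * k`, then the CTF, then zero-mean Gaussian shot/digitization
#' noise with SD `51 * k`.
#'
#' @param k Noise level (>= 0); `k = 0` is the noise-free CTF-filtered image.
#' @param n_micrographs Number of micrographs in the set.
#' @param particles_per_micrograph Particles planted per micrograph.
#' @param micrograph_size Micrograph side length in pixels.
#' @param template_size Template (and truth box) side length in pixels.
#' @param min_center_distance Minimum pairwise center distance in pixels;
#'   defaults to `0.75 * template_size`.
#' @param seed Master seed for the set.
#' @param ctf A [ctf_params()] object.
#' @param template_amplitude Peak template intensity; the default puts the
#'   `k = 1` set in the signal-to-noise regime of simulated cryo-EM studies
#'   (SNR near 1 at the lowest noise level).
#' @return A list of class `sim_spec` with the derived fields
#'   `structural_noise_sd = 88 * k` and `shot_noise_sd = 51 * k`.
#' @export
sim_spec <- function(k = 1, n_micrographs = 20,
                     particles_per_micrograph = 250,
                     micrograph_size = 1024, template_size = 64,
                     min_center_distance = NULL, seed = 1,
                     ctf = ctf_params(), template_amplitude = 570) {
  if (k < 0) stop_cfg("k must be nonnegative")
  if (n_micrographs < 0 || particles_per_micrograph < 0)
    stop_cfg("counts must be nonnegative")
  structure(list(k = k, n_micrographs = as.integer(n_micrographs),
                 particles_per_micrograph =
                   as.integer(particles_per_micrograph),
                 micrograph_size = as.integer(micrograph_size),
                 template_size = as.integer(template_size),
                 min_center_distance =
                   min_center_distance %||% (0.75 * template_size),
                 seed = as.integer(seed), ctf = ctf,
                 template_amplitude = template_amplitude,
                 structural_noise_sd = 88 * k, shot_noise_sd = 51 * k),
            class = "sim_spec")
}

# rejection-sample n centers with pairwise distance >= dmin inside
# [lo, hi] x [lo, hi]; bounded per-point retries, and for tight packings a
# bounded number of restarts from scratch (sequential placement can jam
# even when a valid configuration exists)
sample_centers <- function(n, lo, hi, dmin, max_tries = 1e4,
                           max_restarts = 40) {
  for (attempt in seq_len(max_restarts)) {
    cx <- numeric(n); cy <- numeric(n)
    placed <- 0L
    for (i in seq_len(n)) {
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        px <- runif(1, lo, hi); py <- runif(1, lo, hi)
        if (i == 1 || all((cx[seq_len(i - 1)] - px)^2 +
                          (cy[seq_len(i - 1)] - py)^2 >= dmin^2)) {
          cx[i] <- px; cy[i] <- py; ok <- TRUE; break
        }
      }
      if (!ok) break
      placed <- i
    }
    if (placed == n) return(list(cx = cx, cy = cy))
  }
  stop_cfg("could not place ", n, " particles at min distance ", dmin,
           "; use a larger micrograph or fewer particles")
}

#' Simulate one micrograph with known ground truth
#'
#' Pipeline order: (1) plant randomly rotated templates at rejection-sampled
#' positions; (2) add structural noise (SD `88 * k`); (3) apply the CTF;
#' (4) add shot noise (SD `51 * k`). All randomness derives from
#' `spec$seed` and `index`, so any micrograph of a set can be regenerated
#' independently.
#'
#' @param spec A [sim_spec()].
#' @param index Micrograph index within the set (1-based).
#' @return A list with `micrograph` (the final image), `boxes` (ground
#'   truth, `w = h = template_size`, confidence 1), and `intermediates`
#'   (`clean`, `post_structural`, `post_ctf`, `clean_ctf` = CTF-filtered
#'   clean composite).
#' @export
simulate_micrograph <- function(spec, index = 1) {
  tmpl <- make_template(spec$template_size, seed = spec$seed,
                        amplitude = spec$template_amplitude)
  L <- spec$micrograph_size; ts <- spec$template_size
  with_seed(child_seed(spec$seed, "simulate", index), {
    half <- ts / 2
    pos <- sample_centers(spec$particles_per_micrograph, half, L - half,
                          spec$min_center_distance)
    clean <- matrix(0, L, L)
    n <- spec$particles_per_micrograph
    corner_x <- integer(n); corner_y <- integer(n)
    angles <- runif(n, 0, 360)
    for (i in seq_len(n)) {
      # integer placement; the recorded truth center is the exact center
      # of the planted ts x ts block in 0-based coordinates
      corner_x[i] <- round(pos$cx[i] - half)
      corner_y[i] <- round(pos$cy[i] - half)
      rot <- rotate_template(tmpl, angles[i])
      rr <- corner_y[i] + seq_len(ts)  # 1-based rows
      cc <- corner_x[i] + seq_len(ts)
      clean[rr, cc] <- clean[rr, cc] + rot
    }
    boxes <- boxes_df(cx = corner_x + (ts - 1) / 2,
                      cy = corner_y + (ts - 1) / 2, w = ts, h = ts)
    post_structural <- clean +
      matrix(rnorm(L * L, 0, spec$structural_noise_sd), L)
    post_ctf <- apply_ctf(post_structural, spec$ctf)
    final <- post_ctf + matrix(rnorm(L * L, 0, spec$shot_noise_sd), L)
    list(micrograph = micrograph(final,
                                 identifier = sprintf("sim_k%g_%03d",
                                                      spec$k, index)),
         boxes = boxes,
         intermediates = list(clean = clean,
                              post_structural = post_structural,
                              post_ctf = post_ctf,
                              clean_ctf = apply_ctf(clean, spec$ctf)))
  })
}

#' Empirical signal-to-noise ratio of a simulated micrograph
#'
#' Signal power divided by noise power: the variance of the CTF-filtered
#' clean composite over the variance of everything added on top of it
#' (final minus CTF-filtered clean).
#'
#' @param sim Output of [simulate_micrograph()].
#' @return SNR ratio, or `NA` when the noise power is zero (`k = 0`).
#' @export
empirical_snr <- function(sim) {
  signal <- sim$intermediates$clean_ctf
  noise <- sim$micrograph - signal
  vn <- stats::var(as.vector(noise))
  if (vn == 0) return(NA_real_)
  stats::var(as.vector(signal)) / vn
}

#' Simulate a full micrograph set, optionally writing it to disk
#'
#' @param spec A [sim_spec()].
#' @param out_dir If non-`NULL`, write each micrograph as MRC (mode 2), the
#'   truth as EMAN1 `.box` files, and a `manifest.json` with the spec and
#'   per-micrograph particle counts.
#' @return Invisibly, the list of [simulate_micrograph()] results.
#' @export
simulate_dataset <- function(spec, out_dir = NULL) {
  sims <- lapply(seq_len(spec$n_micrographs),
                 function(i) simulate_micrograph(spec, i))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(sims)) {
      base <- sprintf("sim_%03d", i)
      write_mrc(sims[[i]]$micrograph, file.path(out_dir,
                                                paste0(base, ".mrc")),
                pixel_size = spec$ctf$pixel_size)
      write_boxes(sims[[i]]$boxes, file.path(out_dir, paste0(base, ".box")),
                  format = "eman1_box")
    }
    manifest <- list(spec = unclass(spec)[setdiff(names(spec), "ctf")],
                     ctf = unclass(spec$ctf),
                     micrographs = sprintf("sim_%03d.mrc",
                                           seq_along(sims)),
                     n_particles = vapply(sims, function(s) nrow(s$boxes),
                                          integer(1)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(sims)
}
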