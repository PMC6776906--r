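# Shared fixtures: small configurations and builders used across the suite.
# Everything is generated in code; no binary fixtures.

# Default-geometry config with a fixed seed; override fields via ...
test_sim_config <- function(seed = 1L, ...) {
  args <- list(...)
  do.call(sim_config, c(list(rng_seed = seed), args))
}

# Noise-free config (no shot noise, no read noise) for geometric oracles.
noiseless_config <- function(seed = 1L, ...) {
  test_sim_config(seed, noise = list(gaussian_sd = 0, poisson_gain = 0), ...)
}

# Marker amplitude tuned so the blurred peak sits near a target SNR
# (signal at punctum peak over the total noise sd at that intensity).
snr_amplitude <- function(snr, gaussian_sd = 25, poisson_gain = 0.5,
                          background = 300, psf_attenuation = 0.85) {
  f <- function(a) {
    peak <- background + psf_attenuation * a
    noise <- sqrt(gaussian_sd^2 + peak * poisson_gain)
    psf_attenuation * a / noise - snr
  }
  uniroot(f, c(1, 1e5))$root
}

# Greedy one-to-one matching of detections to planted objects within
# `max_dist` pixels; returns counts for precision/recall/F1.
match_detections <- function(det, truth, max_dist = 3) {
  if (nrow(det) == 0) {
    return(list(tp = 0, fp = 0, fn = nrow(truth), f1 = 0))
  }
  used <- rep(FALSE, nrow(truth))
  tp <- 0
  for (i in seq_len(nrow(det))) {
    d2 <- (truth$row - det$row[i])^2 + (truth$col - det$col[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= max_dist^2) {
      used[j] <- TRUE
      tp <- tp + 1
    }
  }
  fp <- nrow(det) - tp
  fn <- nrow(truth) - tp
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  list(tp = tp, fp = fp, fn = fn,
       f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
}

# Brute-force O(n^2 k^2) Gaussian convolution, independent of the
# matrix-multiplication implementation in gaussian_blur().
brute_blur <- function(img, sigma, truncate = 4) {
  h <- max(1L, ceiling(truncate * sigma))
  g <- dnorm(-h:h, sd = sigma)
  nr <- nrow(img)
  nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      acc <- 0
      wsum <- 0
      for (dr in -h:h) {
        for (dc in -h:h) {
          rr <- r + dr
          c2 <- cc + dc
          if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc) {
            w <- g[dr + h + 1] * g[dc + h + 1]
            acc <- acc + w * img[rr, c2]
            wsum <- wsum + w
          }
        }
      }
      out[r, cc] <- acc / wsum
    }
  }
  out
}

# Brute-force robust z against a reference vector: (x - median) / (1.4826 * MAD).
brute_robust_z <- function(x, ref = x) {
  med <- median(ref)
  mad_raw <- median(abs(ref - med))
  (x - med) / (1.4826 * mad_raw)
}

# Well-summary table built directly from per-sample values (one well per
# sample, all QC-passing, damage-treated), for z-score unit tests.
summary_from_values <- function(values, staining = "ubiquitin_FK2",
                                genes = sprintf("G%02d", seq_along(values))) {
  out <- data.frame(
    well_id = sprintf("W%03d", seq_along(values)),
    gene = genes, reagent = "pool", treatment = "damaged",
    staining = staining, n_cells = 100L,
    median_percent = values, mean_percent = values, qc_pass = TRUE
  )
  class(out) <- c("well_summary", "data.frame")
  out
}

# Student-t upper tail by numerical integration of the density written out
# from its closed form (independent of stats::pt / stats::dt).
t_tail_numeric <- function(t, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  integrate(dens, abs(t), Inf, rel.tol = 1e-12)$value
}
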