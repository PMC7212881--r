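## Independent oracles and tiny fixtures shared across tests.

## Exhaustive pair-enumeration GLCM: loops over every reference pixel and
## counts the pair with its offset partner. Deliberately naive and
## structurally unrelated to glcm().
glcm_oracle <- function(levelimg, d, orientation_deg, levels) {
  off <- switch(as.character(orientation_deg),
                "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d))
  counts <- matrix(0, levels, levels)
  nr <- nrow(levelimg); nc <- ncol(levelimg)
  for (r in seq_len(nr)) {
    for (cl in seq_len(nc)) {
      r2 <- r + off[1]; c2 <- cl + off[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        i <- levelimg[r, cl] + 1L; j <- levelimg[r2, c2] + 1L
        counts[i, j] <- counts[i, j] + 1
      }
    }
  }
  counts
}

## Direct two-Gaussian Bayes posterior: evaluates both multivariate normal
## densities with the pooled covariance explicitly and normalizes.
posterior_oracle <- function(x, mu0, mu1, sigma, priors) {
  dens <- function(mu) {
    p <- length(x)
    z <- x - mu
    exp(-0.5 * as.numeric(t(z) %*% solve(sigma) %*% z)) /
      sqrt((2 * pi)^p * det(sigma))
  }
  d0 <- priors[1] * dens(mu0)
  d1 <- priors[2] * dens(mu1)
  unname(d1 / (d0 + d1))
}

## A small non-constant FoV with reproducible texture.
tiny_fov <- function(nr = 48, nc = 64, seed = 42, channel = "CARS",
                     pixel_size_um = 1) {
  set.seed(seed)
  px <- matrix(runif(nr * nc), nr, nc) +
    outer(seq_len(nr) / nr, seq_len(nc) / nc)
  mp_fov(px, pixel_size_um = pixel_size_um, channel = channel,
         sample_id = "T", grid_row = 0L, grid_col = 0L)
}

## Texture config with short distances, for FoVs smaller than 40 px.
small_config <- function(channels = c("CARS", "TPEF")) {
  texture_config(distances_um = c(2, 5), channels = channels)
}

## Plain numeric matrix, shorn of all attributes, for bit-exact comparisons.
strip_mat <- function(m) matrix(as.numeric(m), nrow(m), ncol(m))

## Multivariate normal draw via the Cholesky transform.
mvtnorm_draw <- function(n, mu, sigma) {
  p <- length(mu)
  matrix(rnorm(n * p), n, p) %*% chol(sigma) + matrix(mu, n, p, byrow = TRUE)
}
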