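#' Parameters of the multi-scale Hessian vesselness filter
#'
#' The filter enhances curvilinear (vessel-like) structures by analyzing the
#' eigenvalues \eqn{\lambda_1, \lambda_2} (\eqn{|\lambda_1| \le |\lambda_2|})
#' of the scale-normalized image Hessian. At each scale \eqn{\sigma} the
#' response is
#' \deqn{V_\sigma = \exp(-R_B^2 / 2\beta^2)\,(1 - \exp(-S^2 / 2c^2))}
#' with blobness \eqn{R_B = \lambda_1/\lambda_2} and structureness
#' \eqn{S = \sqrt{\lambda_1^2 + \lambda_2^2}}, zeroed where the eigenvalue
#' sign does not match the requested polarity; the final response is the
#' per-pixel maximum over scales.
#'
#' @param sigmas strictly increasing Gaussian scales in pixels (vessel
#'   half-widths to respond to). Default `1:5` px covers coronary calibers at
#'   typical angiographic zoom.
#' @param beta blobness sensitivity \eqn{\beta > 0}; default 0.5 (the
#'   reference-filter convention).
#' @param c structureness sensitivity \eqn{c > 0} expressed on the `[0, 1]`
#'   intensity scale. Default `15/255`: the classic 8-bit default re-expressed
#'   for unit-scale images (the Hessian scales linearly with intensity).
#' @param polarity `"dark-on-bright"` (contrast-filled vessels in standard
#'   display; keeps \eqn{\lambda_2 > 0}) or `"bright-on-dark"`.
#' @return a `frangi_params` list.
#' @export
frangi_params <- function(sigmas = c(1, 2, 3, 4, 5), beta = 0.5, c = 15 / 255,
                          polarity = c("dark-on-bright", "bright-on-dark")) {
  polarity <- match.arg(polarity)
  if (!is.numeric(sigmas) || length(sigmas) == 0L || any(!is.finite(sigmas)) ||
      any(sigmas <= 0) || is.unsorted(sigmas, strictly = TRUE))
    ct_parameter_error("sigmas must be a non-empty strictly increasing positive vector")
  if (!is_scalar_number(beta) || beta <= 0)
    ct_parameter_error("beta must be strictly positive")
  if (!is_scalar_number(c) || c <= 0)
    ct_parameter_error("c must be strictly positive")
  structure(list(sigmas = as.numeric(sigmas), beta = beta, c = c,
                 polarity = polarity),
            class = "frangi_params")
}

## ---- separable convolution with reflect padding ---------------------------

#' Reflect-pad a matrix by r rows/cols on each side ("symmetric" reflection,
#' edge pixel not repeated beyond itself: a b c -> b a | a b c | c b).
#' @noRd
pad_reflect <- function(m, r) {
  if (r == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (r >= nr || r >= nc)
    ct_scale_error("frame smaller than the largest Gaussian support")
  ri <- c(r:1, 1:nr, nr:(nr - r + 1))
  ci <- c(r:1, 1:nc, nc:(nc - r + 1))
  m[ri, ci]
}

#' Convolve a padded matrix with a separable kernel pair (rows then cols) by
#' shift-and-add; `m` must already be reflect-padded by `r` on all sides.
#' @noRd
conv_sep_padded <- function(m, kr, kc, r, out_nr, out_nc) {
  ## pass 1: along rows (vertical direction, kernel kr)
  tmp <- matrix(0, out_nr, ncol(m))
  for (j in seq_along(kr)) {
    if (kr[j] != 0)
      tmp <- tmp + kr[j] * m[(j):(j + out_nr - 1L), , drop = FALSE]
  }
  ## pass 2: along cols (horizontal direction, kernel kc)
  out <- matrix(0, out_nr, out_nc)
  for (j in seq_along(kc)) {
    if (kc[j] != 0)
      out <- out + kc[j] * tmp[, (j):(j + out_nc - 1L), drop = FALSE]
  }
  out
}

#' Sampled Gaussian and its first/second derivatives on a symmetric support.
#' The smoothing kernel is normalized to unit sum; derivative kernels keep the
#' analytic amplitude (scale normalization is applied to the Hessian).
#' @noRd
gauss_kernels <- function(sigma, radius) {
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  g1 <- (-x / sigma^2) * g
  g2 <- ((x^2 - sigma^2) / sigma^4) * g
  list(g = g, g1 = g1, g2 = g2)
}

#' Scale-normalized Hessian of a frame at one Gaussian scale
#'
#' @return list of matrices `hrr`, `hrc`, `hcc` (second derivatives along rows,
#'   mixed, along cols), each multiplied by `sigma^2` (gamma = 2 normalization)
#'   so responses are comparable across scales.
#' @noRd
hessian_at_scale <- function(frame, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- gauss_kernels(sigma, r)
  p <- pad_reflect(frame, r)
  nr <- nrow(frame); nc <- ncol(frame)
  s2 <- sigma^2
  list(
    hrr = s2 * conv_sep_padded(p, k$g2, k$g,  r, nr, nc),
    hrc = s2 * conv_sep_padded(p, k$g1, k$g1, r, nr, nc),
    hcc = s2 * conv_sep_padded(p, k$g,  k$g2, r, nr, nc)
  )
}

#' Multi-scale Frangi vesselness
#'
#' Computes the per-pixel vesselness response of a single grayscale frame:
#' the maximum over the configured scales of the Hessian-eigenvalue response
#' (see [frangi_params()]). To avoid boundary artifacts from the Gaussian
#' derivative support, the response is forcibly zeroed on a margin of
#' `ceiling(3 * max(sigmas))` pixels.
#'
#' @param frame numeric matrix with finite values (intensities in `[0, 1]`).
#' @param params a [frangi_params()] object.
#' @return numeric matrix in `[0, 1]`, same dimensions as `frame`.
#' @examples
#' f <- matrix(1, 40, 40); f[18:21, ] <- 0  # dark horizontal band
#' v <- frangi_vesselness(f, frangi_params(sigmas = c(1, 2, 3)))
#' range(v)
#' @export
frangi_vesselness <- function(frame, params = frangi_params()) {
  if (!is.matrix(frame) || !is.numeric(frame) || !all(is.finite(frame)))
    ct_validation_error("frame must be a finite numeric matrix")
  if (!inherits(params, "frangi_params"))
    ct_parameter_error("params must be a frangi_params object")
  margin <- as.integer(ceiling(3 * max(params$sigmas)))
  if (2L * margin >= min(dim(frame)))
    ct_scale_error(sprintf(
      "frame (%dx%d) smaller than support of largest scale (margin %d px)",
      nrow(frame), ncol(frame), margin))

  v <- matrix(0, nrow(frame), ncol(frame))
  two_b2 <- 2 * params$beta^2
  two_c2 <- 2 * params$c^2
  for (sigma in params$sigmas) {
    h <- hessian_at_scale(frame, sigma)
    ## eigenvalues of the symmetric 2x2 Hessian, closed form
    mean_h <- (h$hrr + h$hcc) / 2
    delta  <- sqrt(((h$hrr - h$hcc) / 2)^2 + h$hrc^2)
    e1 <- mean_h + delta
    e2 <- mean_h - delta
    ## order by |.|: lambda2 is the larger-magnitude eigenvalue
    swap <- abs(e1) > abs(e2)
    lambda1 <- ifelse(swap, e2, e1)
    lambda2 <- ifelse(swap, e1, e2)

    rb2 <- ifelse(lambda2 == 0, 0, (lambda1 / lambda2)^2)
    s2  <- lambda1^2 + lambda2^2
    resp <- exp(-rb2 / two_b2) * (1 - exp(-s2 / two_c2))
    keep <- if (params$polarity == "dark-on-bright") lambda2 > 0 else lambda2 < 0
    resp[!keep] <- 0
    v <- pmax(v, resp)
  }
  ## zero the unreliable border band
  v[c(seq_len(margin), seq.int(nrow(v) - margin + 1L, nrow(v))), ] <- 0
  v[, c(seq_len(margin), seq.int(ncol(v) - margin + 1L, ncol(v)))] <- 0
  v
}
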