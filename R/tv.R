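# Exact 1-D total-variation denoising by Condat's direct non-iterative
# algorithm: taut-string tracking of the running segment with lower/upper
# tube bounds.  O(n) in practice.

.tv1d <- function(y, lam) {
  N <- length(y)
  if (N <= 1L || lam == 0) return(y)
  x <- numeric(N)
  k <- k0 <- km <- kp <- 1L
  vmin <- y[1] - lam; vmax <- y[1] + lam
  umin <- lam; umax <- -lam
  repeat {
    if (k == N) {
      if (umin < 0) {                       # forced negative jump at the end
        x[k0:km] <- vmin
        k <- k0 <- km <- km + 1L
        vmin <- y[k]
        umin <- lam
        umax <- y[k] + lam - vmax
        next
      } else if (umax > 0) {                # forced positive jump at the end
        x[k0:kp] <- vmax
        k <- k0 <- kp <- kp + 1L
        vmax <- y[k]
        umax <- -lam
        umin <- y[k] - lam - vmin
        next
      } else {                              # the last segment is flat
        x[k0:N] <- vmin + umin / (k - k0 + 1)
        return(x)
      }
    }
    if (y[k + 1L] + umin < vmin - lam) {    # negative jump is certain
      x[k0:km] <- vmin
      k <- k0 <- km <- kp <- km + 1L
      vmin <- y[k]; vmax <- y[k] + 2 * lam
      umin <- lam; umax <- -lam
    } else if (y[k + 1L] + umax > vmax + lam) {  # positive jump is certain
      x[k0:kp] <- vmax
      k <- k0 <- km <- kp <- kp + 1L
      vmin <- y[k] - 2 * lam; vmax <- y[k]
      umin <- lam; umax <- -lam
    } else {                                # extend the current segment
      k <- k + 1L
      umin <- umin + y[k] - vmin
      umax <- umax + y[k] - vmax
      if (umin >= lam) {
        vmin <- vmin + (umin - lam) / (k - k0 + 1)
        umin <- lam
        km <- k
      }
      if (umax <= -lam) {
        vmax <- vmax + (umax + lam) / (k - k0 + 1)
        umax <- -lam
        kp <- k
      }
    }
  }
}

#' Total-variation denoising of per-bin anomaly scores
#'
#' Computes the exact minimizer of
#' \deqn{\tfrac12 \lVert u - s \rVert_2^2 + \lambda \sum_i |u_{i+1} - u_i|}
#' for a 1-D signal `s`, i.e. the proximal operator of the (anisotropic)
#' total-variation seminorm.  The solution is piecewise constant, which
#' matches the segmental structure of copy-number signals: smoothing pools
#' information across adjacent bins so that whole aberrant segments, not
#' isolated noisy bins, stand out.  When a grouping factor is supplied the
#' problem is solved independently within each group (chromosomes are not
#' coupled).
#'
#' @param scores Numeric vector of per-bin scores (finite).
#' @param lam Non-negative penalty; `0` returns the input unchanged, and a
#'   very large value returns each group's mean.
#' @param chrom Optional grouping vector (e.g. chromosome of each bin),
#'   same length as `scores`.
#' @return Numeric vector of smoothed scores.
#' @export
tvDenoise <- function(scores, lam, chrom = NULL) {
  if (!is.numeric(scores) || any(!is.finite(scores)))
    stop("scores must be finite numeric")
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0)
    stop("lam must be a single non-negative number")
  if (is.null(chrom))
    return(.tv1d(scores, lam))
  stopifnot(length(chrom) == length(scores))
  out <- numeric(length(scores))
  for (g in unique(chrom)) {
    i <- which(chrom == g)
    out[i] <- .tv1d(scores[i], lam)
  }
  out
}
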