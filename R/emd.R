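#' Empirical mode decomposition by cubic-spline sifting
#'
#' Standard Huang-style sifting: upper and lower envelopes are cubic
#' splines through the local extrema, the envelope mean is subtracted
#' until the component is near zero-mean (Cauchy-type stopping criterion),
#' and the component is removed from the signal before extracting the
#' next, lower-frequency one. Components come out in decreasing order of
#' contributing frequency.
#'
#' @param x numeric signal.
#' @param max_imfs maximum number of intrinsic mode functions to extract.
#' @param max_sifts maximum sifting iterations per IMF.
#' @param tol Cauchy stopping tolerance on consecutive sift iterates.
#' @return list with `imfs` (list of IMFs, highest frequency first) and
#'   `residual`.
#' @export
emd_decompose <- function(x, max_imfs = 4L, max_sifts = 8L, tol = 0.2) {
  n <- length(x)
  t_all <- seq_len(n)
  imfs <- list()
  res <- x
  for (k in seq_len(max_imfs)) {
    h <- res
    ok <- FALSE
    for (s in seq_len(max_sifts)) {
      d <- diff(h)
      sg <- diff(sign(d))
      imax <- which(sg < 0) + 1L
      imin <- which(sg > 0) + 1L
      if (length(imax) < 3L || length(imin) < 3L) break
      up <- stats::spline(c(1L, imax, n), c(h[1L], h[imax], h[n]),
                          xout = t_all)$y
      lo <- stats::spline(c(1L, imin, n), c(h[1L], h[imin], h[n]),
                          xout = t_all)$y
      m <- (up + lo) / 2
      h_new <- h - m
      ok <- TRUE
      if (sum(m^2) / max(sum(h^2), 1e-30) < tol^2) { h <- h_new; break }
      h <- h_new
    }
    if (!ok) break
    imfs[[k]] <- h
    res <- res - h
  }
  list(imfs = imfs, residual = res)
}
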