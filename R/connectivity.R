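#' Histogram plug-in mutual information (bits)
#'
#' Functional connectivity between two electrode signals is estimated as
#' I(X;Y) = sum p(a,b) log2( p(a,b) / (p(a) p(b)) ) over a `bins x bins`
#' joint histogram with per-variable equal-width bin edges spanning
#' \[min, max\]. The plug-in estimate is nonnegative by construction
#' (clipped at 0 against floating-point round-off). Equal-width binning is
#' invariant to affine rescaling of either input, so MI does not depend on
#' amplifier gain or DC offset.
#'
#' @param x,y Numeric vectors of equal length `>= bins`.
#' @param bins Number of bins per variable (default 8).
#' @return Mutual information in bits; a constant input (degenerate
#'   marginal, zero entropy) gives 0.
#' @export
histogram_mi <- function(x, y, bins = 8L) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= bins, bins >= 2L, all(is.finite(x)),
            all(is.finite(y)))
  ix <- bin_index(x, bins)
  iy <- bin_index(y, bins)
  if (is.null(ix) || is.null(iy)) return(0)  # constant marginal
  n <- length(x)
  joint <- tabulate((iy - 1L) * bins + ix, nbins = bins * bins) / n
  px <- tabulate(ix, nbins = bins) / n
  py <- tabulate(iy, nbins = bins) / n
  pxy <- matrix(joint, bins, bins)
  denom <- outer(px, py)
  nz <- pxy > 0
  max(0, sum(pxy[nz] * log2(pxy[nz] / denom[nz])))
}

# Equal-width bin assignment on [min, max]; NULL for a constant vector.
bin_index <- function(x, bins) {
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(NULL)
  ix <- floor((x - rng[1L]) / (rng[2L] - rng[1L]) * bins) + 1L
  pmin.int(as.integer(ix), bins)
}

#' Mutual-information adjacency matrix of a window's EEG channels
#'
#' Computes [histogram_mi()] for every unordered pair of EEG channels,
#' yielding a complete weighted functional-connectivity graph: symmetric,
#' nonnegative, zero diagonal. No thresholding or normalization is applied;
#' downstream graph measures use the weighted formulas directly.
#'
#' @param window An `emo_window` (or any object with an `eeg`
#'   channels-x-samples matrix with rownames).
#' @param bins Histogram bins per variable (default 8).
#' @return An `emo_adjacency`: the weight matrix with channel labels as
#'   dimnames.
#' @export
connectivity_matrix <- function(window, bins = 8L) {
  eeg <- window$eeg
  stopifnot(is.matrix(eeg), nrow(eeg) >= 2L, !is.null(rownames(eeg)))
  n <- nrow(eeg)
  labels <- rownames(eeg)
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      w <- tryCatch(histogram_mi(eeg[i, ], eeg[j, ], bins),
                    error = function(e)
                      stop("pair (", labels[i], ", ", labels[j], "): ",
                           conditionMessage(e)))
      W[i, j] <- W[j, i] <- w
    }
  }
  structure(W, class = c("emo_adjacency", "matrix", "array"))
}

#' Validate adjacency-matrix invariants
#'
#' @param W Square numeric matrix.
#' @return `W` invisibly; errors if not symmetric nonnegative with zero
#'   diagonal and at least 2 nodes.
#' @export
check_adjacency <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W), nrow(W) >= 2L)
  if (any(W < 0)) stop("adjacency weights must be nonnegative")
  if (any(diag(W) != 0)) stop("adjacency diagonal must be zero")
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-12, check.attributes = FALSE)))
    stop("adjacency matrix must be symmetric")
  invisible(W)
}
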