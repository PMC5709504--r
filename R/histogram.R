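#' Binned cell-cycle-time histogram
#'
#' Container for a density histogram of cell-cycle times: strictly increasing
#' bin edges and nonnegative density heights whose total area must be within
#' `[0.9, 1.1]` of one. This is the object the least-squares fitter consumes.
#'
#' @param bin_edges Strictly increasing vector of `n + 1` bin edges (time).
#' @param heights Vector of `n` density heights (1/time).
#' @return A tibble of class `"cct_histogram"` with columns `bin_left`,
#'   `bin_right`, `mid` and `density`.
#' @seealso [generate_synthetic_histogram()], [fit_cctd()],
#'   [read_cct_histogram()]
#' @export
cct_histogram <- function(bin_edges, heights) {
  if (length(bin_edges) != length(heights) + 1) {
    abort("`bin_edges` must have one more entry than `heights`.")
  }
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    abort("`bin_edges` must be strictly increasing.")
  }
  if (any(heights < 0)) abort("Density heights must be nonnegative.")
  area <- sum(heights * diff(bin_edges))
  if (area < 0.9 || area > 1.1) {
    abort(sprintf(
      "Histogram area %.4f is outside [0.9, 1.1]; heights must be densities.",
      area))
  }
  out <- tibble(bin_left = bin_edges[-length(bin_edges)],
                bin_right = bin_edges[-1],
                mid = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
                density = as.numeric(heights))
  structure(out, class = c("cct_histogram", class(out)))
}

#' Generate a synthetic cell-cycle-time histogram
#'
#' Stands in for experimental CCT histograms (which are typically published as
#' figures, not deposited data): draws `n` cell-cycle times from a known
#' distribution with [sample_cct()] and bins them into `bins` equal-width
#' density bins over `[0, max(sample)]`. The histogram area is exactly one.
#'
#' @param p A [cct_params] object — the generating distribution.
#' @param n Number of sampled cell-cycle times (`>= 100`).
#' @param bins Number of equal-width bins (`>= 3`).
#' @param seed Optional integer seed; same seed, same histogram.
#' @return A [cct_histogram].
#' @export
generate_synthetic_histogram <- function(p, n = 1e5, bins = 50, seed = NULL) {
  if (n < 100) abort("`n` must be at least 100 samples.")
  if (bins < 3) abort("`bins` must be at least 3.")
  x <- sample_cct(p, n, seed = seed)
  edges <- seq(0, max(x), length.out = bins + 1)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = bins)
  cct_histogram(edges, counts / (n * diff(edges)))
}

#' Read / write a cell-cycle-time histogram CSV
#'
#' Two-column CSV format `bin_left_edge, density_height` with one row per bin
#' plus a final row carrying the right edge of the last bin (its height field
#' is empty).
#'
#' @param path File path.
#' @param h A [cct_histogram].
#' @return `read_cct_histogram()` returns a [cct_histogram];
#'   `write_cct_histogram()` returns `path` invisibly.
#' @export
read_cct_histogram <- function(path) {
  d <- utils::read.csv(path, header = TRUE)
  n <- nrow(d)
  cct_histogram(bin_edges = d[[1]], heights = d[[2]][-n])
}

#' @rdname read_cct_histogram
#' @export
write_cct_histogram <- function(h, path) {
  stopifnot(inherits(h, "cct_histogram"))
  d <- data.frame(bin_left_edge = c(h$bin_left, h$bin_right[nrow(h)]),
                  density_height = c(h$density, NA))
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}
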