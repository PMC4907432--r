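#' Seeded 1-D k-means++ clustering of intensities
#'
#' k-means++ initialisation (first centre uniform over pixels, subsequent
#' centres sampled with probability proportional to squared distance from the
#' nearest chosen centre) followed by Lloyd iterations via [stats::kmeans].
#' Runs on the distinct intensity values weighted by their multiplicities,
#' which is exact for 1-D data and fast on large images. The global RNG state
#' is saved and restored, so callers see fully deterministic behaviour for a
#' fixed `seed` without side effects.
#'
#' @param x numeric vector of intensities.
#' @param k number of clusters, >= 2; reduced with a warning when `x` has
#'   fewer distinct values.
#' @param seed integer RNG seed.
#' @return list with `centers` (sorted ascending), `k` (possibly reduced),
#'   `boundaries` (k-1 midpoints between adjacent centres), and
#'   `assign_fun(v)` mapping intensities to cluster index (1 = darkest).
#' @export
kmeanspp_1d <- function(x, k, seed = 0) {
  stopifnot(k >= 2)
  vals <- sort(unique(x))
  if (length(vals) < k) {
    warning(sprintf("only %d distinct values; reducing k from %d",
                    length(vals), k))
    k <- length(vals)
  }
  if (k < 2) stop("need at least 2 distinct intensity values to cluster")
  cnt <- tabulate(match(x, vals), nbins = length(vals))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ## k-means++ seeding on the weighted distinct values
  centers <- numeric(k)
  centers[1] <- vals[sample.int(length(vals), 1, prob = cnt)]
  d2 <- (vals - centers[1])^2
  for (j in seq_len(k - 1) + 1) {
    w <- cnt * d2
    if (all(w == 0)) {  # all remaining mass sits on chosen centres
      centers[j] <- vals[which.max(d2)]
    } else {
      centers[j] <- vals[sample.int(length(vals), 1, prob = w)]
    }
    d2 <- pmin(d2, (vals - centers[j])^2)
  }
  ## weighted Lloyd on distinct values (exact for the full multiset)
  centers <- sort(centers)
  for (it in seq_len(200)) {
    bnd <- (centers[-1] + centers[-k]) / 2
    cl <- findInterval(vals, bnd) + 1L
    new_c <- vapply(seq_len(k), function(j) {
      m <- cl == j
      if (any(m)) sum(vals[m] * cnt[m]) / sum(cnt[m]) else centers[j]
    }, 0)
    new_c <- sort(new_c)
    if (max(abs(new_c - centers)) < 1e-10) { centers <- new_c; break }
    centers <- new_c
  }
  bnd <- (centers[-1] + centers[-k]) / 2
  list(centers = centers, k = k, boundaries = bnd,
       assign_fun = function(v) findInterval(v, bnd) + 1L)
}
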