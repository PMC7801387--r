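# The topological irregularity (TDA) score: each 2-s window is time-delay
# embedded into R^d, degree-1 Vietoris-Rips persistent homology is computed
# on the resulting point cloud, and the area under the Betti-1 curve is the
# window score. A clean oscillation embeds to a closed loop (one dominant,
# long-lived hole); irregular slowed activity produces a different loop
# structure, which the Betti-curve area summarizes in a single number.

#' Time-delay embedding of a scalar series
#'
#' Point `i` is `(x[i], x[i + lag], ..., x[i + (dim - 1) * lag])`, giving
#' `N - (dim - 1) * lag` points in `dim` dimensions (Takens-style state
#' space reconstruction).
#'
#' @param x Numeric vector (the window samples).
#' @param dim Embedding dimension, at least 2.
#' @param lag Delay in samples, positive integer. The default used by the
#'   pipeline is `round(sampling_rate / 10)`, about 100 ms.
#' @return Numeric matrix, one point per row.
#' @export
delay_embed <- function(x, dim = 3, lag = 1) {
  stopifnot(dim >= 2, lag >= 1, dim == round(dim), lag == round(lag))
  n <- length(x) - (dim - 1) * lag
  if (n < 1L) stop("window too short for embedding")
  idx <- outer(seq_len(n), (seq_len(dim) - 1L) * lag, `+`)
  matrix(x[idx], nrow = n, ncol = dim)
}

#' Degree-1 Vietoris-Rips persistence of a point cloud
#'
#' In the Rips filtration a simplex enters at its largest pairwise
#' (Euclidean) distance. Degree-1 birth/death pairs are computed by GF(2)
#' boundary-matrix reduction in compiled code; deaths are capped at
#' `max_filtration` and zero-length pairs are discarded.
#'
#' @param cloud Numeric matrix, one point per row.
#' @param max_filtration Largest filtration scale, or `"auto"` (the cloud
#'   diameter, so every loop's death is resolved and the Betti-curve area
#'   is finite without a global constant).
#' @param degree 1 (scored) or 0 (connected-component merge scales,
#'   reported for diagnostics only).
#' @return A `persistence_diagram`: data frame with `birth` and `death`
#'   columns plus attributes `degree`, `max_filtration`, `diameter`.
#' @export
rips_persistence_h1 <- function(cloud, max_filtration = "auto", degree = 1) {
  cloud <- as.matrix(cloud)
  storage.mode(cloud) <- "double"
  stopifnot(nrow(cloud) >= 1L, all(is.finite(cloud)), degree %in% c(0, 1))
  maxf <- if (identical(max_filtration, "auto")) -1 else as.numeric(max_filtration)
  res <- .rips_pairs_cpp(cloud, maxf)
  pairs <- if (degree == 1) res$h1 else res$h0
  keep <- pairs[, 2] > pairs[, 1]
  df <- data.frame(birth = pairs[keep, 1], death = pairs[keep, 2])
  df <- df[order(df$birth, df$death), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("persistence_diagram", "data.frame"),
            degree = degree, max_filtration = res$max_filtration,
            diameter = res$diameter)
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("<persistence_diagram> degree %d, %d pairs, scale [0, %.4g]\n",
              attr(x, "degree"), nrow(x), attr(x, "max_filtration")))
  if (nrow(x)) print.data.frame(utils::head(x, 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' @export
plot.persistence_diagram <- function(x, ...) {
  lim <- c(0, attr(x, "max_filtration"))
  plot(x$birth, x$death, xlim = lim, ylim = lim, xlab = "birth",
       ylab = "death", pch = 19,
       main = sprintf("degree-%d persistence", attr(x, "degree")), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Betti curve of a persistence diagram
#'
#' `counts[j]` is the number of pairs alive at grid value `eps_j`, i.e.
#' with `birth <= eps_j < death`, on a uniform grid from 0 to
#' `max_filtration`.
#'
#' @param diagram A `persistence_diagram`.
#' @param grid_size Number of grid points (>= 2).
#' @param max_filtration Grid upper end; defaults to the diagram's.
#' @return A `betti_curve`: list with `grid` and `counts`.
#' @export
betti_curve <- function(diagram, grid_size = 200,
                        max_filtration = attr(diagram, "max_filtration")) {
  if (grid_size < 2L) stop("grid_size must be at least 2")
  grid <- seq(0, max_filtration, length.out = grid_size)
  counts <- vapply(grid, function(eps) {
    sum(diagram$birth <= eps & eps < diagram$death)
  }, numeric(1))
  structure(list(grid = grid, counts = counts,
                 max_filtration = max_filtration),
            class = "betti_curve")
}

#' @export
plot.betti_curve <- function(x, ...) {
  plot(x$grid, x$counts, type = "s", xlab = expression(epsilon),
       ylab = expression(beta[1](epsilon)), main = "Betti-1 curve", ...)
  invisible(x)
}

#' Area under a Betti curve
#'
#' Left-rectangular-rule integral over the grid; refines to the exact value
#' [betti_area_exact()] (the total persistence, sum of death − birth) as
#' the grid grows. At the default 200-point grid the discretization error
#' is at most one grid step times the curve maximum.
#'
#' @param curve A `betti_curve`.
#' @return Numeric area.
#' @export
betti_area <- function(curve) {
  stopifnot(inherits(curve, "betti_curve"))
  step <- curve$grid[2] - curve$grid[1]
  sum(curve$counts[-length(curve$counts)]) * step
}

#' @rdname betti_area
#' @param diagram A `persistence_diagram`.
#' @export
betti_area_exact <- function(diagram) {
  sum(diagram$death - diagram$birth)
}

#' Topological irregularity score of a single window
#'
#' Z-scores the window (so the score is amplitude-invariant), delay-embeds
#' it, subsamples by uniform stride to at most `max_points` points
#' (deterministic), computes degree-1 Rips persistence with the filtration
#' capped at the cloud diameter, and returns the Betti-1 curve area.
#'
#' @param x Samples of one QC-passed window (µV).
#' @param sampling_rate Hz (after any decimation).
#' @param params The `tda` element of [bseeg_config()].
#' @return Numeric score (non-negative; the signed subject score is formed
#'   in [aggregate_tda()]).
#' @export
tda_window_score <- function(x, sampling_rate, params = bseeg_config()$tda) {
  x <- as.numeric(x)
  lag <- if (is.null(params$embed_lag)) max(1L, round(sampling_rate / 10)) else
    params$embed_lag
  if (isTRUE(params$normalize)) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("zero-variance window cannot be normalized")
    x <- (x - mean(x)) / s
  }
  cloud <- delay_embed(x, dim = params$embed_dim, lag = lag)
  if (nrow(cloud) > params$max_points) {
    stride <- ceiling(nrow(cloud) / params$max_points)
    cloud <- cloud[seq(1L, nrow(cloud), by = stride), , drop = FALSE]
  }
  dg <- rips_persistence_h1(cloud, max_filtration = params$max_filtration)
  betti_area(betti_curve(dg, grid_size = params$grid_size))
}

#' Aggregate per-window TDA scores into a subject-channel score
#'
#' Median (default) or mean of the window scores, minus `center_offset`.
#' The offset (default 0) lets a deployment express the score relative to a
#' reference cohort so that irregular recordings land positive and normal
#' ones negative.
#'
#' @param window_scores Numeric vector of per-window scores.
#' @param params List with `aggregate` and `center_offset` elements.
#' @return Numeric scalar, or `NA` (with a warning) for empty input.
#' @export
aggregate_tda <- function(window_scores, params = bseeg_config()$tda) {
  window_scores <- window_scores[!is.na(window_scores)]
  if (!length(window_scores)) {
    warning("no usable windows: score is missing")
    return(NA_real_)
  }
  agg <- switch(params$aggregate,
                median = stats::median(window_scores),
                mean = mean(window_scores),
                stop("unknown aggregate: ", params$aggregate))
  agg - params$center_offset
}
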