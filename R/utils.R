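## Internal helpers shared across modules.

# round-half-up; base round() rounds halves to even, which would make
# rasterization depend on parity of the pixel index
round_half_up <- function(x) floor(x + 0.5)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_if_not_number <- function(x, what, positive = FALSE, nonneg = FALSE) {
  if (!is_scalar_number(x)) {
    abort(sprintf("`%s` must be a single finite number.", what))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", what))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0.", what))
  invisible(x)
}

# coerce a points argument (n x 2 matrix, data frame with x/y, or length-2
# vector) to an n x 2 numeric matrix with columns x, y
as_points_matrix <- function(points, allow_empty = TRUE) {
  if (is.null(points) || (is.atomic(points) && length(points) == 0L)) {
    pts <- matrix(numeric(0), ncol = 2L)
  } else if (is.data.frame(points)) {
    if (!all(c("x", "y") %in% names(points))) {
      abort("Point data frames must have columns `x` and `y`.")
    }
    pts <- cbind(as.numeric(points$x), as.numeric(points$y))
  } else if (is.matrix(points)) {
    if (ncol(points) != 2L) abort("Point matrices must have two columns (x, y).")
    pts <- points
    storage.mode(pts) <- "double"
  } else if (is.numeric(points) && length(points) == 2L) {
    pts <- matrix(as.numeric(points), ncol = 2L)
  } else {
    abort("Points must be an n x 2 matrix, a data frame with x/y, or c(x, y).")
  }
  colnames(pts) <- c("x", "y")
  if (!allow_empty && nrow(pts) == 0L) abort("At least one point is required.")
  pts
}

# Minimum-cost one-to-one assignment on a (possibly rectangular) cost matrix.
# Returns an integer vector of length nrow(cost): column assigned to each row,
# NA where the row is left unassigned (only when nrow > ncol).
solve_assignment <- function(cost) {
  nr <- nrow(cost)
  nc <- ncol(cost)
  if (nr == 0L || nc == 0L) return(rep(NA_integer_, nr))
  if (nr == 1L && nc == 1L) return(1L)
  if (nr <= nc) {
    sol <- clue::solve_LSAP(cost)
    as.integer(sol)
  } else {
    sol <- clue::solve_LSAP(t(cost))
    out <- rep(NA_integer_, nr)
    out[as.integer(sol)] <- seq_len(nc)
    out
  }
}

# Euclidean distance matrix between two n x 2 / m x 2 point sets
cross_dist <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

# 2-D convolution with zero padding, output cropped to the input size.
# Kernel must have odd dimensions.  Used for every PSF application.
convolve2d <- function(img, kernel) {
  kd <- dim(kernel)
  if (any(kd %% 2L == 0L)) abort("Convolution kernels must have odd sides.")
  EBImage::filter2(img, kernel, boundary = 0)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

clip_gray <- function(x) pmin(pmax(x, 0), 255)
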