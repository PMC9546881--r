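# shared fixtures: tiny configs and hand-built frames used across tests

# a frame with `heads` (n x 2) and optional tails rendered through the
# exported pipeline ops on a square frame
build_frame <- function(heads, tails = NULL, n = 160,
                        params = appearance_params()) {
  hb <- rasterize_points(heads, n)
  i5 <- render_head_center(hb, make_gaussian_psf(params$sigma_head), params)
  i6 <- render_membrane(hb, make_halo_psf(params$sigma_membrane), params)
  i8 <- if (is.null(tails)) {
    matrix(0, n, n)
  } else {
    render_flagellum(rasterize_points(tails, n),
                     make_ridge_psf(params$sigma_flagellum), params)
  }
  compose_sperm_image(i5, i6, i8)
}

# brute-force OSPA by enumerating all injections of the smaller set
ospa_brute <- function(X, Y, c = 20, p = 2) {
  if (nrow(X) > nrow(Y)) { tmp <- X; X <- Y; Y <- tmp }
  m <- nrow(X); n <- nrow(Y)
  if (n == 0) return(0)
  if (m == 0) return(c)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  for (subset in utils::combn(n, m, simplify = FALSE)) {
    for (perm in perms(subset)) {
      d <- sqrt(rowSums((X - Y[perm, , drop = FALSE])^2))
      best <- min(best, sum(pmin(d, c)^p))
    }
  }
  ((best + c^p * (n - m)) / n)^(1 / p)
}

# brute-force maximum matching under a distance cutoff (for small sets)
max_matching_brute <- function(G, D, cutoff) {
  ng <- nrow(G); nd <- nrow(D)
  if (ng == 0 || nd == 0) return(0L)
  dmat <- sqrt(outer(G[, 1], D[, 1], "-")^2 + outer(G[, 2], D[, 2], "-")^2)
  best <- 0L
  assign_next <- function(i, used, count) {
    if (i > ng) { best <<- max(best, count); return(invisible(NULL)) }
    assign_next(i + 1L, used, count)  # leave truth i unmatched
    for (j in seq_len(nd)) {
      if (!used[j] && dmat[i, j] <= cutoff) {
        used[j] <- TRUE
        assign_next(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  assign_next(1L, rep(FALSE, nd), 0L)
  best
}
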