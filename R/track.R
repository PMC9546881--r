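## Multi-target trackers over per-frame detections.
##
## All four algorithms share the constant-velocity Kalman core, Euclidean
## gating, 2-consecutive-hit confirmation and 3-consecutive-miss deletion;
## they differ only in how gated detections are associated to tracks:
##   nn    - per-track greedy nearest neighbour (track-id order, each
##           detection used once)
##   gnn   - global nearest neighbour: min-cost one-to-one assignment
##   pdaf  - per-track probabilistic weighting of all gated detections
##   jpdaf - joint probabilistic data association: feasible joint events
##           enumerated exactly within clusters of tracks sharing gated
##           detections (clusters above `jpdaf_max_cluster` tracks fall
##           back to a hard GNN assignment within the cluster)

TRACKER_ALGOS <- c("nn", "gnn", "pdaf", "jpdaf")

#' Track detections across frames
#'
#' Builds multi-frame tracks from a per-frame detection table using one of
#' four data-association algorithms on a shared constant-velocity Kalman
#' filter.  Unassociated detections start tentative tracks, which are
#' confirmed after `confirm_hits` consecutive associations and closed after
#' `max_misses` consecutive misses; only tracks that reach confirmation are
#' reported, and trailing coasted (miss-only) rows are trimmed.
#'
#' @param detections Tibble with columns `frame` (0-based, ordered), `x`,
#'   `y` (as from [detect_cells()]).
#' @param algo One of `"nn"`, `"gnn"`, `"pdaf"`, `"jpdaf"`.
#' @param cfg [kalman_config()].
#' @param n_frames Total number of frames (defaults to `max(frame) + 1`).
#' @param jpdaf_max_cluster Largest cluster enumerated exactly (default 8).
#' @return Tibble with columns `track_id`, `frame`, `x`, `y`, `coasted`.
#' @examples
#' det <- tibble::tibble(frame = 0:4, x = 10 + 2 * (0:4), y = 20, area = 9)
#' track_cells(det, "gnn")
#' @export
track_cells <- function(detections, algo = TRACKER_ALGOS,
                        cfg = kalman_config(), n_frames = NULL,
                        jpdaf_max_cluster = 8) {
  algo <- match.arg(algo, TRACKER_ALGOS)
  if (nrow(detections) == 0) {
    return(tibble::tibble(track_id = integer(0), frame = integer(0),
                          x = numeric(0), y = numeric(0),
                          coasted = logical(0)))
  }
  mats <- kalman_matrices(cfg)
  n_frames <- n_frames %||% (max(detections$frame) + 1L)
  det_by <- split(detections[c("x", "y")], detections$frame)

  tracks <- list()     # each: state, hits, misses, confirmed, rows, id
  next_id <- 1L
  warned_cluster <- FALSE
  done <- list()

  for (f in seq_len(n_frames) - 1L) {
    Z <- det_by[[as.character(f)]]
    Z <- if (is.null(Z)) matrix(numeric(0), ncol = 2L) else cbind(Z$x, Z$y)
    nz <- nrow(Z)
    nt <- length(tracks)

    # predict
    for (i in seq_len(nt)) tracks[[i]]$state <- kalman_predict(tracks[[i]]$state, mats)
    pred <- if (nt > 0) {
      t(vapply(tracks, function(tr) tr$state$x[1:2], numeric(2)))
    } else matrix(numeric(0), ncol = 2L)

    gate_mat <- if (nt > 0 && nz > 0) cross_dist(pred, Z) <= cfg$gate else
      matrix(FALSE, nt, nz)
    dmat <- if (nt > 0 && nz > 0) cross_dist(pred, Z) else matrix(0, nt, nz)

    used <- rep(FALSE, nz)
    assoc <- vector("list", nt)   # per track: NULL miss, z index vector + beta

    if (nt > 0 && nz > 0) {
      if (algo == "nn") {
        for (i in seq_len(nt)) {
          ok <- which(gate_mat[i, ] & !used)
          if (length(ok) > 0) {
            j <- ok[which.min(dmat[i, ok])]
            used[j] <- TRUE
            assoc[[i]] <- list(j = j, hard = TRUE)
          }
        }
      } else if (algo == "gnn") {
        big <- cfg$gate * (max(nt, nz) + 1)
        cost <- ifelse(gate_mat, dmat, big)
        sol <- solve_assignment(cost)
        for (i in seq_len(nt)) {
          j <- sol[i]
          if (!is.na(j) && gate_mat[i, j]) {
            used[j] <- TRUE
            assoc[[i]] <- list(j = j, hard = TRUE)
          }
        }
      } else if (algo == "pdaf") {
        det_beta <- rep(0, nz)   # strongest association of each detection
        for (i in seq_len(nt)) {
          ok <- which(gate_mat[i, ])
          if (length(ok) == 0) next
          st <- tracks[[i]]$state
          S <- mats$H %*% st$P %*% t(mats$H) + mats$R
          nus <- sweep(Z[ok, , drop = FALSE], 2, st$x[1:2])
          lik <- cfg$p_detect * gauss_lik(nus, S)
          # parametric PDAF: beta_i prop. to P_D f(z_i)/lambda, beta_0 to 1-P_D
          w <- lik / cfg$clutter_density
          denom <- (1 - cfg$p_detect) + sum(w)
          beta <- w / denom
          beta0 <- (1 - cfg$p_detect) / denom
          # a track whose miss hypothesis dominates is treated as missed
          # for maintenance; otherwise lost tracks coast forever inside
          # crowded gates
          if (beta0 <= 0.8) {
            assoc[[i]] <- list(j = ok, beta = beta, beta0 = beta0,
                               hard = FALSE)
          }
          det_beta[ok] <- pmax(det_beta[ok], beta)
        }
        # a gated detection only counts as consumed when some track claims
        # it with substantial probability; weakly-explained detections may
        # still initiate tracks
        used <- det_beta > cfg$spawn_claim
      } else { # jpdaf
        res <- jpda_associate(tracks, Z, gate_mat, dmat, mats, cfg,
                              jpdaf_max_cluster)
        assoc <- res$assoc
        used <- res$used
        if (res$fell_back && !warned_cluster) {
          warned_cluster <- TRUE
          warn("JPDAF cluster larger than the exact-enumeration limit; using per-cluster GNN approximation.")
        }
      }
    }

    # update, bookkeeping
    for (i in seq_len(nt)) {
      tr <- tracks[[i]]
      a <- assoc[[i]]
      if (is.null(a)) {
        tr$misses <- tr$misses + 1L
        tr$hits <- 0L
        coasted <- TRUE
      } else {
        if (isTRUE(a$hard)) {
          tr$state <- kalman_update(tr$state, Z[a$j, ], mats)
        } else {
          tr$state <- kalman_update_pda(tr$state, Z[a$j, , drop = FALSE],
                                        a$beta, a$beta0, mats)
        }
        tr$misses <- 0L
        tr$hits <- tr$hits + 1L
        if (!tr$confirmed && tr$hits >= cfg$confirm_hits) tr$confirmed <- TRUE
        coasted <- FALSE
      }
      tr$rows[[length(tr$rows) + 1L]] <-
        c(f, tr$state$x[1], tr$state$x[2], coasted)
      tracks[[i]] <- tr
    }

    # duplicate-track merging for the probabilistic associators: soft
    # assignments let two tracks coalesce onto one cell; keep the elder
    if (algo %in% c("pdaf", "jpdaf") && length(tracks) > 1L) {
      pos <- t(vapply(tracks, function(tr) tr$state$x[1:2], numeric(2)))
      dd <- cross_dist(pos, pos)
      drop <- rep(FALSE, length(tracks))
      for (i in seq_along(tracks)) {
        if (drop[i]) next
        dups <- which(dd[i, ] < 3 & seq_along(tracks) > i & !drop)
        drop[dups] <- TRUE
      }
      if (any(drop)) {
        done <- c(done, Filter(function(tr) tr$confirmed, tracks[drop]))
        tracks <- tracks[!drop]
      }
    }

    # close dead tracks
    if (nt > 0) {
      dead <- vapply(tracks, function(tr) tr$misses >= cfg$max_misses, logical(1))
      if (any(dead)) {
        done <- c(done, tracks[dead])
        tracks <- tracks[!dead]
      }
    }

    # unassociated detections spawn tentative tracks
    for (j in which(!used)) {
      tracks[[length(tracks) + 1L]] <- list(
        state = new_kalman_state(Z[j, ], cfg), hits = 1L, misses = 0L,
        confirmed = cfg$confirm_hits <= 1L,
        rows = list(c(f, Z[j, 1], Z[j, 2], FALSE)), id = next_id)
      next_id <- next_id + 1L
    }
  }

  done <- c(done, tracks)
  out <- purrr::map_dfr(done, function(tr) {
    if (!tr$confirmed) return(NULL)
    m <- do.call(rbind, tr$rows)
    # trim trailing coasted rows (never-updated tail of a dying track)
    keep <- max(which(m[, 4] == 0))
    m <- m[seq_len(keep), , drop = FALSE]
    tibble::tibble(track_id = tr$id, frame = as.integer(m[, 1]),
                   x = m[, 2], y = m[, 3], coasted = m[, 4] == 1)
  })
  if (nrow(out) > 0) out <- dplyr::arrange(out, .data$track_id, .data$frame)
  out
}

# joint probabilistic data association within connected clusters
jpda_associate <- function(tracks, Z, gate_mat, dmat, mats, cfg, max_cluster) {
  nt <- length(tracks); nz <- nrow(Z)
  assoc <- vector("list", nt)
  used <- rep(FALSE, nz)
  fell_back <- FALSE

  # connected components of the track-detection gating graph
  t_comp <- rep(NA_integer_, nt)
  z_comp <- rep(NA_integer_, nz)
  comp <- 0L
  for (i0 in seq_len(nt)) {
    if (!is.na(t_comp[i0])) next
    if (!any(gate_mat[i0, ])) { next }  # isolated track: miss
    comp <- comp + 1L
    queue_t <- i0
    while (length(queue_t) > 0) {
      i <- queue_t[1]; queue_t <- queue_t[-1]
      if (!is.na(t_comp[i])) next
      t_comp[i] <- comp
      zs <- which(gate_mat[i, ] & is.na(z_comp))
      z_comp[zs] <- comp
      for (z in which(gate_mat[i, ])) {
        queue_t <- c(queue_t, which(gate_mat[, z] & is.na(t_comp)))
      }
    }
  }

  if (comp == 0L) return(list(assoc = assoc, used = used, fell_back = FALSE))

  for (cl in seq_len(comp)) {
    ti <- which(t_comp == cl)
    zi <- which(z_comp == cl)
    if (length(ti) > max_cluster) {
      # approximation: hard GNN within the cluster
      fell_back <- TRUE
      big <- cfg$gate * (length(ti) + length(zi) + 1)
      cost <- ifelse(gate_mat[ti, zi, drop = FALSE],
                     dmat[ti, zi, drop = FALSE], big)
      sol <- solve_assignment(cost)
      for (a in seq_along(sol)) {
        j <- sol[a]
        if (!is.na(j) && gate_mat[ti[a], zi[j]]) {
          assoc[[ti[a]]] <- list(j = zi[j], hard = TRUE)
          used[zi[j]] <- TRUE
        }
      }
      next
    }

    # per-track likelihood of each gated detection in the cluster
    lik <- matrix(0, length(ti), length(zi))
    for (a in seq_along(ti)) {
      st <- tracks[[ti[a]]]$state
      S <- mats$H %*% st$P %*% t(mats$H) + mats$R
      ok <- gate_mat[ti[a], zi]
      if (any(ok)) {
        nus <- sweep(Z[zi[ok], , drop = FALSE], 2, st$x[1:2])
        lik[a, ok] <- gauss_lik(nus, S)
      }
    }

    # enumerate joint events: per track, 0 (miss) or an unused detection
    beta <- matrix(0, length(ti), length(zi))
    beta0 <- numeric(length(ti))
    enumerate <- function(a, usedz, weight) {
      if (a > length(ti)) {
        for (b in seq_along(ti)) {
          j <- usedz[b]
          if (j == 0L) beta0[b] <<- beta0[b] + weight
          else beta[b, j] <<- beta[b, j] + weight
        }
        return(invisible(NULL))
      }
      # miss branch
      usedz[a] <- 0L
      enumerate(a + 1L, usedz, weight * (1 - cfg$p_detect))
      # assignment branches
      for (j in seq_along(zi)) {
        if (lik[a, j] > 0 && !(j %in% usedz[seq_len(a - 1L)])) {
          usedz[a] <- j
          enumerate(a + 1L, usedz,
                    weight * cfg$p_detect * lik[a, j] / cfg$clutter_density)
        }
      }
      invisible(NULL)
    }
    enumerate(1L, integer(length(ti)), 1)

    tot <- beta0 + rowSums(beta)
    det_claim <- rep(0, length(zi))
    for (a in seq_along(ti)) {
      if (tot[a] <= 0) next
      bj <- beta[a, ] / tot[a]
      nzj <- which(bj > 0)
      if (length(nzj) == 0) next   # effectively a miss
      b0 <- beta0[a] / tot[a]
      if (b0 <= 0.8) {   # dominant miss hypothesis: leave as a miss
        assoc[[ti[a]]] <- list(j = zi[nzj], beta = bj[nzj], beta0 = b0,
                               hard = FALSE)
      }
      det_claim <- det_claim + bj
    }
    # detections claimed with substantial joint probability are consumed;
    # weakly-explained ones may still initiate tracks
    used[zi[det_claim > cfg$spawn_claim]] <- TRUE
  }
  list(assoc = assoc, used = used, fell_back = fell_back)
}
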