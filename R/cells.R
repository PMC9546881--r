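## Per-cell simulation state: creation, kinematic advance, mode transitions.
##
## A cell is a list: id, mode, t_ref (absolute time the current mode was
## initialized), params (mode-specific block), head, heading, tail (M x 2
## matrix), history (recent head positions, for trailing tails), intensity
## (factor in (0, 1] scaling the cell's deviation from background), and
## tail_gain (the cell's fixed flagellum calibration constant; NA until
## calibrated from its first rendered tail response).

new_cell <- function(id, mode, params, head, heading, t_ref = 0,
                     history = NULL, tail = NULL, intensity = 1) {
  structure(
    list(id = id, mode = mode, params = params,
         head = as.numeric(head), heading = heading, t_ref = t_ref,
         history = history, tail = tail, intensity = intensity,
         tail_gain = NA_real_),
    class = "casa_cell"
  )
}

# set a mode's offsets so that its closed-form head at local time 0 equals
# `start` and its motion direction approximates `heading`
init_mode_state <- function(id, mode, start, heading, t_ref, config,
                            intensity = 1) {
  T <- 1 / config$fps
  if (mode == "circular") {
    p <- config$circular
    p$phase0 <- heading - pi / 2          # tangent of the circle = heading
    p$t_beat0 <- runif(1, 0, 1 / max(p$f_s, 1e-9))
    p$offset <- c(0, 0)
    h0 <- circular_head(0, p)
    p$offset <- start - c(h0$x, h0$y)
    cell <- new_cell(id, mode, p, start, circular_heading(0, p), t_ref,
                     intensity = intensity)
    cell$tail <- circular_tail_xy(0, start, p)
    cell
  } else if (mode == "linear") {
    p <- config$linear
    p$theta_r <- heading
    p$t_beat0 <- runif(1, 0, 1 / max(p$f_l, 1e-9))
    p$A_c <- ribbon_constant(p$A_har)
    p$offset <- c(0, 0)
    h0 <- linear_head(0, p)
    p$offset <- start - c(h0$x, h0$y)
    cell <- new_cell(id, mode, p, start, heading, t_ref,
                     intensity = intensity)
    cell$tail <- linear_tail_xy(0, start, p)
    cell
  } else if (mode == "hyperactive") {
    p <- config$hyperactive
    n <- history_length(T)
    hist <- brownian_history(start, p, T, n)
    cell <- new_cell(id, mode, p, start, heading, t_ref,
                     history = hist, intensity = intensity)
    cell$tail <- trailing_tail_xy(hist, n, p$M)
    cell
  } else if (mode == "immotile") {
    # frozen snapshot of a hyperactive-style trailing tail
    p <- config$hyperactive
    n <- history_length(T)
    hist <- brownian_history(start, p, T, n)
    cell <- new_cell(id, "immotile", p, start, heading, t_ref,
                     history = hist, intensity = intensity)
    cell$tail <- trailing_tail_xy(hist, n, p$M)
    cell
  } else {
    abort(sprintf("Unknown swim mode '%s'.", mode))
  }
}

# history of past Brownian positions ending at `start` (oldest first)
brownian_history <- function(start, p, T, n) {
  steps <- matrix(p$sigma_b * sqrt(T) * rnorm(2L * n), ncol = 2L)
  pos <- rbind(matrix(0, 1, 2), apply(steps, 2, cumsum))
  pos <- sweep(pos, 2, pos[n + 1L, ] - start)  # translate end to `start`
  pos
}

tail_matrix <- function(tail_df) cbind(x = tail_df$x, y = tail_df$y)

# advance one cell to absolute time t (frame period T)
advance_cell <- function(cell, t, T) {
  tau <- t - cell$t_ref
  if (cell$mode == "circular") {
    h <- circular_head(tau, cell$params)
    cell$head <- c(h$x, h$y)
    cell$heading <- circular_heading(tau, cell$params)
    cell$tail <- circular_tail_xy(tau, cell$head, cell$params)
  } else if (cell$mode == "linear") {
    h <- linear_head(tau, cell$params)
    cell$head <- c(h$x, h$y)
    cell$tail <- linear_tail_xy(tau, cell$head, cell$params)
  } else if (cell$mode == "hyperactive") {
    if (tau > 0) {
      prev <- cell$head
      cell$head <- hyperactive_step(prev, cell$params, T)
      d <- cell$head - prev
      if (sum(abs(d)) > 0) cell$heading <- atan2(d[2], d[1])
      n <- history_length(T)
      cell$history <- tail(rbind(cell$history, cell$head), n + 1L)
      cell$tail <- trailing_tail_xy(cell$history, n, cell$params$M)
      # recalibrate the flagellum gain while the trailing history is still
      # filling (the polyline length is changing); once full, the gain is a
      # per-cell calibration constant
      if (!isTRUE(cell$gain_locked)) {
        cell$tail_gain <- NA_real_
        cell$gain_locked <- nrow(cell$history) >= n + 1L
      }
    }
  }
  # immotile: frozen
  cell
}

#' Resample a cell's swim mode from a transition model
#'
#' Draws the next mode from the transition row of the cell's current mode.
#' On a transition the cell is re-initialized in the new mode at its current
#' head position with its current heading preserved (mode parameters are
#' taken from the scene configuration's per-mode blocks); otherwise the cell
#' is returned unchanged.
#'
#' @param cell A cell state as created by the scene simulator.
#' @param tm [transition_model()].
#' @param config [simulation_config()] supplying the per-mode parameter
#'   blocks for re-initialization.
#' @param t Absolute scene time of the transition check, s.
#' @return The (possibly re-initialized) cell.
#' @export
step_mode <- function(cell, tm, config = simulation_config(), t = 0) {
  stopifnot(inherits(tm, "transition_model"))
  probs <- tm$prob[cell$mode, ]
  new_mode <- sample(SWIM_MODES, 1L, prob = probs)
  if (new_mode == cell$mode) return(cell)
  init_mode_state(cell$id, new_mode, cell$head, cell$heading, t, config,
                  intensity = cell$intensity)
}
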