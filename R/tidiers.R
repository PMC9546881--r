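## broom-style tidiers for the evaluation result objects.

#' Tidy an OSPA result
#'
#' @param x An `ospa_result` from [ospa()].
#' @param ... Unused.
#' @return One-row tibble with the total distance and its components.
#' @export
tidy.ospa_result <- function(x, ...) {
  tibble::tibble(total = x$total, localization = x$localization,
                 cardinality = x$cardinality)
}

#' @rdname tidy.ospa_result
#' @export
glance.ospa_result <- function(x, ...) {
  tibble::tibble(total = x$total, localization = x$localization,
                 cardinality = x$cardinality, c = x$c, p = x$p,
                 n_x = x$n_x, n_y = x$n_y)
}

#' Tidy a CLEAR-MOT report
#'
#' `tidy()` returns the headline metrics in long form; `glance()` returns a
#' one-row summary with counts.
#'
#' @param x A `mot_report` from [clear_mot()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mot_report <- function(x, ...) {
  tibble::tibble(
    metric = c("motp", "fp_rate", "miss_rate", "mismatch_rate", "mota"),
    value = c(x$motp, x$fp_rate, x$miss_rate, x$mismatch_rate, x$mota))
}

#' @rdname tidy.mot_report
#' @export
glance.mot_report <- function(x, ...) {
  tibble::tibble(motp = x$motp, fp_rate = x$fp_rate,
                 miss_rate = x$miss_rate, mismatch_rate = x$mismatch_rate,
                 mota = x$mota, n_truth = x$n_truth,
                 n_matches = x$n_matches, c_T = x$c_T)
}
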