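# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' generator calls are reproducible without disturbing the global stream.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Signal a classed lickbox error
#' @noRd
lb_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "lickbox_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

stop_param <- function(msg) lb_stop(msg, "lickbox_param_error")
stop_data  <- function(msg) lb_stop(msg, "lickbox_data_error")

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is_scalar_num(x)) stop_param(sprintf("`%s` must be a finite numeric scalar", name))
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper) {
    stop_param(sprintf("`%s` = %g is outside its admissible range", name, x))
  }
  invisible(x)
}
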