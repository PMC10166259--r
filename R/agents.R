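# Agent policies standing in for the animal. An agent is called once per
# trial with an observation list and returns an action list:
#   obs: trial, block, rewarded_spout (oracle field used only by the
#        "perfect" agent), last = list(side, outcome, rewarded, cue_type)
#        or NULL on the first trial.
#   action: type ("lick", "enter_no_lick", "no_entry"), side ("left"/"right",
#        only for "lick"), np_latency_s, walk_s, lick_latency_s.
# Each agent owns a private RNG stream (its .Random.seed is saved and
# restored around every draw) so engine-level randomness such as
# probabilistic reward never perturbs the policy, and vice versa.

agent_rng <- function(env, fn) {
  outer <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  if (is.null(env$rng_state)) {
    set.seed(env$seed)
    env$rng_state <- get(".Random.seed", envir = globalenv())
  }
  assign(".Random.seed", env$rng_state, envir = globalenv())
  out <- fn()
  env$rng_state <- get(".Random.seed", envir = globalenv())
  if (is.null(outer)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", outer, envir = globalenv())
  }
  out
}

# Latencies drawn per trial; the jitter also decorrelates the nose-poke,
# head-entry and reward alignments used by the modulation classifier.
draw_latencies <- function() {
  list(np_latency_s = stats::runif(1, 0.5, 2.0),
       walk_s = stats::runif(1, 0.3, 1.2),
       lick_latency_s = stats::runif(1, 0.2, 1.2))
}

#' Construct an agent policy
#'
#' Available kinds:
#' * `"perfect"` — always licks the currently rewarded spout (an omniscient
#'   oracle used to exercise the reversal logic).
#' * `"side_biased"` — licks left with probability `params$p_left`
#'   (default 0.8), ignoring feedback.
#' * `"epsilon_random"` — with probability `params$epsilon` (default 0.1)
#'   picks a side uniformly, otherwise repeats the last rewarded side;
#'   `epsilon = 1` is a uniform random licker.
#' * `"wsls_qlearner"` — keeps one action value per side, updated as
#'   `Q <- Q + alpha * (r - Q)` with `r = 1` on water and 0 otherwise
#'   (`params$alpha`, default 0.6), and samples sides by softmax with
#'   inverse temperature `params$beta` (default 8). Behaves win-stay /
#'   lose-shift at high `alpha` and `beta`.
#' * `"no_entry"` — never initiates a trial (degenerate control).
#'
#' All agents are deterministic given their seed.
#'
#' @param kind policy kind, see above.
#' @param params named list of kind-specific parameters.
#' @param seed integer seed of the agent's private RNG stream.
#' @return object of class `lick_agent`: list with `kind`, `params`, `seed`
#'   and the policy closure `fn(obs)`.
#' @export
make_agent <- function(kind = c("perfect", "side_biased", "epsilon_random",
                                "wsls_qlearner", "no_entry"),
                       params = list(), seed = 1) {
  kind <- match.arg(kind)
  env <- new.env(parent = emptyenv())
  env$seed <- as.integer(seed)
  env$rng_state <- NULL
  sides <- c("left", "right")
  fn <- switch(kind,
    perfect = function(obs) {
      agent_rng(env, function() {
        c(list(type = "lick", side = obs$rewarded_spout), draw_latencies())
      })
    },
    side_biased = {
      p_left <- if (is.null(params$p_left)) 0.8 else params$p_left
      check_scalar(p_left, "p_left", 0, 1)
      function(obs) {
        agent_rng(env, function() {
          side <- if (stats::runif(1) < p_left) "left" else "right"
          c(list(type = "lick", side = side), draw_latencies())
        })
      }
    },
    epsilon_random = {
      eps <- if (is.null(params$epsilon)) 0.1 else params$epsilon
      check_scalar(eps, "epsilon", 0, 1)
      function(obs) {
        agent_rng(env, function() {
          if (is.null(env$stay_side)) env$stay_side <- sample(sides, 1)
          if (!is.null(obs$last) && isTRUE(obs$last$rewarded)) {
            env$stay_side <- obs$last$side
          }
          side <- if (stats::runif(1) < eps) sample(sides, 1) else env$stay_side
          c(list(type = "lick", side = side), draw_latencies())
        })
      }
    },
    wsls_qlearner = {
      alpha <- if (is.null(params$alpha)) 0.6 else params$alpha
      beta <- if (is.null(params$beta)) 8 else params$beta
      check_scalar(alpha, "alpha", 0, 1)
      check_scalar(beta, "beta", 0)
      env$q <- c(left = 0.5, right = 0.5)
      function(obs) {
        agent_rng(env, function() {
          if (!is.null(obs$last) && !is.null(obs$last$side) &&
              !is.na(obs$last$side)) {
            r <- as.numeric(isTRUE(obs$last$rewarded))
            s <- obs$last$side
            env$q[s] <- env$q[s] + alpha * (r - env$q[s])
          }
          p <- exp(beta * env$q); p <- p / sum(p)
          side <- sample(sides, 1, prob = p)
          c(list(type = "lick", side = side), draw_latencies())
        })
      }
    },
    no_entry = function(obs) list(type = "no_entry")
  )
  structure(list(kind = kind, params = params, seed = as.integer(seed),
                 fn = fn, env = env),
            class = "lick_agent")
}

#' @export
print.lick_agent <- function(x, ...) {
  cat(sprintf("<lick_agent> kind=%s seed=%d\n", x$kind, x$seed))
  invisible(x)
}
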