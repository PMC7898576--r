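#' Initialize a ZEST threshold tracker
#'
#' ZEST maintains a discretized probability density over the listener's
#' detection threshold (in dB of intensity increment) and presents each trial
#' at the posterior mean. The prior is a truncated Gaussian on the grid,
#' centered on the 10 dB starting difference limen.
#'
#' @param prior_mean_db Prior mean (and hence first presented level),
#'   default 10 dB.
#' @param prior_sd_db Prior SD (default 6 dB).
#' @param grid Threshold support in dB (default -10 to 30 by 0.1).
#' @return A `zest_state`: list with `grid`, `pdf` (sums to 1), `history`
#'   (tibble of `level_db`, `response`), `n_observations`.
#' @export
init_zest <- function(prior_mean_db = 10, prior_sd_db = 6,
                      grid = seq(-10, 30, by = 0.1)) {
  if (length(grid) < 2L || any(diff(grid) <= 0)) {
    abort("`grid` must be increasing with positive step.")
  }
  if (prior_mean_db < min(grid) || prior_mean_db > max(grid)) {
    abort("The prior mean lies outside the threshold grid.")
  }
  pdf <- dnorm(grid, prior_mean_db, prior_sd_db)
  pdf <- pdf / sum(pdf)
  structure(
    list(
      grid = grid,
      pdf = pdf,
      history = tibble(level_db = numeric(0), response = logical(0)),
      n_observations = 0L
    ),
    class = "zest_state"
  )
}

#' Level to present next: the posterior mean
#'
#' @param state A `zest_state`.
#' @return Posterior mean threshold in dB.
#' @export
next_level <- function(state) {
  stopifnot(inherits(state, "zest_state"))
  sum(state$grid * state$pdf)
}

#' Bayesian update of the threshold density after one observation
#'
#' Multiplies the current density by the likelihood of the observed response
#' under the assumed psychometric function
#' \deqn{P(yes \mid L, \theta) = \gamma + (1 - \gamma - \lambda)\,
#'   \Phi((L - \theta)/\sigma)}
#' and renormalizes. `gamma` (false-alarm/guess rate), `lambda` (lapse rate)
#' and `sigma` (slope spread) parameterize the family ZEST assumes about the
#' listener; they are conventional defaults, configurable because the
#' procedure's behaviour, not any one listener, is being modelled.
#'
#' @param state A `zest_state`.
#' @param level_db Presented level in dB.
#' @param response `TRUE` for "yes" (detected), `FALSE` for "no".
#' @param sigma_db Assumed psychometric spread (default 2 dB).
#' @param gamma Guess/false-alarm floor (default 0.02).
#' @param lambda Lapse ceiling (default 0.02).
#' @return The updated `zest_state`.
#' @export
zest_update <- function(state, level_db, response, sigma_db = 2,
                        gamma = 0.02, lambda = 0.02) {
  stopifnot(inherits(state, "zest_state"), is.logical(response))
  p_yes <- gamma + (1 - gamma - lambda) *
    pnorm((level_db - state$grid) / sigma_db)
  like <- if (response) p_yes else 1 - p_yes
  post <- state$pdf * like
  z <- sum(post)
  if (z <= 0 || !is.finite(z)) {
    abort("Posterior mass is zero: the likelihood annihilated the density.")
  }
  state$pdf <- post / z
  state$history <- bind_rows(
    state$history,
    tibble(level_db = level_db, response = response)
  )
  state$n_observations <- state$n_observations + 1L
  state
}

#' Final threshold estimate after the stopping quota
#'
#' The mean of the threshold density on the last observation. Errors if
#' called before the stopping quota (default 20 observations) is consumed.
#'
#' @param state A `zest_state`.
#' @param quota Required observation count (default 20).
#' @return Threshold estimate in dB.
#' @export
final_threshold <- function(state, quota = 20L) {
  stopifnot(inherits(state, "zest_state"))
  if (state$n_observations < quota) {
    abort(sprintf(
      "Only %d of %d observations consumed; threshold not final.",
      state$n_observations, quota
    ))
  }
  next_level(state)
}

# Posterior SD of the current density.
zest_posterior_sd <- function(state) {
  m <- next_level(state)
  sqrt(sum(state$pdf * (state$grid - m)^2))
}

#' A simulated psychometric observer
#'
#' A stochastic listener whose probability of reporting a deviant at level
#' `L` is `fa + (1 - fa - lapse) * pnorm((L - threshold)/slope)`; detections
#' come with a lognormal response time, so sufficiently slow responses fall
#' outside the scoring window and count as misses.
#'
#' @param true_threshold_db The observer's actual threshold, dB.
#' @param slope_db Psychometric spread (smaller = steeper), dB; must be > 0.
#'   Use a very small value (e.g. 1e-6) for an effectively deterministic
#'   step observer.
#' @param lapse_rate,false_alarm_rate Rates in [0, 0.5).
#' @param rt_meanlog,rt_sdlog Lognormal response-time parameters (ms scale).
#' @return A `psychometric_observer`.
#' @export
psychometric_observer <- function(true_threshold_db = 6, slope_db = 2,
                                  lapse_rate = 0.02, false_alarm_rate = 0.02,
                                  rt_meanlog = log(450), rt_sdlog = 0.3) {
  if (slope_db <= 0) abort("`slope_db` must be positive.")
  if (lapse_rate < 0 || lapse_rate >= 0.5 ||
    false_alarm_rate < 0 || false_alarm_rate >= 0.5) {
    abort("Lapse and false-alarm rates must lie in [0, 0.5).")
  }
  structure(
    list(
      true_threshold_db = true_threshold_db,
      slope_db = slope_db,
      lapse_rate = lapse_rate,
      false_alarm_rate = false_alarm_rate,
      rt_meanlog = rt_meanlog,
      rt_sdlog = rt_sdlog
    ),
    class = "psychometric_observer"
  )
}

# One simulated response to a deviant at `level_db`: detection draw plus a
# response time. Uses the ambient RNG stream (seed controlled by the caller).
observer_respond <- function(observer, level_db) {
  p <- observer$false_alarm_rate +
    (1 - observer$false_alarm_rate - observer$lapse_rate) *
      pnorm((level_db - observer$true_threshold_db) / observer$slope_db)
  detected <- runif(1) < p
  rt <- if (detected) rlnorm(1, observer$rt_meanlog, observer$rt_sdlog) else NA_real_
  list(detected = detected, rt_ms = rt)
}

#' Run a full simulated adaptive deviance-detection experiment
#'
#' Interleaves four independent ZEST trackers — one per probed grid position —
#' over a deviant schedule. On each deviant loop the tracker for that
#' position supplies the level (its posterior mean, clipped to
#' `level_range`), the observer responds, responses later than
#' `response_window_ms` after probe onset are scored as misses, and the
#' tracker is updated. Standard loops are recorded as `no_deviant` trials.
#'
#' @param schedule A [schedule_run()] tibble.
#' @param observer A [psychometric_observer()].
#' @param prior_mean_db,prior_sd_db,grid Passed to [init_zest()].
#' @param sigma_db,gamma,lambda ZEST's assumed psychometric family
#'   (see [zest_update()]).
#' @param response_window_ms Scoring window after probe onset (default 1000).
#' @param level_range Physical limits for presented levels, dB (default
#'   c(0, 30)); out-of-range posterior means are clipped and flagged.
#' @param quota Stopping rule: observations per position (default taken from
#'   the schedule attribute).
#' @param seed Integer seed for the observer's randomness.
#' @return A `zest_experiment`: list with `trials` (one row per loop:
#'   `loop_index`, `trial_kind`, `probe_position`, `level_db`,
#'   `level_clipped`, `response`, `response_time_ms`) and `thresholds`
#'   (`probe_position`, `threshold_db`, `n_obs`, `posterior_sd`), plus the
#'   final `states`.
#' @export
run_experiment <- function(schedule, observer,
                           prior_mean_db = 10, prior_sd_db = 6,
                           grid = seq(-10, 30, by = 0.1),
                           sigma_db = 2, gamma = 0.02, lambda = 0.02,
                           response_window_ms = 1000,
                           level_range = c(0, 30),
                           quota = attr(schedule, "quota") %||% 20L,
                           seed = 1L) {
  stopifnot(is.data.frame(schedule), inherits(observer, "psychometric_observer"))
  positions <- attr(schedule, "probe_positions") %||%
    sort(unique(schedule$probe_position[!is.na(schedule$probe_position)]))
  states <- lapply(setNames(nm = as.character(positions)), function(p) {
    init_zest(prior_mean_db, prior_sd_db, grid)
  })
  nl <- nrow(schedule)
  level <- rep(NA_real_, nl)
  clipped <- rep(FALSE, nl)
  resp <- rep(NA_character_, nl)
  rt <- rep(NA_real_, nl)
  with_seed(seed, {
    for (i in seq_len(nl)) {
      if (schedule$kind[i] != "deviant") next
      p <- as.character(schedule$probe_position[i])
      if (is.null(states[[p]])) {
        abort(sprintf("Schedule probes position %s but no tracker exists for it.", p))
      }
      lv <- next_level(states[[p]])
      lv_clip <- min(max(lv, level_range[1]), level_range[2])
      clipped[i] <- lv_clip != lv
      level[i] <- lv_clip
      ans <- observer_respond(observer, lv_clip)
      hit <- isTRUE(ans$detected) && !is.na(ans$rt_ms) &&
        ans$rt_ms <= response_window_ms
      resp[i] <- if (hit) "hit" else "miss"
      rt[i] <- if (hit) ans$rt_ms else NA_real_
      states[[p]] <- zest_update(states[[p]], lv_clip, hit,
        sigma_db = sigma_db, gamma = gamma, lambda = lambda
      )
    }
  })
  trials <- tibble(
    loop_index = schedule$loop_index,
    trial_kind = if_else(schedule$kind == "deviant", "deviant", "no_deviant"),
    probe_position = schedule$probe_position,
    level_db = level,
    level_clipped = clipped,
    response = resp,
    response_time_ms = rt
  )
  thresholds <- purrr::imap(states, function(st, p) {
    if (st$n_observations >= quota) {
      tibble(
        probe_position = as.integer(p),
        threshold_db = final_threshold(st, quota),
        n_obs = st$n_observations,
        posterior_sd = zest_posterior_sd(st)
      )
    } else {
      tibble(
        probe_position = as.integer(p),
        threshold_db = NA_real_,
        n_obs = st$n_observations,
        posterior_sd = NA_real_
      )
    }
  }) |> list_rbind()
  if (anyNA(thresholds$threshold_db)) {
    warn("Some positions did not reach the observation quota; their thresholds are NA.")
  }
  structure(
    list(trials = trials, thresholds = thresholds, states = states,
         quota = as.integer(quota), seed = as.integer(seed)),
    class = "zest_experiment"
  )
}

#' @export
print.zest_experiment <- function(x, ...) {
  cat(sprintf(
    "<zest_experiment: %d loops, %d deviant trials, %d tracked positions>\n",
    nrow(x$trials), sum(x$trials$trial_kind == "deviant"), nrow(x$thresholds)
  ))
  print(x$thresholds)
  invisible(x)
}
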