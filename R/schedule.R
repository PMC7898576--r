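#' Schedule a deviance-detection run
#'
#' Builds the loop-by-loop schedule of an adaptive run. The loop is the
#' organizing unit: after every standard (no-deviant) loop there is a
#' `p_deviant` chance (default 80\%) that the next loop carries a deviant in
#' one of the four probed grid positions, sampled without replacement within
#' consecutive blocks of four; after every deviant loop the next loop is
#' always a standard. The run continues until each probed position has
#' received its quota of deviants (default 20), then closes with one trailing
#' standard loop so the final response window fits.
#'
#' @param n_observations_per_position Deviant quota per probed position.
#' @param p_deviant Probability that a standard loop is followed by a deviant.
#' @param probe_positions Four distinct grid indices to probe.
#' @param seed Integer seed; schedules are reproducible from it.
#' @param max_loops Safety cap on schedule length. If the quota is not met by
#'   then (e.g. `p_deviant = 0`) the schedule is returned truncated with a
#'   warning and `attr(., "quota_met") = FALSE`.
#' @return A tibble with one row per loop: `loop_index`,
#'   `kind` (`"standard"`/`"deviant"`), `probe_position` (NA for standards).
#'   Attributes: `probe_positions`, `seed`, `quota`, `quota_met`.
#' @examples
#' sch <- schedule_run(20, 0.8, c(3, 6, 9, 12), seed = 1)
#' table(sch$kind) # 80 deviants
#' @export
schedule_run <- function(n_observations_per_position = 20, p_deviant = 0.8,
                         probe_positions, seed = 1L, max_loops = 1e5) {
  if (p_deviant < 0 || p_deviant > 1) abort("`p_deviant` must be in [0, 1].")
  if (n_observations_per_position < 1) {
    abort("`n_observations_per_position` must be >= 1.")
  }
  probe_positions <- as.integer(probe_positions)
  if (length(probe_positions) != 4L || anyDuplicated(probe_positions)) {
    abort("`probe_positions` must be 4 distinct grid indices.")
  }
  quota <- as.integer(n_observations_per_position)
  target <- 4L * quota

  kind <- integer(0) # 0 standard, 1 deviant
  pos <- integer(0)
  with_seed(seed, {
    kind <- integer(max_loops)
    pos <- rep(NA_integer_, max_loops)
    bag <- sample(probe_positions)
    bag_i <- 1L
    n_dev <- 0L
    i <- 1L
    kind[1L] <- 0L # run opens with a standard loop
    while (n_dev < target && i < max_loops) {
      i <- i + 1L
      if (kind[i - 1L] == 1L) {
        kind[i] <- 0L # 100% standard after a deviant
      } else if (runif(1) < p_deviant) {
        kind[i] <- 1L
        n_dev <- n_dev + 1L
        pos[i] <- bag[bag_i]
        bag_i <- bag_i + 1L
        if (bag_i > 4L) {
          bag <- sample(probe_positions)
          bag_i <- 1L
        }
      } else {
        kind[i] <- 0L
      }
    }
    quota_met <- n_dev >= target
    if (quota_met && i < max_loops) {
      i <- i + 1L # trailing standard closes the run
      kind[i] <- 0L
    }
    kind <- kind[seq_len(i)]
    pos <- pos[seq_len(i)]
  })
  if (!quota_met) {
    warn(sprintf(
      "Deviant quota not reached within max_loops = %d (%d of %d deviants).",
      max_loops, sum(kind == 1L), target
    ))
  }
  out <- tibble(
    loop_index = seq_along(kind),
    kind = if_else(kind == 1L, "deviant", "standard"),
    probe_position = pos
  )
  attr(out, "probe_positions") <- probe_positions
  attr(out, "seed") <- as.integer(seed)
  attr(out, "quota") <- quota
  attr(out, "quota_met") <- quota_met
  out
}

# Fraction of standard loops (with a successor) followed by a deviant —
# the empirical deviant-after-standard rate of a schedule.
#' Empirical deviant-after-standard rate of a schedule
#'
#' @param schedule A [schedule_run()] tibble.
#' @param max_standards Use at most this many standard loops (counted from the
#'   start); `Inf` uses all.
#' @return Proportion in [0, 1].
#' @export
deviant_after_standard_rate <- function(schedule, max_standards = Inf) {
  k <- schedule$kind
  is_std <- which(k[-length(k)] == "standard")
  if (is.finite(max_standards)) is_std <- head(is_std, max_standards)
  if (length(is_std) == 0L) abort("Schedule has no standard loop with a successor.")
  mean(k[is_std + 1L] == "deviant")
}
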