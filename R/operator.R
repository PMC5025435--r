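# Synthetic generator for manually operated lever-arm maneuvers.
#
# A manual operator cannot reproduce a maneuver exactly: realized stop
# angles, plateau velocity and resting time vary from repetition to
# repetition.  This module emulates that variability with seeded
# truncated-normal jitter so that the stochastic critical-time scans of the
# protocol layer can be reproduced exactly.  Mechanical stops bound the range
# of motion at +/-(90 + alpha_plus): the realized stop angles may undershoot
# the stops but never exceed them.

#' Operator variability specification
#'
#' @param stop_angle_sd_deg Standard deviation of the stop-angle jitter
#'   (degrees) before capping at the mechanical stop.
#' @param velocity_fraction_sd Relative standard deviation of the plateau
#'   velocity (fraction of the nominal velocity).
#' @param resting_time_sd_s Standard deviation of the resting-time jitter
#'   (s).
#' @param ramp_time_s Fixed acceleration ramp of the manual movements (s); a
#'   human operator cannot start or stop instantaneously.
#' @param seed Integer seed making every replicate reproducible.
#' @return An object of class `operator_noise`.
#' @details Defaults (2 deg, 10 %, 0.5 s, 0.15 s) describe plausible manual
#'   execution variability; they produce an inconclusive scan band a few
#'   seconds wide, the behaviour observed with a human operator.  They are
#'   free parameters of the generator, not measured quantities.
#' @export
operator_noise <- function(stop_angle_sd_deg = 2, velocity_fraction_sd = 0.1,
                           resting_time_sd_s = 0.5, ramp_time_s = 0.15,
                           seed = 1L) {
  .check_positive(stop_angle_sd_deg, "stop_angle_sd_deg", strict = FALSE)
  .check_positive(velocity_fraction_sd, "velocity_fraction_sd",
                  strict = FALSE)
  .check_positive(resting_time_sd_s, "resting_time_sd_s", strict = FALSE)
  .check_positive(ramp_time_s, "ramp_time_s", strict = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("invalid parameter `seed`: must be a single integer", call. = FALSE)
  }
  structure(
    list(stop_angle_sd_deg = stop_angle_sd_deg,
         velocity_fraction_sd = velocity_fraction_sd,
         resting_time_sd_s = resting_time_sd_s,
         ramp_time_s = ramp_time_s,
         seed = as.integer(seed)),
    class = "operator_noise")
}

# run `expr` under a deterministic RNG stream and restore the caller's RNG
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# standard-normal draw truncated to +/- 3 SD (rejection sampling)
.rtrunc3 <- function() {
  repeat {
    z <- rnorm(1L)
    if (abs(z) <= 3) return(z)
  }
}

# stable per-replicate stream derived from (seed, replicate_index)
.replicate_seed <- function(seed, replicate_index) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(replicate_index)) %%
               2147483629) + 1L
}

#' Sample one manually executed maneuver trace
#'
#' Draws a noisy realization of a maneuver: both stop angles receive
#' independent truncated-normal jitter (+/- 3 SD) capped at the mechanical
#' stop `90 + alpha_plus` (undershoot allowed, overshoot mechanically
#' impossible), the plateau velocity is scaled by `1 + eta` with truncated
#' Gaussian `eta`, and the resting time is jittered and floored at zero.
#' Identical `(seed, replicate_index)` pairs give bit-identical traces; with
#' all SDs zero the result equals [build_trace()] with the same ramp time.
#'
#' @param spec A [maneuver_spec()] (nominal maneuver).
#' @param noise An [operator_noise()].
#' @param replicate_index Replicate number (>= 0); selects the reproducible
#'   noise stream.
#' @param sample_step Sampling step of the exported series (s).
#' @return An `orientation_trace` whose `realized` element records the
#'   perturbed stop angles, velocity and resting time.
#' @export
sample_manual_trace <- function(spec, noise, replicate_index = 0L,
                                sample_step = 0.001) {
  stopifnot(inherits(spec, "maneuver_spec"), inherits(noise, "operator_noise"))
  draws <- .with_seed(.replicate_seed(noise$seed, replicate_index), {
    c(a1 = .rtrunc3(), a2 = .rtrunc3(), v = .rtrunc3(), t = .rtrunc3())
  })
  stop_nominal <- 90 + spec$extension_angle_deg
  stop1 <- stop_nominal + min(draws[["a1"]] * noise$stop_angle_sd_deg, 0)
  stop2 <- stop_nominal + min(draws[["a2"]] * noise$stop_angle_sd_deg, 0)
  v <- spec$maneuver_velocity_deg_s *
    max(1 + draws[["v"]] * noise$velocity_fraction_sd, 0.1)
  tp <- max(spec$resting_time_s + draws[["t"]] * noise$resting_time_sd_s, 0)
  spec_used <- spec
  spec_used$ramp_time_s <- noise$ramp_time_s
  segments <- .build_segments(stop1, stop2, v, tp, spec$final_observation_s,
                              noise$ramp_time_s)
  .trace_from_segments(segments, spec_used, sample_step,
                       realized = list(stop1_deg = stop1, stop2_deg = stop2,
                                       velocity_deg_s = v,
                                       resting_time_s = tp,
                                       replicate_index = replicate_index,
                                       seed = noise$seed))
}

#' Decide an experiment from consecutive repetition outcomes
#'
#' The experimental decision rule: a configuration counts as decided only
#' after `k` consecutive repetitions with the same outcome.  Outcomes are
#' scanned left to right in the order the repetitions were performed; the
#' first completed run of length `k` decides, matching sequential
#' experimental practice.
#'
#' @param outcomes Character vector of `"success"` / `"failure"` (logical
#'   vectors are accepted, `TRUE` = success), in temporal order.
#' @param k Required run length (>= 1); the experiments used 3.
#' @return `"success"`, `"failure"`, or `"inconclusive"` if no run of length
#'   `k` has completed.
#' @examples
#' consecutive_decision(c("success", "success", "success"))     # success
#' consecutive_decision(c("success", "failure", "success"), 3)  # inconclusive
#' @export
consecutive_decision <- function(outcomes, k = 3L) {
  if (length(outcomes) == 0L) {
    stop("invalid input `outcomes`: must contain at least one outcome",
         call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop("invalid parameter `k`: must be >= 1", call. = FALSE)
  }
  if (is.logical(outcomes)) {
    outcomes <- ifelse(outcomes, "success", "failure")
  }
  if (!all(outcomes %in% c("success", "failure"))) {
    stop("invalid input `outcomes`: values must be \"success\" or ",
         "\"failure\"", call. = FALSE)
  }
  run_val <- outcomes[1L]
  run_len <- 1L
  if (run_len >= k) return(run_val)
  for (o in outcomes[-1L]) {
    if (o == run_val) run_len <- run_len + 1L
    else {
      run_val <- o
      run_len <- 1L
    }
    if (run_len >= k) return(run_val)
  }
  "inconclusive"
}
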