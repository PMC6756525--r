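#' Interaction-zone parameters of the two-rate dive process
#'
#' The five quantities shared by the synthetic-raft generator and the
#' Bayesian inference: the intrinsic per-second dive probability `p0`, the
#' elevated per-second probability `p1` after a qualifying conspecific dive,
#' and the interaction zone within which a conspecific dive qualifies as a
#' cue — it must have occurred within the previous `lag` seconds, at a
#' distance of less than `dist` body lengths, and within the focal bird's
#' visual arc of `arc` degrees (total arc, symmetric about the heading, so
#' the absolute bearing must not exceed `arc / 2`).
#'
#' Defaults are the posterior means inferred from field video of European
#' shag foraging rafts, so a raft simulated with the default parameters
#' reproduces the empirically estimated diving process.
#'
#' @param p0 Intrinsic dive probability per second, in \[0, 1\].
#' @param p1 Social dive probability per second, in \[0, 1\]. `p1 < p0` is
#'   allowed; inference must be able to express inhibition.
#' @param lag Cue lag window in seconds (> 0).
#' @param dist Cue detection distance in body lengths (> 0).
#' @param arc Total visual arc in degrees, in \[0, 360\].
#' @return An object of class `dive_params` (a named list).
#' @export
dive_params <- function(p0 = 0.0634, p1 = 0.1484, lag = 1.67,
                        dist = 70.28, arc = 216.06) {
  stopifnot(is.finite(p0), is.finite(p1), is.finite(lag), is.finite(dist),
            is.finite(arc), p0 >= 0, p0 <= 1, p1 >= 0, p1 <= 1,
            lag > 0, dist > 0, arc >= 0, arc <= 360)
  structure(list(p0 = p0, p1 = p1, lag = lag, dist = dist, arc = arc),
            class = "dive_params")
}

#' @export
print.dive_params <- function(x, ...) {
  cat(sprintf(
    "Two-rate dive process: p0 = %.4g /s, p1 = %.4g /s,\n  cue zone: lag <= %.3g s, dist < %.4g BL, |bearing| <= %.4g deg (arc %.4g)\n",
    x$p0, x$p1, x$lag, x$dist, x$arc / 2, x$arc))
  invisible(x)
}

#' Uniform prior bounds for the dive-process parameters
#'
#' Independent uniform priors: lag in \[0.5, 2\] s, distance in \[0, 100\]
#' BL, arc in \[0, 360\] degrees and both per-second probabilities in
#' \[0, 1\]. The candidate-cue lists built by [discretize_dives()] use the
#' upper bounds of the lag and distance priors, so the likelihood of any
#' admissible proposal can be evaluated from the precomputed cues.
#'
#' @param lag,dist,arc,p0,p1 Length-2 numeric `c(lower, upper)` bounds.
#' @return An object of class `dive_priors`: a named list of bounds.
#' @export
dive_priors <- function(p0 = c(0, 1), p1 = c(0, 1), lag = c(0.5, 2),
                        dist = c(0, 100), arc = c(0, 360)) {
  pr <- list(p0 = p0, p1 = p1, lag = lag, dist = dist, arc = arc)
  for (nm in names(pr)) {
    b <- pr[[nm]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2])
      stop("prior bounds for '", nm, "' must be finite with lower < upper")
  }
  structure(pr, class = "dive_priors")
}

#' Configuration of a simulated foraging raft
#'
#' Movement defaults emulate the observed rafts: mean surface speed 1.1
#' body lengths per second and mean nearest-neighbour distance 9.3 BL, with
#' loosely aligned, polarized motion and a mild tendency to fall in behind
#' the nearest bird ahead, which produces the front–back neighbour
#' anisotropy seen in the field data. The movement rule itself is surrogate
#' structure (no movement equations were estimated from the field data); it
#' only has to carry the dive process and its qualitative spatial structure.
#'
#' Dive trials are drawn on the `decision_step` grid (default 0.5 s, the
#' same discretization the inference model uses): at each interval start the
#' social state of every surfaced bird is evaluated from the exact times and
#' locations of earlier conspecific dives, the bird dives within the
#' interval with probability `1 - (1 - p_sec)^decision_step`, and the exact
#' dive instant is drawn uniformly within the interval. Movement integrates
#' at `sim_step` (the video frame step).
#'
#' @param n_birds Number of birds (0 gives an empty raft).
#' @param duration Clip length in seconds.
#' @param sim_step Movement integration step in seconds (default 1/25 s,
#'   one video frame); must divide `duration` and be at most 0.5 s.
#' @param mean_speed,speed_sd Per-bird base speed distribution, BL/s.
#' @param target_nnd Target mean nearest-neighbour distance, BL; controls
#'   the initial placement density (the arena is unbounded).
#' @param heading_noise Heading noise, degrees per movement step.
#' @param alignment_weight Steering weight toward the shared travel
#'   direction (per step, dimensionless).
#' @param attraction_weight Steering weight toward the raft centroid.
#' @param follow_weight Steering weight toward the nearest neighbour in the
#'   front half-plane; > 0 yields front–back density anisotropy.
#' @param dive_params A [dive_params()] object.
#' @param decision_step Dive-decision interval in seconds (default 0.5).
#' @param travel_direction Shared travel direction, degrees (0 = +x,
#'   counter-clockwise).
#' @param respawn If `TRUE`, every dive schedules a fresh bird (new id) at a
#'   random location after an exponential delay; by default dived birds
#'   simply leave the surface population, as resurfacing birds are never
#'   linked back to their pre-dive track.
#' @param respawn_rate Rate of the exponential respawn delay (1/s).
#' @param seed Default seed used when [simulate_raft()] is called without
#'   one.
#' @return An object of class `raft_config`.
#' @export
raft_config <- function(n_birds = 103, duration = 60, sim_step = 0.04,
                        mean_speed = 1.1, speed_sd = 0.3, target_nnd = 9.3,
                        heading_noise = 4, alignment_weight = 0.08,
                        attraction_weight = 0.02, follow_weight = 0.05,
                        dive_params = raftdives::dive_params(),
                        decision_step = 0.5, travel_direction = 0,
                        respawn = FALSE, respawn_rate = 0.1, seed = 1L) {
  stopifnot(n_birds >= 0, duration > 0, sim_step > 0, sim_step <= 0.5,
            mean_speed > 0, speed_sd >= 0, target_nnd > 0,
            heading_noise >= 0, alignment_weight >= 0,
            attraction_weight >= 0, follow_weight >= 0,
            decision_step > 0, inherits(dive_params, "dive_params"))
  n_steps <- duration / sim_step
  if (abs(n_steps - round(n_steps)) > 1e-8)
    stop("duration must be a whole number of sim_steps")
  structure(list(
    n_birds = as.integer(n_birds), duration = duration, sim_step = sim_step,
    mean_speed = mean_speed, speed_sd = speed_sd, target_nnd = target_nnd,
    heading_noise = heading_noise, alignment_weight = alignment_weight,
    attraction_weight = attraction_weight, follow_weight = follow_weight,
    dive_params = dive_params, decision_step = decision_step,
    travel_direction = travel_direction, respawn = respawn,
    respawn_rate = respawn_rate, seed = as.integer(seed)
  ), class = "raft_config")
}

# Wrap angles (degrees) to (-180, 180].
wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

# Per-interval dive probability from a per-second probability
# (complementary-hazard thinning; exact for a Bernoulli process).
step_prob <- function(p_sec, step) 1 - (1 - p_sec)^step
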