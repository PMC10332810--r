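#' Configuration for synthetic arena trajectories
#'
#' Groups of flies walking in a circular arena are modelled as independent
#' Gaussian random walks with a reflecting boundary. During odor-pulse
#' epochs a radial (upwind) drift is added; during quadrant choice-test
#' epochs steps are accepted by a Metropolis rule whose stationary
#' occupancy density is `quadrant_bias` in the favored (paired-odor)
#' quadrants relative to the disfavored ones, so the stationary
#' favored/disfavored occupancy ratio approaches `quadrant_bias`.
#'
#' @param n_flies flies per arena (default 15).
#' @param arena_radius arena radius in mm (default 50).
#' @param frame_rate_hz tracking rate (default 5).
#' @param step_sd per-axis step SD, mm per frame (default 4; about
#'   20 mm/s of walking at the default rate).
#' @param upwind_drift radial outward drift in mm/s applied while an odor
#'   pulse is on (default 0; drift is always 0 outside stimulus epochs).
#' @param quadrant_bias stationary occupancy ratio favored:disfavored during
#'   choice tests (default 1: uniform).
#' @param seed RNG seed.
#' @return an `arena_synth_config` list.
#' @export
arena_synth_config <- function(n_flies = 15, arena_radius = 50,
                               frame_rate_hz = 5, step_sd = 4,
                               upwind_drift = 0, quadrant_bias = 1,
                               seed = 1) {
  if (n_flies < 1) stop("need at least one fly", call. = FALSE)
  if (arena_radius <= 0 || frame_rate_hz <= 0 || step_sd < 0)
    stop("arena_radius, frame_rate_hz must be positive; step_sd >= 0", call. = FALSE)
  if (quadrant_bias <= 0) stop("quadrant_bias must be positive", call. = FALSE)
  structure(list(n_flies = as.integer(n_flies), arena_radius = arena_radius,
                 frame_rate_hz = frame_rate_hz, step_sd = step_sd,
                 upwind_drift = upwind_drift, quadrant_bias = quadrant_bias,
                 seed = seed),
            class = "arena_synth_config")
}

#' Stimulus timeline for an arena run
#'
#' @param epochs tibble with columns `type` (`"air"`, `"pulse"`, or
#'   `"choice"`), `onset_s`, `offset_s`. `"pulse"` epochs carry the upwind
#'   drift; `"choice"` epochs apply the quadrant bias.
#' @param paired_quadrants integer vector (subset of 1:4) holding the
#'   paired odor during choice tests; quadrant `q` spans angles
#'   `[(q-1) * 90, q * 90)` degrees. Opposing quadrants share an odor, so
#'   the default `c(1, 3)` puts the paired odor in two opposing quadrants.
#' @return an `arena_timeline` list.
#' @export
arena_timeline <- function(epochs, paired_quadrants = c(1, 3)) {
  stopifnot(all(c("type", "onset_s", "offset_s") %in% names(epochs)))
  if (!all(epochs$type %in% c("air", "pulse", "choice")))
    stop("epoch type must be air, pulse or choice", call. = FALSE)
  if (any(epochs$onset_s >= epochs$offset_s))
    stop("epoch onset must precede offset", call. = FALSE)
  stopifnot(all(paired_quadrants %in% 1:4))
  structure(list(epochs = tibble::as_tibble(epochs),
                 paired_quadrants = as.integer(paired_quadrants)),
            class = "arena_timeline")
}

epoch_type_at <- function(timeline, t) {
  e <- timeline$epochs
  hit <- which(t >= e$onset_s & t < e$offset_s)
  if (length(hit) == 0) "air" else e$type[hit[1]]
}

#' Quadrant index of points
#'
#' Quadrant `q` spans polar angles `[(q-1) * 90, q * 90)` degrees about the
#' arena center; a point exactly on a boundary belongs to the quadrant that
#' starts there (the counter-clockwise-adjacent one), so rotating all
#' positions by 90 degrees permutes quadrants cyclically.
#'
#' @param x,y coordinates (mm).
#' @param center arena center, length-2 numeric.
#' @return integer vector in 1:4.
#' @export
quadrant_of <- function(x, y, center = c(0, 0)) {
  ang <- atan2(y - center[2], x - center[1])      # (-pi, pi]
  ang <- ang %% (2 * pi)                          # [0, 2*pi)
  pmin(4L, as.integer(floor(ang / (pi / 2))) + 1L)
}

#' Generate arena trajectories for a group of flies
#'
#' Flies start uniformly distributed over the arena disk (the stationary
#' distribution of the unbiased walk, so unstimulated epochs carry no
#' systematic radial trend) and take independent Gaussian steps with radial
#' reflection at the boundary. See [arena_synth_config()] for the stimulus-
#' conditioned drift and quadrant bias.
#'
#' @param config an [arena_synth_config()].
#' @param timeline an [arena_timeline()].
#' @param duration_s run length in seconds; default the last epoch offset.
#' @param run_id identifier stored with the trajectories.
#' @return a tibble with columns `run_id`, `fly_id`, `frame`, `t_s`,
#'   `x_mm`, `y_mm`, with attributes `arena_radius`, `center`,
#'   `frame_rate_hz`.
#' @export
gen_arena_trajectories <- function(config, timeline,
                                   duration_s = max(timeline$epochs$offset_s),
                                   run_id = 1L) {
  stopifnot(inherits(config, "arena_synth_config"),
            inherits(timeline, "arena_timeline"))
  c_ <- config
  R <- c_$arena_radius
  nfr <- as.integer(ceiling(duration_s * c_$frame_rate_hz))
  favored <- quadrant_membership(timeline$paired_quadrants)
  withr::with_seed(c_$seed, {
    # uniform start over the disk
    r0 <- R * sqrt(stats::runif(c_$n_flies))
    th0 <- stats::runif(c_$n_flies, 0, 2 * pi)
    x <- r0 * cos(th0); y <- r0 * sin(th0)
    X <- matrix(NA_real_, nfr, c_$n_flies)
    Y <- matrix(NA_real_, nfr, c_$n_flies)
    drift_per_frame <- c_$upwind_drift / c_$frame_rate_hz
    for (fr in seq_len(nfr)) {
      t_now <- (fr - 1) / c_$frame_rate_hz
      type <- epoch_type_at(timeline, t_now)
      nx <- x + stats::rnorm(c_$n_flies, sd = c_$step_sd)
      ny <- y + stats::rnorm(c_$n_flies, sd = c_$step_sd)
      if (type == "pulse" && drift_per_frame != 0) {
        r <- pmax(sqrt(x^2 + y^2), 1e-9)
        nx <- nx + drift_per_frame * x / r
        ny <- ny + drift_per_frame * y / r
      }
      refl <- reflect_into_disk(nx, ny, R)
      nx <- refl$x; ny <- refl$y
      if (type == "choice" && c_$quadrant_bias != 1) {
        # Metropolis: target density quadrant_bias in favored quadrants, 1 elsewhere
        dens <- function(px, py) ifelse(favored[quadrant_of(px, py)],
                                        c_$quadrant_bias, 1)
        acc <- stats::runif(c_$n_flies) < dens(nx, ny) / dens(x, y)
        nx <- ifelse(acc, nx, x)
        ny <- ifelse(acc, ny, y)
      }
      x <- nx; y <- ny
      X[fr, ] <- x; Y[fr, ] <- y
    }
  })
  out <- tibble::tibble(
    run_id = run_id,
    fly_id = rep(seq_len(c_$n_flies), each = nfr),
    frame = rep(seq_len(nfr), times = c_$n_flies),
    t_s = (rep(seq_len(nfr), times = c_$n_flies) - 1) / c_$frame_rate_hz,
    x_mm = as.vector(X),
    y_mm = as.vector(Y)
  )
  attr(out, "arena_radius") <- R
  attr(out, "center") <- c(0, 0)
  attr(out, "frame_rate_hz") <- c_$frame_rate_hz
  out
}

quadrant_membership <- function(paired_quadrants) {
  fav <- rep(FALSE, 4)
  fav[paired_quadrants] <- TRUE
  fav
}

# fold a point radially back inside the disk (reflecting boundary)
reflect_into_disk <- function(x, y, R) {
  r <- sqrt(x^2 + y^2)
  out <- r > R
  if (any(out)) {
    r_new <- 2 * R - r[out]
    r_new <- pmax(pmin(r_new, R), 0)   # clamp pathological large steps
    scale <- r_new / r[out]
    x[out] <- x[out] * scale
    y[out] <- y[out] * scale
  }
  list(x = x, y = y)
}
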