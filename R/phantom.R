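#' Specification of a synthetic angiography phantom
#'
#' The phantom emulates an ex-vivo bleeding rig at desk scale: a thin
#' tubular "vessel" (a dialyzer-fiber stand-in) carries a contrast bolus
#' front at constant speed, and an optional breakpoint lets contrast
#' extravasate into a slowly filling, slowly clearing blob — the imaging
#' signature of active bleeding. Frames are sampled at a low frame rate
#' with additive i.i.d. Gaussian noise.
#'
#' The per-pixel temporal profile is
#' `enhancement(t) = A * (1 - exp(-r * s)) * exp(-w * s)` with
#' `s = t - toa`, zero before arrival; `r` is the fill (rise) rate and `w`
#' the washout rate (`clear_rate` for extravasated pixels, which by
#' construction clears more slowly than the intravascular washout). Default
#' rates make the bolus front effectively sub-frame sharp at 6 fps,
#' matching a pressured injection.
#'
#' @param height,width image size in pixels.
#' @param n_frames number of frames (>= 6).
#' @param fps frames per second (default 6).
#' @param tube_path polyline of `(x, y)` pixel coordinates (matrix with two
#'   columns); default an S-curve across the image.
#' @param tube_radius_px tube radius in pixels (>= 1).
#' @param front_speed bolus front speed along the tube, px/s.
#' @param bolus_amplitude peak-scale enhancement A (intensity units).
#' @param rise_rate intravascular fill rate r (1/s).
#' @param washout_rate intravascular washout rate w (1/s).
#' @param breakpoint `NULL` for an intact tube, or a list with
#'   `position_frac` (0-1 along the path), `leak_radius_px`,
#'   `leak_fill_rate` (1/s), `leak_clear_rate` (1/s, must be smaller than
#'   `washout_rate`) and `spread_speed` (px/s radial pooling speed).
#' @param noise_sigma additive Gaussian noise std (intensity units).
#' @param seed integer RNG seed; identical spec implies bit-identical
#'   output.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 128, width = 128, n_frames = 60, fps = 6,
                         tube_path = NULL, tube_radius_px = 3,
                         front_speed = 25, bolus_amplitude = 100,
                         rise_rate = 30, washout_rate = 0.25,
                         breakpoint = list(position_frac = 0.6,
                                           leak_radius_px = 8,
                                           leak_fill_rate = 1.5,
                                           leak_clear_rate = 0.05,
                                           spread_speed = 4),
                         noise_sigma = 2, seed = 1L) {
  if (n_frames < 6L) stop("`n_frames` must be >= 6", call. = FALSE)
  if (fps <= 0) stop("`fps` must be positive", call. = FALSE)
  if (front_speed <= 0) stop("`front_speed` must be positive", call. = FALSE)
  if (tube_radius_px < 1) stop("`tube_radius_px` must be >= 1", call. = FALSE)
  if (is.null(tube_path)) tube_path <- default_tube_path(height, width)
  tube_path <- as.matrix(tube_path)
  if (ncol(tube_path) != 2L || nrow(tube_path) < 2L)
    stop("`tube_path` must be a polyline matrix with columns x, y",
         call. = FALSE)
  if (any(tube_path[, 1] < 1 | tube_path[, 1] > width |
          tube_path[, 2] < 1 | tube_path[, 2] > height))
    stop("`tube_path` leaves the image bounds", call. = FALSE)
  if (!is.null(breakpoint)) {
    need <- c("position_frac", "leak_radius_px", "leak_fill_rate",
              "leak_clear_rate", "spread_speed")
    missing_f <- setdiff(need, names(breakpoint))
    if (length(missing_f))
      stop("`breakpoint` is missing field(s): ",
           paste(missing_f, collapse = ", "), call. = FALSE)
    if (breakpoint$leak_radius_px < 1)
      stop("`leak_radius_px` must be >= 1", call. = FALSE)
    if (breakpoint$leak_clear_rate >= washout_rate)
      stop("`leak_clear_rate` must be smaller than `washout_rate`: ",
           "extravasated contrast clears slower than intravascular",
           call. = FALSE)
  }
  structure(list(height = height, width = width, n_frames = n_frames,
                 fps = fps, tube_path = tube_path,
                 tube_radius_px = tube_radius_px, front_speed = front_speed,
                 bolus_amplitude = bolus_amplitude, rise_rate = rise_rate,
                 washout_rate = washout_rate, breakpoint = breakpoint,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# gentle S-curve across the image, kept away from the borders
default_tube_path <- function(height, width) {
  s <- seq(0, 1, length.out = 40)
  cbind(x = 8 + s * (width - 16),
        y = height / 2 + 0.25 * height * sin(2 * pi * 0.8 * s))
}

# resample a polyline to ~0.5 px steps; returns points and arc positions
polyline_resample <- function(path, step = 0.5) {
  d <- sqrt(rowSums(diff(path)^2))
  cum <- c(0, cumsum(d))
  s <- unique(c(seq(0, cum[length(cum)], by = step), cum[length(cum)]))
  list(pts = cbind(stats::approx(cum, path[, 1], xout = s)$y,
                   stats::approx(cum, path[, 2], xout = s)$y),
       arc = s, length = cum[length(cum)])
}

#' Generate a synthetic DSA phantom with ground truth
#'
#' Builds the sequence described by a [phantom_spec()] together with the
#' true vessel mask, leak (extravasation) mask and the ideal per-pixel
#' arrival-time map `toa_true`: a pixel on the tube at arc distance `d`
#' from the injection end arrives at `d / front_speed`; leak pixels start
#' filling when the front reaches the breakpoint and pool radially at
#' `spread_speed`. `toa_true` is finite exactly on the union of the two
#' masks and is nondecreasing along the tube path.
#'
#' The RNG state of the caller is left untouched; the noise draw is seeded
#' from `spec$seed`, so identical specs give bit-identical sequences.
#' Frames are snapped to the storage grid (see [snap_to_storage()]) so a
#' [save_sequence()] / [load_sequence()] round trip is exact.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_truth`: `sequence`
#'   ([dsa_sequence()]), `vessel_mask`, `leak_mask`, `toa_true`, `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  rs <- polyline_resample(spec$tube_path)
  cols <- rep(seq_len(w), each = h)
  rows <- rep(seq_len(h), times = w)
  # nearest path point per pixel -> distance and arc position
  d2min <- rep(Inf, h * w); arc <- rep(NA_real_, h * w)
  for (i in seq_len(nrow(rs$pts))) {
    dd <- (cols - rs$pts[i, 1])^2 + (rows - rs$pts[i, 2])^2
    upd <- dd < d2min
    d2min[upd] <- dd[upd]; arc[upd] <- rs$arc[i]
  }
  vessel <- sqrt(d2min) <= spec$tube_radius_px
  toa <- ifelse(vessel, arc / spec$front_speed, NA_real_)

  leak <- rep(FALSE, h * w)
  if (!is.null(spec$breakpoint)) {
    bp <- spec$breakpoint
    bp_arc <- bp$position_frac * rs$length
    bp_pt <- rs$pts[which.min(abs(rs$arc - bp_arc)), ]
    t_break <- bp_arc / spec$front_speed
    dl <- sqrt((cols - bp_pt[1])^2 + (rows - bp_pt[2])^2)
    leak <- dl <= bp$leak_radius_px
    toa_leak <- t_break + dl / bp$spread_speed
    sel <- leak & !vessel
    toa[sel] <- toa_leak[sel]
    # where blob and tube overlap the pixel perfuses at the earlier of the two
    ov <- leak & vessel
    toa[ov] <- pmin(toa[ov], toa_leak[ov])
  }

  vessel_m <- matrix(vessel, h, w)
  leak_m <- matrix(leak, h, w)
  toa_m <- matrix(toa, h, w)

  profile <- function(s, r, wsh) ifelse(s > 0, (1 - exp(-r * s)) * exp(-wsh * s), 0)
  tms <- (seq_len(spec$n_frames) - 1) / spec$fps
  frames <- array(0, c(spec$n_frames, h, w))
  leak_only <- leak & !vessel
  overlap <- leak & vessel
  for (k in seq_len(spec$n_frames)) {
    s <- tms[k] - toa
    e <- numeric(h * w)
    iv <- vessel & !leak
    e[iv] <- spec$bolus_amplitude *
      profile(s[iv], spec$rise_rate, spec$washout_rate)
    if (any(leak)) {
      bp <- spec$breakpoint
      e[leak_only] <- spec$bolus_amplitude *
        profile(s[leak_only], bp$leak_fill_rate, bp$leak_clear_rate)
      e[overlap] <- spec$bolus_amplitude *
        pmax(profile(s[overlap], spec$rise_rate, spec$washout_rate),
             profile(s[overlap], bp$leak_fill_rate, bp$leak_clear_rate))
    }
    frames[k, , ] <- matrix(e, h, w)
  }
  if (spec$noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv()))
    set.seed(spec$seed)
    frames <- frames + array(stats::rnorm(length(frames), 0,
                                          spec$noise_sigma), dim(frames))
  }
  frames <- snap_to_storage(frames)
  structure(list(sequence = dsa_sequence(frames, spec$fps,
                                         source = "<phantom>"),
                 vessel_mask = vessel_m, leak_mask = leak_m,
                 toa_true = toa_m, spec = spec),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(paste0("<phantom_truth> %d x %d px, %d frames at %g fps; ",
                     "%d vessel px, %d leak px%s\n"),
              x$spec$height, x$spec$width, x$spec$n_frames, x$spec$fps,
              sum(x$vessel_mask), sum(x$leak_mask),
              if (is.null(x$spec$breakpoint)) " (intact tube)" else ""))
  invisible(x)
}

#' Generate a battery of randomized phantom cases
#'
#' Emulates a multi-group bench experiment at desk scale: `n_cases`
#' phantoms with specs drawn from documented ranges (front speed 15-35
#' px/s, amplitude 60-140, noise sigma 1-3, breakpoint position 0.35-0.8
#' along the tube, leak radius 6-10 px), a fraction of which contain a
#' breakpoint. Deterministic given `seed`; the caller's RNG state is
#' untouched.
#'
#' @param n_cases number of cases (>= 1).
#' @param breakpoint_fraction fraction of cases containing a leak.
#' @param seed integer seed.
#' @param height,width,n_frames,fps geometry shared by all cases.
#' @param noise_sigma `NULL` to draw per-case noise from 1-3, or a fixed
#'   value (e.g. 0 for noiseless ground-truth studies).
#' @return List with `cases` (list of `phantom_truth`) and `labels`
#'   (data frame: case, has_breakpoint, front_speed, amplitude,
#'   noise_sigma).
#' @export
make_experiment_battery <- function(n_cases = 27, breakpoint_fraction = 0.8,
                                    seed = 1L, height = 96, width = 96,
                                    n_frames = 48, fps = 6,
                                    noise_sigma = NULL) {
  if (n_cases < 1L) stop("`n_cases` must be >= 1", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  n_leak <- round(breakpoint_fraction * n_cases)
  has_bp <- sample(rep(c(TRUE, FALSE), c(n_leak, n_cases - n_leak)))
  draw <- function(lo, hi) stats::runif(1, lo, hi)
  cases <- vector("list", n_cases)
  labels <- data.frame(case = seq_len(n_cases), has_breakpoint = has_bp,
                       front_speed = NA_real_, amplitude = NA_real_,
                       noise_sigma = NA_real_)
  for (i in seq_len(n_cases)) {
    sp <- phantom_spec(
      height = height, width = width, n_frames = n_frames, fps = fps,
      front_speed = draw(15, 35), bolus_amplitude = draw(60, 140),
      noise_sigma = if (is.null(noise_sigma)) draw(1, 3) else noise_sigma,
      breakpoint = if (has_bp[i])
        list(position_frac = draw(0.35, 0.8),
             leak_radius_px = draw(6, 10),
             leak_fill_rate = draw(1, 2),
             leak_clear_rate = draw(0.02, 0.08),
             spread_speed = draw(3, 6)) else NULL,
      seed = sample.int(.Machine$integer.max, 1))
    labels$front_speed[i] <- sp$front_speed
    labels$amplitude[i] <- sp$bolus_amplitude
    labels$noise_sigma[i] <- sp$noise_sigma
    cases[[i]] <- generate_phantom(sp)
  }
  list(cases = cases, labels = labels)
}
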