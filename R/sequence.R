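# Acquisition model: free-running 3D golden-angle radial sequence with a
# repeating 3-shot magnetization-preparation cycle (IR, IR+T2prep(30 ms),
# IR+T2prep(60 ms)), spoiled gradient-echo readouts.

#' Sequence parameter set
#'
#' Collects the timing and geometry of the free-running acquisition: each
#' shot holds \code{spokes_per_shot} spoiled-GRE readouts (repetition time
#' \code{TR}), preceded by its preparation pulses and a delay \code{Tgap},
#' and followed by a recovery time \code{Tex}, so that
#' \code{spokes_per_shot * TR + Tgap + Tex == shot_interval}.
#'
#' @param n_shots number of shots in the scan
#' @param spokes_per_shot readouts per shot
#' @param TR repetition time (ms)
#' @param TE echo time (ms); bookkeeping only
#' @param Tgap delay between preparation pulses and the first readout (ms)
#' @param Tex recovery time between the last readout and the next
#'   preparation pulse (ms)
#' @param flip_angle readout flip angle (degrees)
#' @param shot_interval shot-to-shot interval (ms)
#' @param prep_cycle character vector giving the preparation type of each
#'   shot in the repeating cycle; entries are \code{"IR"} or
#'   \code{"IR+T2prep(<te>)"} with \code{<te>} the T2-preparation echo time
#'   in ms
#' @param samples_per_spoke readout samples per spoke; defaults to
#'   \code{readout_os * matrix}
#' @param fov field of view (mm, isotropic)
#' @param matrix reconstructed matrix size per axis (voxels)
#' @param readout_os readout oversampling factor
#' @return an object of class \code{sequence_params}
#' @export
sequence_params <- function(n_shots = 300, spokes_per_shot = 195, TR = 10.3,
                            TE = 4.6, Tgap = 9.5, Tex = 182, flip_angle = 6,
                            shot_interval = 2200,
                            prep_cycle = c("IR", "IR+T2prep(30)", "IR+T2prep(60)"),
                            samples_per_spoke = NULL, fov = 200, matrix = 48,
                            readout_os = 2) {
  if (n_shots < 1 || spokes_per_shot < 1) stop_invalid("n_shots and spokes_per_shot must be >= 1")
  if (any(c(TR, Tgap, Tex, shot_interval) <= 0)) stop_invalid("all times must be positive")
  timing <- spokes_per_shot * TR + Tgap + Tex
  if (abs(timing - shot_interval) > 1e-6)
    stop_invalid("inconsistent timing: spokes_per_shot*TR + Tgap + Tex = %.3f ms != shot_interval = %.3f ms",
                 timing, shot_interval)
  te <- parse_prep(prep_cycle)
  if (is.null(samples_per_spoke)) samples_per_spoke <- readout_os * matrix
  structure(list(n_shots = n_shots, spokes_per_shot = spokes_per_shot, TR = TR,
                 TE = TE, Tgap = Tgap, Tex = Tex, flip_angle = flip_angle,
                 shot_interval = shot_interval, prep_cycle = prep_cycle,
                 prep_te = te, samples_per_spoke = samples_per_spoke,
                 fov = fov, matrix = matrix, readout_os = readout_os),
            class = "sequence_params")
}

# T2-prep echo time per cycle position (0 = none)
parse_prep <- function(prep_cycle) {
  vapply(prep_cycle, function(p) {
    if (p == "IR") return(0)
    m <- regmatches(p, regexec("^IR\\+T2prep\\(([0-9.]+)\\)$", p))[[1]]
    if (length(m) != 2) stop_invalid("unknown preparation type '%s'", p)
    as.numeric(m[2])
  }, numeric(1), USE.NAMES = FALSE)
}

#' 3D golden-angle radial directions
#'
#' Deterministic low-discrepancy spoke directions from the double-golden-angle
#' recursion: the m-th direction (m = 0, 1, ...) has polar coordinate
#' \code{z = frac(m * 0.46557123...)} on the upper hemisphere and azimuth
#' \code{2*pi*frac(m * 0.68232780...)}.  The sequence is prefix-stable: the
#' first n directions do not depend on how many more are generated.
#'
#' @param n number of directions (>= 1)
#' @return an n x 3 matrix of unit vectors
#' @export
generate_golden_angle_directions <- function(n) {
  if (length(n) != 1 || is.na(n) || n < 1) stop_invalid("n must be >= 1")
  m <- seq_len(n) - 1
  phi1 <- 0.4656145110
  phi2 <- 0.6823278038
  z <- (m * phi1) %% 1
  az <- 2 * pi * ((m * phi2) %% 1)
  st <- sqrt(pmax(0, 1 - z^2))
  d <- cbind(st * cos(az), st * sin(az), z)
  # exact unit norm
  d / sqrt(rowSums(d^2))
}

#' Build the spoke schedule of a free-running scan
#'
#' Lays out every spoke of the scan with its shot index, index within the
#' shot, golden-angle direction, absolute timestamp, time since the shot's
#' inversion pulse (\code{Tgap + j*TR}), and preparation type from the
#' repeating cycle.
#'
#' @param params a \code{\link{sequence_params}} object
#' @return a \code{spoke_schedule}: a data.frame with one row per spoke and
#'   the parameter set stored as an attribute
#' @export
build_schedule <- function(params) {
  stopifnot(inherits(params, "sequence_params"))
  ns <- params$n_shots; sp <- params$spokes_per_shot
  m <- seq_len(ns * sp) - 1L
  shot <- m %/% sp
  j <- m %% sp
  ncyc <- length(params$prep_cycle)
  cyc <- shot %% ncyc
  sched <- data.frame(
    spoke = m + 1L,
    shot = shot,
    index_in_shot = j,
    cycle_pos = cyc,
    t_index = cyc * sp + j + 1L,   # row of the dictionary time axis
    time = shot * params$shot_interval + params$Tgap + j * params$TR,
    time_since_inversion = params$Tgap + j * params$TR,
    prep_type = params$prep_cycle[cyc + 1L],
    prep_te = params$prep_te[cyc + 1L]
  )
  dirs <- generate_golden_angle_directions(ns * sp)
  sched$dir_x <- dirs[, 1]; sched$dir_y <- dirs[, 2]; sched$dir_z <- dirs[, 3]
  attr(sched, "params") <- params
  class(sched) <- c("spoke_schedule", "data.frame")
  sched
}

#' Keep only the first shots of a schedule
#'
#' Retrospective undersampling keeps the first \code{round(fraction *
#' n_shots)} whole shots (round half up), preserving acquisition order.
#'
#' @param schedule a \code{spoke_schedule}
#' @param fraction fraction of shots to keep, in (0, 1]
#' @return the truncated \code{spoke_schedule}
#' @export
retrospective_undersample <- function(schedule, fraction) {
  stopifnot(inherits(schedule, "spoke_schedule"))
  if (length(fraction) != 1 || is.na(fraction) || fraction <= 0 || fraction > 1)
    stop_invalid("fraction must be in (0, 1]")
  params <- attr(schedule, "params")
  keep_shots <- floor(fraction * params$n_shots + 0.5)
  keep_shots <- max(1L, keep_shots)
  out <- schedule[schedule$shot < keep_shots, , drop = FALSE]
  params$n_shots <- as.integer(keep_shots)
  attr(out, "params") <- params
  class(out) <- c("spoke_schedule", "data.frame")
  out
}

#' Scan time of a number of shots
#' @param params a \code{\link{sequence_params}} object
#' @param n_shots_kept number of shots acquired (>= 1)
#' @return scan time in minutes
#' @export
scan_time <- function(params, n_shots_kept = params$n_shots) {
  stopifnot(inherits(params, "sequence_params"))
  if (n_shots_kept < 1) stop_invalid("n_shots_kept must be >= 1")
  n_shots_kept * params$shot_interval / 60000
}

#' Radial trajectory of a schedule
#'
#' Full-diameter spokes through the k-space center: sample i (0-based) of a
#' spoke with direction d sits at \code{k = (i - Ns/2) * dk * d} with
#' \code{dk = 1/(readout_os * fov)} cycles/mm, so the center sample is at
#' exactly k = 0 and the edge reaches the Nyquist radius of the matrix.
#'
#' @param schedule a \code{spoke_schedule}
#' @return list with \code{k} (samples x spokes x 3 array, cycles/mm),
#'   \code{kr} (signed radius per sample, cycles/mm), \code{center_index}
#'   (1-based readout index of the k = 0 sample)
#' @export
spoke_trajectory <- function(schedule) {
  params <- attr(schedule, "params")
  ns <- params$samples_per_spoke
  dk <- 1 / (params$readout_os * params$fov)
  kr <- (seq_len(ns) - 1 - ns / 2) * dk
  dirs <- as.matrix(schedule[, c("dir_x", "dir_y", "dir_z")])
  M <- nrow(dirs)
  k <- array(0, c(ns, M, 3))
  for (a in 1:3) k[, , a] <- outer(kr, dirs[, a])
  list(k = k, kr = kr, center_index = ns / 2 + 1)
}
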