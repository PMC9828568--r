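# Raw-data container (hierarchical directory store with JSON metadata and
# raw little-endian float64 datasets -- lossless for complex data), NIfTI
# volume helpers, and the validated pipeline configuration.

flatten_named <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (prefix == "") nm else paste0(prefix, "/", nm)
    v <- x[[nm]]
    if (is.list(v) && !is.null(names(v)) && !is.data.frame(v))
      out <- c(out, flatten_named(v, key))
    else out[[key]] <- v
  }
  out
}

#' Write / read the raw-data container
#'
#' Hierarchical datasets are stored as a directory: a \code{meta.json}
#' index (shapes, dtypes, schema version, attributes) plus one raw
#' little-endian binary file per dataset (complex values as interleaved
#' re/im doubles).  Round trips are bit-identical.
#'
#' @param path container directory
#' @param data named (possibly nested) list of numeric/complex/integer
#'   arrays and character scalars
#' @param attrs named list of scalar attributes (units, provenance, ...)
#' @return \code{read_container} returns the flat named list (names use
#'   \code{/} as group separator) with attributes restored
#' @export
write_container <- function(path, data, attrs = list()) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  flat <- flatten_named(data)
  meta <- list(schema_version = 1L, attrs = attrs, datasets = list())
  for (nm in names(flat)) {
    v <- flat[[nm]]
    file <- paste0(gsub("/", "__", nm), ".bin")
    dtype <- if (is.complex(v)) "complex" else if (is.character(v)) "character"
      else if (is.integer(v)) "integer" else "double"
    meta$datasets[[nm]] <- list(file = file, dtype = dtype,
                                dim = dim(v) %||% length(v))
    con <- file(file.path(path, file), "wb")
    if (dtype == "complex") {
      buf <- numeric(2 * length(v))
      buf[c(TRUE, FALSE)] <- Re(v); buf[c(FALSE, TRUE)] <- Im(v)
      writeBin(buf, con, size = 8, endian = "little")
    } else if (dtype == "character") {
      writeChar(paste(v, collapse = "\n"), con, eos = NULL)
    } else if (dtype == "integer") {
      writeBin(as.integer(v), con, size = 4, endian = "little")
    } else {
      writeBin(as.numeric(v), con, size = 8, endian = "little")
    }
    close(con)
  }
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(path, "meta.json"))
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop_invalid("not a container: missing %s", mf)
  meta <- jsonlite::fromJSON(mf, simplifyVector = TRUE)
  if (is.null(meta$schema_version) || meta$schema_version != 1)
    stop_invalid("unsupported container schema version")
  out <- list()
  for (nm in names(meta$datasets)) {
    ds <- meta$datasets[[nm]]
    fp <- file.path(path, ds$file)
    nelem <- prod(ds$dim)
    con <- file(fp, "rb")
    v <- switch(ds$dtype,
      complex = {
        buf <- readBin(con, "double", 2 * nelem, size = 8, endian = "little")
        complex(real = buf[c(TRUE, FALSE)], imaginary = buf[c(FALSE, TRUE)])
      },
      character = strsplit(readChar(con, file.size(fp), useBytes = TRUE), "\n")[[1]],
      integer = readBin(con, "integer", nelem, size = 4, endian = "little"),
      readBin(con, "double", nelem, size = 8, endian = "little"))
    close(con)
    if (ds$dtype != "character" && length(ds$dim) > 1) dim(v) <- ds$dim
    out[[nm]] <- v
  }
  attr(out, "container_attrs") <- meta$attrs
  out
}

#' Save / load a \code{radial_kspace} object as a container
#' @param kobj a \code{radial_kspace} object
#' @param path container directory
#' @param ground_truth include the simulation ground-truth group
#' @return \code{load_kspace_container} returns the restored object
#' @export
save_kspace_container <- function(kobj, path, ground_truth = TRUE) {
  params <- attr(kobj$schedule, "params")
  sched <- kobj$schedule
  data <- list(
    kspace = kobj$kspace,
    trajectory = kobj$traj$k,
    weights = kobj$weights,
    center_samples = as.complex(kobj$center_samples),
    spoke_times = sched$time,
    t_index = as.integer(sched$t_index),
    prep_te = sched$prep_te,
    cardiac_phase = as.integer(kobj$cardiac_phase))
  if (!is.null(kobj$ground_truth$physio))
    data$r_peaks <- kobj$ground_truth$physio$r_peaks
  if (ground_truth && !is.null(kobj$ground_truth)) {
    gt <- kobj$ground_truth
    data$gt <- list(t1 = gt$t1, t2 = gt$t2, pd = gt$pd,
                    labels = gt$labels,
                    translations = gt$translations)
    for (q in seq_along(gt$fields)) {
      f <- gt$fields[[q]]
      data$gt[[sprintf("field_q%02d", q)]] <-
        array(c(f$ux, f$uy, f$uz), c(dim(f$ux), 3))
    }
    data$gt$coils <- gt$coils
  }
  attrs <- list(units_k = "cycles/mm", units_time = "ms",
                n_coils = kobj$n_coils, Q = kobj$Q %||% 1,
                noise_sd = kobj$noise_sd, seed = kobj$seed,
                resp_corrected = isTRUE(kobj$resp_corrected),
                params = unclass(params)[setdiff(names(params), "prep_te")])
  write_container(path, data, attrs)
}

#' @rdname save_kspace_container
#' @export
load_kspace_container <- function(path) {
  d <- read_container(path)
  at <- attr(d, "container_attrs")
  p <- at$params
  params <- sequence_params(n_shots = p$n_shots, spokes_per_shot = p$spokes_per_shot,
                            TR = p$TR, TE = p$TE, Tgap = p$Tgap, Tex = p$Tex,
                            flip_angle = p$flip_angle, shot_interval = p$shot_interval,
                            prep_cycle = unlist(p$prep_cycle),
                            samples_per_spoke = p$samples_per_spoke,
                            fov = p$fov, matrix = p$matrix, readout_os = p$readout_os)
  schedule <- build_schedule(params)
  M <- dim(d$kspace)[2]
  schedule <- schedule[seq_len(M), , drop = FALSE]
  attr(schedule, "params") <- params
  class(schedule) <- c("spoke_schedule", "data.frame")
  traj <- spoke_trajectory(schedule)
  traj$k <- d$trajectory   # stored trajectory is authoritative (bit-exact)
  gt <- NULL
  if (!is.null(d$`gt/t1`)) {
    Q <- at$Q
    fields <- vector("list", Q)
    for (q in seq_len(Q)) {
      a <- d[[sprintf("gt/field_q%02d", q)]]
      if (!is.null(a))
        fields[[q]] <- list(ux = a[, , , 1], uy = a[, , , 2], uz = a[, , , 3])
    }
    gt <- list(t1 = d$`gt/t1`, t2 = d$`gt/t2`, pd = d$`gt/pd`,
               labels = d$`gt/labels`, translations = d$`gt/translations`,
               coils = d$`gt/coils`, fields = fields)
  }
  structure(list(kspace = d$kspace, traj = traj, schedule = schedule,
                 n_coils = at$n_coils,
                 center_samples = matrix(d$center_samples, M, at$n_coils),
                 weights = d$weights,
                 cardiac_phase = d$cardiac_phase, Q = at$Q,
                 r_peaks = d$r_peaks,
                 ground_truth = gt, noise_sd = at$noise_sd, seed = at$seed,
                 resp_corrected = isTRUE(at$resp_corrected)),
            class = "radial_kspace")
}

#' Write a volume (or 4D stack) as NIfTI
#' @param vol numeric array (complex volumes are written as magnitude)
#' @param path output file
#' @param voxel_mm voxel size
#' @return the path, invisibly
#' @export
write_volume_nifti <- function(vol, path, voxel_mm = 1) {
  if (is.complex(vol)) vol <- Mod(vol)
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(voxel_mm, min(3, length(dim(vol))))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Default pipeline configuration
#'
#' All reconstruction defaults: r = 3 singular contrasts, 16 cardiac
#' phases, 4 ADMM iterations with 9 (LRI) / 3 (LRMC) CG iterations,
#' lambda = 750, mu = 0.02, 5x5x5 patches with up to 20 similar patches in
#' a 20x20x20 window, 5 respiratory bins with a 40\% diastolic window.
#'
#' @return nested configuration list
#' @export
default_config <- function() {
  list(
    seed = 1,
    data_fraction = 1.0,
    sequence = list(n_shots = 30, spokes_per_shot = 195, TR = 10.3, TE = 4.6,
                    Tgap = 9.5, Tex = 182, flip_angle = 6, shot_interval = 2200,
                    prep_cycle = c("IR", "IR+T2prep(30)", "IR+T2prep(60)"),
                    fov = 200, matrix = 48, readout_os = 2),
    phantom = list(ef = 0.6, snr = 30, n_coils = 8, rr_mean = 900, rr_sd = 30,
                   resp_period = 4000, resp_amp = c(1, 1, 8), jitter = FALSE),
    resp = list(n_bins = 5, window = 0.4, window_center = 0.75),
    dictionary = list(n_t1 = 138, t1_range = c(200, 3000),
                      n_t2 = 303, t2_range = c(10, 200)),
    recon = list(r = 3, Q = 16, n_admm = 4, n_cg_lri = 9, n_cg_lrmc = 3,
                 lambda = 750, mu = 0.02, patch = 5, n_sim = 20, window = 20,
                 stride = 2, cand_stride = 2, ref_level = 3000,
                 weighting = "sqrt", n_virtual_coils = 0,
                 cine_source = "lri"))
}

check_keys <- function(cfg, ref, path = "") {
  for (nm in names(cfg)) {
    if (!nm %in% names(ref))
      stop_invalid("unknown configuration key '%s%s'", path, nm)
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]]))) {
      if (!is.list(cfg[[nm]])) stop_invalid("'%s%s' must be a block", path, nm)
      check_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "/"))
    }
  }
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, rejects unknown keys, and fills every omitted key
#' from \code{\link{default_config}}.
#'
#' @param path YAML file (NULL = defaults only)
#' @param overrides named nested list applied after the file
#' @return validated configuration with attribute \code{hash}
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  check_keys(user, cfg)
  check_keys(overrides, cfg)
  cfg <- utils::modifyList(cfg, user)
  cfg <- utils::modifyList(cfg, overrides)
  attr(cfg, "hash") <- fnv1a(as.character(
    jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)))
  cfg
}

#' Echo a configuration (with resolved seed) next to an output
#' @param cfg configuration list
#' @param path output file (JSON)
#' @return the path, invisibly
#' @export
write_config_echo <- function(cfg, path) {
  writeLines(as.character(jsonlite::toJSON(
    list(config = cfg, hash = attr(cfg, "hash"),
         package_version = as.character(utils::packageVersion("freerun"))),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)), path)
  invisible(path)
}
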