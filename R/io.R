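#' Read a 3-D scalar NIfTI volume
#'
#' Spacing and origin are taken from the stored transform (voxel-to-world
#' matrix): spacing from the column norms, origin from the translation.
#'
#' @param path NIfTI-1 file (`.nii` / `.nii.gz`).
#' @return an [image3d].
#' @export
read_image <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop(sprintf("expected a 3-D scalar volume, got %d dimensions",
                 length(dim(img))))
  m <- RNifti::xform(img)
  spacing <- sqrt(colSums(m[1:3, 1:3]^2))
  origin <- m[1:3, 4]
  arr <- array(as.numeric(img), dim(img))
  image3d(arr, spacing, origin)
}

nifti_with_geometry <- function(data, spacing, origin) {
  img <- RNifti::asNifti(data)
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  RNifti::`sform<-`(img, structure(m, code = 2L))
}

#' Write an image as NIfTI-1
#' @param img an [image3d].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(is_image3d(img))
  RNifti::writeNifti(nifti_with_geometry(img$data, img$spacing, img$origin),
                     path)
  invisible(path)
}

#' Read / write a displacement field as 4-D NIfTI
#'
#' Stored as a 4-D volume whose last axis holds the (x, y, z) displacement
#' components in mm.
#'
#' @param dvf a [dvf3d].
#' @param path NIfTI file path.
#' @return `write_dvf`: `path` invisibly; `read_dvf`: a [dvf3d].
#' @export
write_dvf <- function(dvf, path) {
  stopifnot(is_dvf3d(dvf))
  d <- dim(dvf$ux)
  arr <- array(c(dvf$ux, dvf$uy, dvf$uz), c(d, 3))
  RNifti::writeNifti(nifti_with_geometry(arr, dvf$spacing, dvf$origin), path)
  invisible(path)
}

#' @rdname write_dvf
#' @export
read_dvf <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L || dim(img)[4] != 3L)
    stop("expected a 4-D displacement volume with 3 components")
  m <- RNifti::xform(img)
  spacing <- sqrt(colSums(m[1:3, 1:3]^2))
  origin <- m[1:3, 4]
  d <- dim(img)[1:3]
  arr <- array(as.numeric(img), dim(img))
  dvf3d(array(arr[, , , 1], d), array(arr[, , , 2], d),
        array(arr[, , , 3], d), spacing, origin)
}

#' Read / write landmark tables
#'
#' CSV with columns `id, x_mm, y_mm, z_mm, frame`.
#'
#' @param landmarks n-by-3 matrix of coordinates (mm).
#' @param path CSV path.
#' @param frame frame label stored with the points (default 0).
#' @return `write_landmarks`: `path` invisibly; `read_landmarks`: a data
#'   frame.
#' @export
write_landmarks <- function(landmarks, path, frame = 0L) {
  landmarks <- matrix(as.numeric(landmarks), ncol = 3)
  df <- data.frame(id = seq_len(nrow(landmarks)),
                   x_mm = landmarks[, 1], y_mm = landmarks[, 2],
                   z_mm = landmarks[, 3], frame = frame)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path)
  need <- c("id", "x_mm", "y_mm", "z_mm", "frame")
  if (!all(need %in% names(df)))
    stop("landmark file must have columns id, x_mm, y_mm, z_mm, frame")
  df
}

#' Read / write a breathing waveform
#'
#' CSV with columns `t_s, displacement_mm`.
#'
#' @param waveform a `breathing_waveform`.
#' @param path CSV path.
#' @return `write_waveform`: `path` invisibly; `read_waveform`: a
#'   `breathing_waveform`.
#' @export
write_waveform <- function(waveform, path) {
  stopifnot(inherits(waveform, "breathing_waveform"))
  write.csv(data.frame(t_s = waveform$time,
                       displacement_mm = waveform$displacement),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  df <- read.csv(path)
  if (!all(c("t_s", "displacement_mm") %in% names(df)))
    stop("waveform file must have columns t_s, displacement_mm")
  dt <- if (nrow(df) > 1) diff(df$t_s[1:2]) else 1
  structure(list(time = df$t_s, displacement = df$displacement_mm,
                 frame_rate = 1 / dt, duration = nrow(df) * dt),
            class = "breathing_waveform")
}

#' Read a YAML run configuration
#'
#' Validates and fills a run configuration with sections `phantom`
#' (arguments of [phantom_spec()]), `waveform` ([irregular_waveform()]),
#' `noise` (`level`, `seed`), `demons` ([demons_params()]), `pipeline`
#' (`mode`: `"two_step"` or `"one_step"`), and `seed`.
#'
#' @param path YAML file.
#' @return object of class `run_config` with `phantom`, `waveform`, `noise`,
#'   `demons`, `mode`, `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration must be a YAML mapping")
  seed <- as.integer(cfg$seed %||% 1L)
  known <- function(args, fn) {
    extra <- setdiff(names(args), names(formals(fn)))
    if (length(extra))
      stop(sprintf("unknown configuration keys: %s",
                   paste(extra, collapse = ", ")))
    args
  }
  ph <- known(cfg$phantom %||% list(), phantom_spec)
  if (is.null(ph$seed)) ph$seed <- seed
  wf <- known(cfg$waveform %||% list(), irregular_waveform)
  if (is.null(wf$seed)) wf$seed <- seed + 1L
  dm <- known(cfg$demons %||% list(), demons_params)
  noise <- cfg$noise %||% list()
  mode <- (cfg$pipeline %||% list())$mode %||% "two_step"
  if (!mode %in% c("two_step", "one_step"))
    stop("pipeline mode must be 'two_step' or 'one_step'")
  structure(list(
    phantom = do.call(phantom_spec, ph),
    waveform = do.call(irregular_waveform, wf),
    noise = list(level = noise$level %||% 0.02,
                 seed = as.integer(noise$seed %||% (seed + 2L))),
    demons = do.call(demons_params, dm),
    mode = mode, seed = seed, raw = cfg),
    class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
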