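#' Retina-contingent gain transform
#'
#' Maps an eye trace to the world and retinal trajectories of a stimulus
#' moving contingent on that eye motion. Per frame, the stimulus's world
#' displacement equals `gain` times the eye displacement, so its retinal
#' displacement (world minus eye) equals `gain - 1` times the eye
#' displacement. The sign convention is that positive gain moves the stimulus
#' in the same direction as the eye: gain 0 is a world-fixed stimulus, gain
#' +1 is retinally stabilized, and gains below +1 slip in the direction of
#' retinal slip. For example, under gain -1.5 an eye step of +2 arcmin
#' produces a world step of -3 arcmin and a retinal step of magnitude
#' 5 arcmin.
#'
#' All three returned trajectories are displacement-based: they start at
#' (0, 0) so only displacements, never absolute screen coordinates, are
#' compared downstream. The transform is applied to per-frame increments;
#' for saccade-free drift this is identical to scaling displacement from the
#' trace start.
#'
#' @param eye an [eye_trace()] with finite positions.
#' @param gain dimensionless gain (the study used -1.5, +1.5, and 0).
#' @return an object of class `trajectory_set`: list with `eye`, `world`,
#'   `retinal` (n x 2 displacement matrices anchored at the origin), `gain`,
#'   and `frame_rate`.
#' @seealso [diffusion_scaling()] for the induced diffusion-constant factors.
#' @examples
#' tr <- eye_trace(cbind(c(0, 2), c(0, 0)))
#' ts <- apply_gain(tr, -1.5)
#' ts$world[2, ]   # (-3, 0): moved 3 arcmin opposite the eye
#' ts$retinal[2, ] # (-5, 0): 5 arcmin of retinal displacement
#' @export
apply_gain <- function(eye, gain) {
  pos <- as_positions(eye)
  stopifnot_scalar(gain, "gain")
  if (any(!is.finite(pos))) {
    stop("eye positions must be finite to apply a gain", call. = FALSE)
  }
  eye_d <- sweep(pos, 2L, pos[1L, ]) # re-anchor at the origin
  world <- gain * eye_d
  retinal <- world - eye_d           # = (gain - 1) * eye displacement
  colnames(world) <- colnames(retinal) <- c("x", "y")
  structure(
    list(eye = eye_d, world = world, retinal = retinal,
         gain = gain, frame_rate = frame_rate_of(eye)),
    class = "trajectory_set"
  )
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set: gain %+g, %d frames @ %g Hz>\n",
              x$gain, nrow(x$eye), x$frame_rate))
  invisible(x)
}

#' @export
as.data.frame.trajectory_set <- function(x, ...) {
  n <- nrow(x$eye)
  data.frame(
    frame = seq_len(n),
    t_s = (seq_len(n) - 1) / x$frame_rate,
    x_arcmin = x$eye[, 1], y_arcmin = x$eye[, 2],
    world_x = x$world[, 1], world_y = x$world[, 2],
    ret_x = x$retinal[, 1], ret_y = x$retinal[, 2]
  )
}

#' Diffusion-constant scaling factors of a gain
#'
#' The gain transform scales every displacement, hence every mean square
#' displacement, by an exact factor: the stimulus's world-motion diffusion
#' constant is `gain^2` times the eye's, and its retinal-motion diffusion
#' constant is `(gain - 1)^2` times the eye's. The scaling exponent alpha is
#' unchanged by either transform. For gain -1.5 the factors are 2.25 and
#' 6.25 (the stimulus slips 2.5x more than a world-fixed object); for gain
#' +1.5 they are 2.25 and 0.25 (half the retinal motion of a world-fixed
#' object).
#'
#' @param gain dimensionless gain.
#' @return named numeric vector `c(world = gain^2, retinal = (gain - 1)^2)`.
#' @examples
#' diffusion_scaling(-1.5) # world 2.25, retinal 6.25
#' diffusion_scaling(0)    # world 0, retinal 1 (pure retinal slip)
#' @export
diffusion_scaling <- function(gain) {
  stopifnot_scalar(gain, "gain")
  c(world = gain^2, retinal = (gain - 1)^2)
}

#' Total path length of a trajectory
#'
#' Sum of per-frame Euclidean displacement magnitudes, in arcminutes. Useful
#' for expressing how far a retina-contingent stimulus travels across the
#' retina relative to a world-fixed one: for a shared eye trace the retinal
#' path of a gain `g` stimulus is `|g - 1|` times the eye's path.
#'
#' @param positions n x 2 position matrix (or [eye_trace()]).
#' @return total path length (arcmin).
#' @export
path_length <- function(positions) {
  pos <- as_positions(positions)
  st <- pos[-1L, , drop = FALSE] - pos[-nrow(pos), , drop = FALSE]
  sum(sqrt(rowSums(st^2)))
}
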