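#' Orthorhombic simulation box
#'
#' Constructs a periodic orthorhombic box from its three edge lengths.
#' Triclinic cells are not supported and are rejected with an error.
#'
#' @param edge_lengths Numeric vector of three positive edge lengths
#'   (Angstrom).  A 3x3 matrix is accepted if it is diagonal.
#' @return A `simulation_box`: numeric length-3 vector of edge lengths.
#' @examples
#' b <- simulation_box(c(60.015, 60.015, 60.015))
#' box_volume(b)
#' @export
simulation_box <- function(edge_lengths) {
  if (is.matrix(edge_lengths)) {
    if (!all(dim(edge_lengths) == c(3, 3)))
      stop("box matrix must be 3x3")
    off <- edge_lengths[row(edge_lengths) != col(edge_lengths)]
    if (any(abs(off) > 1e-9))
      stop("triclinic boxes are not supported (off-diagonal box elements)")
    edge_lengths <- diag(edge_lengths)
  }
  edge_lengths <- as.numeric(edge_lengths)
  if (length(edge_lengths) == 1) edge_lengths <- rep(edge_lengths, 3)
  if (length(edge_lengths) != 3 || anyNA(edge_lengths))
    stop("box must have three edge lengths")
  if (any(edge_lengths <= 0)) stop("box edge lengths must be positive")
  structure(edge_lengths, class = "simulation_box")
}

#' Box volume
#' @param box A `simulation_box` (or plain length-3 numeric).
#' @return Volume in Angstrom^3.
#' @export
box_volume <- function(box) prod(as.numeric(box))

as_box <- function(box) {
  if (inherits(box, "simulation_box")) return(box)
  simulation_box(box)
}

#' Minimum-image distance between two points
#'
#' Euclidean norm of the component-wise nearest-image displacement in an
#' orthorhombic periodic box.
#'
#' @param a,b Numeric 3-vectors (Angstrom).
#' @param box A `simulation_box`.
#' @return Distance in Angstrom.
#' @examples
#' minimum_image_distance(c(1, 0, 0), c(9, 0, 0), simulation_box(10))  # 2
#' @export
minimum_image_distance <- function(a, b, box) {
  box <- as.numeric(as_box(box))
  d <- as.numeric(b) - as.numeric(a)
  d <- d - box * round(d / box)
  sqrt(sum(d * d))
}

# Nearest-image displacement of each row of `mat` from point `ref`.
min_image_disp <- function(mat, ref, box) {
  box <- as.numeric(box)
  d <- sweep(mat, 2, as.numeric(ref))
  d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
}

# Minimum-image distances between rows of `mat` and point `ref`.
min_image_dist_vec <- function(mat, ref, box) {
  d <- min_image_disp(mat, ref, box)
  sqrt(rowSums(d * d))
}
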