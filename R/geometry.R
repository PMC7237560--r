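# Cell, cluster and sphere phantoms; source-position sampling; region
# classification.  Coordinates are Cartesian in um; all distances are
# Euclidean.

#' Source distributions
#'
#' The supported subcellular source distributions: uniform on the cell
#' surface, uniform in the cytoplasm, uniform in the nucleus, or uniform
#' in the whole cell.
#'
#' @return character vector of distribution names.
#' @export
sourceDistributions <- function()
  c("cell_surface", "cytoplasm", "nucleus", "whole_cell")

#' Construct a cell phantom
#'
#' @param cellRadius outer cell radius in um (default 7, a 14 um cell).
#' @param nucleusRadius nucleus radius in um (default 5).
#' @param membraneThickness membrane thickness in um (default 0.010,
#'   i.e. 10 nm, lining the inside of the cell surface).
#' @param center cell centre (um).
#' @param density mass density in g/cm3.
#' @return a \linkS4class{CellModel}.
#' @examples
#' cellVolume(cellModel())  # about 1436.8 um3
#' @export
cellModel <- function(cellRadius = 7, nucleusRadius = 5,
                      membraneThickness = 0.010,
                      center = c(0, 0, 0), density = 1) {
  new("CellModel", cellRadius = cellRadius, nucleusRadius = nucleusRadius,
      membraneThickness = membraneThickness, center = as.numeric(center),
      density = density)
}

#' Construct a water sphere phantom
#'
#' @param radius sphere radius in um.
#' @param density mass density in g/cm3.
#' @return a \linkS4class{SpherePhantom}.
#' @export
spherePhantom <- function(radius, density = 1) {
  new("SpherePhantom", radius = radius, density = density)
}

#' Phantom volumes
#'
#' Closed-form volumes of the cell and its compartments.  The membrane is
#' the thin shell just inside the cell surface; the cytoplasm is the shell
#' between the nucleus and the membrane.  The three compartment volumes
#' sum exactly to the cell volume.
#'
#' @param cell a \linkS4class{CellModel}.
#' @return volume in um3.
#' @export
cellVolume <- function(cell) 4 / 3 * pi * cell@cellRadius^3

#' @rdname cellVolume
#' @export
nucleusVolume <- function(cell) 4 / 3 * pi * cell@nucleusRadius^3

#' @rdname cellVolume
#' @export
membraneVolume <- function(cell) {
  rin <- cell@cellRadius - cell@membraneThickness
  4 / 3 * pi * (cell@cellRadius^3 - rin^3)
}

#' @rdname cellVolume
#' @export
cytoplasmVolume <- function(cell) {
  rin <- cell@cellRadius - cell@membraneThickness
  4 / 3 * pi * (rin^3 - cell@nucleusRadius^3)
}

#' Assemble the 19-cell simple-cubic cluster
#'
#' Places copies of `cell` on a simple cubic lattice: the central cell at
#' the origin, 6 first-neighbourhood cells at one pitch along the axes,
#' and 12 second-neighbourhood cells at pitch*sqrt(2) along the face
#' diagonals.
#'
#' @param cell the template \linkS4class{CellModel} (its `center` is ignored).
#' @param pitch lattice pitch in um; defaults to one cell diameter
#'   (cells in direct contact).
#' @return a \linkS4class{ClusterModel}.
#' @examples
#' cl <- makeCluster(cellModel())
#' table(cl@neighbourhood)
#' @export
makeCluster <- function(cell, pitch = 2 * cell@cellRadius) {
  if (pitch < 2 * cell@cellRadius)
    stop("cells overlap: pitch (", pitch, " um) < cell diameter (",
         2 * cell@cellRadius, " um)")
  p <- pitch
  n1 <- rbind(c(p, 0, 0), c(-p, 0, 0), c(0, p, 0),
              c(0, -p, 0), c(0, 0, p), c(0, 0, -p))
  s <- c(-1, 1)
  n2 <- do.call(rbind, c(
    lapply(s, function(a) t(sapply(s, function(b) c(a * p, b * p, 0)))),
    lapply(s, function(a) t(sapply(s, function(b) c(a * p, 0, b * p)))),
    lapply(s, function(a) t(sapply(s, function(b) c(0, a * p, b * p))))))
  centers <- rbind(c(0, 0, 0), n1, n2)
  labels <- c("central", rep("n1", 6), rep("n2", 12))
  cells <- lapply(seq_len(nrow(centers)), function(i) {
    c2 <- cell
    c2@center <- centers[i, ]
    c2
  })
  new("ClusterModel", cells = cells, neighbourhood = labels, pitch = p)
}

# uniform points in the spherical shell a <= r < b around `center`
.uniformShell <- function(n, a, b, center = c(0, 0, 0)) {
  r <- (a^3 + (b^3 - a^3) * stats::runif(n))^(1 / 3)
  .isotropic(n) * r + matrix(center, n, 3, byrow = TRUE)
}

# n isotropic unit vectors
.isotropic <- function(n) {
  u <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  cbind(s * cos(phi), s * sin(phi), u)
}

#' Sample decay positions in a source region
#'
#' Draws uniform positions in the requested subcellular region:
#' `cell_surface` on the sphere of the cell radius, `nucleus` uniform in
#' the nucleus ball, `cytoplasm` uniform in the shell between nucleus and
#' the inner membrane surface, `whole_cell` uniform in the full cell ball.
#'
#' @param region one of [sourceDistributions()].
#' @param cell a \linkS4class{CellModel}.
#' @param n number of positions.
#' @param surfaceMode where on the 10 nm membrane a `cell_surface` source
#'   sits: `"outer"` (the cell surface, default), `"mid"` or `"shell"`
#'   (uniform through the membrane).  The differences are far below the
#'   transport resolution.
#' @return `n` x 3 matrix of positions in um.
#' @examples
#' p <- sampleSourcePositions("nucleus", cellModel(), 100)
#' max(sqrt(rowSums(p^2)))  # <= 5
#' @export
sampleSourcePositions <- function(region, cell, n,
                                  surfaceMode = c("outer", "mid", "shell")) {
  region <- match.arg(region, sourceDistributions())
  surfaceMode <- match.arg(surfaceMode)
  R <- cell@cellRadius
  rin <- R - cell@membraneThickness
  ctr <- cell@center
  switch(region,
    cell_surface = switch(surfaceMode,
      outer = .isotropic(n) * R + matrix(ctr, n, 3, byrow = TRUE),
      mid = .isotropic(n) * (R - cell@membraneThickness / 2) +
        matrix(ctr, n, 3, byrow = TRUE),
      shell = .uniformShell(n, rin, R, ctr)),
    nucleus = .uniformShell(n, 0, cell@nucleusRadius, ctr),
    cytoplasm = .uniformShell(n, cell@nucleusRadius, rin, ctr),
    whole_cell = .uniformShell(n, 0, R, ctr))
}

#' Classify points by cell region
#'
#' Radial classification with half-open shells `[inner, outer)`: a point
#' exactly on the nucleus boundary belongs to the cytoplasm and a point
#' exactly on the inner membrane surface belongs to the membrane.
#'
#' @param points 3-vector or n x 3 matrix of positions (um).
#' @param cell a \linkS4class{CellModel}.
#' @return character vector: `"nucleus"`, `"cytoplasm"`, `"membrane"` or
#'   `"outside"`.
#' @examples
#' regionOf(c(6, 0, 0), cellModel())  # cytoplasm
#' @export
regionOf <- function(points, cell) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  d <- sweep(points, 2, cell@center)
  r <- sqrt(rowSums(d^2))
  rin <- cell@cellRadius - cell@membraneThickness
  out <- rep("outside", length(r))
  out[r < cell@cellRadius] <- "membrane"
  out[r < rin] <- "cytoplasm"
  out[r < cell@nucleusRadius] <- "nucleus"
  out
}
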