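# Orientation-averaged projected areas and the hard-sphere combination.

# Bondi van der Waals radii (Angstrom) for common elements; deuterium
# shares the hydrogen radius. User-overridable everywhere radii are taken.
.bondi <- c(H = 1.20, D = 1.20, He = 1.40, C = 1.70, N = 1.55, O = 1.52,
            F = 1.47, Ne = 1.54, Na = 2.27, Mg = 1.73, Si = 2.10,
            P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88, K = 2.75,
            Br = 1.85, I = 1.98)

#' Default van der Waals radii
#'
#' Bondi radii (Angstrom) for the elements bundled with the package,
#' optionally subset by element symbol.
#'
#' @param elements Optional character vector of element symbols.
#' @return Named numeric vector of radii in Angstrom.
#' @export
default_radii <- function(elements = NULL) {
  if (is.null(elements)) return(.bondi)
  miss <- setdiff(unique(elements), names(.bondi))
  if (length(miss))
    stop("no default radius for element(s): ", paste(miss, collapse = ", "),
         "; supply radii explicitly", call. = FALSE)
  .bondi[elements]
}

resolve_radii <- function(geometry, radii) {
  if (is.null(radii)) return(unname(default_radii(geometry$element)))
  if (!is.null(names(radii))) return(unname(default_radii_from(radii, geometry)))
  if (length(radii) == 1L) radii <- rep(radii, nrow(geometry))
  if (length(radii) != nrow(geometry))
    stop("`radii` must be length 1, one per atom, or named by element",
         call. = FALSE)
  if (any(radii <= 0)) stop("radii must be > 0", call. = FALSE)
  as.numeric(radii)
}

default_radii_from <- function(table, geometry) {
  miss <- setdiff(unique(geometry$element), names(table))
  if (length(miss))
    stop("radius table lacks element(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  r <- table[geometry$element]
  if (any(r <= 0)) stop("radii must be > 0", call. = FALSE)
  r
}

# Uniform random rotation matrices via normalized quaternions.
random_rotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  lapply(seq_len(n), function(i) {
    w <- q[i, 1]; x <- q[i, 2]; y <- q[i, 3]; z <- q[i, 4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  })
}

#' Orientation-averaged projected area of a molecule
#'
#' Monte Carlo estimate of the mean area of the union of atomic disks
#' projected onto a plane, averaged over uniformly random rigid rotations
#' (uniform quaternion sampling). Each orientation's union area is itself
#' estimated by uniform point sampling inside a fixed bounding disk, which
#' is unbiased for arbitrary overlap topology; a single atom is returned
#' exactly as \eqn{\pi r^2}. The estimate is deterministic for a fixed
#' seed, and its standard error (attribute `"se"`) scales as
#' \eqn{1/\sqrt{n_{orientations}}}.
#'
#' @param geometry Data frame with `element`, `x`, `y`, `z` columns
#'   (Angstrom), e.g. from [read_xyz()].
#' @param radii `NULL` for bundled Bondi radii, a named per-element vector,
#'   or one radius per atom (Angstrom).
#' @param n_orientations Number of random orientations (>= 1).
#' @param n_points Sample points per orientation for the union area.
#' @param seed Optional RNG seed for reproducibility.
#' @return Mean projected area in Angstrom^2, with attribute `"se"` (its
#'   Monte Carlo standard error; 0 for a single atom).
#' @export
#' @examples
#' atom <- data.frame(element = "Ar", x = 0, y = 0, z = 0)
#' projected_area(atom)                     # exactly pi * 1.88^2
projected_area <- function(geometry, radii = NULL, n_orientations = 500,
                           n_points = 256, seed = NULL) {
  geometry <- validate_geometry(geometry)
  if (n_orientations < 1) stop("`n_orientations` must be >= 1",
                               call. = FALSE)
  r <- resolve_radii(geometry, radii)
  coords <- as.matrix(geometry[, c("x", "y", "z")])
  if (nrow(coords) == 1L) {
    return(structure(pi * r^2, se = 0))
  }
  coords <- sweep(coords, 2, colMeans(coords))
  bound <- max(sqrt(rowSums(coords^2)) + r)    # rotation-invariant bound
  areas <- with_seed(seed, {
    rots <- random_rotations(n_orientations)
    vapply(rots, function(rm) {
      xy <- coords %*% t(rm)[, 1:2]            # project along lab z
      rad <- bound * sqrt(stats::runif(n_points))
      ang <- stats::runif(n_points, 0, 2 * pi)
      px <- rad * cos(ang); py <- rad * sin(ang)
      inside <- rep(FALSE, n_points)
      for (a in seq_len(nrow(xy))) {
        inside <- inside |
          ((px - xy[a, 1])^2 + (py - xy[a, 2])^2 <= r[a]^2)
      }
      pi * bound^2 * mean(inside)
    }, numeric(1))
  })
  structure(mean(areas), se = stats::sd(areas) / sqrt(n_orientations))
}

#' Hard-sphere cross section from orientation-averaged projected areas
#'
#' Computes each partner's orientation-averaged projected area, converts
#' it to an effective radius \eqn{r = \sqrt{A/\pi}}, and combines them as
#' \eqn{\sigma_{hs} = \pi (r_a + r_b)^2}. The combination rule is isolated
#' here so it can be swapped if a different convention is preferred.
#'
#' @param geom_a,geom_b Geometries of the two partners (data frames with
#'   `element`, `x`, `y`, `z`).
#' @param radii_a,radii_b Radii specifications as in [projected_area()].
#' @param n_orientations,n_points,seed Monte Carlo controls, shared by
#'   both partners.
#' @return Hard-sphere cross section in Angstrom^2, with attributes
#'   `"area_a"`, `"area_b"` (the per-partner averaged areas) and `"se"`
#'   (propagated standard error).
#' @export
projected_area_sigma <- function(geom_a, radii_a = NULL, geom_b,
                                 radii_b = NULL, n_orientations = 500,
                                 n_points = 256, seed = NULL) {
  seeds <- if (is.null(seed)) list(NULL, NULL) else list(seed, seed + 1L)
  a <- projected_area(geom_a, radii_a, n_orientations, n_points, seeds[[1]])
  b <- projected_area(geom_b, radii_b, n_orientations, n_points, seeds[[2]])
  ra <- sqrt(as.numeric(a) / pi); rb <- sqrt(as.numeric(b) / pi)
  sig <- pi * (ra + rb)^2
  # d sigma / d A = (ra + rb) / r for each partner
  se <- sqrt(((ra + rb) / max(ra, 1e-12) * attr(a, "se"))^2 +
               ((ra + rb) / max(rb, 1e-12) * attr(b, "se"))^2)
  structure(sig, area_a = as.numeric(a), area_b = as.numeric(b), se = se)
}
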