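polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cross <- x * y2 - x2 * y
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) abort("degenerate polygon (zero area).")
  c(sum((x + x2) * cross), sum((y + y2) * cross)) / (6 * a)
}

validate_outline <- function(xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2 || nrow(xy) < 3) {
    abort("a soma outline needs at least 3 (x, y) vertices.")
  }
  storage.mode(xy) <- "double"
  if (any(!is.finite(xy))) abort("outline vertices must be finite.")
  xy
}

#' Directional diameters of a polygonal soma outline
#'
#' Width of the polygon's projection onto each direction theta sampled
#' uniformly in `[0, pi)`, after translating the outline to its area
#' centroid. In the dense-direction limit the maximum over theta is the
#' diameter along the most-changed diagonal used in soma morphometry.
#'
#' @param outline Matrix or data frame of ordered `(x, y)` vertices, um.
#' @param n_directions Number of sampled directions (default 180).
#' @return Tibble with `theta_rad`, `diameter_um`.
#' @export
soma_diameters <- function(outline, n_directions = 180) {
  xy <- validate_outline(outline)
  ctr <- polygon_centroid(xy)
  xy <- sweep(xy, 2, ctr)
  theta <- (seq_len(n_directions) - 1) * pi / n_directions
  proj <- xy %*% rbind(cos(theta), sin(theta))
  tibble(
    theta_rad = theta,
    diameter_um = apply(proj, 2, max) - apply(proj, 2, min)
  )
}

#' Largest directional diameter change between two soma outlines
#'
#' Quantifies how much a compressed soma bulges: for each sampled
#' direction, the diameter of the `during` outline minus that of the
#' `before` outline; the reported change is the maximum over directions
#' (the diagonal showing the largest diameter change). Both outlines are
#' centred on their own area centroids first, so the measure ignores
#' translation; direction sampling makes it rotation-insensitive up to the
#' angular resolution.
#'
#' @param before,during Ordered `(x, y)` vertex matrices/data frames, um.
#' @param n_directions Number of sampled directions (default 180).
#' @return One-row tibble with `diameter_change_um`, `theta_rad`,
#'   `diameter_before_um`, `diameter_during_um`.
#' @export
#' @examples
#' sq <- cbind(c(-5, 5, 5, -5), c(-5, -5, 5, 5))
#' wide <- cbind(c(-7, 7, 7, -7), c(-5, -5, 5, 5))
#' soma_diameter_change(sq, wide) # 4 um along x
soma_diameter_change <- function(before, during, n_directions = 180) {
  db <- soma_diameters(before, n_directions)
  dd <- soma_diameters(during, n_directions)
  change <- dd$diameter_um - db$diameter_um
  i <- which.max(change)
  tibble(
    diameter_change_um = change[i],
    theta_rad = db$theta_rad[i],
    diameter_before_um = db$diameter_um[i],
    diameter_during_um = dd$diameter_um[i]
  )
}
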