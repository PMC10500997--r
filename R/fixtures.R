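#' Idealized helical anchor template
#'
#' Generates the anchor points of a regular helix, emulating the periodic
#' NMR-derived heparin geometry used as a starting template: anchor `k` sits
#' at angle `k * twist` on a cylinder of the given radius, raised by `rise`
#' per residue.  All virtual-bond lengths are equal by construction and the
#' internal coordinates are periodic with period one in the residue index.
#' With `twist = 0` and `radius = 0` the helix degenerates to a straight
#' chain of spacing `rise`.
#'
#' The default rise of 5 Angstrom per residue gives a dp12 contour length of
#' 60 Angstrom at full extension - a fixture convention matching the scale of
#' experimental end-to-end distances, not a claim about true heparin geometry.
#'
#' @param dp Number of residues (`>= 2`); the template has `dp + 1` anchors.
#' @param rise Rise per residue along the helix axis, Angstrom (> 0).
#' @param twist Twist per residue, degrees.
#' @param radius Helix radius, Angstrom.
#' @return A numeric `(dp + 1) x 3` anchor matrix suitable as the `template`
#'   argument of [build_chain()].
#' @export
#' @examples
#' tpl <- make_helix_template(12, rise = 4, twist = 180, radius = 1)
#' ch <- build_chain(12, cg_params(), template = tpl)
make_helix_template <- function(dp, rise = 5.0, twist = 60, radius = 2.0) {
  if (!is.numeric(dp) || dp != round(dp) || dp < 2) stop("dp must be an integer >= 2")
  if (rise <= 0) stop("rise must be > 0")
  k <- 0:dp
  phi <- k * twist * pi / 180
  cbind(radius * cos(phi), radius * sin(phi), k * rise)
}

#' Toy two-site geometry for energy-term oracles
#'
#' Builds a fully explicit pair of interaction sites (head, tail and
#' orientation for each) in a controlled mutual arrangement, bypassing chain
#' construction.  Used to exercise individual energy terms at hand-computable
#' geometries.
#'
#' @param r Center-center separation along +x, Angstrom.
#' @param arrangement `"side"` (both site axes +z, perpendicular to the
#'   separation: the side-to-side approach), `"end"` (both axes +x, along the
#'   separation: end-to-end), or `"random"` (axes drawn uniformly on the
#'   sphere from `seed`).
#' @param head_offset,tail_offset Signed displacements of head and tail from
#'   the site center along the site axis, Angstrom.
#' @param charges Length-2 site charges, e.
#' @param seed RNG seed for `arrangement = "random"`.
#' @return A list with `center`, `head`, `tail`, `axis` (each a 2 x 3 matrix,
#'   rows = sites) and `charges`.
#' @export
make_toy_dimer <- function(r = 6, arrangement = c("side", "end", "random"),
                           head_offset = 1, tail_offset = -1,
                           charges = c(-2, -2), seed = 1) {
  arrangement <- match.arg(arrangement)
  centers <- rbind(c(0, 0, 0), c(r, 0, 0))
  axes <- switch(arrangement,
    side = rbind(c(0, 0, 1), c(0, 0, 1)),
    end  = rbind(c(1, 0, 0), c(1, 0, 0)),
    random = {
      set.seed(seed)
      v <- matrix(stats::rnorm(6), 2, 3)
      v / sqrt(rowSums(v^2))
    })
  list(center = centers,
       head = centers + head_offset * axes,
       tail = centers + tail_offset * axes,
       axis = axes,
       charges = charges)
}
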