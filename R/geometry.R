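# Backbone geometry primitives ------------------------------------------

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(x) sqrt(sum(x^2))

unitv <- function(x) {
  n <- vnorm(x)
  if (n < 1e-10) stop("degenerate zero-length vector in geometry construction")
  x / n
}

#' Place an atom from internal coordinates
#'
#' Natural-extension-reference-frame (NeRF) placement: returns the position
#' `d` such that `|d - c| = bond`, the angle b-c-d equals `angle`, and the
#' torsion a-b-c-d equals `torsion`.
#'
#' @param a,b,c Reference 3-vectors (Angstrom).
#' @param bond Bond length c-d in Angstrom.
#' @param angle Planar angle b-c-d in radians.
#' @param torsion Dihedral a-b-c-d in radians.
#' @return A 3-vector.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  bc <- unitv(c - b)
  ab <- b - a
  n_vec <- cross3(ab, bc)
  if (vnorm(n_vec) < 1e-8) stop("collinear reference atoms in internal-coordinate placement")
  n_hat <- unitv(n_vec)
  m_hat <- cross3(n_hat, bc)
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(torsion),
          bond * sin(angle) * sin(torsion))
  c + d2[1] * bc + d2[2] * m_hat + d2[3] * n_hat
}

#' Ideal virtual C-beta position from backbone atoms
#'
#' Constructs the tetrahedral C-beta position implied by the N, CA and C
#' atoms of a residue, used so that glycine (and residues with missing side
#' chains) still contributes a C-beta to the inter-residue distance block of
#' the edge features. The construction is equivariant: rigidly transforming
#' the three inputs transforms the output identically.
#'
#' @param n,ca,c Backbone N, C-alpha and C coordinates (3-vectors, Angstrom).
#' @return A 3-vector: the virtual C-beta position (`|CB - CA|` close to 1.53).
#' @examples
#' cb <- virtual_cbeta(c(1.46, 0, 0), c(0, 0, 0), c(-0.55, 1.42, 0))
#' sqrt(sum((cb - c(0, 0, 0))^2)) # ~1.53
#' @export
virtual_cbeta <- function(n, ca, c) {
  stopifnot(length(n) == 3, length(ca) == 3, length(c) == 3)
  b <- ca - n
  cc <- c - ca
  a <- cross3(b, cc)
  if (vnorm(a) < 1e-6) {
    stop("backbone atoms are collinear; cannot construct a virtual C-beta")
  }
  # Ideal-geometry linear combination in the local (N, CA, C) frame.
  ca + (-0.58273431) * a + 0.56802827 * b + (-0.54067466) * cc
}

# Orthonormal local frame from backbone (N, CA, C): rows are the axes.
# e1 along CA->C, e2 the in-plane component of CA->N, e3 completing the
# right-handed set. Errors on (near-)collinear input.
local_frame <- function(n, ca, c) {
  e1 <- unitv(c - ca)
  u <- n - ca
  u_perp <- u - sum(u * e1) * e1
  if (vnorm(u_perp) < 1e-8) stop("collinear backbone atoms; local frame undefined")
  e2 <- unitv(u_perp)
  e3 <- cross3(e1, e2)
  rbind(e1, e2, e3)
}

# Reconstruct a missing carbonyl O. With the next residue's N available the
# C=O bond points opposite the bisector of C->N(next) and C->CA; otherwise
# the O is placed anti-periplanar to N via internal coordinates.
reconstruct_oxygen <- function(n, ca, c, n_next = NULL) {
  if (!is.null(n_next)) {
    d <- -(unitv(n_next - c) + unitv(ca - c))
    c + 1.231 * unitv(d)
  } else {
    place_atom(n, ca, c, bond = 1.231, angle = 120.8 * pi / 180, torsion = pi)
  }
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation.
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(x, rot, trans) {
  sweep(x %*% t(rot), 2, trans, "+")
}
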