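#' Radius of two equal children under generalized area-preserving branching
#'
#' When a bough of radius `parent` splits into two equal children, the
#' radius scaling relation r_a^alpha + r_b^alpha = r_c^alpha forces each
#' child to have radius `parent * 2^(-1/alpha)`.  At `alpha = 1` diameters
#' simply halve; at `alpha = 2` (da Vinci's rule, preserved cross-sectional
#' area) the factor is `1/sqrt(2)`; at `alpha = 3` (Murray's law) it is the
#' cube-root factor `2^(-1/3)` of the classical "doubling the cube" problem.
#'
#' Radii and diameters are interchangeable everywhere in this package: the
#' scaling relation is homogeneous, so the factor 2 cancels.
#'
#' @param parent Parent branch radius (or diameter), positive.
#' @param alpha Radius scaling exponent, positive.
#' @return The common child radius, in the units of `parent`.
#' @seealso [complete_triplet()] for unequal children.
#' @examples
#' symmetric_child_radius(1, 2)   # 1/sqrt(2)
#' symmetric_child_radius(10, 1)  # diameters sum: 5
#' @export
symmetric_child_radius <- function(parent, alpha) {
  check_positive(parent, "parent")
  check_positive(alpha, "alpha")
  parent * 2^(-1 / alpha)
}

#' Solve branch proportions for two children of given ratio
#'
#' The scaling relation r_a^alpha + r_b^alpha = r_c^alpha is one equation in
#' three radii: it pins down all three proportions only once the ratio
#' a:b between the two children is fixed.  Given the parent radius, the
#' child ratio and alpha, the children are recovered in closed form:
#' `child_b = parent * (1 + ratio^alpha)^(-1/alpha)`, `child_a = ratio * child_b`.
#'
#' @param parent Parent branch radius, positive.
#' @param ratio Ratio of child a to child b, positive.
#' @param alpha Radius scaling exponent, positive.
#' @return Named numeric vector `c(child_a, child_b)` satisfying the
#'   scaling relation exactly (to floating point).
#' @examples
#' complete_triplet(5, 0.75, 2)  # the 3-4-5 right triangle
#' complete_triplet(2, 1, 1)     # diameters sum: two children of 1
#' @export
complete_triplet <- function(parent, ratio, alpha) {
  check_positive(parent, "parent")
  check_positive(ratio, "ratio")
  check_positive(alpha, "alpha")
  child_b <- parent * (1 + ratio^alpha)^(-1 / alpha)
  c(child_a = ratio * child_b, child_b = child_b)
}

#' Approximate number of branches of a given radius
#'
#' Counting branches along transects that bisect a self-similar tree gives
#' n = (r0 / r)^alpha branches of radius approximately r, where r0 is the
#' trunk radius.  At alpha = 2 a 10-fold contrast in radius implies roughly
#' 100 branches; doubling the resolving power reveals 2^alpha times more
#' branches.  Exact for ideal symmetric trees, approximate otherwise.
#'
#' @param trunk_radius Radius of the main stem, positive.
#' @param radius Branch radius of interest, positive and at most
#'   `trunk_radius`.
#' @param alpha Radius scaling exponent, positive.
#' @return The (generally non-integer) predicted branch count.
#' @examples
#' branch_count(10, 1, 2)  # 100
#' @export
branch_count <- function(trunk_radius, radius, alpha) {
  check_positive(trunk_radius, "trunk_radius")
  check_positive(radius, "radius")
  check_positive(alpha, "alpha")
  if (radius > trunk_radius) {
    stop("`radius` must not exceed `trunk_radius` (branches are no thicker than the trunk)",
         call. = FALSE)
  }
  (trunk_radius / radius)^alpha
}

#' Check conservation of r^alpha across every transect of a tree
#'
#' In a tree whose radii obey r_a^alpha + r_b^alpha = r_c^alpha at every
#' ramification, the sum of r^alpha over any transect -- a cut separating
#' all leaves from the root exactly once -- equals r0^alpha for the trunk.
#' This function enumerates one transect per tree depth: at depth g the
#' transect holds every branch of generation g together with every terminal
#' branch of smaller generation (carried through, since an unbranched limb
#' crosses all deeper transects).  It returns the maximum over depths of
#' the relative deviation `|sum(r_i^alpha) - r0^alpha| / r0^alpha`.
#'
#' A tree generated by [generate_tree()] passes at its generating alpha to
#' floating-point accuracy; checking it at any other exponent reveals a
#' positive deviation as soon as one ramification is asymmetric.
#'
#' @param tree A `branch_tree` as returned by [generate_tree()].
#' @param alpha Exponent at which to test conservation.
#' @return Largest relative deviation over all depth transects
#'   (non-negative scalar; 0 for a single unbranched trunk).
#' @export
check_flow_conservation <- function(tree, alpha) {
  stopifnot(inherits(tree, "branch_tree"))
  check_positive(alpha, "alpha")
  b <- tree$branches
  if (nrow(b) == 0L) stop("tree has no branches", call. = FALSE)
  r0a <- b$radius[is.na(b$parent_id)]^alpha
  is_terminal <- !(b$id %in% b$parent_id)
  worst <- 0
  for (g in 0:max(b$generation)) {
    on_transect <- b$generation == g | (is_terminal & b$generation < g)
    dev <- abs(sum(b$radius[on_transect]^alpha) - r0a) / r0a
    worst <- max(worst, dev)
  }
  worst
}

# shared argument guard: positive finite scalar
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive finite number", name), call. = FALSE)
  }
  invisible(x)
}
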