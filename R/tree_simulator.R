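#' Generate a random self-similar tree with exact radius scaling
#'
#' Grows a binary tree from a single trunk.  At every ramification an
#' asymmetry ratio `u` (smaller child : larger child) is drawn uniformly on
#' `[asymmetry_low, asymmetry_high]`; the child radii then come from
#' [complete_triplet()] so that `r_a^alpha + r_b^alpha = r_c^alpha` holds
#' exactly, and the child lengths from the same construction with exponent
#' `beta` and the same `u` (slimmer children are also shorter).  A branch
#' whose radius falls below `stop_ratio * trunk_radius` is kept but not
#' subdivided further, so the radius contrast spanned by the tree is
#' roughly `1/stop_ratio`.  Higher `alpha` shrinks radii more gently per
#' ramification and therefore packs exponentially more branches into the
#' same contrast.
#'
#' Child directions are `parent angle +/- (branch_angle + jitter)` with
#' jitter drawn uniformly on `[-angle_jitter, angle_jitter]` per child (the
#' smaller child takes the `+` side).  Random draws are consumed in
#' depth-first, child-a-first order -- at each ramification the ratio `u`,
#' then the two jitters -- so a given `(parameters, seed)` pair always
#' reproduces the identical branch list.  Geometry affects only rendering,
#' never the diameter statistics.
#'
#' @param alpha Radius scaling exponent (> 0).
#' @param beta Length scaling exponent (> 0); defaults to `alpha`.
#' @param stop_ratio Stop subdividing once a branch radius drops below
#'   `stop_ratio * trunk_radius`; in (0, 1).
#' @param asymmetry_low,asymmetry_high Bounds of the uniform draw of the
#'   smaller:larger child ratio; `0 < asymmetry_low <= asymmetry_high <= 1`.
#'   Equal bounds of 1 give a perfectly symmetric tree.
#' @param seed Integer seed; the function leaves the caller's RNG state
#'   untouched.
#' @param trunk_radius,trunk_length Trunk dimensions (arbitrary unit).
#' @param branch_angle Mean half-angle between children, radians.
#' @param angle_jitter Half-width of the uniform angular jitter, radians.
#' @param max_branches Budget guarding against runaway recursion when
#'   `stop_ratio` is very small.
#' @return An object of class `branch_tree`: a list with `branches` (a
#'   data frame with one row per branch: `id`, `parent_id`, `radius`,
#'   `length`, `generation`, `x0`, `y0`, `x1`, `y1`, `angle`) and the
#'   generating parameters.
#' @examples
#' tr <- generate_tree(alpha = 2, seed = 1)
#' nrow(tr$branches)
#' check_flow_conservation(tr, 2)  # ~ 0
#' @export
generate_tree <- function(alpha = 2, beta = alpha, stop_ratio = 0.1,
                          asymmetry_low = 0.6, asymmetry_high = 1,
                          seed = 1L, trunk_radius = 1, trunk_length = 10,
                          branch_angle = 0.35, angle_jitter = 0.15,
                          max_branches = 1e6) {
  check_positive(alpha, "alpha")
  check_positive(beta, "beta")
  if (!is.numeric(stop_ratio) || stop_ratio <= 0 || stop_ratio >= 1) {
    stop("`stop_ratio` must lie in (0, 1)", call. = FALSE)
  }
  if (!(asymmetry_low > 0 && asymmetry_low <= asymmetry_high &&
        asymmetry_high <= 1)) {
    stop("need 0 < asymmetry_low <= asymmetry_high <= 1", call. = FALSE)
  }
  check_positive(trunk_radius, "trunk_radius")
  check_positive(trunk_length, "trunk_length")
  if (branch_angle < 0 || angle_jitter < 0) {
    stop("angles must be non-negative", call. = FALSE)
  }

  rows <- vector("list", 1024L)
  n_rows <- 0L
  add_row <- function(row) {
    n_rows <<- n_rows + 1L
    if (n_rows > length(rows)) length(rows) <<- 2L * n_rows
    rows[[n_rows]] <<- row
  }
  r_min <- stop_ratio * trunk_radius

  with_seed(seed, {
    # stack of branches whose subdivision is pending; child a pushed last
    # so it is processed first (depth-first, child-a-first draw order)
    trunk <- c(id = 1, parent_id = NA, radius = trunk_radius,
               length = trunk_length, generation = 0,
               x0 = 0, y0 = 0, x1 = 0, y1 = trunk_length, angle = pi / 2)
    add_row(trunk)
    stack <- list(trunk)
    next_id <- 2L
    while (length(stack) > 0L) {
      br <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (br[["radius"]] < r_min) next  # kept, not subdivided
      u <- stats::runif(1L, asymmetry_low, asymmetry_high)
      jit_a <- stats::runif(1L, -angle_jitter, angle_jitter)
      jit_b <- stats::runif(1L, -angle_jitter, angle_jitter)
      rad <- complete_triplet(br[["radius"]], u, alpha)
      len <- complete_triplet(br[["length"]], u, beta)
      ang <- c(br[["angle"]] + branch_angle + jit_a,
               br[["angle"]] - branch_angle - jit_b)
      kids <- vector("list", 2L)
      for (j in 1:2) {
        kids[[j]] <- c(id = next_id, parent_id = br[["id"]],
                       radius = rad[[j]], length = len[[j]],
                       generation = br[["generation"]] + 1,
                       x0 = br[["x1"]], y0 = br[["y1"]],
                       x1 = br[["x1"]] + len[[j]] * cos(ang[j]),
                       y1 = br[["y1"]] + len[[j]] * sin(ang[j]),
                       angle = ang[j])
        add_row(kids[[j]])
        next_id <- next_id + 1L
      }
      if (n_rows > max_branches) {
        stop(sprintf("branch budget exceeded (%d branches); increase `stop_ratio` or `max_branches`",
                     as.integer(max_branches)), call. = FALSE)
      }
      stack[[length(stack) + 1L]] <- kids[[2L]]
      stack[[length(stack) + 1L]] <- kids[[1L]]
    }
  })

  branches <- as.data.frame(do.call(rbind, rows[seq_len(n_rows)]))
  branches$id <- as.integer(branches$id)
  branches$parent_id <- as.integer(branches$parent_id)
  branches$generation <- as.integer(branches$generation)
  structure(list(branches = branches, trunk_radius = trunk_radius,
                 trunk_length = trunk_length, alpha = alpha, beta = beta,
                 stop_ratio = stop_ratio,
                 asymmetry = c(asymmetry_low, asymmetry_high),
                 branch_angle = branch_angle, angle_jitter = angle_jitter,
                 seed = seed),
            class = "branch_tree")
}

#' @export
print.branch_tree <- function(x, ...) {
  b <- x$branches
  n_term <- sum(!(b$id %in% b$parent_id))
  cat(sprintf(paste0("Self-similar branching tree: %d branches ",
                     "(%d terminal), %d generations\n"),
              nrow(b), n_term, max(b$generation)))
  cat(sprintf("  alpha = %g, beta = %g, stop_ratio = %g, asymmetry in [%g, %g], seed = %d\n",
              x$alpha, x$beta, x$stop_ratio, x$asymmetry[1], x$asymmetry[2],
              as.integer(x$seed)))
  cat(sprintf("  radius range %.4g .. %.4g (contrast %.3g-fold)\n",
              min(b$radius), max(b$radius), max(b$radius) / min(b$radius)))
  invisible(x)
}

#' Construct a bag of branch diameters
#'
#' A flat list of branch diameters with unit and provenance labels.  The
#' topology of the source tree is deliberately not recorded: counting the
#' number of branches at each magnitude of diameter estimates alpha far
#' more robustly than solving the scaling relation at individual branch
#' points, so only the diameters themselves are kept.
#'
#' @param diameters Numeric vector of positive diameters.
#' @param unit Unit string (e.g. `"cm"`, or `"user"` for unconverted
#'   annotation units).
#' @param source_label Free-text provenance (file name, artwork, simulation).
#' @param replicate_tag Observer or replicate identifier.
#' @return An object of class `diameter_sample`.
#' @export
diameter_sample <- function(diameters, unit = "user", source_label = "",
                            replicate_tag = "") {
  diameters <- as.numeric(diameters)
  if (length(diameters) == 0L) stop("empty diameter sample", call. = FALSE)
  if (any(!is.finite(diameters)) || any(diameters <= 0)) {
    stop("all diameters must be positive and finite", call. = FALSE)
  }
  structure(list(diameters = diameters, unit = unit,
                 source_label = source_label, replicate_tag = replicate_tag),
            class = "diameter_sample")
}

#' @export
print.diameter_sample <- function(x, ...) {
  cat(sprintf("Diameter sample: %d branches [%s]%s%s\n",
              length(x$diameters), x$unit,
              if (nzchar(x$source_label)) paste0(", ", x$source_label) else "",
              if (nzchar(x$replicate_tag)) paste0(" (", x$replicate_tag, ")") else ""))
  cat(sprintf("  range %.4g .. %.4g, median %.4g\n",
              min(x$diameters), max(x$diameters),
              stats::median(x$diameters)))
  invisible(x)
}

#' Draw diameters from the power-law model assumed by the estimator
#'
#' Samples `n` diameters with tail distribution
#' `P(d >= x) = (xm / x)^alpha` for `x >= xm` by inverse transform,
#' `d = xm * U^(-1/alpha)` with `U ~ Uniform(0, 1]`.  This is the
#' continuous Pareto model implied for a randomly selected branch of a
#' self-similar tree, and the ground truth for estimator recovery tests.
#'
#' @param alpha Tail (cumulative-distribution) exponent, > 0.
#' @param xm Lower cutoff, > 0; every draw is at least `xm`.
#' @param n Number of draws, >= 1.
#' @param seed Integer seed; caller's RNG state is preserved.
#' @param source_label,replicate_tag Passed to [diameter_sample()].
#' @return A [diameter_sample()].
#' @examples
#' s <- sample_diameters(2, 1, 1000, seed = 7)
#' mean(s$diameters >= 2)  # ~ (1/2)^2 = 0.25
#' @export
sample_diameters <- function(alpha, xm, n, seed = 1L,
                             source_label = "pareto simulation",
                             replicate_tag = "") {
  check_positive(alpha, "alpha")
  check_positive(xm, "xm")
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be at least 1", call. = FALSE)
  }
  d <- with_seed(seed, xm * stats::runif(as.integer(n))^(-1 / alpha))
  diameter_sample(d, unit = "user", source_label = source_label,
                  replicate_tag = replicate_tag)
}

#' Extract branch diameters from a generated tree
#'
#' Emits one diameter (twice the radius) per branch, optionally perturbed
#' by independent lognormal measurement noise with median 1 and coefficient
#' of variation `noise_cv`, emulating the scatter of hand annotation.
#'
#' @param tree A `branch_tree`.
#' @param noise_cv Coefficient of variation of the multiplicative noise;
#'   0 returns exact diameters.
#' @param seed Integer seed for the noise draws.
#' @return A [diameter_sample()] in the tree's units.
#' @export
tree_to_diameters <- function(tree, noise_cv = 0, seed = 1L) {
  stopifnot(inherits(tree, "branch_tree"))
  if (!is.numeric(noise_cv) || noise_cv < 0) {
    stop("`noise_cv` must be non-negative", call. = FALSE)
  }
  d <- 2 * tree$branches$radius
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    d <- d * with_seed(seed, stats::rlnorm(length(d), meanlog = 0, sdlog = sdlog))
  }
  diameter_sample(d, unit = "user",
                  source_label = sprintf("simulated tree (alpha = %g, seed = %d)",
                                         tree$alpha, as.integer(tree$seed)),
                  replicate_tag = if (noise_cv > 0)
                    sprintf("noise_cv = %g, seed = %d", noise_cv, as.integer(seed))
                  else "exact")
}

# evaluate expr under a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
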