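# Independent oracles used to cross-check closed-form results.

# maximise the binned log-likelihood by brute-force grid search over alpha
# (geometric-in-bin-index model); independent of the closed-form estimate
grid_search_alpha <- function(counts, lambda, step = 1e-4, upper = 10) {
  kv <- as.integer(names(counts))
  n <- sum(counts)
  s <- sum(kv * counts)
  grid <- seq(step, upper, by = step)
  ll <- n * log(1 - lambda^(-grid)) - grid * log(lambda) * s
  grid[which.max(ll)]
}

# bracketing root-finder for the child-proportion equation
# g(x) = (ratio*x)^alpha + x^alpha - parent^alpha, solved for x = child_b
root_find_child_b <- function(parent, ratio, alpha) {
  g <- function(x) (ratio * x)^alpha + x^alpha - parent^alpha
  stats::uniroot(g, lower = 1e-12, upper = parent, tol = 1e-12)$root
}

# build a minimal branch_tree by hand (bypasses the generator)
manual_tree <- function(radius, parent_id, generation, length = radius * 5) {
  n <- length(radius)
  structure(list(
    branches = data.frame(
      id = seq_len(n), parent_id = parent_id, radius = radius,
      length = length, generation = generation,
      x0 = 0, y0 = 0, x1 = 0, y1 = length, angle = pi / 2),
    trunk_radius = radius[1], trunk_length = length[1],
    alpha = NA_real_, beta = NA_real_, stop_ratio = NA_real_,
    asymmetry = c(1, 1), branch_angle = 0, angle_jitter = 0, seed = 0L),
    class = "branch_tree")
}

# write a throwaway SVG document and return its path
temp_svg <- function(...) {
  path <- withr::local_tempfile(fileext = ".svg",
                                .local_envir = parent.frame())
  writeLines(c('<svg xmlns="http://www.w3.org/2000/svg" xmlns:inkscape="http://www.inkscape.org/namespaces/inkscape">',
               ..., "</svg>"), path)
  path
}

# empirical Kolmogorov-Smirnov distance to the Pareto tail (xm/x)^alpha
ks_to_pareto <- function(d, alpha, xm) {
  d <- sort(d)
  emp_hi <- seq_along(d) / length(d)
  emp_lo <- (seq_along(d) - 1) / length(d)
  theo <- 1 - (xm / d)^alpha
  max(pmax(abs(emp_hi - theo), abs(emp_lo - theo)))
}

# pareto sample with small branches censored in proportion to (d/2)^3,
# emulating an annotator increasingly omitting thin strokes
with_censored_sample <- function() {
  set.seed(9)
  d <- 0.25 * stats::runif(50000)^(-1 / 2)
  diameter_sample(d[stats::runif(50000) < pmin(1, (d / 2)^3)])
}
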