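#' Run the full per-work scaling analysis on one diameter sample
#'
#' The canonical per-replicate workflow: log-bin the diameters above the
#' cutoff, fit the tail exponent by maximum likelihood, bootstrap a
#' confidence interval, compute the tail curve, and run the cutoff
#' diagnostic.  Everything random flows from the single `seed`, so a
#' report is regenerable bit-identically from (sample, settings, seed).
#'
#' @param sample A [diameter_sample()].
#' @param xm Lower diameter cutoff for this dataset (same unit as the
#'   sample).  Chosen per work by inspecting the tail curve; see
#'   [choose_xm()] for a non-canonical automatic scan.
#' @param lambda Log-bin base (default 2).
#' @param n_boot,level Bootstrap resamples and CI level.
#' @param seed Integer seed for the bootstrap.
#' @param normalize Logical; if TRUE the exported tail curve divides
#'   diameters by `xm`, making the horizontal axis unitless for
#'   cross-dataset overlays.
#' @return Object of class `scaling_report`: list with `fit`
#'   (a `powerlaw_fit` with CI), `tail` (a [tail_curve()] data frame),
#'   `diagnostic` ([threshold_diagnostic()] output), `settings`, and
#'   provenance (`source_label`, `replicate_tag`, `n_total`).
#' @examples
#' s <- sample_diameters(2, 1, 500, seed = 11)
#' analyze_sample(s, xm = 1, n_boot = 1000, seed = 11)
#' @export
analyze_sample <- function(sample, xm, lambda = 2, n_boot = 10000L,
                           level = 0.95, seed = 1L, normalize = FALSE) {
  stopifnot(inherits(sample, "diameter_sample"))
  fit <- fit_powerlaw(sample, xm, lambda, ci = TRUE, n_boot = n_boot,
                      seed = seed, level = level)
  tc <- tail_curve(sample)
  if (normalize) tc$diameter <- tc$diameter / xm
  diag <- threshold_diagnostic(sample, fit)
  structure(list(fit = fit, tail = tc, diagnostic = diag,
                 settings = list(xm = xm, lambda = lambda, n_boot = n_boot,
                                 level = level, seed = as.integer(seed),
                                 normalize = normalize),
                 source_label = sample$source_label,
                 replicate_tag = sample$replicate_tag,
                 unit = sample$unit,
                 n_total = length(sample$diameters)),
            class = "scaling_report")
}

#' @export
print.scaling_report <- function(x, ...) {
  cat(sprintf("Scaling analysis of %s%s (n = %d, unit %s)\n",
              x$source_label,
              if (nzchar(x$replicate_tag)) paste0(" [", x$replicate_tag, "]") else "",
              x$n_total, x$unit))
  print(x$fit)
  if (isTRUE(x$diagnostic$available)) {
    cat(sprintf("  cutoff diagnostic: local tail slope %.3f vs -alpha %.3f -> %s\n",
                x$diagnostic$local_slope, -x$fit$alpha_hat,
                if (x$diagnostic$flag) "FLAGGED (xm may be too low)" else "ok"))
  } else {
    cat("  cutoff diagnostic: unavailable (< 3 distinct diameters in first bin)\n")
  }
  invisible(x)
}

#' Write a scaling report to disk
#'
#' Emits a machine-readable JSON summary plus a CSV of the tail curve, so
#' plots can be regenerated with any backend.  File names are prefixed by
#' `stem`.
#'
#' @param report A `scaling_report` from [analyze_sample()].
#' @param dir Output directory (created if needed).
#' @param stem File-name stem, default derived from the source label.
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir, stem = NULL) {
  stopifnot(inherits(report, "scaling_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- stem %||% gsub("[^A-Za-z0-9._-]+", "_",
                         paste0(report$source_label,
                                if (nzchar(report$replicate_tag))
                                  paste0("_", report$replicate_tag) else ""))
  fit <- report$fit
  json_path <- file.path(dir, paste0(stem, "_fit.json"))
  jsonlite::write_json(list(
    source = report$source_label, replicate = report$replicate_tag,
    unit = report$unit, n_total = report$n_total,
    alpha_hat = fit$alpha_hat,
    ci = list(lower = fit$ci[["lower"]], upper = fit$ci[["upper"]],
              level = fit$ci_level),
    xm = fit$xm, lambda = fit$lambda,
    n_used = fit$n_used, n_excluded_below_xm = fit$n_excluded,
    log_likelihood = fit$log_likelihood,
    n_degenerate_redrawn = fit$n_degenerate_redrawn %||% 0L,
    diagnostic = report$diagnostic[c("available", "flag", "local_slope",
                                     "ratio_dev")],
    settings = report$settings,
    package_version = as.character(utils::packageVersion("branchscale"))
  ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  tail_path <- file.path(dir, paste0(stem, "_tail.csv"))
  utils::write.csv(report$tail, tail_path, row.names = FALSE)
  invisible(c(fit = json_path, tail = tail_path))
}

#' Simulate a tree and write all its artefacts
#'
#' Generates one tree with [generate_tree()] and writes: the branch table
#' (`<stem>_tree.csv`), a rendered SVG (`<stem>.svg`, one stroke per
#' branch with round caps and width equal to the branch diameter), a
#' binary raster in plain-text PGM (`<stem>.pgm`), and the diameter list
#' (`<stem>_diameters.csv`).  Deterministic under the seed: repeated runs
#' produce byte-identical files.
#'
#' @param dir Output directory.
#' @param stem File-name stem, default `"tree"`.
#' @param size Raster side (power of two).
#' @param ... Passed to [generate_tree()] (alpha, beta, stop_ratio, seed, ...).
#' @return Named character vector of the files written, invisibly.
#' @export
simulate_tree_files <- function(dir, stem = "tree", size = 256L, ...) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tree <- generate_tree(...)
  paths <- c(tree = file.path(dir, paste0(stem, "_tree.csv")),
             svg = file.path(dir, paste0(stem, ".svg")),
             raster = file.path(dir, paste0(stem, ".pgm")),
             diameters = file.path(dir, paste0(stem, "_diameters.csv")))
  utils::write.csv(tree$branches, paths[["tree"]], row.names = FALSE)
  write_tree_svg(tree, paths[["svg"]])
  write_pgm(rasterize_tree(tree, size = size), paths[["raster"]])
  write_csv_diameters(tree_to_diameters(tree), paths[["diameters"]])
  invisible(paths)
}

#' Render a tree as an SVG drawing
#'
#' One `<line>` per branch, stroke width equal to the branch diameter,
#' round line caps; y axis flipped so the tree grows upward.
#'
#' @param tree A `branch_tree`.
#' @param path Output file.
#' @param canvas Canvas side in user units (default 512).
#' @param margin Blank margin fraction per edge.
#' @return `path`, invisibly.
#' @export
write_tree_svg <- function(tree, path, canvas = 512, margin = 0.05) {
  stopifnot(inherits(tree, "branch_tree"))
  b <- tree$branches
  xlim <- range(c(b$x0 - b$radius, b$x0 + b$radius, b$x1 - b$radius, b$x1 + b$radius))
  ylim <- range(c(b$y0 - b$radius, b$y0 + b$radius, b$y1 - b$radius, b$y1 + b$radius))
  span <- max(xlim[2] - xlim[1], ylim[2] - ylim[1])
  sc <- (1 - 2 * margin) * canvas / span
  ox <- (canvas - sc * (xlim[2] - xlim[1])) / 2 - sc * xlim[1]
  oy <- (canvas - sc * (ylim[2] - ylim[1])) / 2 - sc * ylim[1]
  fx <- function(x) sc * x + ox
  fy <- function(y) canvas - (sc * y + oy)  # SVG y grows downward
  lines <- sprintf(
    '  <line x1="%.4f" y1="%.4f" x2="%.4f" y2="%.4f" stroke-width="%.4f"/>',
    fx(b$x0), fy(b$y0), fx(b$x1), fy(b$y1), 2 * sc * b$radius)
  writeLines(c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
                       as.integer(canvas), as.integer(canvas),
                       as.integer(canvas), as.integer(canvas)),
               ' <g stroke="black" stroke-linecap="round" fill="none">',
               lines, ' </g>', '</svg>'), path)
  invisible(path)
}

#' Write a binary image as plain-text PGM
#'
#' Plain (ASCII, `P2`) PGM with maxval 1: occupied pixels are 1 (ink),
#' empty pixels 0.  Row 1 of the file is the top of the image.
#'
#' @param image A [binary_image()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path) {
  stopifnot(inherits(image, "binary_image"))
  m <- image$occupancy[image$size:1, , drop = FALSE]  # top row first
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", image$size, image$size), "1"), con)
  writeLines(apply(m, 1L, function(r) paste(as.integer(r), collapse = " ")), con)
  invisible(path)
}

#' Read a plain-text PGM/PBM file as a binary image
#'
#' Accepts plain `P1` (bitmap) and `P2` (graymap) files; any gray value
#' above half the maxval counts as occupied in `P2`, and `1` is ink in
#' `P1` as usual.
#'
#' @param path File path.
#' @return A [binary_image()].
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  magic <- toks[1]
  if (!magic %in% c("P1", "P2")) {
    stop(sprintf("'%s' is not a plain P1/P2 PGM file", path), call. = FALSE)
  }
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  if (magic == "P2") {
    maxval <- as.numeric(toks[4])
    vals <- as.numeric(toks[-(1:4)]) > maxval / 2
  } else {
    vals <- as.numeric(toks[-(1:3)]) == 1
  }
  if (length(vals) != w * h) stop("PGM pixel count mismatch", call. = FALSE)
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  binary_image(m[h:1, , drop = FALSE])  # back to row 1 = bottom
}
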