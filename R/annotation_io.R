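#' Read branch-diameter annotations from an SVG overlay
#'
#' Morphometric annotation of artwork or photographs is done by overlaying
#' straight line segments, each drawn perpendicular to a branch so that its
#' length records the branch diameter.  This reader extracts every straight
#' segment -- native `<line>` elements and two-point `<path>` elements in
#' absolute (`M ... L ...`) or relative (`m ... l ...`) coordinates,
#' including implicit line-to pairs -- composes all ancestor and element
#' `transform` attributes (matrix, translate, scale, rotate, skewX, skewY),
#' and returns the Euclidean lengths of the transformed segments as
#' diameters.  Curved paths are not diameter marks and are skipped with a
#' reported count; zero-length segments are excluded with a warning naming
#' the element.
#'
#' Lengths are scale-free for exponent estimation (any constant unit factor
#' cancels from the scaling relations), so by default they are reported in
#' SVG user units.  If `scale` is given, lengths are multiplied by it; if
#' it is absent but the document declares a physical width (e.g.
#' `width="21cm"`) together with a `viewBox`, a user-unit-to-physical
#' factor is derived from those.
#'
#' @param path Path to an SVG file.
#' @param layer Optional id or label of a group: only segments inside a
#'   group whose `id` or `inkscape:label` equals `layer` are read, letting
#'   one file carry several observer replicates.
#' @param scale Optional multiplier from user units to physical units.
#' @param unit Unit string attached to the output when `scale` is supplied
#'   (default `"cm"`); ignored otherwise.
#' @param replicate_tag Replicate label stored on the sample (defaults to
#'   `layer` when given).
#' @return A [diameter_sample()].  The number of curved elements skipped
#'   is attached as attribute `"n_curves_skipped"`.
#' @examples
#' svg <- tempfile(fileext = ".svg")
#' writeLines(c('<svg xmlns="http://www.w3.org/2000/svg">',
#'              '<line x1="0" y1="0" x2="3" y2="4"/>', '</svg>'), svg)
#' read_svg_annotations(svg)$diameters  # 5
#' @export
read_svg_annotations <- function(path, layer = NULL, scale = NULL,
                                 unit = "cm", replicate_tag = NULL) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop(sprintf("cannot parse '%s' as SVG: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  root <- xml2::xml_root(doc)

  segs <- list()   # each: c(x1, y1, x2, y2) after transforms
  ids <- character()
  n_curves <- 0L

  nodes <- xml2::xml_find_all(doc, ".//*[local-name()='line' or local-name()='path' or local-name()='polyline']")
  for (node in nodes) {
    if (!is.null(layer) && !node_in_layer(node, layer)) next
    nm <- xml2::xml_name(node)
    pts <- switch(nm,
                  line = line_points(node),
                  path = path_points(node),
                  polyline = polyline_points(node))
    if (is.null(pts)) { n_curves <- n_curves + 1L; next }
    m <- node_transform(node, root)
    p1 <- m %*% c(pts[1], pts[2], 1)
    p2 <- m %*% c(pts[3], pts[4], 1)
    segs[[length(segs) + 1L]] <- c(p1[1], p1[2], p2[1], p2[2])
    id <- xml2::xml_attr(node, "id")
    ids <- c(ids, if (is.na(id)) sprintf("<%s #%d>", nm, length(segs)) else id)
  }
  if (length(segs) == 0L) {
    stop(sprintf("no line-segment annotations found in '%s'%s", path,
                 if (is.null(layer)) "" else sprintf(" (layer '%s')", layer)),
         call. = FALSE)
  }
  seg_mat <- do.call(rbind, segs)
  if (any(!is.finite(seg_mat))) {
    stop("non-finite coordinates in annotation segments", call. = FALSE)
  }
  len <- sqrt((seg_mat[, 3] - seg_mat[, 1])^2 + (seg_mat[, 4] - seg_mat[, 2])^2)
  zero <- len == 0
  if (any(zero)) {
    warning(sprintf("excluded %d zero-length segment(s): %s", sum(zero),
                    paste(ids[zero], collapse = ", ")), call. = FALSE)
    len <- len[!zero]
    if (length(len) == 0L) {
      stop("all annotation segments have zero length", call. = FALSE)
    }
  }
  if (n_curves > 0L) {
    message(sprintf("skipped %d curved/multi-point element(s) (not diameter marks)",
                    n_curves))
  }
  out_unit <- "user"
  if (is.null(scale)) {
    scale <- svg_unit_scale(root)
    if (!is.null(scale)) out_unit <- attr(scale, "unit")
    else scale <- 1
  } else {
    check_positive(scale, "scale")
    out_unit <- unit
  }
  s <- diameter_sample(len * as.numeric(scale), unit = out_unit,
                       source_label = basename(path),
                       replicate_tag = replicate_tag %||%
                         (if (is.null(layer)) "" else layer))
  attr(s, "n_curves_skipped") <- n_curves
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

node_in_layer <- function(node, layer) {
  for (anc in xml2::xml_parents(node)) {
    id <- xml2::xml_attr(anc, "id")
    lab <- xml2::xml_attr(anc, "label")  # matches inkscape:label
    if (identical(id, layer) || identical(lab, layer)) return(TRUE)
  }
  FALSE
}

line_points <- function(node) {
  v <- suppressWarnings(vapply(c("x1", "y1", "x2", "y2"), function(a)
    as.numeric(xml2::xml_attr(node, a)), numeric(1)))
  v[is.na(v)] <- 0  # SVG defaults missing line coordinates to 0
  v
}

polyline_points <- function(node) {
  v <- suppressWarnings(as.numeric(strsplit(
    trimws(xml2::xml_attr(node, "points")), "[ ,\t\n]+")[[1]]))
  if (length(v) != 4L || any(is.na(v))) return(NULL)  # not a two-point mark
  v
}

# two-point paths only: "M x y L x y", "M x,y x,y", "m dx,dy l dx,dy", ...
path_points <- function(node) {
  d <- xml2::xml_attr(node, "d")
  if (is.na(d)) return(NULL)
  toks <- regmatches(d, gregexpr("[MmLlZzHhVvCcSsQqTtAa]|-?[0-9.eE+]+", d))[[1]]
  if (any(toks %in% c("C", "c", "S", "s", "Q", "q", "T", "t", "A", "a"))) {
    return(NULL)  # curve commands: not a diameter mark
  }
  cur <- c(0, 0); start <- NULL; pts <- list(); rel <- FALSE; mode <- ""
  i <- 1L
  num <- function(j) suppressWarnings(as.numeric(toks[j]))
  while (i <= length(toks)) {
    tk <- toks[i]
    if (tk %in% c("M", "m", "L", "l")) {
      mode <- "xy"; rel <- tk %in% c("m", "l"); i <- i + 1L
    } else if (tk %in% c("H", "h", "V", "v")) {
      mode <- tolower(tk); rel <- tk %in% c("h", "v"); i <- i + 1L
    } else if (tk %in% c("Z", "z")) {
      i <- i + 1L  # closing a 2-point path adds no new point
    } else {
      if (mode == "xy") {
        p <- c(num(i), num(i + 1L)); i <- i + 2L
        if (rel && length(pts) > 0L) p <- cur + p
      } else if (mode == "h") {
        p <- c(if (rel) cur[1] + num(i) else num(i), cur[2]); i <- i + 1L
      } else if (mode == "v") {
        p <- c(cur[1], if (rel) cur[2] + num(i) else num(i)); i <- i + 1L
      } else {
        return(NULL)
      }
      if (any(is.na(p))) return(NULL)
      cur <- p
      pts[[length(pts) + 1L]] <- p
      if (length(pts) > 2L) return(NULL)  # more than two points: not a mark
    }
  }
  if (length(pts) != 2L) return(NULL)
  c(pts[[1]], pts[[2]])
}

# composed affine transform (3x3) from root down to and including node
node_transform <- function(node, root) {
  chain <- rev(xml2::xml_parents(node))
  m <- diag(3)
  for (anc in chain) m <- m %*% parse_transform(xml2::xml_attr(anc, "transform"))
  m %*% parse_transform(xml2::xml_attr(node, "transform"))
}

parse_transform <- function(spec) {
  m <- diag(3)
  if (is.na(spec) || !nzchar(trimws(spec))) return(m)
  calls <- regmatches(spec, gregexpr("[a-zA-Z]+\\s*\\([^)]*\\)", spec))[[1]]
  for (cl in calls) {
    fn <- sub("\\s*\\(.*", "", cl)
    args <- suppressWarnings(as.numeric(strsplit(
      gsub(".*\\(|\\)", "", cl), "[ ,\t\n]+")[[1]]))
    args <- args[!is.na(args)]
    t <- switch(fn,
      matrix = if (length(args) == 6)
        rbind(c(args[1], args[3], args[5]),
              c(args[2], args[4], args[6]), c(0, 0, 1)),
      translate = rbind(c(1, 0, args[1]),
                        c(0, 1, if (length(args) > 1) args[2] else 0),
                        c(0, 0, 1)),
      scale = {
        sy <- if (length(args) > 1) args[2] else args[1]
        diag(c(args[1], sy, 1))
      },
      rotate = {
        a <- args[1] * pi / 180
        r <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
        if (length(args) == 3) {
          tr1 <- rbind(c(1, 0, args[2]), c(0, 1, args[3]), c(0, 0, 1))
          tr2 <- rbind(c(1, 0, -args[2]), c(0, 1, -args[3]), c(0, 0, 1))
          tr1 %*% r %*% tr2
        } else r
      },
      skewX = rbind(c(1, tan(args[1] * pi / 180), 0), c(0, 1, 0), c(0, 0, 1)),
      skewY = rbind(c(1, 0, 0), c(tan(args[1] * pi / 180), 1, 0), c(0, 0, 1)),
      NULL)
    if (is.null(t)) {
      stop(sprintf("unsupported or malformed transform '%s'", cl),
           call. = FALSE)
    }
    m <- m %*% t
  }
  m
}

# user-units-per-physical-unit factor from width/viewBox, if declared
svg_unit_scale <- function(root) {
  w <- xml2::xml_attr(root, "width")
  vb <- xml2::xml_attr(root, "viewBox")
  if (is.na(w) || is.na(vb)) return(NULL)
  mt <- regmatches(w, regexec("^\\s*([0-9.eE+-]+)\\s*(cm|mm|in|pt|pc)\\s*$", w))[[1]]
  if (length(mt) != 3L) return(NULL)
  phys <- as.numeric(mt[2])
  # convert declared width to cm
  phys_cm <- phys * switch(mt[3], cm = 1, mm = 0.1, `in` = 2.54,
                           pt = 2.54 / 72, pc = 2.54 / 6)
  vbv <- suppressWarnings(as.numeric(strsplit(trimws(vb), "[ ,]+")[[1]]))
  if (length(vbv) != 4L || any(is.na(vbv)) || vbv[3] <= 0) return(NULL)
  structure(phys_cm / vbv[3], unit = "cm")
}

#' Read a plain-text diameter list
#'
#' Reads one diameter per row from a CSV file with a header row.  Rows
#' with missing, non-numeric or non-positive values are rejected with
#' their row numbers, since a non-positive branch diameter can only be a
#' recording error.
#'
#' @param path CSV file path.
#' @param column Name of the diameter column (default `"diameter"`).
#' @param unit Unit string for the resulting sample.
#' @param source_label,replicate_tag Provenance labels; `source_label`
#'   defaults to the file name.
#' @return A [diameter_sample()].
#' @export
read_csv_diameters <- function(path, column = "diameter", unit = "user",
                               source_label = NULL, replicate_tag = "") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!column %in% names(df)) {
    stop(sprintf("column '%s' not found in '%s' (columns: %s)", column, path,
                 paste(names(df), collapse = ", ")), call. = FALSE)
  }
  raw <- df[[column]]
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(val) | val <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("non-positive or non-numeric diameter(s) in '%s' at data row(s) %s",
                 path, paste(utils::head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
  diameter_sample(val, unit = unit, source_label = source_label %||% basename(path),
                  replicate_tag = replicate_tag)
}

#' Write a diameter sample as CSV
#'
#' One diameter per row under a `diameter` header, at full precision, so
#' a write/read round trip reproduces the sample exactly.
#'
#' @param sample A [diameter_sample()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_csv_diameters <- function(sample, path) {
  stopifnot(inherits(sample, "diameter_sample"))
  df <- data.frame(diameter = format(sample$diameters, digits = 17,
                                     scientific = FALSE, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
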