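#' Neuronal morphology as a table of cylindrical sections
#'
#' A morphology is a tibble of frustum sections forming a tree rooted at a
#' single soma section. The soma is represented by the usual
#' sphere-equivalent cylinder (length = diameter, so the lateral area equals
#' the sphere area). Optional 3D columns (`x0..z1`) carry coordinates for
#' SWC export.
#'
#' @param sections A data frame with columns `id`, `parent_id` (NA for the
#'   root), `parent_pos` (0-1 attachment point along the parent), `length`
#'   (um), `diam_prox`, `diam_dist` (um), `region` (`"soma"` or
#'   `"dendrite"`).
#'
#' @return A tibble of class `neuro_morphology`.
#' @export
morphology <- function(sections) {
  sections <- as_tibble(sections)
  need <- c("id", "parent_id", "parent_pos", "length", "diam_prox", "diam_dist", "region")
  if (!all(need %in% names(sections))) {
    abort(paste("morphology needs columns:", paste(need, collapse = ", ")),
          class = "chloridyn_invalid_parameter")
  }
  root <- which(is.na(sections$parent_id))
  if (length(root) != 1L || sections$region[root] != "soma") {
    abort("morphology must have exactly one root section of region 'soma'",
          class = "chloridyn_invalid_parameter")
  }
  if (any(sections$length <= 0) || any(sections$diam_prox <= 0) ||
      any(sections$diam_dist <= 0)) {
    abort("lengths and diameters must be > 0", class = "chloridyn_build_error")
  }
  if (anyDuplicated(sections$id)) {
    abort("section ids must be unique", class = "chloridyn_invalid_parameter")
  }
  # tree check: every parent exists and walking up terminates at the root
  idx <- match(sections$parent_id, sections$id)
  if (any(is.na(idx[-root]))) {
    abort("parent_id refers to a missing section", class = "chloridyn_invalid_parameter")
  }
  for (i in seq_len(nrow(sections))) {
    seen <- integer()
    j <- i
    while (!is.na(sections$parent_id[j])) {
      if (j %in% seen) abort("morphology contains a cycle", class = "chloridyn_invalid_parameter")
      seen <- c(seen, j)
      j <- match(sections$parent_id[j], sections$id)
    }
  }
  class(sections) <- c("neuro_morphology", class(tibble()))
  sections
}

section_area <- function(length, diam_prox, diam_dist) {
  # lateral frustum area with the slant approximated by the length
  # (consistent with thin, gently tapering neurites)
  pi * (diam_prox + diam_dist) / 2 * length
}

section_volume <- function(length, diam_prox, diam_dist) {
  r1 <- diam_prox / 2; r2 <- diam_dist / 2
  pi * length / 3 * (r1^2 + r1 * r2 + r2^2)
}

#' Membrane area, volume and capacitance of a morphology
#'
#' @param morph A [morphology()].
#' @param cm Specific membrane capacitance, uF/cm^2.
#' @param region Optional region filter (`"soma"`, `"dendrite"`).
#'
#' @return Area in um^2, volume in um^3, capacitance in pF.
#' @export
morphology_area <- function(morph, region = NULL) {
  m <- if (is.null(region)) morph else morph[morph$region == region, ]
  sum(section_area(m$length, m$diam_prox, m$diam_dist))
}

#' @rdname morphology_area
#' @export
morphology_volume <- function(morph, region = NULL) {
  m <- if (is.null(region)) morph else morph[morph$region == region, ]
  sum(section_volume(m$length, m$diam_prox, m$diam_dist))
}

#' @rdname morphology_area
#' @export
morphology_capacitance <- function(morph, cm = 1) {
  0.01 * cm * morphology_area(morph) # pF = 0.01 * uF/cm^2 * um^2
}

#' Read and write SWC morphology files
#'
#' Standard 7-column SWC (`id type x y z radius parent`, space separated,
#' `#` comments, root parent -1). [read_swc()] returns the raw sample table;
#' [swc_to_morphology()] converts it to the section representation, building
#' one section per non-root sample (proximal radius taken from the parent
#' sample). [write_swc()] accepts either a sample table or a morphology with
#' coordinate columns.
#'
#' @param path File path.
#' @param x An SWC sample tibble (`id`, `type`, `x`, `y`, `z`, `radius`,
#'   `parent`) or a `neuro_morphology` with coordinates.
#'
#' @return `read_swc()`: a tibble of SWC samples. `write_swc()`: `path`,
#'   invisibly.
#' @export
read_swc <- function(path) {
  dat <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z", "radius", "parent"))
  as_tibble(dat)
}

#' @rdname read_swc
#' @export
write_swc <- function(x, path) {
  if (inherits(x, "neuro_morphology")) x <- morphology_to_swc(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC morphology (id type x y z radius parent)", con)
  writeLines(sprintf("%d %d %s %s %s %s %d", x$id, x$type,
                     format(x$x, digits = 17, trim = TRUE),
                     format(x$y, digits = 17, trim = TRUE),
                     format(x$z, digits = 17, trim = TRUE),
                     format(x$radius, digits = 17, trim = TRUE),
                     x$parent), con)
  invisible(path)
}

#' @rdname read_swc
#' @export
swc_to_morphology <- function(x) {
  x <- as_tibble(x)
  root <- which(x$parent == -1)
  if (length(root) != 1L) {
    abort("SWC must have exactly one root sample", class = "chloridyn_invalid_parameter")
  }
  soma_id <- x$id[root]
  pidx <- match(x$parent, x$id)
  secs <- purrr::map(which(x$parent != -1), function(i) {
    p <- pidx[i]
    len <- sqrt((x$x[i] - x$x[p])^2 + (x$y[i] - x$y[p])^2 + (x$z[i] - x$z[p])^2)
    dp <- if (x$parent[i] == soma_id) 2 * x$radius[i] else 2 * x$radius[p]
    tibble(id = x$id[i],
           parent_id = x$parent[i],
           parent_pos = 1,
           length = len,
           diam_prox = dp,
           diam_dist = 2 * x$radius[i],
           region = if (x$type[i] == 1) "soma" else "dendrite",
           x0 = x$x[p], y0 = x$y[p], z0 = x$z[p],
           x1 = x$x[i], y1 = x$y[i], z1 = x$z[i])
  })
  soma <- tibble(id = soma_id, parent_id = NA_integer_, parent_pos = NA_real_,
                 length = 2 * x$radius[root], diam_prox = 2 * x$radius[root],
                 diam_dist = 2 * x$radius[root], region = "soma",
                 x0 = x$x[root], y0 = x$y[root], z0 = x$z[root],
                 x1 = x$x[root], y1 = x$y[root], z1 = x$z[root])
  morphology(dplyr::bind_rows(soma, secs))
}

morphology_to_swc <- function(morph) {
  if (!all(c("x0", "x1") %in% names(morph))) {
    abort("morphology has no coordinates; cannot write SWC",
          class = "chloridyn_invalid_parameter")
  }
  root <- which(is.na(morph$parent_id))
  tibble(
    id = c(morph$id[root], morph$id[-root]),
    type = c(1L, ifelse(morph$region[-root] == "soma", 1L, 3L)),
    x = c(morph$x0[root], morph$x1[-root]),
    y = c(morph$y0[root], morph$y1[-root]),
    z = c(morph$z0[root], morph$z1[-root]),
    radius = c(morph$diam_prox[root] / 2, morph$diam_dist[-root] / 2),
    parent = c(-1L, morph$parent_id[-root])
  )
}
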