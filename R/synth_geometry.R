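#' Generate ground-truth geometry for a synthetic muscle field
#'
#' Emulates a transversely cut muscle section: fibre cross-sections are
#' packed convex-ish polygons obtained as multiplicatively weighted Voronoi
#' cells of Poisson-disc seed points, separated by a sarcolemma wall of
#' approximately `wall_thickness_px`. A wall ring of the same thickness runs
#' along the frame edge so every fibre interior is enclosed by membrane.
#' Optional confounder regions (vessels, adipose, connective tissue) are
#' created by converting whole cells to the requested class, never destroying
#' more than 20% of the fibres.
#'
#' The returned label image uses: `0` background, `>= 1` fibre interiors
#' (consecutive labels), `-1` sarcolemma wall, `-2` vessel, `-3` adipose,
#' `-4` connective tissue.
#'
#' @param rows,cols Frame size in pixels.
#' @param n_fibres Number of seeded cells (>= 1).
#' @param wall_thickness_px Typical wall thickness in pixels (>= 1).
#' @param confounder_fracs Optional named numeric vector with entries among
#'   `vessel`, `adipose`, `connective`: target area fraction per class.
#' @param seed Integer seed; identical arguments and seed give a bit-identical
#'   geometry.
#' @param patch_px Arc length (pixels) of the staining-heterogeneity patches
#'   the wall is subdivided into; the renderer draws one intensity per patch,
#'   so this sets the spatial scale of between-ROI variability.
#' @return An object of class `field_geometry` with fields `label_image`,
#'   `wall_mask`, `wall_midline`, `wall_pair`, `wall_tangent`, `fibre_count`,
#'   `wall_thickness_px`, `seeds`, `weights`, `nearest`.
#' @export
generate_geometry <- function(rows = 512L, cols = 512L, n_fibres = 30L,
                              wall_thickness_px = 4L, confounder_fracs = NULL,
                              seed = 1L, patch_px = 8L) {
  if (!is_count(n_fibres, 1) || !is_count(wall_thickness_px, 1))
    stop_dq("n_fibres and wall_thickness_px must be positive integers",
            class = "dq_parameter_error")
  if (n_fibres * (2 * wall_thickness_px + 6)^2 > rows * cols)
    stop_dq("geometry infeasible: too many fibres for the frame",
            class = "dq_parameter_error")
  t <- wall_thickness_px
  with_seed(seed, {
    pts <- poisson_disc(rows, cols, n_fibres, t)
    w <- runif(n_fibres, 0.85, 1.15)

    rowg <- matrix(0:(rows - 1), rows, cols)
    colg <- matrix(0:(cols - 1), rows, cols, byrow = TRUE)
    d1 <- matrix(Inf, rows, cols); d2 <- d1
    i1 <- matrix(0L, rows, cols); i2 <- i1
    for (i in seq_len(n_fibres)) {
      di <- sqrt((rowg - pts[i, 1])^2 + (colg - pts[i, 2])^2) * w[i]
      closer2 <- !(di < d1) & (di < d2)
      d2[closer2] <- di[closer2]; i2[closer2] <- i
      closer1 <- di < d1
      d2[closer1] <- d1[closer1]; i2[closer1] <- i1[closer1]
      d1[closer1] <- di[closer1]; i1[closer1] <- i
    }

    gap <- d2 - d1
    edge_dist <- pmin(rowg, rows - 1 - rowg, colg, cols - 1 - colg)
    ring <- edge_dist < t
    wall_between <- gap < t & !ring

    # confounders: convert whole cells, smallest-area first within a seeded
    # random order, until the requested area fraction is reached
    class_codes <- c(vessel = -2L, adipose = -3L, connective = -4L)
    cell_class <- rep(0L, n_fibres)            # 0 = fibre
    if (!is.null(confounder_fracs) && length(confounder_fracs) > 0) {
      bad <- setdiff(names(confounder_fracs), names(class_codes))
      if (length(bad) || is.null(names(confounder_fracs)))
        stop_dq("unknown confounder class(es): ", paste(bad, collapse = ", "),
                class = "dq_parameter_error")
      cell_area <- tabulate(i1[!(ring | wall_between)], n_fibres)
      pool <- sample.int(n_fibres)
      max_convert <- n_fibres - ceiling(0.8 * n_fibres)
      for (cls in names(confounder_fracs)) {
        target <- confounder_fracs[[cls]] * rows * cols
        acc <- 0
        for (i in pool) {
          if (acc >= target) break
          if (cell_class[i] != 0L) next
          if (sum(cell_class != 0L) >= max_convert)
            stop_dq("confounder fractions would destroy more than 20% of fibres",
                    class = "dq_parameter_error")
          cell_class[i] <- class_codes[[cls]]
          acc <- acc + cell_area[i]
        }
      }
    }

    fibre_ids <- which(cell_class == 0L)
    relabel <- integer(n_fibres)
    relabel[fibre_ids] <- seq_along(fibre_ids)

    label <- matrix(0L, rows, cols)
    interior <- !(ring | wall_between)
    lab_cell <- ifelse(cell_class[i1] == 0L, relabel[i1], cell_class[i1])
    label[interior] <- lab_cell[interior]
    on_wall <- ring | wall_between
    # sarcolemma only borders fibres; walls owned by a confounder cell join it
    wall_owner_fibre <- cell_class[i1] == 0L
    label[on_wall & wall_owner_fibre] <- -1L
    label[on_wall & !wall_owner_fibre] <- cell_class[i1][on_wall & !wall_owner_fibre]

    wall_mask <- label == -1L

    # unordered wall segment key: frame-edge walls pair the cell with 0
    pair <- matrix(0L, rows, cols)
    pk <- pmin(i1, i2) * 1000L + pmax(i1, i2)
    pair[wall_mask] <- ifelse(ring[wall_mask], i1[wall_mask], pk[wall_mask])

    # local wall tangent: perpendicular to the seed-to-seed axis; frame walls
    # run along the nearest edge
    i2s <- pmax(i2, 1L)                    # i2 is 0 only for one-fibre fields
    dyn <- pts[i2s, 1] - pts[i1, 1]
    dxn <- pts[i2s, 2] - pts[i1, 2]
    tang <- (atan2(dyn, dxn) + pi / 2) %% pi
    tang <- matrix(tang, rows, cols)
    horiz <- pmin(rowg, rows - 1 - rowg) <= pmin(colg, cols - 1 - colg)
    tang[ring & horiz] <- 0
    tang[ring & !horiz] <- pi / 2
    tangent <- matrix(NA_real_, rows, cols)
    tangent[wall_mask] <- tang[wall_mask]

    midline <- wall_mask &
      ((!ring & gap <= 1.2) | (ring & abs(edge_dist - (t - 1) / 2) <= 0.6))

    # staining-heterogeneity patches: each wall segment is subdivided along
    # its tangent into arcs of ~patch_px so between-ROI variability acts at
    # the scale of an ROI
    patch <- matrix(0L, rows, cols)
    wpos <- colg[wall_mask] * cos(tang[wall_mask]) +
      rowg[wall_mask] * sin(tang[wall_mask])
    pid <- paste(pair[wall_mask], floor(wpos / patch_px))
    patch[wall_mask] <- match(pid, unique(pid))

    structure(list(label_image = label, wall_mask = wall_mask,
                   wall_midline = midline, wall_pair = pair,
                   wall_patch = patch, patch_px = patch_px,
                   wall_tangent = tangent,
                   fibre_count = length(fibre_ids),
                   wall_thickness_px = t, rows = rows, cols = cols,
                   seeds = pts, weights = w, nearest = i1,
                   cell_class = cell_class, seed = seed),
              class = "field_geometry")
  })
}

# Poisson-disc style dart throwing; the minimum spacing relaxes when the
# requested density cannot be reached.
poisson_disc <- function(rows, cols, n, wall_t) {
  dmin <- 0.72 * sqrt(rows * cols / n)
  pts <- matrix(numeric(0), 0, 2)
  fails <- 0
  while (nrow(pts) < n) {
    cand <- c(runif(1, 0, rows - 1), runif(1, 0, cols - 1))
    if (nrow(pts) == 0 ||
        min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= dmin^2) {
      pts <- rbind(pts, cand); fails <- 0
    } else {
      fails <- fails + 1
      if (fails > 400) {
        dmin <- dmin * 0.9; fails <- 0
        if (dmin < 2 * wall_t)
          stop_dq("geometry infeasible: cannot place ", n, " seeds",
                  class = "dq_parameter_error")
      }
    }
  }
  unname(pts)
}

#' @export
print.field_geometry <- function(x, ...) {
  cat(sprintf("<field_geometry> %dx%d px, %d fibres, wall %d px (%.0f wall px), seed %d\n",
              x$rows, x$cols, x$fibre_count, x$wall_thickness_px,
              sum(x$wall_mask), x$seed))
  invisible(x)
}
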