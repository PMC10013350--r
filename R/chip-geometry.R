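#' Parametric microchannel-network layouts
#'
#' Build one of the three channel-network architectures used for in-channel
#' scratch-wound electro-stimulation: a plain straight channel, a t-junction,
#' or the four-branch "peace sign" in which the two anode-containing branches
#' are angled toward the junction and a fourth "scratch runway" branch allows
#' the wounding tool to pass through the wound zone.
#'
#' Coordinates are in millimetres with the origin at the network junction,
#' x to the right and y up. All branches default to the runway width of
#' 0.9 mm (sized for a p10 pipette wounding tool); the out-of-plane channel
#' height defaults to 0.08 mm and sets the sheet conductance used by the
#' field solver.
#'
#' @param layout_kind One of `"straight"`, `"t_junction"`, `"peace_sign"`.
#' @param branch_length_mm Length of the main branches (mm).
#' @param anode_branch_length_mm Length of the two angled anode branches of
#'   the peace-sign layout (mm). The default (7 mm) keeps the anode-end
#'   reservoirs clear of the runway reservoir at the default +/-45 deg angles.
#' @param width_mm Channel width for all branches (mm).
#' @param runway_width_mm Width of the scratch-runway branch (mm).
#' @param anode_angle_deg Angle of each peace-sign anode branch away from the
#'   runway axis (deg).
#' @param channel_height_mm Out-of-plane channel height (mm).
#' @param reservoir_radius_mm Radius of the open reservoirs terminating each
#'   branch (mm).
#' @param wound_zone Optional length-4 numeric `c(xmin, xmax, ymin, ymax)`
#'   (mm) overriding the default wound zone centred on the scratch path.
#'
#' @return A `chip_layout` object: a list with tibbles `segments`
#'   (`start_x, start_y, end_x, end_y, width, role`) and `reservoirs`
#'   (`x, y, radius, role`), the `wound_zone` rectangle, and scalar
#'   geometry parameters.
#' @examples
#' chip_layout("peace_sign")
#' chip_layout("straight", branch_length_mm = 5)
#' @export
chip_layout <- function(layout_kind = c("straight", "t_junction", "peace_sign"),
                        branch_length_mm = 5,
                        anode_branch_length_mm = 7,
                        width_mm = 0.9,
                        runway_width_mm = 0.9,
                        anode_angle_deg = 45,
                        channel_height_mm = 0.08,
                        reservoir_radius_mm = 2,
                        wound_zone = NULL) {
  layout_kind <- match.arg(layout_kind)
  dims <- c(branch_length_mm, anode_branch_length_mm, width_mm,
            runway_width_mm, channel_height_mm, reservoir_radius_mm)
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    abort("all layout dimensions must be positive and finite",
          class = "woundfield_invalid_geometry")
  }
  if (anode_angle_deg <= 0 || anode_angle_deg >= 90) {
    abort("anode_angle_deg must lie strictly between 0 and 90",
          class = "woundfield_invalid_geometry")
  }

  L <- branch_length_mm
  w <- width_mm

  seg <- function(sx, sy, ex, ey, width, role) {
    tibble(start_x = sx, start_y = sy, end_x = ex, end_y = ey,
           width = width, role = role)
  }
  res <- function(x, y, role) {
    tibble(x = x, y = y, radius = reservoir_radius_mm, role = role)
  }

  if (layout_kind == "straight") {
    segments <- seg(-L, 0, L, 0, w, "channel")
    reservoirs <- bind_rows(res(-L, 0, "anode"), res(L, 0, "cathode"))
    wz <- wound_zone %||% c(-w / 2, w / 2, -w / 2, w / 2)
  } else if (layout_kind == "t_junction") {
    # two horizontal arms (anodes) and a vertical cathode stem
    segments <- bind_rows(
      seg(-L, 0, 0, 0, w, "anode_branch"),
      seg(0, 0, L, 0, w, "anode_branch_2"),
      seg(0, 0, 0, L, w, "cathode_branch"))
    reservoirs <- bind_rows(res(-L, 0, "anode"), res(L, 0, "anode_2"),
                            res(0, L, "cathode"))
    wz <- wound_zone %||% c(-w / 2, w / 2, -w / 2, w / 2)
  } else {
    # peace sign: cathode branch up, runway down, anode branches angled
    # +/- anode_angle_deg about the runway (-y) axis
    a <- anode_angle_deg * pi / 180
    La <- anode_branch_length_mm
    ax <- La * sin(a)
    ay <- -La * cos(a)
    segments <- bind_rows(
      seg(0, 0, -ax, ay, w, "anode_branch"),
      seg(0, 0, ax, ay, w, "anode_branch_2"),
      seg(0, 0, 0, L, w, "cathode_branch"),
      seg(0, 0, 0, -L, runway_width_mm, "runway"))
    reservoirs <- bind_rows(
      res(-ax, ay, "anode"), res(ax, ay, "anode_2"),
      res(0, L, "cathode"), res(0, -L, "runway"))
    wz <- wound_zone %||%
      c(-runway_width_mm / 2, runway_width_mm / 2, -w / 2, w / 2)
  }

  out <- structure(
    list(layout_kind = layout_kind,
         segments = segments,
         reservoirs = reservoirs,
         wound_zone = wz,
         scratch_runway_width_mm = runway_width_mm,
         channel_height_mm = channel_height_mm),
    class = "chip_layout")
  validate_chip_layout(out)
  out
}

validate_chip_layout <- function(layout) {
  segs <- layout$segments
  if (any(segs$width <= 0)) {
    abort("segment widths must be positive", class = "woundfield_invalid_geometry")
  }
  wz <- layout$wound_zone
  if (length(wz) != 4 || wz[1] >= wz[2] || wz[3] >= wz[4]) {
    abort("wound_zone must be c(xmin, xmax, ymin, ymax) with positive extent",
          class = "woundfield_invalid_geometry")
  }
  hit <- purrr::pmap_lgl(segs, function(start_x, start_y, end_x, end_y, width, ...) {
    cx <- mean(wz[1:2]); cy <- mean(wz[3:4])
    point_segment_distance(cx, cy, start_x, start_y, end_x, end_y) <=
      width / 2 + max(wz[2] - wz[1], wz[4] - wz[3])
  })
  if (!any(hit)) {
    abort("wound_zone does not intersect any channel segment",
          class = "woundfield_invalid_geometry")
  }
  rs <- layout$reservoirs
  if (nrow(rs) >= 2) {
    dd <- as.matrix(stats::dist(rs[, c("x", "y")]))
    lim <- outer(rs$radius, rs$radius, `+`)
    diag(dd) <- Inf
    if (any(dd < lim)) {
      abort("reservoirs overlap; adjust branch lengths or reservoir radius",
            class = "woundfield_invalid_geometry")
    }
  }
  invisible(layout)
}

point_segment_distance <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

#' @export
print.chip_layout <- function(x, ...) {
  cat(sprintf("<chip_layout: %s>\n", x$layout_kind))
  cat(sprintf("  %d segment(s), %d reservoir(s), channel height %.3g mm\n",
              nrow(x$segments), nrow(x$reservoirs), x$channel_height_mm))
  cat(sprintf("  wound zone [%.2f, %.2f] x [%.2f, %.2f] mm\n",
              x$wound_zone[1], x$wound_zone[2], x$wound_zone[3], x$wound_zone[4]))
  invisible(x)
}

#' Rasterise a chip layout onto a sheet-conductance grid
#'
#' Discretises the 2-D channel network onto a regular grid of square cells.
#' Each cell inside a channel segment or reservoir carries the sheet
#' conductance `sigma * channel_height` (the thin-film approximation used by
#' [solve_field()]); cells outside the network are non-conducting. Electrode
#' footprints (discs centred in each reservoir) and the wound-zone mask are
#' rasterised alongside.
#'
#' @param layout A [chip_layout()] object.
#' @param spacing_mm Grid spacing (mm). Must satisfy
#'   `spacing_mm <= min(width)/6` so each channel spans at least six cells.
#' @param sigma_S_m Electrolyte conductivity (S/m); the default is 1x
#'   phosphate-buffered saline.
#' @param margin_mm Non-conducting margin added around the network bounding
#'   box (mm); the margin participates in the thermal solve as bare plastic.
#' @param electrode_radius_mm Radius of the electrode footprint disc placed
#'   at each reservoir centre (mm).
#'
#' @return A `conductivity_map`: list with cell-centre coordinate vectors
#'   `x`, `y` (mm), logical matrix `conducting` (rows index y, columns x),
#'   numeric `g_sheet` (S), integer `segment_id` (0 outside segments),
#'   logical `wound`, a list of logical electrode footprint masks keyed by
#'   reservoir role, and grid metadata.
#' @examples
#' cm <- rasterize_layout(chip_layout("straight"), spacing_mm = 0.1)
#' sum(cm$conducting) * cm$spacing_mm^2 # conducting area, mm^2
#' @export
rasterize_layout <- function(layout, spacing_mm = 0.05, sigma_S_m = 1.54,
                             margin_mm = 1, electrode_radius_mm = 1) {
  stopifnot(inherits(layout, "chip_layout"))
  segs <- layout$segments
  if (nrow(segs) > 0 && spacing_mm > min(segs$width) / 6) {
    abort(sprintf("grid spacing %.3g mm too coarse for narrowest channel %.3g mm (need <= width/6)",
                  spacing_mm, min(segs$width)),
          class = "woundfield_resolution_error")
  }
  rs <- layout$reservoirs
  xs0 <- c(segs$start_x, segs$end_x, rs$x + rs$radius, rs$x - rs$radius,
           layout$wound_zone[1:2])
  ys0 <- c(segs$start_y, segs$end_y, rs$y + rs$radius, rs$y - rs$radius,
           layout$wound_zone[3:4])
  if (length(xs0) == 0) xs0 <- c(-1, 1)
  if (length(ys0) == 0) ys0 <- c(-1, 1)
  # snap extents to the grid so axis-aligned channel walls land on cell edges
  pad <- ceiling(margin_mm / spacing_mm) * spacing_mm
  x0 <- floor(min(xs0) / spacing_mm) * spacing_mm - pad
  x1 <- ceiling(max(xs0) / spacing_mm) * spacing_mm + pad
  y0 <- floor(min(ys0) / spacing_mm) * spacing_mm - pad
  y1 <- ceiling(max(ys0) / spacing_mm) * spacing_mm + pad
  x <- seq(x0 + spacing_mm / 2, x1 - spacing_mm / 2, by = spacing_mm)
  y <- seq(y0 + spacing_mm / 2, y1 - spacing_mm / 2, by = spacing_mm)
  nx <- length(x); ny <- length(y)
  X <- matrix(x, ny, nx, byrow = TRUE)
  Y <- matrix(y, ny, nx)

  segment_id <- matrix(0L, ny, nx)
  conducting <- matrix(FALSE, ny, nx)
  if (nrow(segs) > 0) {
    for (i in seq_len(nrow(segs))) {
      s <- segs[i, ]
      vx <- s$end_x - s$start_x; vy <- s$end_y - s$start_y
      len <- sqrt(vx^2 + vy^2)
      ux <- vx / len; uy <- vy / len
      tpar <- (X - s$start_x) * ux + (Y - s$start_y) * uy
      perp <- abs(-(X - s$start_x) * uy + (Y - s$start_y) * ux)
      inside <- tpar >= 0 & tpar <= len & perp <= s$width / 2
      segment_id[inside & segment_id == 0L] <- i
      conducting <- conducting | inside
    }
    # fill junction wedges where several branches meet
    ends <- rbind(as.matrix(segs[, c("start_x", "start_y")]),
                  as.matrix(segs[, c("end_x", "end_y")]))
    shared <- unique(ends[duplicated(ends), , drop = FALSE])
    if (nrow(shared) > 0) {
      for (j in seq_len(nrow(shared))) {
        r <- max(segs$width) / 2
        conducting <- conducting |
          ((X - shared[j, 1])^2 + (Y - shared[j, 2])^2 <= r^2)
      }
    }
  }
  electrodes <- list()
  in_reservoir <- matrix(FALSE, ny, nx)
  if (nrow(rs) > 0) {
    for (i in seq_len(nrow(rs))) {
      inside <- (X - rs$x[i])^2 + (Y - rs$y[i])^2 <= rs$radius[i]^2
      conducting <- conducting | inside
      in_reservoir <- in_reservoir | inside
      fp <- (X - rs$x[i])^2 + (Y - rs$y[i])^2 <=
        min(electrode_radius_mm, rs$radius[i])^2
      electrodes[[rs$role[i]]] <- fp
    }
  }
  wz <- layout$wound_zone
  wound <- X >= wz[1] & X <= wz[2] & Y >= wz[3] & Y <= wz[4]

  g <- sigma_S_m * layout$channel_height_mm * 1e-3  # S (sheet conductance)
  g_sheet <- matrix(0, ny, nx)
  g_sheet[conducting] <- g

  structure(
    list(x = x, y = y, spacing_mm = spacing_mm,
         conducting = conducting, g_sheet = g_sheet,
         segment_id = segment_id, wound = wound,
         in_reservoir = in_reservoir,
         electrodes = electrodes,
         sigma_S_m = sigma_S_m,
         channel_height_mm = layout$channel_height_mm,
         layout = layout),
    class = "conductivity_map")
}

#' @export
print.conductivity_map <- function(x, ...) {
  cat(sprintf("<conductivity_map: %d x %d cells at %.3g mm (%s)>\n",
              length(x$y), length(x$x), x$spacing_mm, x$layout$layout_kind))
  cat(sprintf("  conducting %d cells (%.3g mm^2), sheet conductance %.3g S\n",
              sum(x$conducting), sum(x$conducting) * x$spacing_mm^2,
              max(x$g_sheet)))
  invisible(x)
}

#' Conducting area of a rasterised map
#'
#' @param map A `conductivity_map`.
#' @return Conducting area in mm^2.
#' @export
conducting_area <- function(map) {
  stopifnot(inherits(map, "conductivity_map"))
  sum(map$conducting) * map$spacing_mm^2
}

#' Write a chip layout to a structured config file
#'
#' Layouts round-trip through a human-readable YAML file so a chip design
#' can be versioned next to the experimental outputs.
#'
#' @param layout A [chip_layout()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chip_config <- function(layout, path) {
  stopifnot(inherits(layout, "chip_layout"))
  cfg <- list(
    layout_kind = layout$layout_kind,
    channel_height_mm = layout$channel_height_mm,
    scratch_runway_width_mm = layout$scratch_runway_width_mm,
    wound_zone_mm = as.numeric(layout$wound_zone),
    segments = purrr::transpose(as.list(layout$segments)),
    reservoirs = purrr::transpose(as.list(layout$reservoirs)))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a chip layout from a structured config file
#'
#' @param path File written by [write_chip_config()].
#' @return A `chip_layout` object.
#' @export
read_chip_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  needed <- c("layout_kind", "channel_height_mm", "scratch_runway_width_mm",
              "wound_zone_mm", "segments", "reservoirs")
  miss <- setdiff(needed, names(cfg))
  if (length(miss) > 0) {
    abort(paste0("chip config missing field(s): ", paste(miss, collapse = ", ")),
          class = "woundfield_schema_error")
  }
  out <- structure(
    list(layout_kind = cfg$layout_kind,
         segments = bind_rows(lapply(cfg$segments, as_tibble)),
         reservoirs = bind_rows(lapply(cfg$reservoirs, as_tibble)),
         wound_zone = as.numeric(cfg$wound_zone_mm),
         scratch_runway_width_mm = cfg$scratch_runway_width_mm,
         channel_height_mm = cfg$channel_height_mm),
    class = "chip_layout")
  validate_chip_layout(out)
  out
}
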