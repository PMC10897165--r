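#' Arena geometry
#'
#' Describes the 2-D arena a fish is tracked in: a circular well/dish or a
#' rectangular tank, together with named regions (inner zone, social strip,
#' ...) and the width of the edge band used by wall-related analyses
#' (thigmotaxis, circling, back-and-forth detection).
#'
#' Coordinate conventions: circular arenas are centred at the origin;
#' rectangular arenas have their origin at the lower-left corner, x to the
#' right and y up. All lengths are millimetres.
#'
#' @param arena_id Character label for the arena.
#' @param shape `"circle"` or `"rectangle"`.
#' @param radius_mm Radius for circular arenas.
#' @param width_mm,height_mm Side lengths for rectangular arenas.
#' @param edge_band_mm Width of the along-the-wall band; must be positive and
#'   smaller than the arena half-extent.
#' @param regions Named list of regions built with [region()].
#' @return An object of class `arena_geometry`.
#' @seealso [make_standard_arena()] for the presets used by the assays.
#' @export
arena_geometry <- function(arena_id, shape = c("circle", "rectangle"),
                           radius_mm = NULL, width_mm = NULL, height_mm = NULL,
                           edge_band_mm, regions = list()) {
  shape <- match.arg(shape)
  if (shape == "circle") {
    if (is.null(radius_mm) || radius_mm <= 0)
      stop("circular arena needs radius_mm > 0")
    half <- radius_mm
  } else {
    if (is.null(width_mm) || is.null(height_mm) || width_mm <= 0 || height_mm <= 0)
      stop("rectangular arena needs width_mm > 0 and height_mm > 0")
    half <- min(width_mm, height_mm) / 2
  }
  if (!is.numeric(edge_band_mm) || edge_band_mm <= 0 || edge_band_mm >= half)
    stop("edge_band_mm must lie in (0, min arena half-extent)")
  if (length(regions) && is.null(names(regions)))
    stop("regions must be a named list")
  if (anyDuplicated(names(regions)))
    stop("region names must be unique")
  structure(list(arena_id = as.character(arena_id), shape = shape,
                 radius_mm = radius_mm, width_mm = width_mm,
                 height_mm = height_mm, edge_band_mm = edge_band_mm,
                 regions = regions),
            class = "arena_geometry")
}

#' @export
print.arena_geometry <- function(x, ...) {
  dims <- if (x$shape == "circle") sprintf("radius %g mm", x$radius_mm)
          else sprintf("%g x %g mm", x$width_mm, x$height_mm)
  cat(sprintf("<arena_geometry> %s: %s %s, edge band %g mm, regions: %s\n",
              x$arena_id, x$shape, dims, x$edge_band_mm,
              if (length(x$regions)) paste(names(x$regions), collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Named region of an arena
#'
#' Regions are the membership primitives for occupancy metrics. All kinds use
#' boundary-inclusive membership, so a point exactly on the region boundary
#' counts as inside (a deterministic tie-break).
#'
#' @param name Region name.
#' @param kind One of `"disk"`, `"rectangle"`, `"annulus"`, `"half_plane"`.
#' @param ... Numeric parameters for the kind:
#'   disk `cx, cy, r`; rectangle `x0, x1, y0, y1`; annulus `cx, cy, r0, r1`;
#'   half_plane `a, b, c` (the set a*x + b*y <= c).
#' @return An object of class `arena_region`.
#' @export
region <- function(name, kind = c("disk", "rectangle", "annulus", "half_plane"),
                   ...) {
  kind <- match.arg(kind)
  p <- list(...)
  need <- switch(kind,
                 disk = c("cx", "cy", "r"),
                 rectangle = c("x0", "x1", "y0", "y1"),
                 annulus = c("cx", "cy", "r0", "r1"),
                 half_plane = c("a", "b", "c"))
  if (!all(need %in% names(p)))
    stop(sprintf("region kind '%s' needs parameters: %s", kind,
                 paste(need, collapse = ", ")))
  p <- p[need]
  if (kind == "disk" && p$r <= 0) stop("disk radius must be > 0")
  if (kind == "rectangle" && (p$x1 <= p$x0 || p$y1 <= p$y0))
    stop("rectangle region must have x1 > x0 and y1 > y0")
  if (kind == "annulus" && (p$r0 < 0 || p$r1 <= p$r0))
    stop("annulus must have 0 <= r0 < r1")
  structure(list(name = as.character(name), kind = kind, params = p),
            class = "arena_region")
}

#' Point-in-region membership
#'
#' Vectorised, boundary-inclusive membership query.
#'
#' @param reg An [region()] object.
#' @param x,y Coordinates in mm (recycled to common length).
#' @return Logical vector.
#' @export
region_contains <- function(reg, x, y) {
  stopifnot(inherits(reg, "arena_region"))
  p <- reg$params
  switch(reg$kind,
         disk = (x - p$cx)^2 + (y - p$cy)^2 <= p$r^2,
         rectangle = x >= p$x0 & x <= p$x1 & y >= p$y0 & y <= p$y1,
         annulus = {
           d2 <- (x - p$cx)^2 + (y - p$cy)^2
           d2 >= p$r0^2 & d2 <= p$r1^2
         },
         half_plane = p$a * x + p$b * y <= p$c)
}

#' Point-in-arena membership (boundary inclusive)
#' @param arena An [arena_geometry()].
#' @param x,y Coordinates in mm.
#' @return Logical vector.
#' @export
arena_contains <- function(arena, x, y) {
  stopifnot(inherits(arena, "arena_geometry"))
  if (arena$shape == "circle") x^2 + y^2 <= arena$radius_mm^2
  else x >= 0 & x <= arena$width_mm & y >= 0 & y <= arena$height_mm
}

#' Distance from a point to the nearest arena wall
#' @inheritParams arena_contains
#' @return Numeric vector of distances in mm (negative outside the arena).
#' @export
wall_distance <- function(arena, x, y) {
  stopifnot(inherits(arena, "arena_geometry"))
  if (arena$shape == "circle") arena$radius_mm - sqrt(x^2 + y^2)
  else pmin(x, arena$width_mm - x, y, arena$height_mm - y)
}

arena_center <- function(arena) {
  if (arena$shape == "circle") c(0, 0)
  else c(arena$width_mm / 2, arena$height_mm / 2)
}

arena_bbox <- function(arena) {
  if (arena$shape == "circle")
    c(x0 = -arena$radius_mm, x1 = arena$radius_mm,
      y0 = -arena$radius_mm, y1 = arena$radius_mm)
  else c(x0 = 0, x1 = arena$width_mm, y0 = 0, y1 = arena$height_mm)
}

# Clamp points onto the arena boundary (used for small tracking overshoots).
clamp_to_arena <- function(arena, x, y) {
  if (arena$shape == "circle") {
    r <- sqrt(x^2 + y^2)
    out <- r > arena$radius_mm & r > 0
    if (any(out)) {
      s <- arena$radius_mm / r[out]
      x[out] <- x[out] * s
      y[out] <- y[out] * s
    }
  } else {
    x <- pmin(pmax(x, 0), arena$width_mm)
    y <- pmin(pmax(y, 0), arena$height_mm)
  }
  list(x = x, y = y)
}

#' Standard arenas used by the assays
#'
#' Presets matching the published assay containers:
#' \describe{
#'   \item{`well24_7dpf`}{one well of a 24-well plate, 18 mm inner diameter
#'     (9 mm radius), used for the 7-dpf larval light/dark assay.}
#'   \item{`dish35_15dpf`}{35-mm diameter dish (17.5 mm radius) for 15-dpf
#'     open-field recording.}
#'   \item{`tank300_open`}{300 x 300 mm novel tank for juvenile/adult
#'     open-field, shoaling and repetitive-behavior assays.}
#'   \item{`mating_tank`}{210 x 100 mm mating tank for the social-preference
#'     assay, with a `"social"` strip within 70 mm of the divider wall
#'     (x in [140, 210]) and the complementary `"nonsocial"` region.}
#' }
#' Edge bands default to roughly one body length for the life stage using
#' the arena (2 mm for the well, 4 mm for the dish, 35 mm for the novel
#' tank, 25 mm for the mating tank).
#'
#' @param preset One of `"well24_7dpf"`, `"dish35_15dpf"`, `"tank300_open"`,
#'   `"mating_tank"`.
#' @param social_width_mm Width of the social strip for `mating_tank`.
#' @return An [arena_geometry()].
#' @export
make_standard_arena <- function(preset, social_width_mm = 70) {
  presets <- c("well24_7dpf", "dish35_15dpf", "tank300_open", "mating_tank")
  if (!is.character(preset) || length(preset) != 1 || !preset %in% presets)
    stop(sprintf("unknown arena preset '%s'; valid presets: %s",
                 paste(preset, collapse = ","), paste(presets, collapse = ", ")))
  switch(preset,
    well24_7dpf = arena_geometry("well24_7dpf", "circle", radius_mm = 9,
                                 edge_band_mm = 2),
    dish35_15dpf = arena_geometry("dish35_15dpf", "circle", radius_mm = 17.5,
                                  edge_band_mm = 4),
    tank300_open = arena_geometry("tank300_open", "rectangle",
                                  width_mm = 300, height_mm = 300,
                                  edge_band_mm = 35),
    mating_tank = {
      w <- 210; h <- 100
      if (social_width_mm <= 0 || social_width_mm >= w)
        stop("social_width_mm must lie in (0, 210)")
      soc <- region("social", "rectangle",
                    x0 = w - social_width_mm, x1 = w, y0 = 0, y1 = h)
      nonsoc <- region("nonsocial", "rectangle",
                       x0 = 0, x1 = w - social_width_mm, y0 = 0, y1 = h)
      arena_geometry("mating_tank", "rectangle", width_mm = w, height_mm = h,
                     edge_band_mm = 25,
                     regions = list(social = soc, nonsocial = nonsoc))
    })
}

#' Concentric inner zone of a circular arena
#'
#' The thigmotaxis index contrasts a central disk ("inner zone") with the
#' remaining outer ring. The default radius fraction of 0.5 makes the inner
#' zone 25% of the arena area.
#'
#' @param arena A circular [arena_geometry()].
#' @param inner_fraction Radius fraction in (0, 1).
#' @return A disk [region()] named `"inner"`.
#' @export
make_inner_zone <- function(arena, inner_fraction = 0.5) {
  stopifnot(inherits(arena, "arena_geometry"))
  if (arena$shape != "circle")
    stop("inner/outer thigmotaxis zones are defined for circular arenas only")
  if (!is.numeric(inner_fraction) || inner_fraction <= 0 || inner_fraction >= 1)
    stop("inner_fraction must lie strictly between 0 and 1")
  region("inner", "disk", cx = 0, cy = 0, r = inner_fraction * arena$radius_mm)
}

#' Outer ring complementary to [make_inner_zone()]
#' @inheritParams make_inner_zone
#' @return An annulus [region()] named `"outer"`.
#' @export
make_outer_zone <- function(arena, inner_fraction = 0.5) {
  inner <- make_inner_zone(arena, inner_fraction)
  region("outer", "annulus", cx = 0, cy = 0,
         r0 = inner$params$r, r1 = arena$radius_mm)
}

#' Light/dark schedule
#'
#' An ordered, contiguous set of light/dark epochs covering the recording.
#'
#' @param epochs `data.frame` with columns `start_s`, `end_s`, `condition`
#'   (`"light"`/`"dark"`), `label`, `cycle` (`NA` outside cycles).
#' @return An object of class `light_schedule` (a data.frame).
#' @export
light_schedule <- function(epochs) {
  need <- c("start_s", "end_s", "condition", "label", "cycle")
  stopifnot(is.data.frame(epochs), all(need %in% names(epochs)))
  epochs <- epochs[order(epochs$start_s), need, drop = FALSE]
  if (nrow(epochs) < 1) stop("schedule needs at least one epoch")
  if (epochs$start_s[1] != 0) stop("first epoch must start at 0 s")
  if (any(epochs$end_s <= epochs$start_s)) stop("epochs must have end_s > start_s")
  if (nrow(epochs) > 1 &&
      any(abs(epochs$start_s[-1] - epochs$end_s[-nrow(epochs)]) > 1e-9))
    stop("epochs must be contiguous and non-overlapping")
  if (!all(epochs$condition %in% c("light", "dark")))
    stop("condition must be 'light' or 'dark'")
  rownames(epochs) <- NULL
  class(epochs) <- c("light_schedule", "data.frame")
  epochs
}

#' Total span of a schedule in seconds
#' @param schedule A [light_schedule()].
#' @export
schedule_span <- function(schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  max(schedule$end_s)
}

#' Epoch label / condition at given times
#'
#' Epochs are left-closed right-open; the final epoch includes its end point.
#'
#' @param schedule A [light_schedule()].
#' @param t_s Numeric times in seconds.
#' @param what `"label"` or `"condition"`.
#' @return Character vector (`NA` outside the schedule span).
#' @export
epoch_at <- function(schedule, t_s, what = c("label", "condition")) {
  what <- match.arg(what)
  stopifnot(inherits(schedule, "light_schedule"))
  idx <- findInterval(t_s, schedule$start_s)
  idx[t_s < 0 | t_s > max(schedule$end_s)] <- NA_integer_
  out <- schedule[[what]][idx]
  out[is.na(idx)] <- NA_character_
  out
}

#' Photomotor-response light/dark protocol
#'
#' Two published timings of the larval assay are in circulation and both are
#' provided; neither is declared canonical:
#' \describe{
#'   \item{`figure`}{20 min light adaptation, 40 min baseline light (L0), then
#'     two cycles of 5 min light / 5 min dark (L1, D1, L2, D2); 80 min total.
#'     Analysis conventionally starts at minute 21, i.e. with L0.}
#'   \item{`methods`}{55 min continuous light (L0) followed by the same two
#'     5/5-min cycles; 75 min (4500 s) total.}
#' }
#'
#' @param variant `"figure"` or `"methods"`.
#' @return A [light_schedule()] with epochs labelled
#'   `adaptation`/`L0`/`L1`/`D1`/`L2`/`D2`.
#' @export
make_pmr_schedule <- function(variant = c("figure", "methods")) {
  variant <- match.arg(variant)
  cyc <- function(t0) data.frame(
    start_s = t0 + c(0, 300, 600, 900),
    end_s = t0 + c(300, 600, 900, 1200),
    condition = c("light", "dark", "light", "dark"),
    label = c("L1", "D1", "L2", "D2"),
    cycle = c(1L, 1L, 2L, 2L))
  if (variant == "figure") {
    base <- data.frame(start_s = c(0, 1200), end_s = c(1200, 3600),
                       condition = "light", label = c("adaptation", "L0"),
                       cycle = NA_integer_)
    light_schedule(rbind(base, cyc(3600)))
  } else {
    base <- data.frame(start_s = 0, end_s = 3300, condition = "light",
                       label = "L0", cycle = NA_integer_)
    light_schedule(rbind(base, cyc(3300)))
  }
}

#' Constant-light schedule for open-field recordings
#' @param duration_s Recording span in seconds.
#' @param label Epoch label, default `"open_field"`.
#' @return A [light_schedule()] with a single light epoch.
#' @export
make_open_field_schedule <- function(duration_s, label = "open_field") {
  light_schedule(data.frame(start_s = 0, end_s = duration_s,
                            condition = "light", label = label,
                            cycle = NA_integer_))
}
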