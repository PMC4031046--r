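#' Court geometry specification
#'
#' Defines the geometry needed to classify a shot location: basket position,
#' three-point arc radius, corner three-point line offset, and court bounds.
#' Defaults are NBA dimensions (feet); other leagues can be modeled by
#' changing the parameters.
#'
#' The coordinate system has its origin at the intersection of the baseline
#' and the court's long axis: `x` is the signed lateral offset (feet) and `y`
#' the distance from the baseline toward half court.  The basket sits at
#' `(0, basket_y)`.  The corner three-point line (vertical line at
#' `|x| = corner_offset`) meets the arc at `y = corner_break_y`
#' (`basket_y + sqrt(arc_radius^2 - corner_offset^2)`); below that height the
#' 2pt/3pt boundary is the corner line, above it the arc.
#'
#' @param basket_y basket distance from the baseline, feet.
#' @param arc_radius three-point arc radius, feet.
#' @param corner_offset lateral offset of the corner three-point line, feet.
#' @param half_court_y half-court line position, feet.
#' @param court_half_width half the court width, feet.
#' @return An object of class `court_spec`.
#' @examples
#' spec <- court_spec()
#' spec$corner_break_y
#' @export
court_spec <- function(basket_y = 5.25, arc_radius = 23.75, corner_offset = 22,
                       half_court_y = 47, court_half_width = 25) {
  if (corner_offset >= arc_radius)
    stopf("corner_offset (%g) must be smaller than arc_radius (%g)",
          corner_offset, arc_radius)
  if (basket_y <= 0 || basket_y >= half_court_y)
    stopf("basket_y must lie strictly between 0 and half_court_y")
  structure(list(
    basket_y = basket_y,
    arc_radius = arc_radius,
    corner_offset = corner_offset,
    corner_break_y = basket_y + sqrt(arc_radius^2 - corner_offset^2),
    half_court_y = half_court_y,
    court_half_width = court_half_width
  ), class = "court_spec")
}

#' Distance of a shot from the basket
#'
#' @param x,y shot coordinates, feet (see [court_spec()]).
#' @param court a [court_spec()].
#' @return Euclidean distance to the basket center, feet (vectorized).
#' @export
shot_distance <- function(x, y, court = court_spec()) {
  sqrt(x^2 + (y - court$basket_y)^2)
}

#' Classify a location as a 2pt or 3pt attempt
#'
#' A location is a 3pt attempt iff it lies beyond the corner line
#' (`|x| > corner_offset` while `y <= corner_break_y`) or beyond the arc
#' (`shot_distance > arc_radius` while `y > corner_break_y`).  Because the
#' corner line is closer to the basket than the arc, locations at a distance
#' between `corner_offset` and `arc_radius` can be either class depending on
#' the angle to the basket.
#'
#' @inheritParams shot_distance
#' @return Integer vector of 2s and 3s.
#' @examples
#' classify_point_value(22.5, 7.25)  # corner three inside the arc radius
#' classify_point_value(0, 28.25)    # above-the-break two at 23 ft
#' @export
classify_point_value <- function(x, y, court = court_spec()) {
  d <- shot_distance(x, y, court)
  corner <- y <= court$corner_break_y
  ifelse((corner & abs(x) > court$corner_offset) |
           (!corner & d > court$arc_radius), 3L, 2L)
}

# ---------------------------------------------------------------------------
# Region maps

new_region_map <- function(kind, labels, groups, assign, placement, court,
                           params = list()) {
  stopifnot(is.function(assign), length(groups) == length(labels))
  structure(list(
    kind = kind, labels = as.integer(labels), groups = groups,
    assign = assign, placement = placement, court = court, params = params
  ), class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map: %s, %d regions>\n", x$kind, length(x$labels)))
  tab <- table(x$groups)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

# sector of an angle (degrees, measured at the basket from the right
# baseline direction): five sectors right corner -> left corner, the two
# corner sectors extended below the basket line.
.sector_of <- function(phi_deg) {
  s <- findInterval(phi_deg, c(36, 72, 108, 144)) + 1L
  s[phi_deg < -90] <- 5L     # left-of-basket baseline zone
  s
}

#' Default 16-region partition of the half court
#'
#' A parameterized reconstruction of a 16-region court partition: a central
#' zone around the basket (`d <= r_inner`), a short-range ring
#' (`r_inner < d <= r_mid`) split into five angular sectors, a long-2pt band
#' (inside the three-point line, `d > r_mid`) split into the same sectors,
#' and five 3pt sectors beyond the line.  Region labels interleave by sector:
#' 3pt regions are 1, 4, 7, 11, 14 (group `THREE`), long-2pt regions are
#' 2, 5, 8, 12, 15 (`LONG2`) and all others are short-2pt (`SHORT2`).
#'
#' Each region also carries a polar placement rectangle (angle range x
#' distance band) that lies entirely inside the region; the synthetic
#' generator samples shot coordinates uniformly from these rectangles, so
#' generated labels and [assign_region()] agree exactly.
#'
#' @param court a [court_spec()].
#' @param r_inner radius of the central zone, feet.
#' @param r_mid inner radius of the long-2pt band, feet.
#' @return A `region_map`.
#' @export
region_map_nba <- function(court = court_spec(), r_inner = 8, r_mid = 16) {
  stopifnot(0 < r_inner, r_inner < r_mid, r_mid < court$corner_offset)
  three <- c(1L, 4L, 7L, 11L, 14L)
  long2 <- c(2L, 5L, 8L, 12L, 15L)
  short <- c(3L, 6L, 9L, 10L, 13L)
  groups <- character(16)
  groups[three] <- "THREE"; groups[long2] <- "LONG2"
  groups[c(short, 16L)] <- "SHORT2"

  assign_fun <- function(x, y) {
    d <- shot_distance(x, y, court)
    phi <- atan2(y - court$basket_y, x) * 180 / pi
    s <- .sector_of(phi)
    pv <- classify_point_value(x, y, court)
    lab <- ifelse(pv == 3L, three[s],
                  ifelse(d <= r_inner, 16L,
                         ifelse(d <= r_mid, short[s], long2[s])))
    lab[abs(x) > court$court_half_width | y < 0 | y > court$half_court_y] <- NA
    as.integer(lab)
  }

  # polar rectangles (degrees, feet) proven inside their region for the
  # default geometry; mirrored for the left side.
  pl <- data.frame(
    label = c(1, 4, 7, 11, 14,  2, 5, 8, 12, 15,  3, 6, 9, 10, 13, 16),
    a_lo  = c(10, 40, 75, 110, 166,  20, 40, 75, 110, 146,
              10, 40, 75, 110, 146, 30),
    a_hi  = c(14, 70, 105, 140, 170,  34, 70, 105, 140, 160,
              34, 70, 105, 140, 170, 150),
    d_lo  = c(22.8, 24.2, 24.2, 24.2, 22.8,  17, 17, 17, 17, 17,
              9, 9, 9, 9, 9, 1),
    d_hi  = c(23.6, 28, 28, 28, 23.6,  23.3, 22, 22, 22, 23.3,
              15.5, 15.5, 15.5, 15.5, 15.5, 7.5)
  )
  pl <- pl[order(pl$label), ]
  rownames(pl) <- NULL

  new_region_map("nba", 1:16, groups, assign_fun, pl, court,
                 params = list(r_inner = r_inner, r_mid = r_mid))
}

#' Region map from explicit polar rectangles
#'
#' Builds an abstract region map in which each region is a polar rectangle
#' around the basket (half-open in both coordinates).  Used for reduced /
#' abstract study designs where the full 16-region court is unnecessary.
#'
#' @param labels integer region labels.
#' @param groups character group per region (`"THREE"`, `"LONG2"`, `"SHORT2"`).
#' @param a_lo,a_hi angular range, degrees.
#' @param d_lo,d_hi distance band, feet.
#' @param court a [court_spec()].
#' @return A `region_map`.
#' @export
region_map_polar <- function(labels, groups, a_lo, a_hi, d_lo, d_hi,
                             court = court_spec()) {
  n <- length(labels)
  stopifnot(length(groups) == n, length(a_lo) == n, length(a_hi) == n,
            length(d_lo) == n, length(d_hi) == n, all(d_lo < d_hi),
            all(a_lo < a_hi), all(groups %in% c("THREE", "LONG2", "SHORT2")))
  ord <- order(as.integer(labels))
  pl <- data.frame(label = as.integer(labels), a_lo = a_lo, a_hi = a_hi,
                   d_lo = d_lo, d_hi = d_hi)[ord, ]
  groups <- unname(groups[ord])
  assign_fun <- function(x, y) {
    d <- shot_distance(x, y, court)
    phi <- atan2(y - court$basket_y, x) * 180 / pi
    out <- rep(NA_integer_, length(d))
    for (r in seq_len(nrow(pl))) {   # label order => lower label wins ties
      hit <- is.na(out) & phi >= pl$a_lo[r] & phi < pl$a_hi[r] &
        d >= pl$d_lo[r] & d < pl$d_hi[r]
      out[hit] <- pl$label[r]
    }
    out
  }
  new_region_map("polar", pl$label, groups, assign_fun, pl, court,
                 params = list(labels = pl$label, groups = groups,
                               a_lo = pl$a_lo, a_hi = pl$a_hi,
                               d_lo = pl$d_lo, d_hi = pl$d_hi))
}

#' Assign shot locations to regions
#'
#' @param x,y coordinates, feet (vectorized).
#' @param map a `region_map`.
#' @return Integer region labels; `NA` for locations outside every region
#'   (such events are excluded from downstream analyses).
#' @export
assign_region <- function(x, y, map = region_map_nba()) {
  map$assign(x, y)
}

#' Coarse group of a region
#'
#' @param label integer region label(s).
#' @param map a `region_map`.
#' @return Character vector in `{"THREE", "LONG2", "SHORT2"}`.
#' @export
region_group <- function(label, map = region_map_nba()) {
  idx <- match(label, map$labels)
  if (anyNA(idx)) stopf("unknown region label(s): %s",
                        paste(label[is.na(idx)], collapse = ", "))
  unname(map$groups[idx])
}

# representative point (polar-rectangle center) per region, used when a
# surrogate draw needs concrete coordinates
region_representative <- function(map) {
  pl <- map$placement
  a <- deg2rad((pl$a_lo + pl$a_hi) / 2)
  d <- (pl$d_lo + pl$d_hi) / 2
  data.frame(label = pl$label,
             x = d * cos(a),
             y = map$court$basket_y + d * sin(a),
             dist = d)
}

# ---------------------------------------------------------------------------
# plain-text (YAML) serialization

#' Write / read a region map as a YAML config
#'
#' Parameterized maps (`nba`, `polar`) round-trip through a plain-text YAML
#' file listing the court constants and the map parameters.
#'
#' @param map a `region_map`.
#' @param path file path.
#' @export
write_region_map <- function(map, path) {
  crt <- map$court
  obj <- list(kind = map$kind,
              court = list(basket_y = crt$basket_y,
                           arc_radius = crt$arc_radius,
                           corner_offset = crt$corner_offset,
                           half_court_y = crt$half_court_y,
                           court_half_width = crt$court_half_width),
              params = map$params)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_region_map
#' @export
read_region_map <- function(path) {
  obj <- yaml::read_yaml(path)
  crt <- do.call(court_spec, obj$court)
  switch(obj$kind,
         nba = region_map_nba(crt, r_inner = obj$params$r_inner,
                              r_mid = obj$params$r_mid),
         polar = region_map_polar(obj$params$labels, obj$params$groups,
                                  obj$params$a_lo, obj$params$a_hi,
                                  obj$params$d_lo, obj$params$d_hi, crt),
         stopf("unknown region map kind '%s'", obj$kind))
}
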