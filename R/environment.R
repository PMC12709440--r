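# Static confinement geometries: pillar obstacle parks, Y-junction and
# multi-channel microfluidic devices, plus the chemotactic forward bias.
# Obstacles are circles; walls are finite segments of half-thickness
# `wall_half` that repel beads through the same WCA force family as
# bead-bead sterics, with the repulsion onset at the surface.

.new_env <- function(obstacles = NULL, walls = NULL, channels = NULL,
                     chemo_dir = c(1, 0), start = c(0, 0), wall_half = 0.25,
                     kind = "free") {
  if (is.null(obstacles))
    obstacles <- data.frame(x = numeric(), y = numeric(), r = numeric())
  if (is.null(walls))
    walls <- data.frame(x1 = numeric(), y1 = numeric(),
                        x2 = numeric(), y2 = numeric())
  if (is.null(channels))
    channels <- data.frame(mx = numeric(), my = numeric(), dx = numeric(),
                           dy = numeric(), width = numeric(),
                           label = character())
  e <- list(obstacles = obstacles, walls = walls, channels = channels,
            chemo_dir = chemo_dir / sqrt(sum(chemo_dir^2)), start = start,
            wall_half = wall_half, kind = kind)
  class(e) <- "cellEnv"
  e
}

#' Free (unconfined) 2D space
#'
#' @param start initial cell-centre position.
#' @return a `cellEnv` with no obstacles, walls or channels.
#' @export
freeSpace <- function(start = c(0, 0)) .new_env(start = start, kind = "free")

#' Square-lattice pillar obstacle park
#'
#' Circular pillars of radius `Robs` on a square lattice of pitch `spacing`,
#' covering a square region of side `extent` centred on the origin. The cell
#' starts at the centre of a lattice cell (the origin), equidistant from the
#' four nearest pillars.
#'
#' @param Robs pillar radius (um).
#' @param spacing lattice pitch (um); must exceed `2 * Robs`.
#' @param extent side length of the covered region (um).
#' @param clearance_warn warn when the pillar surface gap drops below this
#'   value (um), i.e. when the arena is tight for a cell of typical radius.
#' @return a `cellEnv`.
#' @examples
#' env <- obstaclePark(Robs = 4, spacing = 20, extent = 100)
#' nrow(env$obstacles) # 36 pillars (6 x 6)
#' @export
obstaclePark <- function(Robs = 4, spacing = 20, extent = 100,
                         clearance_warn = 7) {
  stopifnot(Robs > 0, extent > 0)
  if (spacing <= 2 * Robs)
    stop("obstacle spacing must exceed the pillar diameter")
  if (spacing - 2 * Robs < clearance_warn)
    warning("pillar surface gap ", spacing - 2 * Robs,
            " um is tight for a typical cell")
  half <- spacing / 2
  coords <- seq(-floor((extent / 2 - half) / spacing) * spacing - half,
                extent / 2, by = spacing)
  coords <- coords[abs(coords) <= extent / 2 + 1e-9]
  grid <- expand.grid(x = coords, y = coords)
  .new_env(obstacles = data.frame(x = grid$x, y = grid$y, r = Robs),
           kind = "obstacle_park")
}

#' Y-junction microchannel device
#'
#' A feeder chamber narrows through a funnel into a straight stem channel
#' which bifurcates at the origin into two straight arms at `+/- arm_angle`.
#' Arm widths are measured perpendicular to the arm axes; `w_left` is the
#' upper arm. A chemotactic bias along the stem axis (+x) drives the cell
#' toward the junction. Channel mouths sit on the arm centrelines next to the
#' junction wedge apex; entry into an arm is scored by
#' [channelEntry()] when every membrane bead is at least `depth` um past the
#' mouth.
#'
#' @param w_left,w_right arm widths (um), upper and lower.
#' @param stem_w stem channel width (um).
#' @param arm_angle arm half-angle from the stem axis (degrees).
#' @param stem_len,arm_len,chamber_len,chamber_w device dimensions (um).
#' @return a `cellEnv` with two labelled channels (`"left"` = upper arm,
#'   `"right"` = lower arm).
#' @export
yJunction <- function(w_left = 10, w_right = 10, stem_w = 10, arm_angle = 45,
                      stem_len = 20, arm_len = 35, chamber_len = 20,
                      chamber_w = 20) {
  stopifnot(w_left > 0, w_right > 0, stem_w > 0)
  a <- arm_angle * pi / 180
  u1 <- c(cos(a), sin(a))    # upper arm axis
  u2 <- c(cos(a), -sin(a))   # lower arm axis
  hw <- stem_w / 2
  fl <- (chamber_w - stem_w) / 2     # 45-degree funnel length
  xf <- -stem_len - fl
  x0 <- xf - chamber_len
  o1 <- c(0, hw)   # upper outer-wall bend point
  o2 <- c(0, -hw)
  # inner-wall support points: offset each outer wall inward by the arm width
  p1 <- o1 + w_left * c(sin(a), -cos(a))
  p2 <- o2 + w_right * c(sin(a), cos(a))
  # apex of the junction wedge: intersection of the two inner-wall lines
  A <- solve(cbind(u1, -u2), p2 - p1)
  apex <- p1 + A[1] * u1
  wl <- function(p, q) data.frame(x1 = p[1], y1 = p[2], x2 = q[1], y2 = q[2])
  walls <- rbind(
    wl(c(x0, -chamber_w / 2), c(x0, chamber_w / 2)),          # back wall
    wl(c(x0, chamber_w / 2), c(xf, chamber_w / 2)),           # chamber top
    wl(c(x0, -chamber_w / 2), c(xf, -chamber_w / 2)),         # chamber bottom
    wl(c(xf, chamber_w / 2), c(-stem_len, hw)),               # funnel top
    wl(c(xf, -chamber_w / 2), c(-stem_len, -hw)),             # funnel bottom
    wl(c(-stem_len, hw), o1),                                 # stem top
    wl(c(-stem_len, -hw), o2),                                # stem bottom
    wl(o1, o1 + arm_len * u1),                                # upper outer
    wl(o2, o2 + arm_len * u2),                                # lower outer
    wl(apex, apex + arm_len * u1),                            # upper inner
    wl(apex, apex + arm_len * u2))                            # lower inner
  c1 <- o1 + (w_left / 2) * c(sin(a), -cos(a))  # upper arm centreline point
  c2 <- o2 + (w_right / 2) * c(sin(a), cos(a))
  m1 <- c1 + sum((apex - c1) * u1) * u1          # mouth: apex projected
  m2 <- c2 + sum((apex - c2) * u2) * u2
  channels <- data.frame(mx = c(m1[1], m2[1]), my = c(m1[2], m2[2]),
                         dx = c(u1[1], u2[1]), dy = c(u1[2], u2[2]),
                         width = c(w_left, w_right),
                         label = c("left", "right"))
  .new_env(walls = walls, channels = channels, chemo_dir = c(1, 0),
           start = c((x0 + xf) / 2, 0), kind = "y_junction")
}

#' Multi-channel path-choice device
#'
#' A feeder chamber pressed against a perforated wall: parallel straight
#' channels of the given widths open at x = 0, separated by thin septa, so a
#' cell driven against the wall touches several mouths at once and chooses
#' among pore sizes. A chemotactic bias along +x drives the cell toward the
#' mouths.
#'
#' @param widths channel widths (um), bottom to top.
#' @param channel_len channel length (um).
#' @param septum wall thickness between adjacent channels (um).
#' @param chamber_len feeder chamber length (um).
#' @return a `cellEnv` with one labelled channel per width.
#' @examples
#' env <- multiChannel(c(2, 4, 6, 8))
#' env$channels$width
#' @export
multiChannel <- function(widths = c(2, 4, 6, 8), channel_len = 30,
                         septum = 3, chamber_len = 25) {
  stopifnot(all(widths > 0), septum > 0)
  if (chamber_len < 18)
    stop("feeder chamber too short for the default cell size")
  k <- length(widths)
  span <- sum(widths) + (k - 1) * septum
  # channel centres, bottom to top, span centred on y = 0
  lo <- -span / 2 + cumsum(c(0, widths[-k] + septum))
  yc <- lo + widths / 2
  chamber_w <- span + 14
  hw <- chamber_w / 2
  wl <- function(x1, y1, x2, y2) data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
  walls <- rbind(
    wl(-chamber_len, -hw, -chamber_len, hw),   # back wall
    wl(-chamber_len, hw, 0, hw),               # chamber top
    wl(-chamber_len, -hw, 0, -hw))             # chamber bottom
  # front wall pieces between and beyond the channel mouths
  edges <- sort(c(-hw, yc - widths / 2, yc + widths / 2, hw))
  for (i in seq(1, length(edges) - 1, by = 2))
    walls <- rbind(walls, wl(0, edges[i], 0, edges[i + 1]))
  for (i in seq_len(k)) {
    walls <- rbind(walls,
                   wl(0, yc[i] - widths[i] / 2, channel_len, yc[i] - widths[i] / 2),
                   wl(0, yc[i] + widths[i] / 2, channel_len, yc[i] + widths[i] / 2))
  }
  channels <- data.frame(mx = 0, my = yc, dx = 1, dy = 0, width = widths,
                         label = paste0("w", widths))
  .new_env(walls = walls, channels = channels, chemo_dir = c(1, 0),
           start = c(-chamber_len + 9, 0), kind = "multi_channel")
}

#' Signed distance from a point to the environment boundary
#'
#' Negative inside an obstacle or wall. Used for geometry checks and plots.
#'
#' @param pt length-2 point.
#' @param env a `cellEnv`.
#' @return signed distance (um); `Inf` in an unconfined environment.
#' @export
envDistance <- function(pt, env) {
  d <- Inf
  ob <- env$obstacles
  if (nrow(ob))
    d <- min(d, sqrt((pt[1] - ob$x)^2 + (pt[2] - ob$y)^2) - ob$r)
  w <- env$walls
  if (nrow(w)) {
    for (i in seq_len(nrow(w))) {
      dx <- w$x2[i] - w$x1[i]; dy <- w$y2[i] - w$y1[i]
      L2 <- dx^2 + dy^2
      tt <- if (L2 > 0) max(0, min(1, ((pt[1] - w$x1[i]) * dx +
                                         (pt[2] - w$y1[i]) * dy) / L2)) else 0
      d <- min(d, sqrt((pt[1] - (w$x1[i] + tt * dx))^2 +
                         (pt[2] - (w$y1[i] + tt * dy))^2) - env$wall_half)
    }
  }
  d
}

#' Channel entry check
#'
#' A cell has entered a channel when *every* membrane bead has travelled at
#' least `depth` um past that channel's mouth line (projection onto the
#' channel axis).
#'
#' @param st a `cellState`.
#' @param env a `cellEnv` with labelled channels.
#' @param depth entry depth criterion (um); default 5.
#' @return the entered channel label, or `NA_character_` if none.
#' @export
channelEntry <- function(st, env, depth = 5) {
  ch <- env$channels
  if (!nrow(ch)) return(NA_character_)
  for (i in seq_len(nrow(ch))) {
    proj <- (st$membrane[, 1] - ch$mx[i]) * ch$dx[i] +
      (st$membrane[, 2] - ch$my[i]) * ch$dy[i]
    lat <- -(st$membrane[, 1] - ch$mx[i]) * ch$dy[i] +
      (st$membrane[, 2] - ch$my[i]) * ch$dx[i]
    # inside this lane: every bead past the mouth AND laterally within the
    # channel (with a wall-thickness margin)
    if (min(proj) >= depth && max(abs(lat)) <= ch$width[i] / 2 + 1)
      return(as.character(ch$label[i]))
  }
  NA_character_
}

#' Serialize an environment to structured text (YAML)
#'
#' @param env a `cellEnv`.
#' @param path output file.
#' @export
writeEnv <- function(env, path) {
  yaml::write_yaml(list(kind = env$kind, wall_half = env$wall_half,
                        chemo_dir = env$chemo_dir, start = env$start,
                        obstacles = env$obstacles, walls = env$walls,
                        channels = env$channels), path)
  invisible(path)
}

#' Read an environment from structured text (YAML)
#'
#' @param path file written by [writeEnv()].
#' @return a `cellEnv`.
#' @export
readEnv <- function(path) {
  z <- yaml::read_yaml(path)
  as_df <- function(x) {
    if (is.null(x) || length(x) == 0) return(NULL)
    if (all(lengths(x) == 0)) return(NULL) # empty columns: no rows
    do.call(data.frame, c(x, stringsAsFactors = FALSE))
  }
  .new_env(obstacles = as_df(z$obstacles), walls = as_df(z$walls),
           channels = as_df(z$channels), chemo_dir = unlist(z$chemo_dir),
           start = unlist(z$start), wall_half = z$wall_half, kind = z$kind)
}

#' @export
print.cellEnv <- function(x, ...) {
  cat(sprintf("cellEnv <%s>: %d obstacles, %d walls, %d channels\n",
              x$kind, nrow(x$obstacles), nrow(x$walls), nrow(x$channels)))
  if (nrow(x$channels))
    cat("  channels:", paste(sprintf("%s (%g um)", x$channels$label,
                                     x$channels$width), collapse = ", "), "\n")
  invisible(x)
}
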