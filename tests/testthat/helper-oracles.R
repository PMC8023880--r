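# Independent oracles and hand-built fixtures. Everything here is computed
# from first principles (exact point-segment distances, atan2 on explicit
# direction vectors, direct ANOVA sums of squares via aov()) so the tests
# never reuse the code paths they check.

# exact minimum distance from a point to a piecewise-linear polyline
oracle_polyline_dist <- function(p, poly) {
  seg <- function(a, b) {
    e <- b - a
    t <- sum((p - a) * e) / sum(e * e)
    t <- max(0, min(1, t))
    sqrt(sum((p - (a + t * e))^2))
  }
  min(vapply(seq_len(nrow(poly) - 1),
             function(i) seg(poly[i, ], poly[i + 1, ]), numeric(1)))
}

# angle of a segment from vertical-up after orienting it upwards (deg,
# positive towards +x)
oracle_axis_angle <- function(p1, p2) {
  d <- p2 - p1
  if (d[2] > 0) d <- -d
  atan2(d[1], -d[2]) * 180 / pi
}

# independent signed femoral-vs-tibial angle: difference of the two axis
# inclinations
oracle_signed_angle <- function(fem_p1, fem_p2, tib_p1, tib_p2) {
  oracle_axis_angle(tib_p1, tib_p2) - oracle_axis_angle(fem_p1, fem_p2)
}

rot_deg <- function(pts, deg, center = c(0, 0)) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(pts, 2, center) %*% t(R), 2, center, "+")
}

# minimal hand-built knee on a small custom schema: straight (optionally
# tapered / rotated) femoral and tibial shafts, explicit condyle and
# plateau margin points
shaft_knee_schema <- function() {
  knee_schema(c(fem_shaft_lateral = 5, fem_shaft_medial = 5,
                fem_condyles = 4, fem_notch_apex = 1, patella = 4,
                tib_plateau = 4, tib_spine_base = 2,
                tib_shaft_medial = 5, tib_shaft_lateral = 5),
              name = "shaft-test")
}

make_shaft_knee <- function(width = 30, extent = c(20, 260), rot = 0,
                            taper_med_deg = 0, taper_lat_deg = 0,
                            origin = c(500, 500), condyle_halfw = 40,
                            plateau = NULL, case_id = "shaft") {
  tm <- tan(taper_med_deg * pi / 180)
  tl <- tan(taper_lat_deg * pi / 180)
  t_f <- seq(extent[2], extent[1], length.out = 5)   # proximal -> distal
  fem_med <- cbind(width / 2 - tm * (t_f - extent[1]), -t_f)
  fem_lat <- cbind(-width / 2 + tl * (t_f - extent[1]), -t_f)
  condyles <- rbind(c(condyle_halfw, 5), c(15, 12), c(-15, 12),
                    c(-condyle_halfw, 5))
  notch <- matrix(c(0, 0), 1)
  patella <- rbind(c(10, -30), c(-10, -30), c(-10, -50), c(10, -50))
  if (is.null(plateau)) {
    plateau <- rbind(c(40, 18), c(15, 22), c(-15, 22), c(-40, 18))
  }
  spines <- rbind(c(5, 15), c(-5, 15))
  t_t <- seq(extent[1], extent[2], length.out = 5)   # proximal -> distal
  tib_med <- cbind(width / 2 - tm * (t_t - extent[1]), 15 + t_t)
  tib_lat <- cbind(-width / 2 + tl * (t_t - extent[1]), 15 + t_t)
  pts <- rbind(fem_lat, fem_med, condyles, notch, patella,
               plateau, spines, tib_med, tib_lat)
  if (rot != 0) pts <- rot_deg(pts, rot)
  pts <- sweep(pts, 2, origin, "+")
  knee_landmark_set(case_id, "right", pts, shaft_knee_schema())
}

# apply a similarity transform (rotate about centroid, scale, translate)
transform_knee <- function(knee, deg = 0, shift = c(0, 0), scale = 1) {
  pts <- knee$points
  ctr <- colMeans(pts)
  pts <- rot_deg(pts, deg, center = ctr)
  pts <- sweep(sweep(pts, 2, ctr, "-") * scale, 2, ctr, "+")
  pts <- sweep(pts, 2, shift, "+")
  knee_landmark_set(knee$case_id, knee$side, pts, knee$schema)
}

# brute-force absolute-agreement single-measures ICC through aov(): an
# independent route to the two-way mean squares
oracle_icc_a1 <- function(obs, pred) {
  n <- length(obs)
  d <- data.frame(y = c(obs, pred),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = d))[[1]]
  MSR <- tab["subj", "Mean Sq"]
  MSC <- tab["rater", "Mean Sq"]
  MSE <- tab["Residuals", "Mean Sq"]
  k <- 2
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}
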