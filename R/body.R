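# Reduced sagittal body model: an articulated chain of nodes (head,
# C1-L5 vertebral levels, sacrum/pelvis, thigh, shank, heel) lying supine.
# Nodes carry lumped segment masses and an effective contact width; joints
# between consecutive nodes carry axial and rotational stiffness about a
# reference rest profile; tension-only ligament springs bridge every other
# node.  This is an explicit surrogate of a full 3-D body model: orderings
# and mechanisms, not absolute pressures, are the quantities it predicts.

#' Body segment mass fractions
#'
#' Published anthropometric segment mass fractions used to lump body mass
#' onto chain nodes: head 8.1%, trunk 49.7%, thighs 20%, shanks 9.3%, feet
#' 2.9%; the remainder (the arms, which lie parallel to the trunk in the
#' supine posture) is folded into the trunk.
#'
#' @return named numeric vector of fractions summing to 1.
#' @export
segment_mass_fractions <- function() {
  f <- c(head = 0.081, trunk = 0.497, thighs = 0.20, shanks = 0.093,
         feet = 0.029)
  f["trunk"] <- f["trunk"] + (1 - sum(f))  # arms lumped into trunk
  f
}

#' Intervertebral disc geometry table
#'
#' Per-disc cross-sectional area, half-depth `c` and effective second moment
#' `I_eff` used to convert joint axial force and moment into a disc stress
#' proxy (|F|/A + |M| c / I).  Values follow typical literature magnitudes
#' (cervical discs a few hundred mm^2, lumbar 1300-1800 mm^2) with a smooth
#' cranio-caudal progression; override via the `disc_geometry` argument of
#' [build_default_body()].
#'
#' @return data frame with `level`, `region`, `area_mm2`, `c_mm`, `I_mm4`.
#' @export
disc_geometry_table <- function() {
  lev <- c(paste0("C", 2:7, "-", c(paste0("C", 3:7), "T1")),
           paste0("T", 1:12, "-", c(paste0("T", 2:12), "L1")),
           paste0("L", 1:5, "-", c(paste0("L", 2:5), "S1")))
  region <- c(rep("cervical", 6), rep("thoracic", 12), rep("lumbar", 5))
  area <- c(seq(220, 420, length.out = 6),
            seq(450, 900, length.out = 12),
            seq(1300, 1800, length.out = 5))
  depth <- c(seq(14, 17, length.out = 6),    # anteroposterior depth (mm)
             seq(18, 30, length.out = 12),
             seq(34, 38, length.out = 5))
  data.frame(level = lev, region = region, area_mm2 = area,
             c_mm = depth / 2, I_mm4 = area * depth^2 / 16)
}

# default effective contact widths (mm) per node group: the lateral size of
# the dorsal contact patch, converting the line model to tributary areas
.default_widths <- function() {
  c(head = 120, cervical = 80, thoracic = 280, lumbar = 220,
    sacrum = 220, thigh = 180, shank = 120, heel = 40)
}

# Default joint stiffness per group: axial N/mm, rotational N.mm/rad.
# The rotational values describe the bending compliance of the dorsal body
# *surface* (trunk draping over a support), not of the ligamentous vertebral
# column: neck and lumbar junctions are compliant, the rib-cage-backed
# thoracic section is an order of magnitude stiffer (the rib cage and pelvis
# stiffen the trunk), and the whole is soft enough that the supine body
# conforms to a foam mattress instead of bridging like a beam.
.default_stiffness <- function() {
  list(
    k_ax  = c(cervical = 500, thoracic = 1000, lumbar = 1500, other = 2000),
    k_rot = c(cervical = 1e3, thoracic = 1e4, lumbar = 2e3, other = 2.5e3)
  )
}

#' Build the default supine body chain
#'
#' Nodes are placed along a neutral (standing) back profile scaled to the
#' subject height; the spine occupies ~49.4% of stature (the tape length,
#' 870 mm, for the 176 cm reference subject), the legs extend caudally on
#' the baseline.  Masses come from [segment_mass_fractions()]; within the
#' trunk, mass is distributed over the vertebral nodes proportionally to
#' their tributary lengths.
#'
#' @param height_cm subject height (140-210 cm).
#' @param mass_kg subject mass (40-150 kg).
#' @param rest_curve optional [spinal_curve] giving the rest back profile of
#'   the spine portion (cranial end first); default: a neutral profile with
#'   mild cervical/lumbar lordosis (TI 0).  Its length is rescaled to the
#'   subject's spine length.
#' @param widths_mm named contact-width overrides per node group.
#' @param stiffness list with `k_ax`/`k_rot` overrides per joint group.
#' @param ligament_E_kPa named vector of ligament moduli (kPa) used for the
#'   tension-only bridging springs (printed reference values; behind
#'   `ligament_unit_scale` because their literature counterparts are
#'   MPa-scale).
#' @param ligament_unit_scale multiplier applied to the ligament moduli.
#' @param disc_geometry disc geometry table, see [disc_geometry_table()].
#' @return object of class `body_model`.
#' @export
build_default_body <- function(height_cm = 176, mass_kg = 74,
                               rest_curve = NULL,
                               widths_mm = .default_widths(),
                               stiffness = .default_stiffness(),
                               ligament_E_kPa = c(ALL = 11.9, PLL = 12.5,
                                                  FL = 2.4, ISL = 3.4,
                                                  IL = 10, CL = 7.7),
                               ligament_unit_scale = 1,
                               disc_geometry = disc_geometry_table()) {
  if (height_cm < 140 || height_cm > 210) stop("height out of range 140-210 cm")
  if (mass_kg < 40 || mass_kg > 150) stop("mass out of range 40-150 kg")
  H <- height_cm * 10  # mm
  Ls <- 870 / 1760 * H  # spine (tape) arclength scales with stature

  name <- c("head", paste0("C", 1:7), paste0("T", 1:12), paste0("L", 1:5),
            "sacrum", "thigh", "shank", "heel")
  group <- c("head", rep("cervical", 7), rep("thoracic", 12),
             rep("lumbar", 5), "sacrum", "thigh", "shank", "heel")
  # arclength fractions of the spine curve for spine nodes
  sfrac <- c(0.02,
             seq(0.11, 0.19, length.out = 7),
             seq(0.23, 0.55, length.out = 12),
             seq(0.60, 0.72, length.out = 5),
             0.82)
  if (is.null(rest_curve)) {
    sc <- Ls / 870  # lordosis depths scale with stature (geometric similarity)
    rest_curve <- make_profile(TI_deg = 0, HD_mm = 40 * sc, CLD_mm = 45 * sc,
                               LLD_mm = 35 * sc, total_length_mm = Ls)
  } else {
    sc <- Ls / curve_length(rest_curve)
    rest_curve <- spinal_curve(rest_curve$x * sc, rest_curve$y * sc,
                               rest_curve$s * sc)
  }
  sx <- stats::approx(rest_curve$s, rest_curve$x, xout = sfrac * Ls)$y
  sy <- stats::approx(rest_curve$s, rest_curve$y, xout = sfrac * Ls)$y
  x_end <- max(sx)
  leg_x <- x_end + c(0.18, 0.38, 0.52) * H
  x <- c(sx, leg_x)
  y <- c(sy, rep(0, 3))
  n <- length(x)

  # tributary lengths: half-spacing to each neighbour, end nodes one-sided
  dxn <- diff(x)
  trib <- c(dxn[1] / 2,
            (dxn[-(n - 1)] + dxn[-1]) / 2,
            dxn[n - 1] / 2)

  fr <- segment_mass_fractions()
  mass <- numeric(n)
  mass[name == "head"] <- fr["head"] * mass_kg
  # trunk mass split anatomically: neck sliver, thorax (+ lumped arms),
  # abdomen over the lumbar nodes, pelvis on the sacrum node; within each
  # group proportional to tributary length
  trunk_split <- c(cervical = 0.0335, thoracic = 0.4690,
                   lumbar = 0.2010, sacrum = 0.2965)
  for (gname in names(trunk_split)) {
    idx <- which(group == gname)
    w <- trib[idx] / sum(trib[idx])
    mass[idx] <- fr["trunk"] * mass_kg * trunk_split[gname] * w
  }
  mass[name == "thigh"] <- fr["thighs"] * mass_kg
  mass[name == "shank"] <- fr["shanks"] * mass_kg
  mass[name == "heel"] <- fr["feet"] * mass_kg

  width <- unname(widths_mm[group])
  nodes <- data.frame(name = name, group = group, x = x, y_rest = y,
                      mass_kg = mass, width_mm = width, trib_mm = trib,
                      area_mm2 = trib * width)

  # joints between consecutive nodes
  jgroup <- ifelse(group[-n] %in% c("cervical", "thoracic", "lumbar") &
                     group[-1] %in% c("cervical", "thoracic", "lumbar",
                                      "sacrum"),
                   group[-n], "other")
  k_ax <- unname(stiffness$k_ax[ifelse(jgroup %in% names(stiffness$k_ax),
                                       jgroup, "other")])
  L0 <- sqrt(diff(x)^2 + diff(y)^2)
  joints <- data.frame(from = seq_len(n - 1), to = 2:n, group = jgroup,
                       k_ax = k_ax, L0 = L0)

  # rotational stiffness at interior nodes; rest turn angles from rest shape
  ig <- group[2:(n - 1)]
  k_rot <- unname(stiffness$k_rot[ifelse(ig %in% names(stiffness$k_rot),
                                         ig, "other")])
  theta0 <- vapply(2:(n - 1), function(i) {
    .turn_angle(x[i - 1], y[i - 1], x[i], y[i], x[i + 1], y[i + 1])
  }, numeric(1))
  rotations <- data.frame(node = 2:(n - 1), k_rot = k_rot, theta0 = theta0)

  # tension-only ligament springs bridging node i and i+2 along the spine;
  # stiffness E * A / L with an assumed 50 mm^2 cross-section
  spine_last <- which(name == "sacrum")
  lf <- seq_len(spine_last - 2)
  ligE <- mean(ligament_E_kPa) * ligament_unit_scale  # kPa
  Llig <- sqrt((x[lf + 2] - x[lf])^2 + (y[lf + 2] - y[lf])^2)
  ligaments <- data.frame(from = lf, to = lf + 2,
                          k = ligE * 1e-3 * 50 / Llig,  # N/mm
                          L0 = Llig)

  # disc levels <-> vertebral joints C2-C3 ... L5-S1
  vert_idx <- which(name %in% c(paste0("C", 2:7), paste0("T", 1:12),
                                paste0("L", 1:5)))
  disc_joint <- vert_idx  # joint j connects node j to j+1
  stopifnot(length(disc_joint) == nrow(disc_geometry))
  discs <- cbind(disc_geometry, joint = disc_joint)

  structure(list(nodes = nodes, joints = joints, rotations = rotations,
                 ligaments = ligaments, discs = discs,
                 height_cm = height_cm, mass_kg = mass_kg),
            class = "body_model")
}

# signed turn angle at (x2,y2) between segments 1->2 and 2->3
.turn_angle <- function(x1, y1, x2, y2, x3, y3) {
  atan2(y3 - y2, x3 - x2) - atan2(y2 - y1, x2 - x1)
}

#' @export
print.body_model <- function(x, ...) {
  cat("<body_model> ", nrow(x$nodes), " nodes, ", x$height_cm, " cm, ",
      x$mass_kg, " kg (node masses sum to ",
      format(sum(x$nodes$mass_kg), digits = 6), " kg)\n", sep = "")
  invisible(x)
}
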