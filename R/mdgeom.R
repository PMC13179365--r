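# Geometric analysis of enzyme-substrate structures and trajectories.
#
# Frames are plain data.frames with columns resno, resname, atom, x, y, z
# (coordinates in Angstrom); a trajectory is a list of frames. Catalytic
# sub-states of the bound substrate are classified from two distances: the
# nucleophile oxygen of the catalytic serine to the attacked ester carbonyl
# carbon (OG-C), and the oxyanion-hole backbone nitrogen to the carbonyl
# oxygen (N-O). "In-oxyanion" frames have the carbonyl oxygen seated in the
# oxyanion hole (N-O < 5 A); "near-active-site" frames are bound but not
# pre-reactive (OG-C < 5.5 A with N-O in [5, 7.5) A); everything else is
# "other".

#' Construct / validate a coordinate frame
#'
#' @param resno integer residue numbers.
#' @param resname residue names (e.g. "SER", "MHT", "HOH").
#' @param atom atom names (e.g. "CA", "OG").
#' @param x,y,z coordinates in Angstrom.
#' @param box optional length-3 orthorhombic box (Angstrom) for periodic
#'   analyses.
#' @return data.frame of class \code{pk_frame}.
#' @export
md_frame <- function(resno, resname, atom, x, y, z, box = NULL) {
  df <- data.frame(resno = as.integer(resno), resname = as.character(resname),
                   atom = as.character(atom), x = as.numeric(x),
                   y = as.numeric(y), z = as.numeric(z),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)) || any(!is.finite(df$z)))
    stop("coordinates must be finite", call. = FALSE)
  if (anyDuplicated(paste(df$resno, df$atom)))
    stop("(residue number, atom name) pairs must be unique within a frame",
         call. = FALSE)
  if (!is.null(box)) {
    stopifnot(length(box) == 3L, all(box > 0))
    attr(df, "box") <- as.numeric(box)
  }
  class(df) <- c("pk_frame", class(df))
  df
}

# resolve one atom selector (list with resno, atom, optional resname)
# to xyz; errors name the missing selector
atom_xyz <- function(frame, sel, what = "atom") {
  idx <- frame$resno == sel$resno & frame$atom == sel$atom
  if (!is.null(sel$resname)) idx <- idx & frame$resname == sel$resname
  i <- which(idx)
  if (length(i) != 1L)
    stop(sprintf("selector '%s' (%s %s%s) matches %d atoms in the frame",
                 what, sel$atom, sel$resno,
                 if (is.null(sel$resname)) "" else paste0("/", sel$resname),
                 length(i)), call. = FALSE)
  c(frame$x[i], frame$y[i], frame$z[i])
}

#' Distance-based catalytic-state criteria
#'
#' Thresholds in Angstrom. Defaults: the near-active-site state requires
#' OG-C < 5.5 and N-O in [5.0, 7.5); the in-oxyanion state requires
#' N-O < 5.0; all cutoffs are strict on their upper bound, so a tie at
#' exactly 5.0 A goes to near-active-site, and the two states are disjoint
#' by construction.
#'
#' @param d_ser_carbonyl_max OG(Ser)-carbonyl-C upper bound for the bound
#'   state (5.5).
#' @param d_oxyanion_near N(oxyanion)-carbonyl-O range \code{c(lo, hi)} of
#'   the near state (\code{c(5.0, 7.5)}).
#' @param d_oxyanion_in N-O upper bound of the in-oxyanion state (5.0; must
#'   equal \code{d_oxyanion_near[1]} so states are disjoint).
#' @param salt_bridge_cutoff minimum side-chain N-O distance defining a
#'   formed salt bridge (4.0).
#' @param hbond_d_max,hbond_angle_min H-bond geometry thresholds (3.5 A,
#'   120 degrees) used by triad competence checks.
#' @return object of class \code{pk_criteria}.
#' @export
geometric_criteria <- function(d_ser_carbonyl_max = 5.5,
                               d_oxyanion_near = c(5.0, 7.5),
                               d_oxyanion_in = 5.0,
                               salt_bridge_cutoff = 4.0,
                               hbond_d_max = 3.5, hbond_angle_min = 120) {
  stopifnot(d_ser_carbonyl_max > 0, length(d_oxyanion_near) == 2L,
            all(d_oxyanion_near > 0), d_oxyanion_near[1] < d_oxyanion_near[2],
            d_oxyanion_in > 0, salt_bridge_cutoff > 0)
  if (!isTRUE(all.equal(d_oxyanion_in, d_oxyanion_near[1])))
    stop("d_oxyanion_in must equal the lower bound of d_oxyanion_near so the states are disjoint",
         call. = FALSE)
  structure(list(d_ser_carbonyl_max = d_ser_carbonyl_max,
                 d_oxyanion_near = d_oxyanion_near,
                 d_oxyanion_in = d_oxyanion_in,
                 salt_bridge_cutoff = salt_bridge_cutoff,
                 hbond_d_max = hbond_d_max, hbond_angle_min = hbond_angle_min),
            class = "pk_criteria")
}

#' Default atom-selection map for state classification
#'
#' The substrate's attacked-ester atom names are an assumption (they are
#' topology-dependent); override any selector to test alternative readings.
#'
#' @param ser_resno catalytic serine residue number (131).
#' @param oxyanion_resno oxyanion-hole backbone-NH residue number (132).
#' @param substrate_resno substrate residue number (500).
#' @param substrate_resname substrate residue name ("MHT").
#' @param carbonyl_c,carbonyl_o attacked-ester carbonyl atom names
#'   ("C1", "O1").
#' @return named list of selectors.
#' @export
default_selection_map <- function(ser_resno = 131, oxyanion_resno = 132,
                                  substrate_resno = 500,
                                  substrate_resname = "MHT",
                                  carbonyl_c = "C1", carbonyl_o = "O1") {
  list(ser_og = list(resno = ser_resno, atom = "OG"),
       oxyanion_n = list(resno = oxyanion_resno, atom = "N"),
       ester_c = list(resno = substrate_resno, resname = substrate_resname,
                      atom = carbonyl_c),
       ester_o = list(resno = substrate_resno, resname = substrate_resname,
                      atom = carbonyl_o))
}

#' Classify one frame into a catalytic sub-state
#'
#' @param frame \code{pk_frame} (or compatible data.frame).
#' @param criteria \code{pk_criteria}.
#' @param selection selector map as from \code{\link{default_selection_map}}.
#' @return one of \code{"in_oxyanion"}, \code{"near_active_site"},
#'   \code{"other"}; deterministic, and every frame receives exactly one
#'   label.
#' @export
classify_frame <- function(frame, criteria = geometric_criteria(),
                           selection = default_selection_map()) {
  stopifnot(inherits(criteria, "pk_criteria"))
  og <- atom_xyz(frame, selection$ser_og, "ser_og")
  nn <- atom_xyz(frame, selection$oxyanion_n, "oxyanion_n")
  cc <- atom_xyz(frame, selection$ester_c, "ester_c")
  oo <- atom_xyz(frame, selection$ester_o, "ester_o")
  d_no <- sqrt(sum((nn - oo)^2))
  d_ogc <- sqrt(sum((og - cc)^2))
  if (d_no < criteria$d_oxyanion_in) return("in_oxyanion")
  if (d_ogc < criteria$d_ser_carbonyl_max &&
      d_no >= criteria$d_oxyanion_near[1] &&
      d_no < criteria$d_oxyanion_near[2]) return("near_active_site")
  "other"
}

#' Per-state occupancy of a trajectory
#'
#' @param trajectory list of frames.
#' @param criteria \code{pk_criteria}.
#' @param selection selector map.
#' @return object of class \code{pk_state_fractions}: named numeric
#'   (in_oxyanion, near_active_site, other) summing to 1, with attribute
#'   \code{n_frames}.
#' @export
state_fractions <- function(trajectory, criteria = geometric_criteria(),
                            selection = default_selection_map()) {
  if (length(trajectory) == 0L)
    stop("empty trajectory", call. = FALSE)
  labels <- vapply(trajectory, classify_frame, "", criteria = criteria,
                   selection = selection)
  lev <- c("in_oxyanion", "near_active_site", "other")
  frac <- as.numeric(table(factor(labels, levels = lev))) / length(labels)
  structure(setNames(frac, lev), n_frames = length(labels),
            class = "pk_state_fractions")
}

#' @export
print.pk_state_fractions <- function(x, ...) {
  cat(sprintf("<state fractions> (n = %d frames)\n", attr(x, "n_frames")))
  for (nm in names(unclass(x)))
    cat(sprintf("  %-18s %.3f\n", nm, unclass(x)[[nm]]))
  invisible(x)
}

#' Hydrogen-bond geometry with out-of-plane angle
#'
#' Distance is H...acceptor; angle is the donor-H...acceptor angle at the
#' hydrogen (180 degrees = collinear, ideal); the out-of-plane angle is 90
#' degrees minus the angle between the plane normal and the
#' acceptor-to-hydrogen direction, so an in-plane hydrogen gives 0 and a
#' hydrogen along the normal gives +90 (sign follows the normal orientation
#' given by the plane-atom order).
#'
#' @param donor,hydrogen,acceptor length-3 coordinates (Angstrom).
#' @param plane_atoms optional 3x3 matrix (rows = points) defining the
#'   acceptor plane, e.g. the amide N, C, O; must be non-collinear.
#' @return list \code{distance}, \code{angle}, \code{out_of_plane}
#'   (NA when no plane given), class \code{pk_hbond}.
#' @export
hbond_geometry <- function(donor, hydrogen, acceptor, plane_atoms = NULL) {
  stopifnot(length(donor) == 3L, length(hydrogen) == 3L,
            length(acceptor) == 3L)
  v_hd <- donor - hydrogen
  v_ha <- acceptor - hydrogen
  dist <- sqrt(sum(v_ha^2))
  if (dist == 0) stop("hydrogen and acceptor coincide", call. = FALSE)
  cosang <- sum(v_hd * v_ha) / sqrt(sum(v_hd^2)) / dist
  angle <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi

  oop <- NA_real_
  if (!is.null(plane_atoms)) {
    plane_atoms <- matrix(plane_atoms, nrow = 3L, byrow = FALSE)
    n <- pracma_cross(plane_atoms[2, ] - plane_atoms[1, ],
                      plane_atoms[3, ] - plane_atoms[1, ])
    nn <- sqrt(sum(n^2))
    if (nn < 1e-10)
      stop("plane atoms are collinear; no plane defined", call. = FALSE)
    n <- n / nn
    v <- hydrogen - acceptor
    cosn <- sum(n * v) / sqrt(sum(v^2))
    oop <- 90 - acos(pmin(pmax(cosn, -1), 1)) * 180 / pi
  }
  structure(list(distance = dist, angle = angle, out_of_plane = oop),
            class = "pk_hbond")
}

#' @export
print.pk_hbond <- function(x, ...) {
  cat(sprintf("<h-bond> d = %.2f A, angle = %.1f deg, out-of-plane = %s\n",
              x$distance, x$angle,
              if (is.na(x$out_of_plane)) "NA" else
                sprintf("%.1f deg", x$out_of_plane)))
  invisible(x)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Salt-bridge occupancy across a trajectory
#'
#' Fraction of frames whose minimum distance between the basic residue's
#' side-chain nitrogen(s) and the acidic residue's carboxylate oxygen(s) is
#' at or below the cutoff. Defaults suit Lys (NZ) against Asp (OD1/OD2).
#'
#' @param trajectory list of frames.
#' @param basic_resno residue number of the basic partner.
#' @param acidic_resno residue number of the acidic partner.
#' @param basic_atoms side-chain N atom names (default \code{"NZ"}; use
#'   \code{c("NE","NH1","NH2")} for Arg).
#' @param acidic_atoms carboxylate O atom names (default
#'   \code{c("OD1","OD2")}; use \code{c("OE1","OE2")} for Glu).
#' @param cutoff contact cutoff in Angstrom (default 4.0).
#' @return fraction in [0, 1] with attribute \code{n_frames}.
#' @export
salt_bridge_occupancy <- function(trajectory, basic_resno, acidic_resno,
                                  basic_atoms = "NZ",
                                  acidic_atoms = c("OD1", "OD2"),
                                  cutoff = 4.0) {
  if (length(trajectory) == 0L) stop("empty trajectory", call. = FALSE)
  .check_number(cutoff, "cutoff", positive = TRUE)
  hit <- vapply(trajectory, function(fr) {
    bi <- fr$resno == basic_resno & fr$atom %in% basic_atoms
    ai <- fr$resno == acidic_resno & fr$atom %in% acidic_atoms
    if (!any(bi))
      stop(sprintf("no side-chain atom of %s found for residue %d",
                   paste(basic_atoms, collapse = "/"), basic_resno),
           call. = FALSE)
    if (!any(ai))
      stop(sprintf("no carboxylate atom of %s found for residue %d",
                   paste(acidic_atoms, collapse = "/"), acidic_resno),
           call. = FALSE)
    B <- as.matrix(fr[bi, c("x", "y", "z")])
    A <- as.matrix(fr[ai, c("x", "y", "z")])
    dmin <- min(sqrt(outer(rowSums(B^2), rowSums(A^2), "+") -
                       2 * B %*% t(A)))
    dmin <= cutoff
  }, TRUE)
  structure(mean(hit), n_frames = length(hit))
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention: looking down the p2-p3 bond, a clockwise rotation
#' of p4 relative to p1 is positive; range (-180, 180]. A mirror image
#' negates the angle.
#'
#' @param p1,p2,p3,p4 length-3 coordinates.
#' @return dihedral in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi angles of a residue
#'
#' phi = C(i-1)-N-CA-C, psi = N-CA-C-N(i+1). Chain termini (missing
#' neighbour atoms) raise an error naming the missing atom.
#'
#' @param frame \code{pk_frame}.
#' @param resno residue number.
#' @return named numeric \code{c(phi, psi)} in degrees.
#' @export
phi_psi <- function(frame, resno) {
  g <- function(rn, at) atom_xyz(frame, list(resno = rn, atom = at),
                                 paste0(at, rn))
  c_prev <- g(resno - 1L, "C")
  n <- g(resno, "N"); ca <- g(resno, "CA"); cc <- g(resno, "C")
  n_next <- g(resno + 1L, "N")
  c(phi = dihedral(c_prev, n, ca, cc), psi = dihedral(n, ca, cc, n_next))
}

#' Radial distribution function of water oxygens around a site
#'
#' Histogram of site-to-oxygen distances normalised by ideal-gas shell
#' counts. With a periodic orthorhombic box (frame attribute \code{box} or
#' the \code{box} argument) distances use the minimum-image convention and
#' the density is N_water / V. Without a box, an open-boundary mode
#' normalises against the mean density inside the \code{r_max} sphere.
#'
#' @param trajectory list of frames.
#' @param ref_sel selector for the reference site (list with resno/atom).
#' @param water_resname water residue name (default "HOH").
#' @param water_atom water oxygen atom name (default "O").
#' @param r_max histogram range, Angstrom (default 10).
#' @param bin_width bin width, Angstrom (default 0.2).
#' @param box optional length-3 box; overrides the frame attribute.
#' @return data.frame \code{r} (bin centers), \code{g} of class
#'   \code{pk_rdf}.
#' @export
water_rdf <- function(trajectory, ref_sel, water_resname = "HOH",
                      water_atom = "O", r_max = 10, bin_width = 0.2,
                      box = NULL) {
  if (length(trajectory) == 0L) stop("empty trajectory", call. = FALSE)
  breaks <- seq(0, r_max, by = bin_width)
  if (max(breaks) < r_max) breaks <- c(breaks, r_max)
  counts <- numeric(length(breaks) - 1L)
  dens <- numeric(length(trajectory))
  for (k in seq_along(trajectory)) {
    fr <- trajectory[[k]]
    b <- if (!is.null(box)) box else attr(fr, "box")
    ref <- atom_xyz(fr, ref_sel, "ref_site")
    wi <- fr$resname == water_resname & fr$atom == water_atom
    if (!any(wi)) stop("no water oxygens selected", call. = FALSE)
    W <- as.matrix(fr[wi, c("x", "y", "z")])
    dx <- sweep(W, 2, ref)
    if (!is.null(b)) {
      for (j in 1:3) dx[, j] <- dx[, j] - b[j] * round(dx[, j] / b[j])
      dens[k] <- nrow(W) / prod(b)
    } else {
      dens[k] <- nrow(W) / (4 / 3 * pi * r_max^3)
    }
    d <- sqrt(rowSums(dx^2))
    counts <- counts + graphics::hist(d[d < max(breaks)], breaks = breaks,
                                      plot = FALSE)$counts
  }
  shell <- 4 / 3 * pi * (breaks[-1]^3 - breaks[-length(breaks)]^3)
  expected <- shell * mean(dens) * length(trajectory)
  out <- data.frame(r = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    g = counts / expected)
  class(out) <- c("pk_rdf", class(out))
  out
}

#' Kabsch superposition and RMSD
#'
#' Least-squares optimal rigid superposition of the mobile structure onto
#' the reference over atoms paired by (residue number, atom name). A proper
#' rotation is enforced (reflections rejected via the determinant sign
#' correction).
#'
#' @param ref,mob frames (\code{pk_frame} or compatible data.frames).
#' @param select optional atom-name filter, e.g. \code{"CA"}; \code{NULL}
#'   uses all shared atoms.
#' @return object of class \code{pk_superposition}: \code{rotation} (3x3),
#'   \code{translation} (applied after rotation), \code{rmsd} (Angstrom),
#'   \code{n_matched}, and \code{transform(xyz)} mapping mobile coordinates
#'   onto the reference frame.
#' @export
kabsch_superpose <- function(ref, mob, select = NULL) {
  key <- function(fr) paste(fr$resno, fr$atom, sep = "_")
  kr <- key(ref); km <- key(mob)
  keep_r <- rep(TRUE, nrow(ref)); keep_m <- rep(TRUE, nrow(mob))
  if (!is.null(select)) {
    keep_r <- ref$atom %in% select
    keep_m <- mob$atom %in% select
  }
  shared <- intersect(kr[keep_r], km[keep_m])
  if (length(shared) < 3L)
    stop(sprintf("only %d matched atoms; need at least 3", length(shared)),
         call. = FALSE)
  P <- as.matrix(mob[match(shared, km), c("x", "y", "z")])  # mobile
  Q <- as.matrix(ref[match(shared, kr), c("x", "y", "z")])  # reference
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Pr <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pr - Qc)^2)))
  translation <- cq - as.numeric(R %*% cp)
  transform <- function(xyz) {
    xyz <- matrix(xyz, ncol = 3L)
    sweep(xyz %*% t(R), 2, translation, "+")
  }
  structure(list(rotation = R, translation = translation, rmsd = rmsd,
                 n_matched = length(shared), transform = transform),
            class = "pk_superposition")
}

#' @export
print.pk_superposition <- function(x, ...) {
  cat(sprintf("<superposition> RMSD = %.3f A over %d matched atoms\n",
              x$rmsd, x$n_matched))
  invisible(x)
}
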