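#' Least-squares rigid superposition of labeled point sets
#'
#' Kabsch superposition: pairs points by the intersection of their labels,
#' then finds the proper rotation and translation minimizing the summed
#' squared deviation of the mobile set from the reference. The singular
#' value decomposition solution guarantees a proper rotation (no
#' reflection).
#'
#' @param mobile,reference \code{calpha_set} data frames (or any data frame
#'   with \code{label}, \code{x}, \code{y}, \code{z} columns).
#' @return A list of class \code{superposition}: \code{transform}
#'   (\code{rigid_transform} mapping mobile onto reference), \code{rmsd}
#'   (Angstrom, over the paired points after transformation), \code{n}
#'   (number of pairs), \code{labels} (paired labels),
#'   \code{excluded_mobile}, \code{excluded_reference} (unpaired labels).
#' @export
kabsch_superpose <- function(mobile, reference) {
  common <- intersect(mobile$label, reference$label)
  if (length(common) < 3)
    stop("need at least 3 paired points; label intersection has ",
         length(common))
  im <- match(common, mobile$label)
  ir <- match(common, reference$label)
  M <- ca_xyz(mobile)[im, , drop = FALSE]
  R <- ca_xyz(reference)[ir, , drop = FALSE]
  cm <- colMeans(M); cr <- colMeans(R)
  Mc <- sweep(M, 2, cm); Rc <- sweep(R, 2, cr)
  sv_m <- svd(Mc)$d
  if (sv_m[2] < 1e-8 * max(sv_m[1], 1e-12))
    stop("degenerate point set: paired points are collinear")
  H <- crossprod(Mc, Rc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tf <- rigid_transform(rot, cr - as.numeric(rot %*% cm))
  dev2 <- rowSums((apply_transform(M, tf) - R)^2)
  structure(list(transform = tf, rmsd = sqrt(mean(dev2)), n = length(common),
                 labels = common,
                 excluded_mobile = setdiff(mobile$label, common),
                 excluded_reference = setdiff(reference$label, common)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition over %d paired C-alpha: RMSD %.3f A (%d/%d unpaired)\n",
              x$n, x$rmsd, length(x$excluded_mobile), length(x$excluded_reference)))
  invisible(x)
}

#' Per-residue deviation after superposition
#'
#' Deviation of each paired residue after applying a rigid transform to the
#' mobile set; the root mean square of the returned deviations equals the
#' superposition RMSD of the same pairing.
#'
#' @param mobile,reference labeled point sets as in
#'   \code{\link{kabsch_superpose}}.
#' @param transform the \code{rigid_transform} to apply to \code{mobile}.
#' @return Data frame with \code{label}, \code{chain}, \code{resno},
#'   \code{segment}, \code{deviation} (Angstrom).
#' @export
per_residue_deviation <- function(mobile, reference, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  common <- intersect(mobile$label, reference$label)
  if (!length(common)) stop("no paired labels")
  im <- match(common, mobile$label)
  ir <- match(common, reference$label)
  M <- apply_transform(ca_xyz(mobile)[im, , drop = FALSE], transform)
  R <- ca_xyz(reference)[ir, , drop = FALSE]
  data.frame(label = common,
             chain = mobile$chain[im], resno = mobile$resno[im],
             segment = if ("segment" %in% names(mobile)) mobile$segment[im] else NA,
             deviation = sqrt(rowSums((M - R)^2)),
             stringsAsFactors = FALSE)
}

#' Fit the axis of a helical segment
#'
#' The C-alpha trace is smoothed with a running average over one helical
#' turn (default window 4 residues) to suppress the periodic wobble of the
#' helix, and the axis is taken as the first principal component of the
#' smoothed, centered trace. The direction sign is chosen so that the axis
#' points from the N- toward the C-terminus.
#'
#' @param points a \code{calpha_set} (or matrix-convertible data frame) of
#'   one segment, in residue order.
#' @param window smoothing window in residues.
#' @return A list of class \code{axis_fit}: \code{direction} (unit vector),
#'   \code{centroid}.
#' @export
fit_helix_axis <- function(points, window = 4) {
  xyz <- if (is.data.frame(points)) ca_xyz(points) else as.matrix(points)
  n <- nrow(xyz)
  if (n < 5) stop("helix axis fit needs at least 5 residues; got ", n)
  w <- min(window, n)
  sm <- apply(xyz, 2, function(v) stats::filter(v, rep(1 / w, w), sides = 2))
  sm <- sm[stats::complete.cases(sm), , drop = FALSE]
  ctr <- colMeans(sm)
  dir <- svd(sweep(sm, 2, ctr))$v[, 1]
  nc <- sm[nrow(sm), ] - sm[1, ]  # N-to-C vector of the smoothed trace
  if (sum(dir * nc) < 0) dir <- -dir
  structure(list(direction = unitize(dir), centroid = ctr), class = "axis_fit")
}

#' Estimate the membrane normal from transmembrane helix axes
#'
#' Fits an axis to each requested TM segment, sign-aligns every axis to the
#' first (flipping those that point the opposite way, as expected for an
#' antiparallel bundle), and returns the normalized mean direction. Errors
#' when the axes have no consensus direction (mean resultant length below
#' 0.5).
#'
#' @param s an \code{atom_table}.
#' @param segments a \code{segment_table} of TM segments (at least 2).
#' @param chain chain to use; default first chain.
#' @param orient optional reference vector; the returned normal is flipped
#'   if needed so its dot product with \code{orient} is positive (use to fix
#'   which side is extracellular).
#' @return Unit length-3 vector.
#' @export
estimate_membrane_normal <- function(s, segments, chain = NULL, orient = NULL) {
  if (nrow(segments) < 2) stop("need at least 2 TM segments")
  ca <- select_calpha(s, chain = chain, segments = segments)
  axes <- t(vapply(segments$segment, function(nm) {
    fit_helix_axis(ca[!is.na(ca$segment) & ca$segment == nm, , drop = FALSE])$direction
  }, numeric(3)))
  flip <- axes %*% axes[1, ] < 0
  axes[flip, ] <- -axes[flip, , drop = FALSE]
  m <- colMeans(axes)
  if (sqrt(sum(m^2)) < 0.5)
    stop("no consensus normal: helix axes are mutually near-orthogonal ",
         "(mean resultant length ", round(sqrt(sum(m^2)), 3), " < 0.5)")
  m <- unitize(m)
  if (!is.null(orient) && sum(m * orient) < 0) m <- -m
  m
}

#' Decompose the inter-domain motion between two conformations
#'
#' Quantifies how the transport domain moves relative to the scaffold
#' domain between two structures of the same protein. Structure \code{b} is
#' first superposed onto \code{a} on the scaffold C-alpha atoms (the
#' scaffold frame); the residual rigid transform of the transport domain is
#' then decomposed into a tilt angle (from the rotation trace) and a
#' translation of the transport-domain centroid, split into components
#' along and perpendicular to the membrane normal. Per-segment axis-angle
#' changes and per-site centroid displacements are measured in the same
#' scaffold frame.
#'
#' @param a,b \code{atom_table} structures of the two conformations.
#' @param segments a \code{segment_table} (applies to both structures).
#' @param scaffold,transport \code{domain_definition}s.
#' @param chain_a,chain_b chains to compare; default first chain of each.
#' @param normal membrane normal (unit vector); estimated from the scaffold
#'   helices of \code{a} when \code{NULL}. Positive direction is reported as
#'   "extracellular".
#' @param sites optional list of \code{site_definition}s whose centroid
#'   displacement is reported.
#' @param tm4_split optional name of a segment whose cytoplasmic half's
#'   angle change is additionally reported (the half of the segment on the
#'   negative-normal side of the scaffold centroid).
#' @return A list of class \code{motion_report}; see fields in the print
#'   method: overall RMSD, along-normal and in-plane translation, tilt,
#'   per-segment angle changes, per-site displacements.
#' @export
domain_motion <- function(a, b, segments, scaffold, transport,
                          chain_a = NULL, chain_b = NULL, normal = NULL,
                          sites = NULL, tm4_split = NULL) {
  stopifnot(inherits(scaffold, "domain_definition"),
            inherits(transport, "domain_definition"))
  if (length(intersect(scaffold$members, transport$members)))
    stop("scaffold and transport domains must be disjoint")
  ca_a <- select_calpha(a, chain = chain_a, segments = segments)
  ca_b <- select_calpha(b, chain = chain_b, segments = segments)
  if (is.null(chain_a)) chain_a <- ca_a$chain[1]
  if (is.null(chain_b)) chain_b <- ca_b$chain[1]
  # pair across chains by residue number: relabel b with a's chain id
  ca_b$label <- paste0(chain_a, ":", ca_b$resno, ca_b$insert)

  pick <- function(ca, dom) {
    out <- ca[!is.na(ca$segment) & ca$segment %in% dom$members, , drop = FALSE]
    if (nrow(out) < 3)
      stop("domain '", dom$name, "' has fewer than 3 resolved C-alpha")
    out
  }
  sc_a <- pick(ca_a, scaffold); sc_b <- pick(ca_b, scaffold)
  tr_a <- pick(ca_a, transport); tr_b <- pick(ca_b, transport)
  miss <- setdiff(union(sc_a$label, tr_a$label), union(sc_b$label, tr_b$label))

  # overall superposition (all segment residues) for the headline RMSD
  overall <- kabsch_superpose(ca_b, ca_a)

  # (1) scaffold frame
  sup_sc <- kabsch_superpose(sc_b, sc_a)
  move_b <- function(ca) { ca[, c("x","y","z")] <- apply_transform(ca_xyz(ca), sup_sc$transform); ca }
  ca_b2 <- move_b(ca_b); tr_b2 <- move_b(tr_b)

  if (is.null(normal)) {
    seg_sc <- segments[segments$segment %in% scaffold$members &
                         segments$chain == chain_a, , drop = FALSE]
    normal <- estimate_membrane_normal(a, seg_sc, chain = chain_a)
  }
  normal <- unitize(normal)

  # (2) residual transport-domain transform, a -> b in the scaffold frame
  sup_tr <- kabsch_superpose(tr_a, tr_b2)
  common <- intersect(tr_a$label, tr_b2$label)
  cen_a <- colMeans(ca_xyz(tr_a)[match(common, tr_a$label), , drop = FALSE])
  cen_b <- colMeans(ca_xyz(tr_b2)[match(common, tr_b2$label), , drop = FALSE])
  shift <- cen_b - cen_a
  along <- sum(shift * normal)
  inplane <- sqrt(max(0, sum(shift^2) - along^2))
  tilt <- rotation_angle(sup_tr$transform$rotation)

  # (3) per-segment axis angle changes in the scaffold frame
  seg_angles <- vapply(segments$segment, function(nm) {
    pa <- ca_a[!is.na(ca_a$segment) & ca_a$segment == nm, , drop = FALSE]
    pb <- ca_b2[!is.na(ca_b2$segment) & ca_b2$segment == nm, , drop = FALSE]
    if (nrow(pa) < 5 || nrow(pb) < 5) return(NA_real_)
    vec_angle(fit_helix_axis(pa)$direction, fit_helix_axis(pb)$direction)
  }, numeric(1))

  # optional: angle change of the cytoplasmic half of one segment
  half_angle <- NULL
  if (!is.null(tm4_split)) {
    mid <- sum(colMeans(ca_xyz(sc_a)) * normal)  # membrane mid-plane height
    # the half is defined once, on structure a, and the same residues are
    # compared in b: the quantity is the reorientation of a fixed stretch
    seg_a <- ca_a[!is.na(ca_a$segment) & ca_a$segment == tm4_split, , drop = FALSE]
    cyto <- seg_a$resno[as.numeric(ca_xyz(seg_a) %*% normal) <= mid]
    lower <- function(ca) {
      p <- ca[!is.na(ca$segment) & ca$segment == tm4_split, , drop = FALSE]
      p[p$resno %in% cyto, , drop = FALSE]
    }
    pa <- lower(ca_a); pb <- lower(ca_b2)
    if (nrow(pa) >= 5 && nrow(pb) >= 5)
      half_angle <- vec_angle(fit_helix_axis(pa)$direction,
                              fit_helix_axis(pb)$direction)
  }

  site_disp <- NULL
  if (!is.null(sites)) {
    b2 <- b
    b2[, c("x","y","z")] <- apply_transform(as.matrix(b[, c("x","y","z")]),
                                            sup_sc$transform)
    site_disp <- vapply(sites, function(st) {
      ca_cent <- site_centroid(a, st)
      cb_cent <- site_centroid(b2, st, chain_map = function(ch) chain_b)
      sqrt(sum((cb_cent - ca_cent)^2))
    }, numeric(1))
    names(site_disp) <- vapply(sites, `[[`, "", "name")
  }

  structure(list(
    overall_rmsd = overall$rmsd,
    scaffold_rmsd = sup_sc$rmsd,
    transport_residual_rmsd = sup_tr$rmsd,
    translation = shift, along_normal = along, in_plane = inplane,
    tilt = tilt, normal = normal,
    segment_angles = seg_angles,
    half_segment_angle = half_angle, half_segment = tm4_split,
    site_displacements = site_disp,
    n_scaffold = sup_sc$n, n_transport = sup_tr$n,
    missing_in_b = miss
  ), class = "motion_report")
}

#' @export
print.motion_report <- function(x, ...) {
  dirword <- if (x$along_normal >= 0) "extracellular" else "cytoplasmic"
  cat(sprintf("Inter-domain motion (scaffold frame, %d scaffold / %d transport C-alpha)\n",
              x$n_scaffold, x$n_transport))
  cat(sprintf("  overall RMSD:         %6.2f A\n", x$overall_rmsd))
  cat(sprintf("  translation:          %6.2f A %s (%.2f A in-plane)\n",
              abs(x$along_normal), dirword, x$in_plane))
  cat(sprintf("  tilt:                 %6.2f deg\n", x$tilt))
  if (!is.null(x$half_segment_angle))
    cat(sprintf("  %s cytoplasmic half:  %5.2f deg\n", x$half_segment,
                x$half_segment_angle))
  if (!is.null(x$site_displacements))
    for (nm in names(x$site_displacements))
      cat(sprintf("  site '%s' displacement: %.2f A\n", nm,
                  x$site_displacements[[nm]]))
  invisible(x)
}

#' Write a motion report as delimited text
#'
#' One metric per row: \code{name}, \code{value}, \code{units}.
#'
#' @param x a \code{motion_report}.
#' @param path output path.
#' @export
write_motion_report <- function(x, path) {
  rows <- data.frame(
    name = c("overall_rmsd", "scaffold_rmsd", "along_normal_translation",
             "in_plane_translation", "tilt",
             paste0("angle_change_", names(x$segment_angles))),
    value = c(x$overall_rmsd, x$scaffold_rmsd, x$along_normal, x$in_plane,
              x$tilt, unname(x$segment_angles)),
    units = c("A", "A", "A", "A", "deg", rep("deg", length(x$segment_angles))),
    stringsAsFactors = FALSE)
  if (!is.null(x$half_segment_angle))
    rows <- rbind(rows, data.frame(
      name = paste0("angle_change_", x$half_segment, "_cytoplasmic_half"),
      value = x$half_segment_angle, units = "deg"))
  if (!is.null(x$site_displacements))
    rows <- rbind(rows, data.frame(
      name = paste0("site_displacement_", gsub("\\s+", "_", names(x$site_displacements))),
      value = unname(x$site_displacements), units = "A"))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
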