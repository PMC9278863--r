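#' Specification of a synthetic transmembrane helix bundle
#'
#' Defines an idealized multi-pass membrane protein: ideal alpha-helical
#' C-alpha traces (rise 1.5 A/residue, twist 100 deg/residue, helix radius
#' 2.3 A) standing on a circle in the membrane plane, with the membrane
#' normal along +z, alternating up/down orientation as in an antiparallel
#' TM bundle, and the helices grouped into two rigid-body domains. With the
#' default eight helices the domain assignment mirrors the elevator-fold
#' convention: helices 1, 4, 5 and 6 form the mobile transport domain and
#' 2, 3, 7, 8 the static scaffold.
#'
#' @param n_helices number of helices (>= 2).
#' @param n_res residues per helix (default 25, a typical TM length).
#' @param rise helical rise per residue (Angstrom).
#' @param twist helical twist per residue (degrees).
#' @param helix_radius C-alpha radius of the ideal helix (Angstrom).
#' @param bundle_radius radius of the circle the helix axes stand on
#'   (Angstrom); the default 12.5 gives ~9.6 A spacing between adjacent
#'   axes of an 8-helix bundle.
#' @param antiparallel alternate helix orientation up/down (default TRUE).
#' @param transport_helices indices of the helices forming the mobile
#'   domain; default \code{c(1, 4, 5, 6)} for 8 helices, the first half
#'   otherwise.
#' @param noise_sd isotropic Gaussian coordinate noise (Angstrom, >= 0).
#' @param seed integer seed fixing the output exactly.
#' @return A list of class \code{bundle_spec}.
#' @export
bundle_spec <- function(n_helices = 8, n_res = 25, rise = 1.5, twist = 100,
                        helix_radius = 2.3, bundle_radius = 12.5,
                        antiparallel = TRUE, transport_helices = NULL,
                        noise_sd = 0, seed = 1) {
  if (n_helices < 2) stop("need at least 2 helices")
  if (helix_radius <= 0 || bundle_radius <= 0) stop("radii must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(transport_helices))
    transport_helices <- if (n_helices == 8) c(1, 4, 5, 6)
                         else seq_len(floor(n_helices / 2))
  if (!all(transport_helices %in% seq_len(n_helices)))
    stop("transport_helices out of range")
  structure(list(n_helices = n_helices, n_res = n_res, rise = rise,
                 twist = twist, helix_radius = helix_radius,
                 bundle_radius = bundle_radius, antiparallel = antiparallel,
                 transport_helices = sort(transport_helices),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "bundle_spec")
}

#' Generate a synthetic helix bundle with known domain structure
#'
#' Builds the C-alpha trace described by a \code{\link{bundle_spec}}. The
#' helices are labeled "TM1".."TMn" with consecutive author numbering
#' (5-residue gaps between helices) on chain A; the noise-free coordinates
#' are retained in the \code{"xyz_ideal"} attribute so that independently
#' re-noised copies can be drawn.
#'
#' @param spec a \code{bundle_spec}.
#' @return A list: \code{structure} (\code{atom_table}), \code{segments}
#'   (\code{segment_table}), \code{transport} and \code{scaffold}
#'   (\code{domain_definition}s), \code{spec}.
#' @export
make_bundle <- function(spec) {
  stopifnot(inherits(spec, "bundle_spec"))
  n <- spec$n_helices; m <- spec$n_res
  helix <- function(h) {
    k <- 0:(m - 1)
    th <- (k * spec$twist) * pi / 180
    local <- cbind(spec$helix_radius * cos(th),
                   spec$helix_radius * sin(th),
                   (k - (m - 1) / 2) * spec$rise)
    if (spec$antiparallel && h %% 2 == 0) {
      # flip by a 180 deg rotation about the local x axis: N terminus up
      local <- local %*% diag(c(1, -1, -1))
    }
    phi <- 2 * pi * (h - 1) / n
    sweep(local, 2, -c(spec$bundle_radius * cos(phi),
                       spec$bundle_radius * sin(phi), 0))
  }
  xyz <- do.call(rbind, lapply(seq_len(n), helix))
  starts <- (seq_len(n) - 1) * (m + 5) + 1
  resno <- as.integer(unlist(lapply(starts, function(s) s:(s + m - 1))))
  xyz_ideal <- xyz
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = spec$noise_sd),
                        ncol = 3)
  }
  s <- atom_table(chain = "A", resno = resno,
                  x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  attr(s, "xyz_ideal") <- xyz_ideal
  segs <- segment_table(paste0("TM", seq_len(n)), "A", starts, starts + m - 1)
  tr <- spec$transport_helices
  list(structure = s, segments = segs,
       transport = domain_definition("transport", paste0("TM", tr), segs),
       scaffold = domain_definition("scaffold",
                                    paste0("TM", setdiff(seq_len(n), tr)), segs),
       spec = spec)
}

#' Specification of a rigid domain motion
#'
#' @param translation signed displacement along the membrane normal (+z)
#'   in Angstrom; negative = toward the cytoplasmic side.
#' @param rotation_deg tilt angle in degrees about an in-plane axis through
#'   the moving-domain C-alpha centroid.
#' @param rotation_axis in-plane rotation axis (default x).
#' @param moving_domain \code{"transport"} or \code{"scaffold"}.
#' @param renoise if TRUE, the motion is applied to the noise-free
#'   coordinates and fresh noise (the bundle's \code{noise_sd}) is drawn
#'   for the moved copy, emulating two independently determined
#'   experimental structures; if FALSE (default) the already-noisy
#'   coordinates are moved rigidly, so the recorded ground truth is exactly
#'   retrievable from the pair.
#' @param seed seed for the fresh noise draw when \code{renoise}.
#' @return A list of class \code{motion_spec}.
#' @export
motion_spec <- function(translation = 3, rotation_deg = 0,
                        rotation_axis = c(1, 0, 0),
                        moving_domain = "transport", renoise = FALSE,
                        seed = 2) {
  structure(list(translation = translation, rotation_deg = rotation_deg,
                 rotation_axis = unitize(rotation_axis),
                 moving_domain = moving_domain, renoise = renoise,
                 seed = as.integer(seed)),
            class = "motion_spec")
}

#' Apply a known rigid motion to one domain of a synthetic bundle
#'
#' Rotates the moving domain by \code{rotation_deg} about an in-plane axis
#' through its C-alpha centroid, then translates it along +z; all other
#' helices stay put. The exact applied transform is recorded in the
#' \code{"ground_truth"} attribute of the returned structure.
#'
#' @param bundle a bundle as returned by \code{\link{make_bundle}}.
#' @param m a \code{motion_spec}.
#' @return The moved \code{atom_table}, with attribute
#'   \code{"ground_truth"} = list(translation, translation_vec, rotation,
#'   rotation_deg, moving_domain).
#' @export
apply_motion <- function(bundle, m) {
  stopifnot(inherits(m, "motion_spec"))
  s <- bundle$structure
  dom <- switch(m$moving_domain, transport = bundle$transport,
                scaffold = bundle$scaffold,
                stop("unknown moving domain '", m$moving_domain, "'"))
  seg <- assign_segments(s, bundle$segments)
  moving <- !is.na(seg) & seg %in% dom$members
  if (!any(moving)) stop("moving domain has no atoms")
  xyz <- as.matrix(s[, c("x", "y", "z")])
  if (m$renoise) {
    xyz <- attr(s, "xyz_ideal")
    if (is.null(xyz)) stop("bundle lacks ideal coordinates; cannot renoise")
  }
  rot <- rotation_about_axis(m$rotation_axis, m$rotation_deg)
  tvec <- c(0, 0, m$translation)
  ctr <- colMeans(xyz[moving, , drop = FALSE])
  moved <- sweep(sweep(xyz[moving, , drop = FALSE], 2, ctr) %*% t(rot), 2,
                 -(ctr + tvec))
  xyz[moving, ] <- moved
  if (m$renoise && bundle$spec$noise_sd > 0) {
    set.seed(m$seed)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = bundle$spec$noise_sd),
                        ncol = 3)
  }
  out <- s
  out[, c("x", "y", "z")] <- xyz
  attr(out, "xyz_ideal") <- NULL
  attr(out, "ground_truth") <- list(
    translation = m$translation, translation_vec = tvec,
    rotation = rot, rotation_deg = m$rotation_deg,
    moving_domain = m$moving_domain)
  out
}

#' Generate a synthetic coupling table with planted contact classes
#'
#' Samples residue pairs of three classes from a bundle's monomer geometry
#' and assigns them scores mimicking a coevolution server's output:
#' \itemize{
#'   \item true contacts: C-alpha distance <= \code{contact_cutoff},
#'     scores uniform in [0.9, 1.0] (significant, satisfied);
#'   \item decoys: distance in [10, 15) A, scores uniform in [0.3, 0.9)
#'     (not significant);
#'   \item "interface" pairs: distance >= 15 A, scores uniform in
#'     [0.9, 1.0] (significant but unsatisfiable in the monomer -- the
#'     planted oligomer-interface / alternative-state class).
#' }
#' All sampled pairs respect the sequence-separation filter
#' (\code{|i - j| >= 5}) of the contact analysis.
#'
#' @param bundle a bundle from \code{\link{make_bundle}}.
#' @param n_true,n_decoy,n_interface class sizes.
#' @param contact_cutoff distance defining a true contact (default 8 A).
#' @param seed integer seed; the same seed gives a byte-identical table.
#' @param path optional file to write the table to (CSV \code{i,j,score});
#'   a sidecar \code{<path>.labels} records the planted class of each pair.
#' @return Data frame \code{i}, \code{j}, \code{score}, \code{class} (the
#'   planted label), invisibly written to \code{path} if given.
#' @export
make_couplings <- function(bundle, n_true = 20, n_decoy = 30, n_interface = 5,
                           contact_cutoff = 8, seed = 1, path = NULL) {
  ca <- select_calpha(bundle$structure, segments = bundle$segments)
  dm <- distance_matrix(ca)
  n <- nrow(ca)
  ut <- which(upper.tri(dm), arr.ind = TRUE)
  sep_ok <- abs(ca$resno[ut[, 1]] - ca$resno[ut[, 2]]) >= 5
  d <- dm[ut]
  pool <- function(cond, n_want, cls) {
    cand <- which(cond & sep_ok)
    if (length(cand) < n_want)
      stop("cannot sample ", n_want, " '", cls, "' pairs; only ",
           length(cand), " candidates")
    cand[sample.int(length(cand), n_want)]
  }
  set.seed(seed)
  ix <- c(pool(d <= contact_cutoff, n_true, "true"),
          pool(d >= 10 & d < 15, n_decoy, "decoy"),
          pool(d >= 15, n_interface, "interface"))
  cls <- rep(c("true", "decoy", "interface"),
             c(n_true, n_decoy, n_interface))
  score <- c(stats::runif(n_true, 0.9, 1.0),
             stats::runif(n_decoy, 0.3, 0.9),
             stats::runif(n_interface, 0.9, 1.0))
  out <- data.frame(
    i = pmin(ca$resno[ut[ix, 1]], ca$resno[ut[ix, 2]]),
    j = pmax(ca$resno[ut[ix, 1]], ca$resno[ut[ix, 2]]),
    score = round(score, 6), class = cls, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$i, out$j), ]
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.csv(out[, c("i", "j", "score")], path, row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(out, paste0(path, ".labels"), row.names = FALSE,
                     quote = FALSE)
  }
  out
}

#' Write the ground truth of a synthetic pair as flat key/value text
#'
#' @param gt the \code{"ground_truth"} attribute of a moved structure.
#' @param path output path.
#' @export
write_ground_truth <- function(gt, path) {
  lines <- c(
    paste0("moving_domain=", gt$moving_domain),
    paste0("translation_A=", gt$translation),
    paste0("rotation_deg=", gt$rotation_deg),
    paste0("rotation_matrix=", paste(signif(gt$rotation, 12), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}
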