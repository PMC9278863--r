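#' Constraint sets for state modeling
#'
#' An ordered list of residue pairs whose mutual distances the modeled
#' state should minimize -- typically significant coupling pairs that are
#' unsatisfied in the starting conformation, with one residue on the moving
#' transport domain and one on the static scaffold.
#'
#' @param i,j parallel integer vectors of author residue numbers.
#' @return Data frame of class \code{constraint_set}.
#' @export
constraint_set <- function(i, j) {
  df <- data.frame(i = as.integer(i), j = as.integer(j))
  if (any(df$i == df$j)) stop("a constraint must link two distinct residues")
  class(df) <- c("constraint_set", "data.frame")
  df
}

#' Rigid translation scan of the transport domain
#'
#' Emulates the construction of an alternative (outward-facing) state of an
#' elevator transporter: the transport domain is translated rigidly along
#' the membrane normal in fixed steps, and at each step the objective --
#' the sum of C-alpha distances over the constraint pairs -- is evaluated.
#' The returned scan holds the full profile, the minimizing translation
#' (ties broken toward the smallest step) and the modeled structure at the
#' minimum; a minimum at the end of the scanned range is flagged as a
#' boundary minimum. The model is purely geometric: no minimization or
#' clash relief is performed, and clashes across the domain boundary are
#' counted, not removed.
#'
#' @param s an \code{atom_table} of the starting conformation.
#' @param segments a \code{segment_table}.
#' @param transport \code{domain_definition} of the moving domain.
#' @param constraints a \code{constraint_set}; exactly one residue of each
#'   pair should sit on the moving domain (pairs with both or neither
#'   residue moving have translation-invariant distances and trigger a
#'   warning but are retained).
#' @param normal unit membrane normal; positive = toward the extracellular
#'   side (estimated from the structure when \code{NULL}).
#' @param chain chain to model; default first chain.
#' @param step step size in Angstrom (default 1.0).
#' @param range numeric length-2 scan range in Angstrom (default
#'   \code{c(0, 15)}, toward the extracellular side).
#' @return A list of class \code{translation_scan}: \code{profile} (data
#'   frame \code{t}, \code{objective}, plus one distance column per pair),
#'   \code{argmin}, \code{boundary_minimum}, \code{model} (the structure at
#'   the argmin), \code{normal}.
#' @export
scan_translation <- function(s, segments, transport, constraints,
                             normal = NULL, chain = NULL, step = 1,
                             range = c(0, 15)) {
  stopifnot(step > 0, length(range) == 2, range[2] >= range[1])
  if (is.null(chain)) chain <- s$chain[!s$het][1]
  if (is.null(normal)) normal <- estimate_membrane_normal(s, segments, chain)
  normal <- unitize(normal)
  seg_all <- select_calpha(s, chain = chain)
  seg_all$segment <- assign_segments(seg_all, segments)
  lookup <- function(r) {
    k <- match(r, seg_all$resno)
    if (anyNA(k))
      stop("constraint residue(s) not resolved in chain ", chain, ": ",
           paste(r[is.na(k)], collapse = ","))
    k
  }
  ki <- lookup(constraints$i); kj <- lookup(constraints$j)
  moving_res <- seg_all$resno[!is.na(seg_all$segment) &
                                seg_all$segment %in% transport$members]
  mi <- constraints$i %in% moving_res
  mj <- constraints$j %in% moving_res
  bad <- mi == mj
  if (any(bad))
    warning(sum(bad), " constraint pair(s) have both or neither residue on ",
            "the moving domain; their distance is translation-invariant")
  pi <- ca_xyz(seg_all)[ki, , drop = FALSE]
  pj <- ca_xyz(seg_all)[kj, , drop = FALSE]
  ts <- seq(range[1], range[2], by = step)
  # per-pair distance at translation t: only the moving-side point shifts
  prof <- vapply(ts, function(t) {
    qi <- pi + (t * mi) %o% normal
    qj <- pj + (t * mj) %o% normal
    sqrt(rowSums((qi - qj)^2))
  }, numeric(nrow(constraints)))
  prof <- matrix(prof, nrow = nrow(constraints))
  obj <- colSums(prof)
  k_min <- which.min(obj)  # which.min takes the first (smallest t) on ties
  argmin <- ts[k_min]
  boundary <- (k_min == length(ts) && length(ts) > 1) ||
    (k_min == 1 && range[1] != 0)
  profile <- data.frame(t = ts, objective = obj)
  pair_nm <- paste0("d_", constraints$i, "_", constraints$j)
  profile[pair_nm] <- t(prof)
  model <- build_model(s, segments, transport, translation = argmin,
                       normal = normal, chain = chain)
  structure(list(profile = profile, argmin = argmin,
                 boundary_minimum = boundary, model = model, normal = normal,
                 step = step, range = range,
                 pair_moving = data.frame(i = constraints$i, j = constraints$j,
                                          i_moving = mi, j_moving = mj)),
            class = "translation_scan")
}

#' @export
print.translation_scan <- function(x, ...) {
  cat(sprintf("Translation scan %g..%g A (step %g): argmin %g A, objective %.2f A%s\n",
              x$range[1], x$range[2], x$step, x$argmin,
              min(x$profile$objective),
              if (x$boundary_minimum) " [boundary minimum]" else ""))
  invisible(x)
}

#' Build a rigid-translation model of an alternative state
#'
#' Translates every atom of the transport-domain residues by
#' \code{translation} Angstrom along the membrane normal (optionally adding
#' a rotation about an in-plane axis through the moving-domain centroid),
#' leaving all other atoms untouched. The applied transform is recorded on
#' the result (written as REMARK records by \code{\link{write_structure}}),
#' and steric clashes introduced across the domain boundary (non-bonded
#' heavy-atom pairs closer than 2.4 Angstrom) are counted in the
#' \code{"clash_count"} attribute.
#'
#' @inheritParams scan_translation
#' @param translation signed displacement along \code{normal} (Angstrom).
#' @param rotation_deg optional tilt about an in-plane axis (default 0).
#' @param rotation_axis in-plane rotation axis (default: perpendicular to
#'   the normal, chosen automatically).
#' @return The modeled \code{atom_table}.
#' @export
build_model <- function(s, segments, transport, translation, normal = NULL,
                        chain = NULL, rotation_deg = 0, rotation_axis = NULL) {
  if (is.null(chain)) chain <- s$chain[!s$het][1]
  if (is.null(normal)) normal <- estimate_membrane_normal(s, segments, chain)
  normal <- unitize(normal)
  seg <- assign_segments(s, segments)
  moving <- !s$het & s$chain == chain & !is.na(seg) & seg %in% transport$members
  if (!any(moving)) stop("no atoms found for the moving domain on chain ", chain)
  xyz <- as.matrix(s[, c("x", "y", "z")])
  rot <- diag(3)
  if (rotation_deg != 0) {
    if (is.null(rotation_axis)) {
      ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      rotation_axis <- unitize(ref - sum(ref * normal) * normal)
    }
    rot <- rotation_about_axis(rotation_axis, rotation_deg)
  }
  ctr <- colMeans(xyz[moving, , drop = FALSE])
  moved <- sweep(sweep(xyz[moving, , drop = FALSE], 2, ctr) %*% t(rot), 2, -ctr)
  moved <- sweep(moved, 2, -translation * normal)
  out <- s
  out[moving, c("x", "y", "z")] <- moved
  # clash count across the moved/static boundary (heavy atoms < 2.4 A)
  static <- !s$het & !moving
  a <- as.matrix(out[moving & out$elesy != "H", c("x", "y", "z")])
  b <- as.matrix(out[static & out$elesy != "H", c("x", "y", "z")])
  clashes <- 0L
  if (nrow(a) && nrow(b)) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    clashes <- sum(d2 < 2.4^2)
  }
  attr(out, "transform_applied") <- rigid_transform(rot,
    translation * normal + ctr - as.numeric(rot %*% ctr))
  attr(out, "clash_count") <- clashes
  class(out) <- c("atom_table", "data.frame")
  out
}

#' Write a translation-scan profile as CSV
#'
#' @param scan a \code{translation_scan}.
#' @param path output path.
#' @export
write_scan_profile <- function(scan, path) {
  utils::write.csv(scan$profile, path, row.names = FALSE)
  invisible(path)
}
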