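#' Pairwise C-alpha distance matrix
#'
#' @param points a \code{calpha_set} (labels must be unique).
#' @return A symmetric matrix of Euclidean C-alpha distances (Angstrom)
#'   with the point labels as dimnames; class \code{c("distance_matrix",
#'   "matrix")}.
#' @export
distance_matrix <- function(points) {
  if (nrow(points) < 2) stop("need at least 2 points")
  if (anyDuplicated(points$label))
    stop("duplicate labels: ",
         paste(unique(points$label[duplicated(points$label)]), collapse = ","))
  m <- as.matrix(stats::dist(ca_xyz(points)))
  m <- (m + t(m)) / 2  # enforce exact symmetry
  diag(m) <- 0
  dimnames(m) <- list(points$label, points$label)
  class(m) <- c("distance_matrix", class(m))
  m
}

#' Distance-difference matrix of two conformations
#'
#' Element-wise difference \code{b - a} of the two intramolecular distance
#' matrices, restricted to their common residue labels. Because
#' intramolecular distances are invariant to rigid motion, the result is
#' zero within any rigid body and nonzero only where residues move relative
#' to each other -- no superposition is involved.
#'
#' @param a,b \code{distance_matrix} objects (or plain labeled symmetric
#'   matrices).
#' @return Signed difference matrix (Angstrom) over the label intersection,
#'   class \code{c("ddm", "matrix")}, with attribute \code{n_common}.
#' @export
ddm <- function(a, b) {
  common <- intersect(rownames(a), rownames(b))
  if (length(common) < 2)
    stop("label intersection has ", length(common), " residues; need >= 2")
  d <- unclass(b)[common, common] - unclass(a)[common, common]
  attr(d, "n_common") <- length(common)
  class(d) <- c("ddm", class(d))
  d
}

#' Aggregate a distance-difference matrix by segment
#'
#' Entry (p, q) is the root mean square of the residue-level
#' distance-difference entries between residues of segment p and segment q
#' (intra-segment entries for p = q, excluding the diagonal). A pair of
#' helices that moves as one rigid body gives a near-zero entry; helix
#' pairs that move relative to each other give large entries.
#'
#' @param d a \code{ddm} matrix with \code{chain:resno} labels.
#' @param segments a \code{segment_table}. Segment names containing no
#'   resolved residue raise an error; residues outside every segment are
#'   excluded and counted in the \code{"n_unassigned"} attribute.
#' @return Symmetric matrix of per-segment RMS differences (Angstrom),
#'   class \code{c("segment_aggregate", "matrix")}.
#' @export
aggregate_by_segment <- function(d, segments) {
  labs <- rownames(d)
  parts <- regmatches(labs, regexec("^([^:]*):(-?[0-9]+)", labs))
  df <- data.frame(chain = vapply(parts, `[`, "", 2),
                   resno = as.integer(vapply(parts, `[`, "", 3)),
                   stringsAsFactors = FALSE)
  seg <- assign_segments(df, segments)
  missing <- setdiff(segments$segment, seg)
  if (length(missing))
    stop("segment(s) with no resolved residues in the matrix: ",
         paste(missing, collapse = ","))
  nm <- segments$segment
  idx <- lapply(nm, function(s) which(!is.na(seg) & seg == s))
  out <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  for (p in seq_along(nm)) for (q in seq_len(p)) {
    block <- d[idx[[p]], idx[[q]], drop = FALSE]
    if (p == q) {
      vals <- block[lower.tri(block)]
      out[p, q] <- if (length(vals)) sqrt(mean(vals^2)) else 0
    } else {
      out[p, q] <- out[q, p] <- sqrt(mean(block^2))
    }
  }
  attr(out, "n_unassigned") <- sum(is.na(seg))
  class(out) <- c("segment_aggregate", class(out))
  out
}

#' Partition segments into rigid-body domains
#'
#' Treats the per-segment RMS distance-difference matrix as a
#' dissimilarity: segments that stay fixed relative to each other are
#' "close" and cluster together. Average-linkage hierarchical clustering
#' cut at \code{k} groups recovers the rigid bodies; the separation score
#' (mean cross-cluster minus mean within-cluster entry) measures how
#' cleanly the bundle splits, and a near-zero score flags the absence of
#' rigid-body substructure (e.g. the two conformations differ only by an
#' overall rigid transform).
#'
#' @param agg a \code{segment_aggregate} matrix.
#' @param k number of domains (default 2).
#' @param min_separation separation score (Angstrom) below which the result
#'   is flagged as having no rigid-body substructure.
#' @return A list of class \code{domain_partition}: \code{domains} (list of
#'   \code{domain_definition}, ordered by their lexicographically smallest
#'   member), \code{separation}, \code{rigid_substructure} (logical).
#' @export
partition_domains <- function(agg, k = 2, min_separation = 0.1) {
  nm <- sort(rownames(agg))  # lexicographic order for deterministic ties
  if (k > length(nm)) stop("k = ", k, " exceeds the ", length(nm), " segments")
  m <- unclass(agg)[nm, nm]
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  grp <- stats::cutree(hc, k = k)
  same <- outer(grp, grp, "==")
  off <- upper.tri(m)
  within <- m[off & same]
  cross <- m[off & !same]
  sep <- mean(cross) - (if (length(within)) mean(within) else 0)
  doms <- lapply(split(nm, grp), function(members)
    domain_definition(paste0("domain_", min(members)), members))
  doms <- doms[order(vapply(doms, function(d) min(d$members), ""))]
  names(doms) <- NULL
  structure(list(domains = doms, separation = sep,
                 rigid_substructure = is.finite(sep) && sep >= min_separation),
            class = "domain_partition")
}

#' @export
print.domain_partition <- function(x, ...) {
  cat(sprintf("Rigid-body partition (separation %.3f A%s)\n", x$separation,
              if (x$rigid_substructure) "" else "; no rigid-body substructure"))
  for (d in x$domains) print(d)
  invisible(x)
}

#' Write a labeled matrix as CSV
#'
#' @param m a matrix with dimnames (distance, distance-difference or
#'   segment-aggregate).
#' @param path output path.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}

#' Render a distance-difference heatmap
#'
#' Residue-level |DDM| heatmap in residue order with segment boundaries
#' annotated; linear color scale from 0 to the matrix maximum.
#'
#' @param d a \code{ddm} matrix.
#' @param segments optional \code{segment_table} for boundary annotation.
#' @param path PNG output path.
#' @export
plot_ddm <- function(d, segments = NULL, path) {
  m <- abs(unclass(d))
  n <- nrow(m)
  grDevices::png(path, width = 900, height = 860)
  on.exit(grDevices::dev.off(), add = TRUE)
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::image(seq_len(n), seq_len(n), m[, n:1], zlim = c(0, max(m, 1e-12)),
                  col = pal, xlab = "residue index", ylab = "residue index",
                  main = "C-alpha distance-difference matrix (|A|)", axes = FALSE)
  graphics::box()
  if (!is.null(segments)) {
    labs <- rownames(m)
    parts <- regmatches(labs, regexec("^([^:]*):(-?[0-9]+)", labs))
    df <- data.frame(chain = vapply(parts, `[`, "", 2),
                     resno = as.integer(vapply(parts, `[`, "", 3)))
    seg <- assign_segments(df, segments)
    br <- which(seg[-1] != seg[-n]) + 0.5
    graphics::abline(v = br, h = n - br + 1, col = "grey40", lty = 3)
    mids <- tapply(seq_len(n), seg, stats::median)
    graphics::axis(1, at = mids, labels = names(mids), tick = FALSE)
    graphics::axis(2, at = n - mids + 1, labels = names(mids), tick = FALSE)
  }
  invisible(path)
}
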