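#' Stage drivers
#'
#' Thin deterministic drivers tying the analysis stages together: each
#' reads its inputs (paths or in-memory objects), runs one stage of the
#' conformational analysis, writes its tables (and optional figures) under
#' \code{out_dir}, and returns the in-memory result. Re-running with the
#' same inputs overwrites the outputs reproducibly. A provenance file
#' (\code{<stage>_provenance.txt}) records every parameter used.
#'
#' @name stage_drivers
#' @param structure_a,structure_b \code{atom_table}s or file paths.
#' @param segments a \code{segment_table} or file path.
#' @param out_dir output directory (created if needed).
#' @param chain_a,chain_b,chain chain selections; default first chain.
#' @param plots write PNG figures as well as tables.
NULL

resolve_structure <- function(x) if (is.character(x)) read_structure(x) else x
resolve_segments <- function(x) if (is.character(x)) read_segments(x) else x

write_provenance <- function(out_dir, stage, params) {
  lines <- c(paste0("stage=", stage),
             vapply(names(params), function(n)
               paste0(n, "=", paste(format(params[[n]]), collapse = ",")),
               ""))
  writeLines(lines, file.path(out_dir, paste0(stage, "_provenance.txt")))
}

#' @rdname stage_drivers
#' @param exclude_segments segment names dropped from the
#'   distance-difference analysis (default \code{"TMa"}: the extra
#'   N-terminal helix resolved in only one conformation).
#' @param k number of rigid-body domains for the partition.
#' @return \code{run_ddm}: list with the \code{ddm} matrix, the
#'   \code{aggregate}, the \code{partition} and the per-residue
#'   \code{deviations}; files \code{ddm.csv}, \code{segment_aggregate.csv},
#'   \code{partition.txt}, \code{deviations.csv} (+ \code{ddm.png}).
#' @export
run_ddm <- function(structure_a, structure_b, segments, out_dir,
                    chain_a = NULL, chain_b = NULL, exclude_segments = "TMa",
                    k = 2, plots = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  a <- resolve_structure(structure_a); b <- resolve_structure(structure_b)
  segs <- resolve_segments(segments)
  segs <- segs[!segs$segment %in% exclude_segments, , drop = FALSE]
  ca_a <- select_calpha(a, chain = chain_a, segments = segs)
  ca_b <- select_calpha(b, chain = chain_b, segments = segs)
  ca_b$label <- paste0(ca_a$chain[1], ":", ca_b$resno, ca_b$insert)
  sup <- kabsch_superpose(ca_b, ca_a)
  dev <- per_residue_deviation(ca_b, ca_a, sup$transform)
  d <- ddm(distance_matrix(ca_a), distance_matrix(ca_b))
  agg <- aggregate_by_segment(d, segs)
  part <- partition_domains(agg, k = k)
  utils::write.csv(dev[, c("chain", "resno", "segment", "deviation")],
                   file.path(out_dir, "deviations.csv"), row.names = FALSE)
  write_matrix_csv(d, file.path(out_dir, "ddm.csv"))
  write_matrix_csv(agg, file.path(out_dir, "segment_aggregate.csv"))
  writeLines(c(
    sprintf("separation_score_A=%.4f", part$separation),
    sprintf("rigid_substructure=%s", part$rigid_substructure),
    vapply(part$domains, function(dd)
      paste0(dd$name, "=", paste(dd$members, collapse = ",")), "")),
    file.path(out_dir, "partition.txt"))
  if (plots) plot_ddm(d, segs, file.path(out_dir, "ddm.png"))
  write_provenance(out_dir, "ddm", list(
    overall_rmsd_A = sup$rmsd, n_paired = sup$n, k = k,
    excluded_segments = exclude_segments))
  invisible(list(superposition = sup, deviations = dev, ddm = d,
                 aggregate = agg, partition = part))
}

#' @rdname stage_drivers
#' @param scaffold,transport \code{domain_definition}s.
#' @param sites optional list of \code{site_definition}s (or a site-table
#'   path).
#' @param normal optional membrane normal.
#' @param tm4_split see \code{\link{domain_motion}}.
#' @return \code{run_motion}: the \code{motion_report}; file
#'   \code{motion_report.tsv}.
#' @export
run_motion <- function(structure_a, structure_b, segments, scaffold,
                       transport, out_dir, chain_a = NULL, chain_b = NULL,
                       normal = NULL, sites = NULL, tm4_split = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  a <- resolve_structure(structure_a); b <- resolve_structure(structure_b)
  segs <- resolve_segments(segments)
  if (is.character(sites)) sites <- read_sites(sites)
  rep <- domain_motion(a, b, segs, scaffold, transport, chain_a, chain_b,
                       normal = normal, sites = sites, tm4_split = tm4_split)
  write_motion_report(rep, file.path(out_dir, "motion_report.tsv"))
  write_provenance(out_dir, "motion", list(
    scaffold = paste(scaffold$members, collapse = "+"),
    transport = paste(transport$members, collapse = "+"),
    normal = signif(rep$normal, 6)))
  invisible(rep)
}

#' @rdname stage_drivers
#' @param couplings a \code{coupling_pairs} data frame or file path.
#' @param domains list of \code{domain_definition}s.
#' @param score_cutoff,contact_cutoff,min_seq_sep,offset see
#'   \code{\link{read_couplings}} and \code{\link{classify_contacts}}.
#' @return \code{run_couplings}: list with the \code{report} and the
#'   \code{candidates}; files \code{contact_report.csv},
#'   \code{interface_candidates.csv} (+ \code{contact_map.png}).
#' @export
run_couplings <- function(couplings, structure_a, segments, domains, out_dir,
                          chain = NULL, score_cutoff = 0.9,
                          contact_cutoff = 10, min_seq_sep = 5, offset = 0,
                          plots = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pairs <- if (is.character(couplings))
    read_couplings(couplings, score_cutoff) else couplings
  s <- resolve_structure(structure_a)
  segs <- resolve_segments(segments)
  rep <- classify_contacts(pairs, s, chain = chain, segments = segs,
                           domains = domains, cutoff = contact_cutoff,
                           min_seq_sep = min_seq_sep, offset = offset)
  cand <- interface_candidates(rep)
  utils::write.csv(as.data.frame(rep), file.path(out_dir, "contact_report.csv"),
                   row.names = FALSE)
  utils::write.csv(cand, file.path(out_dir, "interface_candidates.csv"),
                   row.names = FALSE)
  if (plots) plot_contact_map(rep, file.path(out_dir, "contact_map.png"))
  write_provenance(out_dir, "couplings", list(
    score_cutoff = score_cutoff, contact_cutoff_A = contact_cutoff,
    min_seq_sep = min_seq_sep, offset = offset,
    n_near_diagonal_dropped = attr(rep, "n_near_diagonal_dropped")))
  invisible(list(report = rep, candidates = cand))
}

#' @rdname stage_drivers
#' @param transport2 the moving domain for the scan.
#' @param constraints a \code{constraint_set} or a two-column file.
#' @param step,range scan grid, Angstrom.
#' @return \code{run_scan}: the \code{translation_scan}; files
#'   \code{scan_profile.csv}, \code{model.pdb}, \code{scan_summary.txt}.
#' @export
run_scan <- function(structure_a, segments, transport, constraints, out_dir,
                     chain = NULL, normal = NULL, step = 1, range = c(0, 15)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- resolve_structure(structure_a)
  segs <- resolve_segments(segments)
  if (is.character(constraints)) {
    df <- utils::read.table(constraints, header = TRUE, comment.char = "#")
    constraints <- constraint_set(df[[1]], df[[2]])
  }
  scan <- scan_translation(s, segs, transport, constraints, normal = normal,
                           chain = chain, step = step, range = range)
  write_scan_profile(scan, file.path(out_dir, "scan_profile.csv"))
  write_structure(scan$model, file.path(out_dir, "model.pdb"))
  writeLines(c(
    sprintf("argmin_A=%g", scan$argmin),
    sprintf("objective_at_argmin_A=%.4f", min(scan$profile$objective)),
    sprintf("objective_at_zero_A=%.4f", scan$profile$objective[1]),
    sprintf("boundary_minimum=%s", scan$boundary_minimum),
    sprintf("clash_count=%d", attr(scan$model, "clash_count"))),
    file.path(out_dir, "scan_summary.txt"))
  write_provenance(out_dir, "scan", list(step = step,
                                         range = paste(range, collapse = "..")))
  invisible(scan)
}

#' @rdname stage_drivers
#' @param spec a \code{bundle_spec}.
#' @param motion a \code{motion_spec}.
#' @param n_true,n_decoy,n_interface planted coupling class sizes.
#' @return \code{run_simulate}: list with the bundle, the moved structure
#'   and the coupling table; files \code{bundle_a.pdb}, \code{bundle_b.pdb},
#'   \code{segments.tsv}, \code{couplings.csv}, \code{ground_truth.txt}.
#' @export
run_simulate <- function(spec, motion, out_dir, n_true = 20, n_decoy = 30,
                         n_interface = 5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- make_bundle(spec)
  moved <- apply_motion(bundle, motion)
  write_structure(bundle$structure, file.path(out_dir, "bundle_a.pdb"))
  write_structure(moved, file.path(out_dir, "bundle_b.pdb"))
  write_segments(bundle$segments, file.path(out_dir, "segments.tsv"))
  coup <- make_couplings(bundle, n_true, n_decoy, n_interface,
                         seed = spec$seed, path = file.path(out_dir, "couplings.csv"))
  write_ground_truth(attr(moved, "ground_truth"),
                     file.path(out_dir, "ground_truth.txt"))
  write_provenance(out_dir, "simulate", list(
    seed = spec$seed, noise_sd = spec$noise_sd,
    translation = motion$translation, rotation_deg = motion$rotation_deg))
  invisible(list(bundle = bundle, moved = moved, couplings = coup))
}
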