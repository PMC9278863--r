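#' Read an atomic structure from PDB or mmCIF
#'
#' Parses a coordinate file via bio3d and returns a flat atom table with one
#' row per atom, author residue numbering preserved. Only the first model of
#' a multi-model file is kept. Heteroatoms (ions, lipids, waters) are
#' retained but flagged \code{het = TRUE}; downstream C-alpha selections
#' never include them. Alternate locations are resolved by keeping the
#' highest-occupancy conformer (ties broken toward altloc 'A').
#'
#' @param path path to a PDB or mmCIF file.
#' @param format one of \code{"auto"} (by extension), \code{"pdb"},
#'   \code{"mmcif"}.
#' @return A data frame of class \code{atom_table} with columns
#'   \code{chain}, \code{resno}, \code{insert}, \code{resid}, \code{elety}
#'   (atom name), \code{elesy} (element), \code{x}, \code{y}, \code{z},
#'   \code{het}.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE))
    },
    error = function(e) stop("could not parse '", path, "' as ", format, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (nrow(at) == 0) stop("no atoms found in ", path)
  df <- data.frame(
    chain  = ifelse(is.na(at$chain), "", as.character(at$chain)),
    resno  = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid  = as.character(at$resid),
    elety  = as.character(at$elety),
    elesy  = ifelse(is.na(at$elesy), "", as.character(at$elesy)),
    x = at$x, y = at$y, z = at$z,
    het = at$type != "ATOM",
    stringsAsFactors = FALSE
  )
  # altloc resolution: keep highest occupancy, tie -> 'A' (then file order)
  alt <- ifelse(is.na(at$alt), "", as.character(at$alt))
  occ <- ifelse(is.na(at$o), 1, at$o)
  if (any(alt != "")) {
    key <- paste(df$chain, df$resno, df$insert, df$elety, sep = "\r")
    ord <- order(key, -occ, alt != "A", seq_len(nrow(df)))
    keep <- ord[!duplicated(key[ord])]
    df <- df[sort(keep), , drop = FALSE]
  }
  if (!any(!df$het)) stop("no polymer atoms in ", path)
  if (anyNA(df$x) || anyNA(df$y) || anyNA(df$z) ||
      any(!is.finite(c(df$x, df$y, df$z))))
    stop("non-finite coordinates in ", path)
  rownames(df) <- NULL
  class(df) <- c("atom_table", "data.frame")
  df
}

#' Assemble an atom table from components
#'
#' Constructor used by the synthetic generator and by tests; validates the
#' atom-table invariants (finite coordinates, unique atom identifiers).
#'
#' @param chain,resno,insert,resid,elety,elesy,x,y,z,het atom fields; scalar
#'   values are recycled.
#' @return An \code{atom_table} data frame.
#' @export
atom_table <- function(chain, resno, x, y, z, insert = "", resid = "ALA",
                       elety = "CA", elesy = "C", het = FALSE) {
  df <- data.frame(chain = as.character(chain), resno = as.integer(resno),
                   insert = as.character(insert), resid = as.character(resid),
                   elety = as.character(elety), elesy = as.character(elesy),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   het = as.logical(het), stringsAsFactors = FALSE)
  if (any(!is.finite(c(df$x, df$y, df$z))))
    stop("coordinates must be finite")
  key <- paste(df$chain, df$resno, df$insert, df$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, insert, atom) entries: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  class(df) <- c("atom_table", "data.frame")
  df
}

#' @export
print.atom_table <- function(x, ...) {
  cat(sprintf("Atom table: %d atoms, %d chains (%s), %d polymer residues\n",
              nrow(x), length(unique(x$chain)),
              paste(unique(x$chain), collapse = ","),
              length(unique(paste(x$chain, x$resno, x$insert)[!x$het]))))
  NextMethod()
}

#' Write an atom table as a PDB file
#'
#' Coordinates are written to the standard 3-decimal PDB precision, chains
#' and residues in input order. Any rigid transform recorded on the
#' structure (attribute \code{"transform_applied"}, set by
#' \code{\link{build_model}}) is emitted as REMARK records.
#'
#' @param s an \code{atom_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(is.data.frame(s))
  if (nrow(s) == 0) stop("refusing to write an empty structure")
  if (any(s$resno > 9999 | s$resno < -999))
    stop("residue numbers outside the PDB field width (-999..9999): ",
         paste(range(s$resno), collapse = ".."),
         "; renumber before writing")
  if (nrow(s) > 99999)
    stop("more than 99,999 atoms cannot be represented in fixed-width PDB ",
         "ATOM records; split the structure by chain")
  remarks <- character()
  tf <- attr(s, "transform_applied")
  if (!is.null(tf)) {
    remarks <- c(
      "REMARK   3 RIGID TRANSFORM APPLIED TO MOVED DOMAIN",
      sprintf("REMARK   3 TRANSLATION %10.4f %10.4f %10.4f", tf$translation[1],
              tf$translation[2], tf$translation[3]),
      sprintf("REMARK   3 ROTATION ANGLE %8.3f DEG", rotation_angle(tf$rotation))
    )
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(
    file = tmp,
    xyz = as.numeric(t(as.matrix(s[, c("x", "y", "z")]))),
    type = ifelse(s$het, "HETATM", "ATOM"),
    resno = s$resno, resid = s$resid, chain = s$chain,
    insert = ifelse(s$insert == "", NA, s$insert),
    elety = s$elety, elesy = s$elesy, verbose = FALSE
  )
  writeLines(c(remarks, readLines(tmp)), path)
  invisible(path)
}

#' Select C-alpha atoms, ordered and labeled
#'
#' Returns one C-alpha per polymer residue of the requested chain, ordered
#' by residue number (insertion codes after the unlettered residue), with
#' each row labeled by chain, residue and transmembrane segment. Residues
#' inside a requested segment that lack a C-alpha are excluded with a
#' warning and recorded in the \code{"excluded"} attribute.
#'
#' @param s an \code{atom_table}.
#' @param chain chain identifier; default the first chain in the file.
#' @param segments a segment table (see \code{\link{read_segments}}) to
#'   restrict and label the selection, or \code{"all"} for every residue of
#'   the chain.
#' @return A data frame of class \code{calpha_set} with columns
#'   \code{chain}, \code{resno}, \code{insert}, \code{segment},
#'   \code{label}, \code{x}, \code{y}, \code{z}.
#' @export
select_calpha <- function(s, chain = NULL, segments = "all") {
  stopifnot(is.data.frame(s))
  if (is.null(chain)) chain <- s$chain[!s$het][1]
  if (!chain %in% s$chain) stop("chain '", chain, "' not present (chains: ",
                                paste(unique(s$chain), collapse = ","), ")")
  ca <- s[!s$het & s$chain == chain & s$elety == "CA", , drop = FALSE]
  ca <- ca[order(ca$resno, ca$insert), , drop = FALSE]
  seg_names <- rep(NA_character_, nrow(ca))
  if (!identical(segments, "all")) {
    stopifnot(is.data.frame(segments))
    seg_names <- assign_segments(ca, segments)
    missing_ca <- character()
    for (k in seq_len(nrow(segments))) {
      if (segments$chain[k] != chain) next
      want <- segments$start[k]:segments$end[k]
      have <- ca$resno[!is.na(seg_names) & seg_names == segments$segment[k]]
      gap <- setdiff(want, have)
      if (length(gap))
        missing_ca <- c(missing_ca, paste0(segments$segment[k], ":",
                                           paste(gap, collapse = ",")))
    }
    keep <- !is.na(seg_names)
    ca <- ca[keep, , drop = FALSE]
    seg_names <- seg_names[keep]
    if (length(missing_ca))
      warning("residues without a C-alpha excluded from selection: ",
              paste(missing_ca, collapse = "; "))
    attr_excluded <- missing_ca
  } else {
    attr_excluded <- character()
  }
  out <- data.frame(chain = ca$chain, resno = ca$resno, insert = ca$insert,
                    segment = seg_names,
                    label = paste0(ca$chain, ":", ca$resno, ca$insert),
                    x = ca$x, y = ca$y, z = ca$z, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- attr_excluded
  class(out) <- c("calpha_set", "data.frame")
  out
}

# internal: coordinates of a calpha_set as an n x 3 matrix
ca_xyz <- function(ca) as.matrix(ca[, c("x", "y", "z")])

# internal: segment name for each row of an atom/calpha data frame, NA if none
assign_segments <- function(df, segments) {
  seg <- rep(NA_character_, nrow(df))
  for (k in seq_len(nrow(segments))) {
    hit <- df$chain == segments$chain[k] &
      df$resno >= segments$start[k] & df$resno <= segments$end[k]
    seg[hit] <- segments$segment[k]
  }
  seg
}
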