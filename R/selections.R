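#' Transmembrane segment tables, domains and sites
#'
#' A segment table names the transmembrane helices of a structure as
#' inclusive author-numbered residue ranges; a domain definition groups
#' segments into rigid bodies (canonically a static "scaffold" and a mobile
#' "transport" bundle); a site definition names a set of residues whose
#' centroid displacement is tracked (e.g. a metal-binding region).
#'
#' @param segment,chain,start,end segment table columns: segment name
#'   (e.g. "TM1".."TM8", "TMa"), chain id, inclusive residue range.
#' @return \code{segment_table}: a validated data frame of class
#'   \code{segment_table}.
#' @export
segment_table <- function(segment, chain, start, end) {
  df <- data.frame(segment = as.character(segment), chain = as.character(chain),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (any(df$start > df$end)) stop("segment start must be <= end")
  if (anyDuplicated(df$segment)) stop("duplicate segment names")
  for (ch in unique(df$chain)) {
    d <- df[df$chain == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)]))
      stop("overlapping segments on chain ", ch)
  }
  class(df) <- c("segment_table", "data.frame")
  df
}

#' @rdname segment_table
#' @param path delimited text file with columns
#'   \code{segment,chain,start,end}, one segment per line; \code{'#'} starts
#'   a comment.
#' @export
read_segments <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("segment", "chain", "start", "end")
  if (!all(need %in% names(df)))
    stop("segment table must have columns segment,chain,start,end; found: ",
         paste(names(df), collapse = ","))
  segment_table(df$segment, df$chain, df$start, df$end)
}

#' @rdname segment_table
#' @param s a \code{segment_table}.
#' @export
write_segments <- function(s, path) {
  utils::write.table(as.data.frame(s), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname segment_table
#' @param name domain name ("transport", "scaffold", or any user string).
#' @param members character vector of segment names belonging to the domain.
#' @param segments optional \code{segment_table} to validate members against.
#' @return \code{domain_definition}: a named list with \code{name} and
#'   \code{members}.
#' @export
domain_definition <- function(name, members, segments = NULL) {
  members <- as.character(members)
  if (!length(members)) stop("a domain needs at least one member segment")
  if (!is.null(segments) && !all(members %in% segments$segment))
    stop("domain '", name, "' references unknown segments: ",
         paste(setdiff(members, segments$segment), collapse = ","))
  structure(list(name = name, members = unique(members)),
            class = "domain_definition")
}

#' @export
print.domain_definition <- function(x, ...) {
  cat("Domain '", x$name, "': ", paste(x$members, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Named residue sites
#'
#' @param name site name (e.g. \code{"metal-binding region"}).
#' @param chain,resno parallel vectors of residues forming the site.
#' @param atom_policy \code{"CA"} (centroid of C-alpha atoms) or
#'   \code{"all-heavy"} (centroid of all non-hydrogen atoms).
#' @return An object of class \code{site_definition}.
#' @export
site_definition <- function(name, chain, resno, atom_policy = c("CA", "all-heavy")) {
  atom_policy <- match.arg(atom_policy)
  if (!length(resno)) stop("site '", name, "' has no residues")
  structure(list(name = name,
                 residues = data.frame(chain = as.character(chain),
                                       resno = as.integer(resno),
                                       stringsAsFactors = FALSE),
                 atom_policy = atom_policy),
            class = "site_definition")
}

#' Read site definitions from delimited text
#'
#' One residue per line, columns \code{site,chain,resno}; \code{'#'}
#' comments. Rows sharing a site name form one site.
#'
#' @param path input file.
#' @param atom_policy applied to every site read.
#' @return A named list of \code{site_definition} objects.
#' @export
read_sites <- function(path, atom_policy = "CA") {
  df <- utils::read.table(path, header = TRUE, sep = "", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("site", "chain", "resno")
  if (!all(need %in% names(df)))
    stop("site table must have columns site,chain,resno; found: ",
         paste(names(df), collapse = ","))
  out <- lapply(split(df, df$site), function(d)
    site_definition(d$site[1], d$chain, d$resno, atom_policy))
  out[unique(df$site)]
}

# internal: centroid of a site in a structure; errors if unresolved
site_centroid <- function(s, site, chain_map = identity) {
  res <- site$residues
  pts <- matrix(NA_real_, nrow(res), 3)
  for (k in seq_len(nrow(res))) {
    rows <- s$chain == chain_map(res$chain[k]) & s$resno == res$resno[k] & !s$het
    if (site$atom_policy == "CA") rows <- rows & s$elety == "CA"
    else rows <- rows & s$elesy != "H"
    if (!any(rows))
      stop("site '", site$name, "': residue ", res$chain[k], ":", res$resno[k],
           " not resolved in structure")
    pts[k, ] <- colMeans(as.matrix(s[rows, c("x", "y", "z"), drop = FALSE]))
  }
  colMeans(pts)
}
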