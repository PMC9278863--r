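#' Read a scored evolutionary-coupling pair table
#'
#' Reads the tabular output of coevolution servers (delimited text with at
#' least residue columns \code{i}, \code{j} and a \code{score} column;
#' comma, tab or whitespace separated; header auto-detected). Pairs are
#' normalized to \code{i < j} and deduplicated keeping the maximum score;
#' significance is \code{score >= score_cutoff}.
#'
#' @param path input file.
#' @param score_cutoff significance cutoff on the coupling score
#'   (default 0.9, the usual probability-score convention).
#' @return Data frame of class \code{coupling_pairs} with columns \code{i},
#'   \code{j}, \code{score}, \code{significant}.
#' @export
read_couplings <- function(path, score_cutoff = 0.9) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  toks <- strsplit(gsub("^\\s+|\\s+$", "", first),
                   if (sep == ",") "," else "\\s+")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(toks))))
  df <- utils::read.table(path, header = has_header, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  nms <- tolower(names(df))
  pick <- function(cands) { hit <- which(nms %in% cands); if (length(hit)) hit[1] else NA }
  ci <- pick(c("i", "res_i", "pos_i", "a_i"))
  cj <- pick(c("j", "res_j", "pos_j", "a_j"))
  cs <- pick(c("score", "cn", "probability", "prob"))
  if (!has_header || anyNA(c(ci, cj, cs))) {
    if (ncol(df) < 3)
      stop("coupling table needs columns i, j, score; found: ",
           paste(names(df), collapse = ","))
    num <- which(vapply(df, is.numeric, TRUE))
    if (has_header && length(num) >= 3 && anyNA(c(ci, cj, cs))) {
      stop("could not identify i/j/score columns; found: ",
           paste(names(df), collapse = ","))
    }
    ci <- 1; cj <- 2; cs <- 3
  }
  out <- data.frame(i = as.integer(df[[ci]]), j = as.integer(df[[cj]]),
                    score = as.numeric(df[[cs]]))
  if (any(out$i == out$j)) {
    warning("dropping ", sum(out$i == out$j), " self pair(s)")
    out <- out[out$i != out$j, , drop = FALSE]
  }
  swap <- out$i > out$j
  tmp <- out$i[swap]; out$i[swap] <- out$j[swap]; out$j[swap] <- tmp
  out <- out[order(out$i, out$j, -out$score), , drop = FALSE]
  out <- out[!duplicated(out[, c("i", "j")]), , drop = FALSE]
  out$significant <- out$score >= score_cutoff
  rownames(out) <- NULL
  attr(out, "score_cutoff") <- score_cutoff
  class(out) <- c("coupling_pairs", "data.frame")
  out
}

#' Classify the geometric satisfaction of coupling pairs in a monomer
#'
#' For each coupling pair, measures the minimal distance between the two
#' residues within one chain of the structure and classifies the pair as
#' satisfied (distance at or below the contact cutoff) or not. Pairs are
#' also categorized by the domain membership of their residues: true
#' couplings inside a helix bundle are expected to be satisfied, while
#' significant pairs that remain unsatisfied in the monomer point at
#' oligomer interfaces or alternative conformational states.
#'
#' @param pairs a \code{coupling_pairs} data frame.
#' @param s an \code{atom_table}.
#' @param chain chain to measure in; default first chain.
#' @param segments a \code{segment_table} used to locate each residue.
#' @param domains list of \code{domain_definition}s (typically transport +
#'   scaffold).
#' @param cutoff contact cutoff in Angstrom (default 10, C-alpha).
#' @param atom_policy \code{"CA"} (C-alpha to C-alpha) or
#'   \code{"all-heavy"} (minimum over heavy-atom pairs).
#' @param min_seq_sep drop trivial near-diagonal pairs with
#'   \code{|i - j| < min_seq_sep} (default 5); set 1 to keep all.
#' @param offset added to the table's residue indices to convert them to
#'   author numbering (coupling tables index the alignment query).
#' @return Data frame of class \code{contact_report}: per pair the
#'   distance, \code{satisfied}, \code{segment_i}, \code{segment_j} and
#'   \code{category} (\code{"intra-domain"}, \code{"inter-domain"} or
#'   \code{"unassigned"}). Attributes record the cutoff and the number of
#'   near-diagonal pairs dropped.
#' @export
classify_contacts <- function(pairs, s, chain = NULL, segments, domains,
                              cutoff = 10, atom_policy = c("CA", "all-heavy"),
                              min_seq_sep = 5, offset = 0) {
  atom_policy <- match.arg(atom_policy)
  if (is.null(chain)) chain <- s$chain[!s$het][1]
  n_near <- sum(abs(pairs$i - pairs$j) < min_seq_sep)
  pr <- pairs[abs(pairs$i - pairs$j) >= min_seq_sep, , drop = FALSE]
  coords <- residue_coords(s, chain, atom_policy)
  dom_of <- domain_lookup(domains)
  ri <- pr$i + offset
  rj <- pr$j + offset
  dist <- mapply(function(a, b) min_residue_distance(coords, a, b), ri, rj)
  seg_i <- assign_segments(data.frame(chain = chain, resno = ri), segments)
  seg_j <- assign_segments(data.frame(chain = chain, resno = rj), segments)
  di <- dom_of(seg_i); dj <- dom_of(seg_j)
  category <- ifelse(is.na(dist) | is.na(di) | is.na(dj), "unassigned",
                     ifelse(di == dj, "intra-domain", "inter-domain"))
  out <- data.frame(i = pr$i, j = pr$j, score = pr$score,
                    significant = pr$significant,
                    resno_i = ri, resno_j = rj,
                    distance = dist, satisfied = !is.na(dist) & dist <= cutoff,
                    segment_i = seg_i, segment_j = seg_j, category = category,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "atom_policy") <- atom_policy
  attr(out, "n_near_diagonal_dropped") <- n_near
  attr(out, "chain") <- chain
  class(out) <- c("contact_report", "data.frame")
  out
}

#' Candidate oligomer-interface / alternative-state contacts
#'
#' Significant coupling pairs that are unsatisfied in the monomer, grouped
#' by segment pair and sorted by decreasing score. These are the
#' hypotheses for dimer-interface contacts (fulfilled across protomers) or
#' for contacts formed only in another conformational state.
#'
#' @param report a \code{contact_report} computed on a monomer.
#' @return Data frame of the unsatisfied significant pairs with a
#'   \code{segment_pair} grouping column.
#' @export
interface_candidates <- function(report) {
  cand <- report[report$significant & !report$satisfied & !is.na(report$distance), ,
                 drop = FALSE]
  if (!nrow(cand)) {
    cand$segment_pair <- character(0)
    return(as.data.frame(cand))
  }
  cand$segment_pair <- paste(pmin(cand$segment_i, cand$segment_j),
                             pmax(cand$segment_i, cand$segment_j), sep = "-")
  cand <- cand[order(cand$segment_pair, -cand$score), , drop = FALSE]
  rownames(cand) <- NULL
  as.data.frame(cand)
}

#' Coupling satisfaction in a two-protomer assembly
#'
#' For each pair, takes the best (minimum) distance over within-protomer A,
#' within-protomer B and across the two protomers (both directions), and
#' reports the satisfied fraction. A parallel dimer can satisfy couplings
#' that are geometrically impossible within one monomer.
#'
#' @param pairs a \code{coupling_pairs} data frame.
#' @param s a two-chain \code{atom_table} with matching residue numbering.
#' @param chains the two protomer chains; default the first two chains.
#' @param cutoff contact cutoff (Angstrom).
#' @param min_seq_sep as in \code{\link{classify_contacts}}.
#' @param offset as in \code{\link{classify_contacts}}.
#' @return List: \code{fraction} satisfied, \code{per_pair} data frame with
#'   the best distance and the arrangement (\code{"intra"}/\code{"inter"})
#'   achieving it.
#' @export
dimer_satisfaction <- function(pairs, s, chains = NULL, cutoff = 10,
                               min_seq_sep = 5, offset = 0) {
  ch <- unique(s$chain[!s$het])
  if (is.null(chains)) chains <- ch[seq_len(min(2, length(ch)))]
  if (length(chains) != 2 || !all(chains %in% ch))
    stop("need exactly two protomer chains; have: ", paste(ch, collapse = ","))
  ca <- lapply(chains, function(c) select_calpha(s, chain = c))
  if (max(abs(range(ca_xyz(ca[[1]])) - range(ca_xyz(ca[[2]])))) < 1e-9 &&
      nrow(ca[[1]]) == nrow(ca[[2]]) &&
      max(abs(ca_xyz(ca[[1]]) - ca_xyz(ca[[2]]))) < 1e-9)
    stop("degenerate geometry: the two protomer chains have identical ",
         "coordinates")
  pr <- pairs[abs(pairs$i - pairs$j) >= min_seq_sep, , drop = FALSE]
  ri <- pr$i + offset; rj <- pr$j + offset
  need <- unique(c(ri, rj))
  for (k in 1:2) {
    absent <- setdiff(need, ca[[k]]$resno)
    if (length(absent))
      stop("chain numbering mismatch: residues ",
           paste(utils::head(absent, 10), collapse = ","),
           " unresolved in chain ", chains[k])
  }
  pt <- function(k, r) ca_xyz(ca[[k]])[match(r, ca[[k]]$resno), , drop = FALSE]
  dd <- function(a, b) sqrt(rowSums((a - b)^2))
  d_aa <- dd(pt(1, ri), pt(1, rj))
  d_bb <- dd(pt(2, ri), pt(2, rj))
  d_ab <- dd(pt(1, ri), pt(2, rj))
  d_ba <- dd(pt(2, ri), pt(1, rj))
  best <- pmin(d_aa, d_bb, d_ab, d_ba)
  arrangement <- ifelse(pmin(d_aa, d_bb) <= pmin(d_ab, d_ba), "intra", "inter")
  list(fraction = mean(best <= cutoff),
       per_pair = data.frame(i = pr$i, j = pr$j, score = pr$score,
                             best_distance = best, arrangement = arrangement,
                             satisfied = best <= cutoff))
}

#' Contact-map plot of predicted vs structural contacts
#'
#' Upper triangle: structural contacts of the monomer (grey); predicted
#' significant couplings drawn over them, colored by whether the monomer
#' satisfies them.
#'
#' @param report a \code{contact_report}.
#' @param path PNG output path.
#' @export
plot_contact_map <- function(report, path) {
  grDevices::png(path, width = 820, height = 800)
  on.exit(grDevices::dev.off(), add = TRUE)
  rng <- range(c(report$resno_i, report$resno_j), na.rm = TRUE)
  plot_one <- function() {
    graphics::plot(NA, xlim = rng, ylim = rng, xlab = "residue i",
                   ylab = "residue j", main = sprintf(
                     "Coupling satisfaction (cutoff %.1f A)", attr(report, "cutoff")))
    ok <- report$significant & report$satisfied
    bad <- report$significant & !report$satisfied
    graphics::points(report$resno_i[ok], report$resno_j[ok], pch = 16,
                     col = "firebrick")
    graphics::points(report$resno_i[bad], report$resno_j[bad], pch = 4,
                     col = "black", lwd = 2)
    graphics::legend("topleft", pch = c(16, 4), col = c("firebrick", "black"),
                     legend = c("significant, satisfied in monomer",
                                "significant, unsatisfied (interface/state candidate)"))
  }
  plot_one()
  invisible(path)
}

# internal: per-residue coordinate lookup for one chain
residue_coords <- function(s, chain, atom_policy) {
  at <- s[!s$het & s$chain == chain, , drop = FALSE]
  if (atom_policy == "CA") at <- at[at$elety == "CA", , drop = FALSE]
  else at <- at[at$elesy != "H", , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  lapply(split(seq_len(nrow(at)), at$resno),
         function(ix) xyz[ix, , drop = FALSE])
}

# internal: minimal inter-residue distance, NA when unresolved
min_residue_distance <- function(coords, ri, rj) {
  a <- coords[[as.character(ri)]]; b <- coords[[as.character(rj)]]
  if (is.null(a) || is.null(b)) return(NA_real_)
  min(sqrt(pmax(0, outer(rowSums(a^2), rowSums(b^2), "+") -
                   2 * tcrossprod(a, b))))
}

# internal: function mapping segment name -> domain name (NA outside)
domain_lookup <- function(domains) {
  map <- list()
  for (d in domains) for (m in d$members) map[[m]] <- d$name
  function(seg) {
    out <- rep(NA_character_, length(seg))
    hit <- !is.na(seg) & seg %in% names(map)
    out[hit] <- unlist(map[seg[hit]])
    out
  }
}
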