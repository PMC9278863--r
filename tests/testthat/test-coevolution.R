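test_that("coupling tables are normalized, deduplicated and thresholded", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("i,j,score", "10,20,0.95", "20,10,0.95", "5,40,0.89",
               "7,7,0.99", "12,90,0.4"), f)
  expect_warning(cp <- read_couplings(f), "self pair")
  expect_equal(nrow(cp), 3)
  expect_true(all(cp$i < cp$j))
  expect_equal(sum(cp$i == 10 & cp$j == 20), 1)
  # boundary: 0.89 at cutoff 0.9 is retained but not significant
  expect_false(cp$significant[cp$i == 5 & cp$j == 40])
  expect_true(cp$significant[cp$i == 10 & cp$j == 20])

  # headerless whitespace-separated tables also parse
  f2 <- tempfile()
  writeLines(c("3 30 0.97", "4 44 0.2"), f2)
  cp2 <- read_couplings(f2)
  expect_equal(cp2$score, c(0.97, 0.2))

  f3 <- tempfile()
  writeLines(c("i,j", "1,2"), f3)
  expect_error(read_couplings(f3), "score")
})

test_that("a generated table's significant count matches the generator", {
  b <- test_bundle()
  f <- tempfile(fileext = ".csv")
  cp <- make_couplings(b, n_true = 80, n_decoy = 100, n_interface = 20,
                       seed = 31, path = f)
  got <- read_couplings(f)
  expect_equal(nrow(got), 200)
  expect_equal(sum(got$significant), sum(cp$class != "decoy"))
})

test_that("contact classification matches planted labels at the 10 A cutoff", {
  b <- test_bundle()
  f <- tempfile(fileext = ".csv")
  cp <- make_couplings(b, n_true = 20, n_decoy = 30, n_interface = 5,
                       seed = 32, path = f)
  pairs <- read_couplings(f)
  rep <- classify_contacts(pairs, b$structure, segments = b$segments,
                           domains = list(b$transport, b$scaffold))
  key <- function(d) paste(d$i, d$j)
  planted <- cp$class[match(key(rep), key(cp))]
  expect_equal(rep$satisfied, planted == "true")
  expect_equal(rep$significant, planted != "decoy")
  expect_true(all(rep$category %in% c("intra-domain", "inter-domain")))
})

test_that("near-diagonal pairs are excluded by default but available", {
  b <- test_bundle()
  pairs <- data.frame(i = c(10L, 11L), j = c(11L, 40L),
                      score = c(0.95, 0.95), significant = TRUE)
  rep <- classify_contacts(pairs, b$structure, segments = b$segments,
                           domains = list(b$transport, b$scaffold))
  expect_equal(nrow(rep), 1)
  expect_equal(attr(rep, "n_near_diagonal_dropped"), 1L)
  # with the filter relaxed, sequence-adjacent residues always touch
  rep2 <- classify_contacts(pairs, b$structure, segments = b$segments,
                            domains = list(b$transport, b$scaffold),
                            min_seq_sep = 1, cutoff = 4)
  expect_true(rep2$satisfied[rep2$i == 10 & rep2$j == 11])
})

test_that("unresolved residues fall into the unassigned category", {
  b <- test_bundle()
  pairs <- data.frame(i = c(10L, 10L), j = c(40L, 999L),
                      score = 0.95, significant = TRUE)
  rep <- classify_contacts(pairs, b$structure, segments = b$segments,
                           domains = list(b$transport, b$scaffold))
  expect_equal(rep$category[rep$j == 999], "unassigned")
  expect_true(is.na(rep$distance[rep$j == 999]))
  expect_false(rep$satisfied[rep$j == 999])
})

test_that("classification is invariant under rigid transforms", {
  b <- test_bundle()
  pairs <- make_couplings(b, 10, 10, 3, seed = 33)
  pairs$significant <- pairs$score >= 0.9
  base <- classify_contacts(pairs, b$structure, segments = b$segments,
                            domains = list(b$transport, b$scaffold))
  s2 <- b$structure
  tf <- rigid_transform(rotation_about_axis(c(2, -1, 1), 63), c(-4, 8, 2))
  s2[, c("x", "y", "z")] <- apply_transform(as.matrix(s2[, c("x", "y", "z")]), tf)
  moved <- classify_contacts(pairs, s2, segments = b$segments,
                             domains = list(b$transport, b$scaffold))
  expect_equal(moved$distance, base$distance, tolerance = 1e-8)
  expect_identical(moved$satisfied, base$satisfied)
  expect_identical(moved$category, base$category)
})

test_that("monomer satisfaction is monotone in the contact cutoff", {
  b <- test_bundle()
  pairs <- make_couplings(b, 15, 20, 5, seed = 34)
  pairs$significant <- pairs$score >= 0.9
  fr <- sapply(c(4, 6, 8, 10, 12, 16, 20), function(cut) {
    rep <- classify_contacts(pairs, b$structure, segments = b$segments,
                             domains = list(b$transport, b$scaffold),
                             cutoff = cut)
    mean(rep$satisfied)
  })
  expect_true(all(diff(fr) >= 0))
})

test_that("interface candidates are exactly the planted unsatisfiable pairs", {
  b <- test_bundle()
  cp <- make_couplings(b, 20, 30, 5, seed = 35)
  cp$significant <- cp$score >= 0.9
  rep <- classify_contacts(cp, b$structure, segments = b$segments,
                           domains = list(b$transport, b$scaffold))
  cand <- interface_candidates(rep)
  planted <- cp[cp$class == "interface", ]
  expect_equal(nrow(cand), 5)
  expect_setequal(paste(cand$i, cand$j), paste(planted$i, planted$j))
  expect_true(all(diff(order(cand$segment_pair)) > 0) ||
                !is.unsorted(cand$segment_pair))

  # no unsatisfied pairs -> empty candidate list
  cp0 <- make_couplings(b, 20, 30, 0, seed = 36)
  cp0$significant <- cp0$score >= 0.9
  rep0 <- classify_contacts(cp0, b$structure, segments = b$segments,
                            domains = list(b$transport, b$scaffold))
  expect_equal(nrow(interface_candidates(rep0)), 0)
})

test_that("a parallel dimer satisfies planted interface pairs across protomers", {
  b <- test_bundle()
  cp <- make_couplings(b, 10, 0, 6, seed = 37)
  cp$significant <- cp$score >= 0.9
  mono <- classify_contacts(cp, b$structure, segments = b$segments,
                            domains = list(b$transport, b$scaffold))

  # far-separated copy: no interface gain, dimer fraction == monomer fraction
  far <- b$structure
  far$chain <- "B"
  far$x <- far$x + 500
  dim_far <- rbind(b$structure, far)
  class(dim_far) <- c("atom_table", "data.frame")
  ds_far <- dimer_satisfaction(cp, dim_far, chains = c("A", "B"))
  expect_equal(ds_far$fraction, mean(mono$satisfied))

  # constructed dimer: protomer B placed so that each planted interface
  # pair's partners meet across the interface at <= 6 A
  cand <- interface_candidates(mono)
  ca <- select_calpha(b$structure)
  xyz <- bundlemotion:::ca_xyz(ca)
  pi <- xyz[match(cand$resno_i[1], ca$resno), ]
  pj <- xyz[match(cand$resno_j[1], ca$resno), ]
  shift <- pi - pj + c(3, 0, 0)  # bring B's j-residue 3 A from A's i-residue
  near <- b$structure
  near$chain <- "B"
  near[, c("x", "y", "z")] <- sweep(as.matrix(near[, c("x", "y", "z")]),
                                    2, -shift)
  dim_near <- rbind(b$structure, near)
  class(dim_near) <- c("atom_table", "data.frame")
  one <- cp[cp$i == cand$i[1] & cp$j == cand$j[1], ]
  ds_near <- dimer_satisfaction(one, dim_near, chains = c("A", "B"), cutoff = 8)
  expect_equal(ds_near$fraction, 1)
  expect_equal(ds_near$per_pair$arrangement, "inter")

  # dimer satisfaction never falls below the monomer's
  ds_any <- dimer_satisfaction(cp, dim_near, chains = c("A", "B"))
  expect_gte(ds_any$fraction, mean(mono$satisfied))

  # identical coordinates for both protomers are rejected
  twin <- b$structure
  twin$chain <- "B"
  dim_bad <- rbind(b$structure, twin)
  class(dim_bad) <- c("atom_table", "data.frame")
  expect_error(dimer_satisfaction(cp, dim_bad, chains = c("A", "B")),
               "degenerate")

  # numbering mismatches are named
  short <- far[far$resno > 50, ]
  dim_short <- rbind(b$structure, short)
  class(dim_short) <- c("atom_table", "data.frame")
  expect_error(dimer_satisfaction(cp, dim_short, chains = c("A", "B")),
               "mismatch")
})
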