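#!/usr/bin/env Rscript
# Step 6 -- the same pipeline on experimentally determined structures.
#
# Runs the full analysis on a user-supplied pair of depositions of the
# zinc transporter (metal-bound inward-open reference vs the metal-free
# inward-open conformation, chain B), using the TM definitions of the
# metal-bound structure. Expects, under inst/extdata/reference (or a
# directory given as the first argument):
#   metal_bound.pdb, metal_free.pdb, segments.tsv
# segments.tsv must define TM1..TM8 (and optionally TMa, excluded from the
# DDM by default).
#
# Expected readouts with those inputs: overall C-alpha RMSD ~1.75 A; the
# TM1/4/5/6 vs TM2/3/7/8 rigid-body partition; ~3 A cytoplasmic
# translation and ~11 deg tilt of the transport domain; ~14.5 deg
# reorientation of TM4's cytoplasmic half; ~4.5 A displacement of the
# metal-binding region (H177/E181/Q207/E211); TM3-TM8 > 20 A apart in the
# monomer; and an 8 A outward translation minimizing the six unsatisfied
# coupling-pair distances.

suppressMessages(library(bundlemotion))
args <- commandArgs(trailingOnly = TRUE)
ref_dir <- if (length(args)) args[1] else
  system.file("extdata", "reference", package = "bundlemotion")
files <- file.path(ref_dir, c("metal_bound.pdb", "metal_free.pdb", "segments.tsv"))
if (!all(file.exists(files))) {
  cat("Reference depositions not found under", ref_dir, "\n")
  cat("Place metal_bound.pdb, metal_free.pdb and segments.tsv there, or pass",
      "a directory as the first argument.\n")
  quit(status = 1)
}
out <- "results/reference"
bound <- read_structure(files[1])
free <- read_structure(files[2])
segs <- read_segments(files[3])
scaffold <- domain_definition("scaffold", c("TM2", "TM3", "TM7", "TM8"), segs)
transport <- domain_definition("transport", c("TM1", "TM4", "TM5", "TM6"), segs)

res <- run_ddm(bound, free, segs, file.path(out, "ddm"), chain_b = "B",
               plots = TRUE)
cat("overall RMSD:", round(res$superposition$rmsd, 2), "A\n")
print(res$partition)

metal_site <- site_definition("metal-binding region", rep("A", 4),
                              c(177, 181, 207, 211))
rep <- run_motion(bound, free, segs, scaffold, transport,
                  file.path(out, "motion"), chain_b = "B",
                  sites = list(metal_site), tm4_split = "TM4")
print(rep)

cs <- constraint_set(c(106, 261, 272, 102, 269, 269),
                     c(207, 183, 173, 207, 211, 208))
scan <- run_scan(bound, segs, transport, cs, file.path(out, "state_model"))
print(scan)
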