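#!/usr/bin/env Rscript
# Step 5 -- model the outward-facing state by a constraint-guided scan.
#
# Starting from an inward-open conformation (the reference bundle with its
# transport domain sitting 8 A toward the cytoplasm), the transport domain
# is translated along the membrane normal in 1 A steps. The objective is
# the summed C-alpha distance over six cross-domain constraint pairs that
# the inward state cannot satisfy; its minimum locates the outward-facing
# state, which is written out as a PDB model with the applied transform in
# its header.

suppressMessages(library(bundlemotion))
out <- "results/state_model"

b <- make_bundle(bundle_spec(noise_sd = 0, seed = 1L))
ca <- select_calpha(b$structure, segments = b$segments)
tr <- ca[ca$segment %in% b$transport$members, ]
sc <- ca[ca$segment %in% b$scaffold$members, ]
# six cross-domain pairs aligned in height in the outward state
set.seed(1)
pick <- sample(nrow(tr), 6)
nearest <- sapply(pick, function(k) {
  same_z <- which(abs(sc$z - tr$z[k]) < 1e-9)
  same_z[which.min((sc$x[same_z] - tr$x[k])^2 + (sc$y[same_z] - tr$y[k])^2)]
})
cs <- constraint_set(tr$resno[pick], sc$resno[nearest])
inward <- apply_motion(b, motion_spec(translation = -8, rotation_deg = 0))

scan <- run_scan(inward, b$segments, b$transport, cs, out,
                 normal = c(0, 0, 1), step = 1, range = c(0, 15))
print(scan)
prof <- scan$profile
cat(sprintf("objective: %.1f A at t=0  ->  %.1f A at t=%g A\n",
            prof$objective[1], min(prof$objective), scan$argmin))
cat(sprintf("clashes introduced across the domain boundary: %d\n",
            attr(scan$model, "clash_count")))
cat("Profile, summary and model written to", out, "\n")
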