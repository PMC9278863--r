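# bundlemotion

Rigid-body domain motion analysis for elevator-type membrane transporters.

Secondary transporters of the elevator class carry their substrate-binding
site on a mobile **transport domain** that slides along a static,
oligomer-forming **scaffold domain**. Given two experimentally determined
conformations of such a protein (e.g. a metal-bound and a metal-free state
of a ZIP-family zinc transporter), `bundlemotion` answers four questions a
structural biologist asks of that pair:

1. **Which helices move together?** The C-alpha distance-difference matrix
   (DDM) `Δᵢⱼ = d⁽ᵇ⁾ᵢⱼ − d⁽ᵃ⁾ᵢⱼ` is invariant to rigid motion, so helices
   belonging to one rigid body give near-zero blocks. Aggregating `Δ` to a
   per-helix-pair RMS and clustering that matrix (average linkage) yields
   the rigid-body partition and a separation score
   (`ddm()`, `aggregate_by_segment()`, `partition_domains()`).
2. **How does the mobile domain move?** After a Kabsch (SVD) least-squares
   superposition on the scaffold C-alphas, the residual rigid transform of
   the transport domain is decomposed into a tilt angle
   `θ = arccos((tr R − 1)/2)` and a translation of the domain centroid,
   split along/perpendicular to the membrane normal — estimated as the
   consensus direction of the TM helix axes (`domain_motion()`,
   `estimate_membrane_normal()`).
3. **Which evolutionary couplings does the structure satisfy?** Scored
   residue pairs from a coevolution server are classified by their minimal
   distance in the monomer; significant pairs that no monomer conformation
   can satisfy are candidate oligomer-interface or alternative-state
   contacts, testable in a two-protomer assembly (`classify_contacts()`,
   `interface_candidates()`, `dimer_satisfaction()`).
4. **What does the missing state look like?** A constraint-guided scan
   translates the transport domain along the membrane normal in 1 A steps
   and minimizes the summed C-alpha distance over a constraint pair set,
   emitting the minimizing structure as a geometric model
   (`scan_translation()`, `build_model()`).

A synthetic generator (`make_bundle()`, `apply_motion()`,
`make_couplings()`) builds ideal helix bundles with known rigid-body
motions and planted coupling classes, so the entire pipeline is validated
closed-loop without downloading any structure.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (`Rscript analysis/01_simulate.R`, then `02`…`05`). Step 1 generates
a noisy 8-helix bundle pair whose transport domain (TM1/TM4/TM5/TM6) was
displaced 3 A toward the cytoplasm and tilted 11 degrees; steps 2–3 then
recover, from the coordinates alone:

```
Overall C-alpha RMSD: 1.94 A over 200 residues
Rigid-body partition (separation 1.931 A)
Domain 'domain_TM1': TM1, TM4, TM5, TM6
Domain 'domain_TM2': TM2, TM3, TM7, TM8

Inter-domain motion (scaffold frame, 100 scaffold / 100 transport C-alpha)
  overall RMSD:           1.94 A
  translation:            3.00 A cytoplasmic (0.00 A in-plane)
  tilt:                  11.00 deg
```

The partition, the translation and the tilt equal the planted ground
truth. Step 4 classifies the planted coupling table — all 5
monomer-unsatisfiable significant pairs are returned as interface
candidates, and a parallel dimer placed across the top candidate raises
the satisfied fraction (0.36 → 0.40 in the demo). Step 5 starts from an
inward-open state and recovers the outward-facing model by the constraint
scan:

```
Translation scan 0..15 A (step 1): argmin 8 A, objective 67.83 A
objective: 83.9 A at t=0  ->  67.8 A at t=8 A
```

`analysis/06_reference_pipeline.R` runs the identical pipeline on a pair
of real depositions the user supplies (metal-bound and metal-free
conformations plus a TM-segment table) and prints the same readouts:
overall RMSD, rigid-body partition, translation/tilt decomposition,
metal-site displacement and the outward-translation scan.

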