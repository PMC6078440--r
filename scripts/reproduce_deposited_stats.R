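#!/usr/bin/env Rscript

# Optional, network-dependent reproduction of the deposited-ensemble
# precision statistics and inter-structure homology RMSDs. Downloads
# public PDB entries (5O57 solution ensemble; 5FWW; 2A2V) from RCSB and
# runs the package's estimators on them. Not part of the test suite:
# requires internet access.
#
# Usage: Rscript scripts/reproduce_deposited_stats.R [workdir]

suppressMessages(library(solnmr))

workdir <- commandArgs(trailingOnly = TRUE)[1]
if (is.na(workdir)) workdir <- tempdir()

fetch <- function(id) {
  path <- file.path(workdir, paste0(id, ".pdb"))
  if (!file.exists(path)) {
    utils::download.file(sprintf("https://files.rcsb.org/download/%s.pdb",
                                 id), path, quiet = TRUE)
  }
  read_pdb_ensemble(path)
}

# Ensemble precision of the well-defined CRD1 core (residues 44-47 and
# 50-96): RMSD to the mean structure, backbone and all heavy atoms.
dkk4 <- fetch("5O57")
bb <- rmsd_to_mean(dkk4, "44-47,50-96:backbone")
heavy <- rmsd_to_mean(dkk4, "44-47,50-96:backbone", "44-47,50-96:heavy")
cat(sprintf("5O57 core backbone RMSD-to-mean: %.2f +/- %.2f A\n",
            bb$mean_rmsd, bb$sd_rmsd))
cat(sprintf("5O57 core heavy-atom RMSD-to-mean: %.2f +/- %.2f A\n",
            heavy$mean_rmsd, heavy$sd_rmsd))

# CRD1 vs Dkk1 CRD2 (5FWW chain C) over the printed segment lists.
dkk1 <- fetch("5FWW")
r_crd2 <- segment_rmsd(dkk4, dkk1,
                       "40-57,59-75,78-93", "188-222,238-247,261-266",
                       atom = "CA", chainB = "C")
cat(sprintf("CRD1 vs Dkk1 CRD2 segment RMSD: %.1f A\n", r_crd2))

# CRD1 C-subdomain vs Jingzhaotoxin XI (2A2V).
jtx <- fetch("2A2V")
r_ick <- segment_rmsd(dkk4, jtx, "65-94", "1-22,25-32", atom = "CA")
cat(sprintf("CRD1 C-subdomain vs Jingzhaotoxin XI segment RMSD: %.1f A\n",
            r_ick))
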