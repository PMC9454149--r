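Package: rldock
Title: Reinforcement-Learning Protein-Ligand Docking in Voxelized Pockets
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale framework for rigid protein-ligand binding pose
    search by deep reinforcement learning. Crystal structures are voxelized
    into 18 Angstrom cubic boxes with Gaussian-smoothed per-channel atom
    densities; a discrete translate/rotate agent walks the ligand through the
    box; an asynchronous advantage actor-critic (A3C) learner trains a
    3D-convolutional actor (move policy) and critic (long-term reward
    estimate) against an exponential-RMSD reward; at test time a
    critic-convergence rule stops the greedy search without access to the
    true pose. Includes PDB input/output, dataset filters, a deterministic
    synthetic-complex generator, the full evaluation metric set (RMSD,
    permutation-distance, center-distance, improvement rate, critic distance,
    DCC success rate) and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
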