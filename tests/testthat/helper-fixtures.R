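# Shared fixtures and small utilities for the test suite.  Everything is
# generated in code; no data files.

# Deterministically jitter the interior corner nodes of a mesh (midside
# nodes are re-set to edge midpoints so elements stay straight-sided).
# Used to de-structure the grid for patch tests.
jitter_mesh <- function(mesh, amount, seed = 42) {
  set.seed(seed)
  nv <- max(mesh$elements[, 1:3])
  r <- mesh$nodes[, 1]; z <- mesh$nodes[, 2]
  rng <- apply(mesh$nodes, 2, range)
  interior <- seq_len(nv)
  interior <- interior[r[interior] > rng[1, 1] + 1e-9 &
                         r[interior] < rng[2, 1] - 1e-9 &
                         z[interior] > rng[1, 2] + 1e-9 &
                         z[interior] < rng[2, 2] - 1e-9]
  mesh$nodes[interior, 1] <- r[interior] +
    runif(length(interior), -amount, amount)
  mesh$nodes[interior, 2] <- z[interior] +
    runif(length(interior), -amount, amount)
  for (s in 1:3) {
    a <- mesh$elements[, s]; b <- mesh$elements[, s %% 3 + 1]
    mid <- mesh$elements[, s + 3]
    mesh$nodes[mid, ] <- (mesh$nodes[a, ] + mesh$nodes[b, ]) / 2
  }
  mesh
}

# all nodes lying on the outline of a rectangular fixture mesh
rect_boundary_nodes <- function(mesh) {
  r <- mesh$nodes[, 1]; z <- mesh$nodes[, 2]
  which(abs(r - min(r)) < 1e-8 | abs(r - max(r)) < 1e-8 |
          abs(z - min(z)) < 1e-8 | abs(z - max(z)) < 1e-8)
}

# randomly renumber the nodes of a mesh (elements, tags, edge sets and
# interface table remapped accordingly)
permute_mesh_nodes <- function(mesh, seed = 1) {
  set.seed(seed)
  n <- nrow(mesh$nodes)
  perm <- sample.int(n)          # old id -> new id
  mesh$nodes[perm, ] <- mesh$nodes
  mesh$elements[] <- perm[mesh$elements]
  mesh$tags <- lapply(mesh$tags, function(v) sort(perm[v]))
  mesh$edge_sets <- lapply(mesh$edge_sets, function(e) {
    e[] <- perm[e]; e
  })
  if (!is.null(mesh$interface)) {
    for (cl in c("n1", "n2", "mid"))
      mesh$interface[[cl]] <- perm[mesh$interface[[cl]]]
  }
  mesh
}

# one small bilayer configuration reused across tests
small_bilayer_config <- function(pct_HA = 10, pct_p = 10, T_L = 2,
                                 porous = TRUE, branch = "upper") {
  implant_config("bilayer", T_L = T_L,
                 composition = composite_shell_spec(pct_HA, 100 - pct_HA,
                                                    pct_p),
                 porous = porous, bound_branch = branch)
}
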