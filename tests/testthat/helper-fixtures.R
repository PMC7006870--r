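# Shared fixtures, built in code at test time.

small_design <- function() task_design()

# A compact cohort spec for fast unit tests: the 5-area planted core plus
# three weakly coupled areas, ~8-12 voxels each.
small_spec <- function(n_subjects = 4L, seed = 101L, ...) {
  catalog <- tibble::tibble(
    froi = c("op-BA", "tri-BA", "WA", "preMA", "pre-SMA", "aMFG", "SMG", "AG"),
    min_voxels = 8L, max_voxels = 12L,
    core = c(rep(TRUE, 5), rep(FALSE, 3)),
    obligatory = c(rep(TRUE, 5), rep(FALSE, 3))
  )
  cohort_spec(
    n_subjects = n_subjects,
    froi_catalog = catalog,
    seed = seed,
    ...
  )
}

core_frois <- function() c("op-BA", "tri-BA", "WA", "preMA", "pre-SMA")

# A deterministic toy voxel network:
#   fROI A voxels 0,1,2; fROI B voxels 3,4; 4 cross edges and 1 within edge.
toy_voxel_network <- function() {
  nodes <- tibble::tibble(
    voxel_id = 0:4,
    froi = c("A", "A", "A", "B", "B")
  )
  edges <- tibble::tibble(
    from = c(0L, 0L, 1L, 2L, 0L),
    to = c(3L, 4L, 3L, 4L, 1L),
    weight = c(0.9, 0.8, 0.85, 0.75, 0.95)
  )
  structure(list(nodes = nodes, edges = edges, theta = 0.7, subject_id = "toy"),
            class = "voxel_network")
}

# Minimal froi_network with given normalized edge weights.
toy_fnet <- function(edges) {
  frois <- unique(c(edges$froi_i, edges$froi_j))
  structure(
    list(nodes = tibble::tibble(froi = frois, size = 5L),
         edges = tibble::as_tibble(edges), theta = 0.7, subject_id = "toy"),
    class = "froi_network"
  )
}
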