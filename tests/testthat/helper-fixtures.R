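# Shared fixtures, built in code at load time.

# Coarse hemispherical shell (fast to build, ~500 nodes); cached per session.
coarse_mesh <- local({
  m <- NULL
  function(h = 0.75) {
    key <- paste0("h", h)
    if (is.null(m[[key]]))
      m[[key]] <<- build_shell_mesh(mesh_spec(h_min = h / 3, h_max = h))
    m[[key]]
  }
})

# Full-scale mesh, built once (about a second).
full_mesh <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_shell_mesh(mesh_spec())
    m
  }
})

# One well-stirred unit voxel.
unit_voxel <- function(volume = 1) voxel_chain(1, volumes = volume)

# Birth-death model: influx `molecules_per_s`, unit decay.
birth_death_model <- function(molecules_per_s = 50, volume = 1,
                              decay = 1) {
  u <- one_molecule_uM(volume)
  rd_model(
    species("A", D = 0),
    reaction("birth", "zeroth", k = molecules_per_s * u,
             stoich = c(A = +1)),
    reaction("death", "first", k = decay, reactants = "A",
             stoich = c(A = -1)))
}

# Two-voxel, two-species toy: A <-> B conversion plus diffusion of both.
toy_ab_model <- function(k_ab = 1, k_ba = 0.5, D = 0.5) {
  rd_model(
    species("A", D = D), species("B", D = D),
    reaction("ab", "first", k = k_ab, reactants = "A",
             stoich = c(A = -1, B = +1)),
    reaction("ba", "first", k = k_ba, reactants = "B",
             stoich = c(B = -1, A = +1)))
}

# Empirical cumulative-distribution KS distance between two integer samples.
ks_distance <- function(x, y) {
  g <- sort(unique(c(x, y)))
  max(abs(ecdf(x)(g) - ecdf(y)(g)))
}
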