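# shared toy fixtures, built once per test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small pocket complex used by most unit tests
tiny_sys <- function() cached("tiny", make_toy_complex(
  toy_system_spec(n_receptor_atoms = 24L, pocket_depth = 3, ligand_size = 3L,
                  seed = 7L)))

tiny_engine <- function() cached("tiny_eng", {
  s <- tiny_sys()
  toy_engine(list(s$receptor, s$ligand), eps_in = 1)
})

tiny_coords <- function() {
  s <- tiny_sys()
  rbind(coords(s$receptor), coords(s$ligand))
}

# short-interaction-range probe system (sigma 2 A): far shells of the
# default schedule are far outside the interaction range
shortrange_sys <- function(depth = 0.5) make_toy_complex(
  toy_system_spec(n_receptor_atoms = 16L, receptor_radius = 2.0,
                  pocket_depth = depth, ligand_size = 1L, lj_sigma = 2.0,
                  seed = 7L))

# a bare two-atom structure with explicit parameters, for hand-computable
# energy checks
two_atom_structure <- function(d = 2^(1/6) * 3, charge = c(0, 0),
                               sigma = 3, epsilon = 1, born = 1.5,
                               role = "ligand") {
  molecular_structure(data.frame(
    name = c("A1", "A2"), element = "C", x = c(0, d), y = 0, z = 0,
    charge = charge, sigma = sigma, epsilon = epsilon, born_radius = born,
    mass = 12), role = role, label = "pair")
}

single_ion <- function(q = 1, a = 1.5) {
  molecular_structure(data.frame(
    name = "ION", element = "NA", x = 0, y = 0, z = 0, charge = q,
    sigma = 2.5, epsilon = 0.1, born_radius = a, mass = 23),
    role = "ligand", label = "ion")
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

sphere_pts <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  rho <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * k
  cbind(rho * cos(phi), rho * sin(phi), z)
}

# separable quadratic bowl satisfying the external-engine contract
quad_engine <- function(center, k = 1) {
  structure(list(
    eps_in = 1, eps_w = 78.5, n_atoms = nrow(center),
    masses = rep(12, nrow(center)),
    energy = function(x) k * sum((x - center)^2),
    gradient = function(x) 2 * k * (x - center)),
    class = "energy_model")
}
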