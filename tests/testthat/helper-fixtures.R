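# Small phantoms and configs shared across tests (built in code, no files).

small_phantom_spec <- function(intensity = 100, touching = FALSE) {
  if (touching) {
    sph <- data.frame(x = c(13, 29), y = c(20, 20), z = c(7, 7),
                      r = c(7, 9), intensity = intensity)
    sphere_phantom_spec(shape = c(48, 40, 15), spheres = sph,
                        background_level = 10)
  } else {
    sph <- data.frame(x = c(12, 29), y = c(13, 27), z = c(7, 7),
                      r = c(5, 5), intensity = intensity)
    sphere_phantom_spec(shape = c(42, 40, 14), spheres = sph,
                        background_level = 10)
  }
}

small_patch <- function() patch_spec(c(7, 7, 3))

small_learning <- function(seed = 42L)
  learning_config(K = 16L, L = 2L, n_iter = 4L, seed = seed,
                  max_train = 3000L)

# deterministic random volume
rand_volume <- function(dims, seed = 1) {
  set.seed(seed)
  array(runif(prod(dims), 0, 100), dim = dims)
}
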