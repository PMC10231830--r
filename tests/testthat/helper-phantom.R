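# Shared fixtures: small cubes, phantom pools and a fibrous-RMSE evaluator.

tiny_grid <- function(n = 5) wavelength_grid(420, 420 + 5 * (n - 1), 5)

random_cube <- function(h = 4, w = 4, b = 61, seed = 1,
                        grid = if (b == 61) default_grid() else tiny_grid(b)) {
  set.seed(seed)
  hsi_cube(array(runif(h * w * b, 0, 1.2), c(h, w, b)), grid)
}

random_rgb <- function(h = 8, w = 8, seed = 1) {
  set.seed(seed)
  rgb_image(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)))
}

toy_pools <- function(seed, n_unpaired = 8, n_paired = 4, n_test = 3,
                      size = 32) {
  pc <- function(s) phantom_config(size = c(size, size), seed = s)
  ds <- function(stream, i) hyperstain:::derive_seed(seed, stream, i)
  he <- lapply(seq_len(n_unpaired),
               function(i) generate_phantom(pc(ds(1L, i)))$he_cube)
  evg <- lapply(seq_len(n_unpaired),
                function(i) generate_phantom(pc(ds(2L, i)))$evg_rgb)
  paired <- lapply(seq_len(n_paired),
                   function(i) generate_phantom(pc(ds(3L, i))))
  test <- lapply(seq_len(n_test),
                 function(i) generate_phantom(pc(ds(4L, i))))
  list(unpaired = list(he_cubes = he, evg_rgbs = evg),
       paired = list(he_cubes = lapply(paired, `[[`, "he_cube"),
                     evg_rgbs = lapply(paired, `[[`, "evg_rgb")),
       test = test)
}

mean_fibrous_rmse <- function(gen, test_samples) {
  mean(vapply(test_samples, function(ph) {
    pred <- convert_cube(gen, ph$he_cube)
    fibrous_rmse(ph$evg_rgb, pred, fibrous_mask(ph$evg_rgb))$rmse
  }, numeric(1)))
}

test_basis <- function() {
  ldf <- phantom_ldf(phantom_config(size = c(32, 32), seed = 999))
  resolve_basis("ldf_dyes", ldf = ldf)
}
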