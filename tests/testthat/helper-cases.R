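# Shared fixtures: all synthetic, built in code at test time.

make_volume <- function(arr, spacing = c(1, 1, 1)) pet_volume(arr, spacing)

ball_mask <- function(grid = c(16L, 16L, 16L), radius = 5, center = grid / 2) {
  ax <- lapply(1:3, function(k) seq_len(grid[k]) - center[k])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  roi_mask(array(as.integer(r2 <= radius^2), grid))
}

# a small case with smooth structure + noise, deterministic
toy_case <- function(seed = 1L, grid = c(20L, 20L, 20L), radius = 6) {
  set.seed(seed)
  m <- ball_mask(grid, radius)
  ax <- lapply(1:3, function(k) seq_len(grid[k]) - grid[k] / 2)
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  v <- 5 + 10 * exp(-r2 / 40) + array(rnorm(prod(grid), sd = 0.4), grid)
  list(volume = pet_volume(v), mask = m)
}

# tiny labeled cohort from the generator, shared config
small_cohort <- function(n = 24L, seed = 7L, ...) {
  cfg <- generator_config(n_cases = n, seed = seed, ...)
  generate_cohort(cfg)
}

expect_seeded_equal <- function(expr1, expr2) {
  expect_identical(expr1, expr2)
}
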