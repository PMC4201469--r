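# Shared fixtures, built in code and cached per test run.

fixture_env <- new.env(parent = emptyenv())

# Memoise expensive fixtures so several test files can share them.
fixture <- function(name, expr) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, force(expr), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# Small phantom spec for fast unit tests (32^3 at 0.5 mm, same 16 mm FOV).
small_spec <- function(seed = 0L, ...) {
  phantom_spec(dim = c(32L, 32L, 32L), spacing = 0.5, n_regions = 6L,
               pet_dim = c(16L, 16L, 16L), pet_spacing = 1,
               seed = seed, ...)
}

small_phantom <- function() {
  fixture("small_phantom", make_base_phantom(small_spec()))
}

# Full-scale phantom (64^3 at 0.25 mm), used by registration tests.
std_phantom <- function() {
  fixture("std_phantom", {
    set.seed(7)
    make_base_phantom(phantom_spec())
  })
}

# Random label volume on a small grid.
random_labels <- function(dim = c(8L, 8L, 8L), ids = 0:3, seed = 1L,
                          spacing = 1) {
  set.seed(seed)
  label_volume(array(sample(ids, prod(dim), replace = TRUE), dim),
               spacing = spacing)
}

random_scalar <- function(dim = c(8L, 8L, 8L), seed = 1L, spacing = 1) {
  set.seed(seed)
  scalar_volume(array(rnorm(prod(dim)), dim), spacing = spacing)
}

# Brute-force per-voxel overlap counting (independent oracle).
brute_overlap <- function(ref, auto, id) {
  n_m <- 0L; n_a <- 0L; n_i <- 0L
  rv <- as.integer(ref$data); av <- as.integer(auto$data)
  for (i in seq_along(rv)) {
    m <- rv[i] == id
    a <- av[i] == id
    n_m <- n_m + m
    n_a <- n_a + a
    n_i <- n_i + (m && a)
  }
  list(n_manual = n_m, n_automated = n_a, n_intersection = n_i)
}

# Brute-force per-voxel histogram-argmax fusion with the documented tie
# policy (prefer nonzero, then smallest nonzero id).
brute_fuse <- function(vols) {
  n <- length(vols[[1]]$data)
  out <- integer(n)
  for (i in seq_len(n)) {
    votes <- vapply(vols, function(v) as.integer(v$data[i]), integer(1))
    tab <- table(votes)
    mx <- max(tab)
    cands <- as.integer(names(tab)[tab == mx])
    nz <- cands[cands != 0L]
    out[i] <- if (length(nz)) min(nz) else 0L
  }
  label_volume(array(out, dim(vols[[1]]$data)), affine = vols[[1]]$affine)
}
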