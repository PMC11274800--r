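# Shared fixtures. Generated objects are memoized so expensive chemistry
# runs once per test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(build)
  .fixtures[[name]]
}

fix_small_library <- function() {
  fixture("small_library", gen_scaffold_library(synthetic_library_spec(
    scaffold_pool = c("quinoline", "benzene", "thiophene", "piperidine"),
    frequency = c(8L, 6L, 4L, 2L), n_acyclic = 3L, seed = 42L)))
}

fix_activity <- function() {
  fixture("activity", gen_activity_dataset(synthetic_activity_spec(
    n_active = 30L, n_inactive = 30L, separability = 1,
    ambiguous_fraction = 0.1, contradictory_pairs = 2L, seed = 7L)))
}

# independent dense-matrix Tanimoto oracle (explicit pair loop)
oracle_pairwise_tanimoto <- function(fps) {
  n <- nrow(fps)
  vals <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- fps[i, ] == 1L; b <- fps[j, ] == 1L
      u <- sum(a | b)
      vals <- c(vals, if (u == 0) 1 else sum(a & b) / u)
    }
  }
  vals
}
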