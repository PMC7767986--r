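# Shared small populations, built once per test run.

small_cfg <- function(seed = 11L, ...) {
  args <- list(seed = seed, n_snp = 400L, n_qtl = 40L,
               group_sizes = c(H_bull = 10L, J_bull = 10L, H_cow = 40L,
                               J_cow = 40L, X75_cow = 30L, X50_cow = 60L,
                               X25_cow = 30L))
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

.pop_cache <- new.env(parent = emptyenv())

small_pop <- function() {
  if (is.null(.pop_cache$small)) .pop_cache$small <-
      simulate_population(small_cfg())
  .pop_cache$small
}

# two diverged breeds + F1, sized for breed-assignment recovery checks
breeds_pop <- function() {
  if (is.null(.pop_cache$breeds)) .pop_cache$breeds <- simulate_population(
    sim_config(seed = 21L, n_snp = 2000L, n_qtl = 50L, fst = 0.1,
               group_sizes = c(H_bull = 0L, J_bull = 0L, H_cow = 60L,
                               J_cow = 60L, X75_cow = 30L, X50_cow = 30L,
                               X25_cow = 30L)))
  .pop_cache$breeds
}

expect_no_failures <- function(tab) {
  expect_length(attr(tab, "failures"), 0)
}
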