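# Simulated datasets are expensive; build each once per test run and
# reuse across test files.

.sim_cache <- new.env(parent = emptyenv())

# Study-scale default simulation (1.8 Mbp background, both domain
# families, collapse multiplicities 2/3/5).
default_sim <- function() {
  if (is.null(.sim_cache$default)) {
    .sim_cache$default <- simulate_genome(
      sim_config(seed = 42L),
      file.path(tempdir(), "gadarch_default_sim"))
  }
  .sim_cache$default
}

# Small simulation for unit-level planted-truth checks.
small_sim <- function() {
  if (is.null(.sim_cache$small)) {
    .sim_cache$small <- simulate_genome(
      sim_config(seed = 11L, n_contigs = 2L, contig_length = 100000L,
                 n_genes = 40L, n_go_terms = 12L, n_tri_indel_genes = 4L,
                 domain_families = list(
                   fam_a = list(consensus_length = 60L, n_copies = 6L,
                                pseudogene_fraction = 0.34,
                                collapse = c(2L)))),
      file.path(tempdir(), "gadarch_small_sim"))
  }
  .sim_cache$small
}

small_assembly <- function() {
  if (is.null(.sim_cache$small_asm))
    .sim_cache$small_asm <- read_assembly(small_sim()$files[["assembly"]])
  .sim_cache$small_asm
}

default_assembly <- function() {
  if (is.null(.sim_cache$default_asm))
    .sim_cache$default_asm <- read_assembly(default_sim()$files[["assembly"]])
  .sim_cache$default_asm
}

default_strs <- function() {
  if (is.null(.sim_cache$default_strs))
    .sim_cache$default_strs <- find_strs(default_assembly())
  .sim_cache$default_strs
}

default_census <- function() {
  if (is.null(.sim_cache$default_census)) {
    sim <- default_sim()
    .sim_cache$default_census <- census(
      default_assembly(), sim$truth$profiles,
      read_placed_map(sim$files[["placed"]]))
  }
  .sim_cache$default_census
}
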