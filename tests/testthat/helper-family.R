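# Shared synthetic families, generated once per test run.

.family_cache <- new.env()

cached <- function(key, expr) {
  if (!exists(key, envir = .family_cache))
    assign(key, expr, envir = .family_cache)
  get(key, envir = .family_cache)
}

# A small, fast family: 8 clades, ~90 members.
small_clades <- function() {
  data.frame(
    clade = c("CanA", "CanB", "CanC", "CanD", "CanE", "Semi1",
              "Non1", "Non2"),
    type = c(rep("canonical", 5), "semicanonical",
             rep("noncanonical", 2)),
    size = c(20L, 12L, 12L, 12L, 12L, 10L, 12L, 10L),
    stringsAsFactors = FALSE)
}

small_family <- function() cached("small", {
  generate_family(pin_sim_config(seed = 42, clades = small_clades(),
                                 ref_clade = "CanA"))
})

# Same clades, no truncation or insertions (clean boundaries).
clean_family <- function() cached("clean", {
  generate_family(pin_sim_config(seed = 43, clades = small_clades(),
                                 ref_clade = "CanA", trunc_prob = 0,
                                 target_missing = 0, missing_tol = 1,
                                 insertion_rate = 0))
})

# Full default study conditions (473 sequences, 45% missing).
default_family <- function() cached("default", {
  generate_family(pin_sim_config(seed = 202))
})

default_partitions <- function() cached("default_parts", {
  delineate_all(default_family()$records)
})
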