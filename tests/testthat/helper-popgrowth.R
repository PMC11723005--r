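# shared fixtures, all built in code

# tiny deterministic tree table: 2 clones x 2 trees x ages 2-5
tiny_trees <- function() {
  grid <- expand.grid(
    clone_id = c("A", "B"), tree_id = c("T1", "T2"),
    age = 2:5, stringsAsFactors = FALSE
  )
  tibble::as_tibble(grid) |>
    dplyr::mutate(
      cross_type = ifelse(clone_id == "A", "DxM", "MxD"),
      block = 1L,
      dbh = 2 * age + ifelse(clone_id == "A", 2, 0) +
        ifelse(tree_id == "T2", 0.5, 0),
      height = 1.5 * age + ifelse(clone_id == "A", 1, 0)
    ) |>
    dplyr::select(clone_id, cross_type, block, tree_id, age, dbh, height)
}

write_measurement_csv <- function(rows, path,
                                  header = c("clone_id", "cross_type",
                                             "block", "tree_id", "age",
                                             "dbh_cm", "height_m")) {
  lines <- c(paste(header, collapse = ","),
             apply(rows, 1, paste, collapse = ","))
  writeLines(lines, path)
  path
}

# default simulated trial, shared across tests (computed once per run)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_trial(seed = 1)
    cache
  }
})

shared_traits <- function() derive_traits(shared_sim()$measurements)

# noise-free trial: clone effects only, no tree effects/noise/mortality
noise_free_sim <- function(seed = 7) {
  cfg <- growth_sim_config(
    tree_sd_K = 0, noise_sd = c(dbh = 0, height = 0), mortality = 0
  )
  simulate_trial(cfg, seed = seed)
}
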