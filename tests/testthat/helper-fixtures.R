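# small fixtures shared across test files

# a tiny two-layer model for fast engine tests
tiny_params <- function(...) {
  args <- list(grid_n = 3, layers = c("IV", "VI"),
               neurons_e_per_layer = c(IV = 80, VI = 80),
               neurons_i_per_layer = c(IV = 20, VI = 20),
               gain_e = 2e-4, gain_i = 4e-4, range_e = 1, range_i = 0.4)
  over <- list(...)
  args[names(over)] <- over
  do.call(lcm_params, args)
}

tiny_map <- function() {
  validate_connection_map(data.frame(
    source_layer = c("IV", "IV", "IV", "IV", "VI", "VI", "IV", "VI",
                     "external", "external"),
    source_pop = c("E", "E", "I", "I", "E", "I", "E", "E",
                   "thalamic", "cortico-cortical"),
    target_layer = c("IV", "IV", "IV", "IV", "VI", "VI", "VI", "IV", "IV",
                     "VI"),
    target_pop = c("E", "I", "E", "I", "E", "E", "E", "I", "E", "E"),
    count = c(100, 80, 50, 40, 90, 30, 60, 70, 20, 10),
    category = c(rep("intracortical", 8), "thalamic", "cortico-cortical"),
    stringsAsFactors = FALSE), c("IV", "VI"))
}
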