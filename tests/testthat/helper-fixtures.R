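# Shared fixture builders for the test suite.

# A smooth 2-d test surface for emulator checks.
smooth2 <- function(U) sin(3 * U[, 1]) + U[, 2]^2

# Write a parameter-table CSV and return its path.
write_param_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

tiny_table <- function() {
  data.frame(name = c("a", "b"), mean = c(10, 2), cv = c(0.1, 0.2),
             lower = c(8.04, 1.216), upper = c(11.96, 2.784),
             units = "u", group = "", provenance = "literature",
             stringsAsFactors = FALSE)
}

# Two-member fraction group with the thyroid blood/tissue nominal split.
group_space <- function() {
  parameter_space(data.frame(
    name = c("tissue", "blood"), mean = c(0.724, 0.276), cv = c(0.3, 0.3),
    lower = c(0.3, 0.1), upper = c(1.1, 0.4),
    units = "fraction", group = "thy", provenance = "assumed_default",
    stringsAsFactors = FALSE))
}
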