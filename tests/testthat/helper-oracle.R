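# Independent brute-force oracle for the state space: generate all 3^i slot
# assignments and filter by the constraints, without reusing any package
# enumeration code. Rows are sorted lexicographically (water 0 < tracer 1 <
# vacancy 2) to match the package ordering contract.
brute_force_configs <- function(i) {
  grid <- as.matrix(expand.grid(rep(list(0:2), i)))
  keep <- rowSums(grid == 1) <= 1 & rowSums(grid == 2) <= 1
  m <- grid[keep, , drop = FALSE]
  m <- m[do.call(order, as.data.frame(m)), , drop = FALSE]
  dimnames(m) <- NULL
  m
}

# Brute-force census computed straight off the filtered grid.
brute_force_census <- function(i) {
  m <- brute_force_configs(i)
  tracer <- rowSums(m == 1) == 1
  vacancy <- rowSums(m == 2) == 1
  exit_tracer <- m[, i] == 1
  list(
    i = i,
    n_total = nrow(m),
    n_null = sum(!tracer & !vacancy),
    n_tracer_only = sum(tracer & !vacancy),
    n_vacancy_only = sum(!tracer & vacancy),
    n_tracer_and_vacancy = sum(tracer & vacancy),
    n_d = sum(tracer),
    n_dex = sum(exit_tracer),
    n_f = sum(tracer & !vacancy),
    n_fex = sum(exit_tracer & !vacancy)
  )
}

expect_census_equal <- function(a, b) {
  for (field in names(b)) {
    expect_equal(as.integer(a[[field]]), as.integer(b[[field]]),
                 label = paste0(field, " at i=", b$i))
  }
}
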