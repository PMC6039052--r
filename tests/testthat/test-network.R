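# Network geometry: fanout, normalization, and the wiring audit
# against a brute-force geometric oracle.

# independent enumeration: scan every target cell's position
brute_force_targets <- function(i, ns, nt, radius, exclude_self = FALSE) {
  x <- (i - 0.5) / ns
  rho <- radius / ns
  out <- integer()
  for (j in seq_len(nt)) {
    if (abs((j - 0.5) / nt - x) <= rho + 1e-9) out <- c(out, j)
  }
  if (!length(out)) {
    d <- abs((seq_len(nt) - 0.5) / nt - x)
    out <- which(d < min(d) + 1e-9)[1]  # ties resolve to the lower index
  }
  if (exclude_self) out <- out[out != i]
  out
}

test_that("fanout geometry matches brute-force enumeration", {
  cases <- expand.grid(ns = c(7, 20, 50), nt = c(5, 20, 41),
                       radius = c(0, 0.5, 2, 10))
  for (k in seq_len(nrow(cases))) {
    ns <- cases$ns[k]; nt <- cases$nt[k]; r <- cases$radius[k]
    for (i in seq_len(ns)) {
      expect_identical(
        fanout_targets(i, ns, nt, r),
        as.integer(brute_force_targets(i, ns, nt, r)),
        info = sprintf("ns=%d nt=%d r=%g i=%d", ns, nt, r, i)
      )
    }
  }
})

test_that("fanout has the documented interior count and edge truncation", {
  # thalamic cell 100 of 200 projecting radius 10 onto 1000 -> 101 cells
  expect_length(fanout_targets(100, 200, 1000, 10), 101)
  # radius 0, equal sizes: exactly the aligned cell; self-exclusion empties
  expect_identical(fanout_targets(7, 20, 20, 0), 7L)
  expect_length(fanout_targets(7, 20, 20, 0, exclude_self = TRUE), 0)
  # truncation at the boundary
  interior <- length(fanout_targets(100, 200, 1000, 10))
  edge <- length(fanout_targets(1, 200, 1000, 10))
  expect_lt(edge, interior)
})

test_that("weight normalization divides by input count", {
  expect_equal(normalize_weight(0.15, 1), 0.15)
  expect_equal(normalize_weight(0.15, 21), 0.15 / 21)
  expect_error(normalize_weight(0.15, 0), "n_inputs")
})

test_that("doubling the radius halves interior per-synapse weight", {
  w_of <- function(radius) {
    counts <- vapply(seq_len(200), function(j) {
      length(brute_force_targets(j, 200, 200, radius))
    }, numeric(1))
    # interior receiver count equals interior source count here
    normalize_weight(0.6, max(counts))
  }
  expect_equal(w_of(40) / w_of(20), 0.5, tolerance = 0.05)
})

test_that("built edges match the oracle on a small network", {
  spec <- network_spec(scale = 0.02)  # 20 PY per layer, 4 TC/RE
  nw <- build_network(spec)
  psize <- setNames(nw$populations$size, nw$populations$name)
  for (k in sample(seq_len(nrow(spec$rules)), 8)) {
    rule <- spec$rules[k, ]
    sub <- nw$edges[nw$edges$rule == k, ]
    ns <- psize[[rule$source]]; nt <- psize[[rule$target]]
    expected <- lapply(seq_len(ns), brute_force_targets, ns = ns,
                       nt = nt, radius = rule$radius,
                       exclude_self = rule$source == rule$target)
    got <- split(sub$target_idx, factor(sub$source_idx, seq_len(ns)))
    for (i in seq_len(ns)) {
      expect_identical(sort(unname(got[[i]])), sort(expected[[i]]),
                       info = paste("rule", k, "source", i))
    }
    # normalized weights: g_total / per-target input count
    n_in <- table(factor(sub$target_idx, seq_len(nt)))
    expect_equal(sub$weight,
                 rule$g_total / as.numeric(n_in[sub$target_idx]),
                 tolerance = 1e-12)
  }
})

test_that("per-neuron input conductance totals g_total regardless of radius", {
  for (radius in c(5, 20)) {
    spec <- network_spec(scale = 0.05, py_py_radius = radius)
    nw <- build_network(spec)
    e <- nw$edges
    sub <- e[e$source == "PY_L34" & e$target == "PY_L34" &
               e$receptor == "AMPA", ]
    tot <- tapply(sub$weight, sub$target_idx, sum)
    # every receiving neuron integrates to the printed total
    expect_true(all(abs(tot - 0.6) < 1e-9))
  }
})

test_that("core and matrix thalamus share no synapses and loops close", {
  nw <- build_network(network_spec(scale = 0.1))
  e <- nw$edges
  thal <- c("TC_core", "RE_core", "TC_matrix", "RE_matrix")
  cross <- e$source %in% thal & e$target %in% thal &
    sub("^[A-Z]+_", "", e$source) != sub("^[A-Z]+_", "", e$target)
  expect_equal(sum(cross), 0)
  # reciprocity: every TC has at least one RE input and output
  for (sys in c("core", "matrix")) {
    tc <- paste0("TC_", sys); re <- paste0("RE_", sys)
    n_tc <- nw$populations$size[nw$populations$name == tc]
    expect_setequal(unique(e$target_idx[e$source == re & e$target == tc]),
                    seq_len(n_tc))
    expect_setequal(unique(e$source_idx[e$source == tc & e$target == re]),
                    seq_len(n_tc))
  }
  # matrix thalamocortical synapses weaker than core (broader fanout)
  w_core <- mean(e$weight[e$source == "TC_core" & e$target == "PY_L34" &
                            e$receptor == "AMPA"])
  w_mat <- mean(e$weight[e$source == "TC_matrix" & e$target == "PY_L5" &
                           e$receptor == "AMPA"])
  expect_lt(w_mat, w_core)
})

test_that("an explicit cross-system thalamic rule is rejected", {
  spec <- network_spec(scale = 0.05)
  bad <- spec$rules[1, ]
  bad$source <- "TC_core"; bad$target <- "RE_matrix"
  bad$receptor <- "AMPA"
  spec$rules <- rbind(spec$rules, bad)
  expect_error(build_network(spec), "cross-system")
})

test_that("network construction is deterministic", {
  a <- build_network(network_spec(scale = 0.05))
  b <- build_network(network_spec(scale = 0.05))
  expect_identical(a$edges, b$edges)
})

test_that("disabling normalization fixes per-synapse weight across fanout", {
  w_at <- function(r) {
    spec <- network_spec(scale = 0.1, variant = "onelayer",
                         normalize = FALSE, tc_radius = r)
    e <- build_network(spec)$edges
    unique(round(e$weight[e$source == "TC_core" & e$target == "PY_L1"], 12))
  }
  expect_identical(w_at(10), w_at(40))
})
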