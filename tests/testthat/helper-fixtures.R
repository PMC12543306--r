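# Shared fixtures, built lazily and cached so expensive discovery runs are
# computed once per test session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_cache)) {
    assign(name, build(), .fixture_cache)
  }
  get(name, .fixture_cache)
}

# Small multi-subject study: 4 subjects, 2 datasets, 3 sessions each.
small_multi_design <- function(n_regions = 15, seed = 5) {
  study_design(
    data.frame(
      subject_id = c("s1", "s2", "s3", "s4"),
      dataset_id = c("A", "A", "B", "B"),
      hc_use = c(0, 1, 0, 1),
      n_sessions = 3L, interval_days = 7L, cycle_length = 28L
    ),
    n_regions = n_regions, seed = seed
  )
}

# Recovery/transfer fixture: daily discovery study with only the HC effect
# planted (strong effect; noise dominates individual offsets so the planted
# effect, not subject idiosyncrasy, carries across studies; no dataset
# offset so the HC contrast is not aliased by the dataset offset).
recovery_truth <- function(hc_effect = 1.2) {
  ground_truth_spec(
    hc_effect = hc_effect, e2_effect = 0, p4_effect = 0, motion_effect = 0,
    dataset_offset_scale = 0, individual_offset_scale = 0.1,
    noise_scale = 0.2
  )
}

# Matched external cohort for transfer evaluation: balanced HC use,
# identical generative conditions to the recovery fixture apart from the
# planted effect magnitude.
matched_external_study <- function(hc_effect) {
  generate_study(
    study_design(
      data.frame(subject_id = sprintf("x%02d", 1:10),
                 dataset_id = "external", hc_use = rep(c(0, 1), 5),
                 n_sessions = 4L, interval_days = 7L, cycle_length = 28L),
      n_regions = 50, seed = 29
    ),
    recovery_truth(hc_effect = hc_effect)
  )
}

recovery_study <- function() {
  fixture("recovery_study", function() {
    generate_study(daily_discovery_design(n_regions = 50, seed = 11),
                   recovery_truth())
  })
}

# Discovery run on the recovery fixture (shared by the recovery and
# transfer checks).
recovery_discovery <- function() {
  fixture("recovery_discovery", function() {
    run_discovery(recovery_study(), cv_config("hc", n_iterations = 100,
                                              seed = 7))
  })
}

# Union-find connectivity oracle, independent of igraph: returns TRUE when
# the given (i, j) edges form a single connected subgraph over the nodes
# they touch.
uf_connected <- function(edges) {
  if (!nrow(edges)) return(FALSE)
  nodes <- sort(unique(c(edges[, 1], edges[, 2])))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
    x
  }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[[as.character(a)]] <- b
  }
  length(unique(vapply(nodes, find, numeric(1)))) == 1
}

# Union-find oracle for the largest connected component of an edge list on
# 1..n: returns the edge ids (rows of `edges`) of the component with the
# most edges, ties toward the component holding the smallest node.
uf_largest_component <- function(edges, n) {
  if (!nrow(edges)) return(integer(0))
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  edge_root <- roots[edges[, 1]]
  counts <- table(edge_root)
  best_roots <- as.integer(names(counts)[counts == max(counts)])
  if (length(best_roots) > 1) {
    min_node <- vapply(best_roots, function(rt) min(which(roots == rt)),
                       integer(1))
    best_roots <- best_roots[which.min(min_node)]
  }
  which(edge_root == best_roots)
}

# Jaccard index of two edge-id sets.
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Permute one outcome column of a study's session table (null simulation).
permute_outcome <- function(study, outcome, seed) {
  study$sessions[[outcome]] <- withr::with_seed(
    seed, sample(study$sessions[[outcome]]))
  study
}
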