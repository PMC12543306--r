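#' Describe the session layout of a (synthetic) multi-dataset study
#'
#' A study design lists, per subject-by-dataset block, how many sessions are
#' acquired, at what day spacing, and under which hormonal-contraceptive (HC)
#' condition. The default mirrors a dense-sampling two-dataset design: one
#' subject scanned daily for 30 days naturally cycling and for another 30
#' days while using HCs (two datasets), plus an independent weekly-sampled
#' dataset of three subjects with 10 sessions in total.
#'
#' @param subjects Data frame with columns `subject_id`, `dataset_id`,
#'   `hc_use` (0/1), `n_sessions`, `interval_days`, `cycle_length`.
#' @param n_regions Number of brain regions (>= 10).
#' @param seed Integer seed controlling every random draw of the generator.
#' @return An object of class `"study_design"`.
#' @export
study_design <- function(subjects, n_regions = 50, seed = 1L) {
  need <- c("subject_id", "dataset_id", "hc_use", "n_sessions",
            "interval_days", "cycle_length")
  missing_cols <- setdiff(need, names(subjects))
  if (length(missing_cols)) {
    stop("subjects table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (n_regions < 10) stop("n_regions must be >= 10, got ", n_regions)
  if (any(subjects$n_sessions < 2)) {
    stop("every subject block needs >= 2 sessions")
  }
  if (any(subjects$cycle_length < 21 | subjects$cycle_length > 35)) {
    stop("cycle_length must lie in [21, 35]")
  }
  # HC status must be constant within (subject, dataset)
  key <- paste(subjects$subject_id, subjects$dataset_id)
  if (anyDuplicated(key)) {
    stop("duplicate (subject_id, dataset_id) block in design")
  }
  structure(
    list(subjects = as.data.frame(subjects), n_regions = as.integer(n_regions),
         seed = as.integer(seed)),
    class = "study_design"
  )
}

#' Default daily-sampling discovery design (one subject, two datasets)
#'
#' @param n_regions Number of regions.
#' @param seed Integer seed.
#' @return A `"study_design"` with 60 daily sessions: 30 naturally cycling,
#'   30 under HC use, in separate datasets.
#' @export
daily_discovery_design <- function(n_regions = 50, seed = 1L) {
  study_design(
    data.frame(
      subject_id = c("sub-01", "sub-01"),
      dataset_id = c("dailyNC", "dailyHC"),
      hc_use = c(0L, 1L),
      n_sessions = c(30L, 30L),
      interval_days = c(1L, 1L),
      cycle_length = c(28L, 28L)
    ),
    n_regions = n_regions, seed = seed
  )
}

#' Default weekly-sampling external design (three subjects, 10 sessions)
#'
#' @param n_regions Number of regions.
#' @param seed Integer seed.
#' @return A `"study_design"` with three weekly-sampled subjects (one
#'   naturally cycling, two HC users) totalling 10 sessions.
#' @export
weekly_external_design <- function(n_regions = 50, seed = 2L) {
  study_design(
    data.frame(
      subject_id = c("sub-02", "sub-03", "sub-04"),
      dataset_id = "weekly",
      hc_use = c(0L, 1L, 1L),
      n_sessions = c(3L, 3L, 4L),
      interval_days = 7L,
      cycle_length = c(29L, 27L, 28L)
    ),
    n_regions = n_regions, seed = seed
  )
}

#' Specify planted ground-truth effects for the synthetic generator
#'
#' Each session's latent edge score is a sum of a shared group backbone,
#' dataset and individual offsets, planted HC / estradiol / progesterone /
#' motion edge effects, and i.i.d. Gaussian noise, passed through `tanh` to
#' land in (-1, 1). Each planted effect lives on a connected subgraph so that
#' component-based edge selection can recover it.
#'
#' @param hc_effect,e2_effect,p4_effect,motion_effect Effect magnitudes in
#'   latent edge-score units per unit of the (scaled) predictor.
#' @param n_hc_edges,n_e2_edges,n_p4_edges,n_motion_edges Sizes of the
#'   planted connected edge sets.
#' @param individual_offset_scale,dataset_offset_scale SDs of per-subject and
#'   per-dataset random edge offsets.
#' @param backbone_density Fraction of edges carrying the shared group
#'   backbone.
#' @param backbone_scale Scale of backbone edge scores.
#' @param noise_scale SD of per-session, per-edge Gaussian noise.
#' @param edges Optional named list (`hc`, `e2`, `p4`, `motion`) of fixed
#'   two-column (i, j) edge matrices overriding the population-level draws.
#' @param population_seed Integer seed for *population-level* structure: the
#'   group backbone, the planted effect networks, and the per-dataset and
#'   per-subject offsets (keyed to their ids). Two studies generated with
#'   the same `population_seed` therefore share the group connectome and the
#'   planted effect topography -- the premise of any transfer evaluation --
#'   while each study's sessions, hormones, and noise follow its own design
#'   seed, and a subject appearing in both studies keeps their idiosyncratic
#'   offsets.
#' @return An object of class `"ground_truth_spec"`.
#' @export
ground_truth_spec <- function(hc_effect = 0.8, e2_effect = 0.6,
                              p4_effect = 0.6, motion_effect = 0.3,
                              n_hc_edges = 15L, n_e2_edges = 15L,
                              n_p4_edges = 15L, n_motion_edges = 10L,
                              individual_offset_scale = 0.3,
                              dataset_offset_scale = 0.1,
                              backbone_density = 0.15,
                              backbone_scale = 0.5,
                              noise_scale = 0.1,
                              edges = NULL,
                              population_seed = 100L) {
  scales <- c(individual_offset_scale, dataset_offset_scale,
              backbone_density, backbone_scale, noise_scale)
  if (any(scales < 0)) stop("all scales must be >= 0")
  structure(
    list(
      effects = c(hc = hc_effect, e2 = e2_effect, p4 = p4_effect,
                  motion = motion_effect),
      n_edges = c(hc = as.integer(n_hc_edges), e2 = as.integer(n_e2_edges),
                  p4 = as.integer(n_p4_edges),
                  motion = as.integer(n_motion_edges)),
      individual_offset_scale = individual_offset_scale,
      dataset_offset_scale = dataset_offset_scale,
      backbone_density = backbone_density,
      backbone_scale = backbone_scale,
      noise_scale = noise_scale,
      edges = edges,
      population_seed = as.integer(population_seed)
    ),
    class = "ground_truth_spec"
  )
}

#' Draw a random connected edge set on a region graph
#'
#' Samples `n_edges` distinct edges on `n_regions` nodes whose induced
#' subgraph is connected: a random spanning tree over a sampled node set is
#' grown first, then extra edges are added among those nodes. Used to plant
#' ground-truth components that mirror the largest-connected-component
#' selection of the prediction pipeline.
#'
#' @param n_regions Number of available nodes.
#' @param n_edges Number of edges to place (`1 <= n_edges <= choose(n, 2)`).
#' @param seed Integer seed.
#' @return Integer matrix with columns `i`, `j` (`i < j`), rows in canonical
#'   edge order.
#' @export
plant_connected_component <- function(n_regions, n_edges, seed = 1L) {
  n_regions <- as.integer(n_regions)
  n_edges <- as.integer(n_edges)
  max_edges <- n_regions * (n_regions - 1) / 2
  if (n_edges < 1L) stop("n_edges must be >= 1")
  if (n_edges > max_edges) {
    stop("n_edges = ", n_edges, " exceeds the ", max_edges,
         " possible edges on ", n_regions, " regions")
  }
  # smallest node count whose complete graph holds n_edges
  m_min <- 2L
  while (m_min * (m_min - 1L) / 2L < n_edges) m_min <- m_min + 1L
  m_max <- min(n_regions, n_edges + 1L)

  withr::with_seed(seed, {
    m <- if (m_min >= m_max) m_min else sample(seq.int(m_min, m_max), 1L)
    nodes <- sort(sample.int(n_regions, m))
    # random spanning tree: attach node k to a random earlier node
    tree <- vapply(seq_len(m - 1L), function(k) {
      a <- nodes[k + 1L]
      b <- nodes[if (k == 1L) 1L else sample.int(k, 1L)]
      c(min(a, b), max(a, b))
    }, integer(2))
    edges <- t(tree)
    if (n_edges > m - 1L) {
      all_pairs <- edge_pairs(n_regions)
      cand <- all_pairs[all_pairs[, 1] %in% nodes & all_pairs[, 2] %in% nodes, ,
                        drop = FALSE]
      used <- paste(edges[, 1], edges[, 2])
      cand <- cand[!(paste(cand[, 1], cand[, 2]) %in% used), , drop = FALSE]
      extra <- cand[sample.int(nrow(cand), n_edges - (m - 1L)), , drop = FALSE]
      edges <- rbind(edges, extra)
    }
  })
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("i", "j"))
  edges
}

#' Generate a synthetic functional-connectome study with known ground truth
#'
#' Produces one connectome and one session record per scheduled session.
#' The latent score of edge `e` in session `s` is
#' `backbone_e + dataset_offset + individual_offset +
#'  hc_effect * hc_s * [e in HC set] + e2_effect * e2s_s * [e in E2 set] +
#'  p4_effect * p4s_s * [e in P4 set] + motion_effect * fd_s * [e in FD set] +
#'  noise`, and the stored edge weight is `tanh` of that score, so matrices
#' are symmetric with values in (-1, 1) and unit diagonal. `e2s`/`p4s` are
#' hormone concentrations min-max scaled within dataset; `fd` is the
#' session's mean framewise displacement in mm.
#'
#' @param design A [study_design()].
#' @param truth A [ground_truth_spec()].
#' @return An object of class `"fc_study"`: a list with `sessions` (session
#'   table), `connectomes` (named list of [connectome()] objects, one per
#'   session, keyed `subject_session`), `region_labels`, and `truth` (planted
#'   edge sets as (i, j) matrices plus canonical edge ids, coefficients,
#'   offsets, and the seed).
#' @export
generate_study <- function(design, truth = ground_truth_spec()) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "ground_truth_spec"))
  n <- design$n_regions
  labels <- sprintf("region_%03d", seq_len(n))
  pairs <- edge_pairs(n)
  n_edge <- nrow(pairs)

  # planted masks (fixed edges reused when supplied)
  masks <- list()
  for (k in seq_along(truth$n_edges)) {
    eff <- names(truth$n_edges)[k]
    masks[[eff]] <- if (!is.null(truth$edges[[eff]])) {
      e <- as.matrix(truth$edges[[eff]])
      dimnames(e) <- list(NULL, c("i", "j"))
      e
    } else {
      plant_connected_component(n, truth$n_edges[[eff]],
                                seed = derive_seed(truth$population_seed,
                                                   100 + k))
    }
  }
  mask_ids <- lapply(masks, function(e) edge_id(e[, 1], e[, 2], n))

  subj <- design$subjects
  datasets <- unique(subj$dataset_id)
  subjects <- unique(subj$subject_id)

  # population-level structure: shared across studies drawn with the same
  # population seed, and keyed to dataset/subject ids so repeated ids keep
  # their offsets across studies
  backbone <- withr::with_seed(derive_seed(truth$population_seed, 1L), {
    bb <- numeric(n_edge)
    n_bb <- round(truth$backbone_density * n_edge)
    if (n_bb > 0) {
      sel <- sample.int(n_edge, n_bb)
      bb[sel] <- truth$backbone_scale * stats::rnorm(n_bb, mean = 1, sd = 0.3)
    }
    bb
  })
  ds_off <- lapply(stats::setNames(datasets, datasets), function(d)
    withr::with_seed(derive_seed(truth$population_seed, 2e6 + string_seed(d)),
                     stats::rnorm(n_edge, 0, truth$dataset_offset_scale)))
  ind_off <- lapply(stats::setNames(subjects, subjects), function(s)
    withr::with_seed(derive_seed(truth$population_seed, 4e6 + string_seed(s)),
                     stats::rnorm(n_edge, 0, truth$individual_offset_scale)))

  # session table
  rows <- list()
  for (b in seq_len(nrow(subj))) {
    days <- (seq_len(subj$n_sessions[b]) - 1L) * subj$interval_days[b]
    cyc <- days %% subj$cycle_length[b]
    horm <- simulate_hormone_cycle(
      subj$cycle_length[b], hc_use = subj$hc_use[b] == 1L,
      sample_days = cyc, seed = derive_seed(design$seed, 200 + b)
    )
    fd <- withr::with_seed(derive_seed(design$seed, 300 + b),
      exp(stats::rnorm(length(days), log(0.12), 0.25)))
    rows[[b]] <- data.frame(
      subject_id = subj$subject_id[b],
      dataset_id = subj$dataset_id[b],
      session_id = sprintf("ses-%03d", seq_along(days)),
      hc_use = as.integer(subj$hc_use[b]),
      cycle_day = as.integer(cyc),
      e2 = horm$e2,
      p4 = horm$p4,
      mean_fd = fd
    )
  }
  sessions <- do.call(rbind, rows)
  rownames(sessions) <- NULL

  e2s <- minmax_by(sessions$e2, sessions$dataset_id)
  p4s <- minmax_by(sessions$p4, sessions$dataset_id)

  connectomes <- vector("list", nrow(sessions))
  for (s in seq_len(nrow(sessions))) {
    z <- backbone +
      ds_off[[sessions$dataset_id[s]]] +
      ind_off[[sessions$subject_id[s]]]
    z[mask_ids$hc] <- z[mask_ids$hc] +
      truth$effects[["hc"]] * sessions$hc_use[s]
    z[mask_ids$e2] <- z[mask_ids$e2] + truth$effects[["e2"]] * e2s[s]
    z[mask_ids$p4] <- z[mask_ids$p4] + truth$effects[["p4"]] * p4s[s]
    z[mask_ids$motion] <- z[mask_ids$motion] +
      truth$effects[["motion"]] * sessions$mean_fd[s]
    if (truth$noise_scale > 0) {
      z <- z + withr::with_seed(derive_seed(design$seed, 1000 + s),
        stats::rnorm(n_edge, 0, truth$noise_scale))
    }
    connectomes[[s]] <- unvectorize(tanh(z), labels)
  }
  names(connectomes) <- paste(sessions$subject_id, sessions$session_id,
                              sep = "_")
  # session ids are only unique within a subject-dataset block; disambiguate
  if (anyDuplicated(names(connectomes))) {
    names(connectomes) <- paste(sessions$subject_id, sessions$dataset_id,
                                sessions$session_id, sep = "_")
    sessions$session_id <- paste(sessions$dataset_id, sessions$session_id,
                                 sep = "_")
  }

  structure(
    list(
      sessions = sessions,
      connectomes = connectomes,
      region_labels = labels,
      truth = list(masks = masks, mask_ids = mask_ids,
                   effects = truth$effects, seed = design$seed,
                   noise_scale = truth$noise_scale,
                   individual_offset_scale = truth$individual_offset_scale,
                   dataset_offset_scale = truth$dataset_offset_scale)
    ),
    class = "fc_study"
  )
}

#' Stack a study's connectomes into a session-by-edge matrix
#'
#' @param study An `"fc_study"` (from [generate_study()] or [load_study()]).
#' @return Numeric matrix, one row per session (in session-table order), one
#'   column per edge in canonical order.
#' @export
edge_matrix <- function(study) {
  stopifnot(inherits(study, "fc_study"))
  t(vapply(study$connectomes, vectorize,
           numeric(length(study$region_labels) *
                     (length(study$region_labels) - 1) / 2)))
}

#' @export
print.fc_study <- function(x, ...) {
  cat("<fc_study> ", nrow(x$sessions), " sessions, ",
      length(unique(x$sessions$subject_id)), " subject(s), ",
      length(unique(x$sessions$dataset_id)), " dataset(s), ",
      length(x$region_labels), " regions\n", sep = "")
  invisible(x)
}

# Subset a study's sessions (and connectomes) by logical/integer index.
subset_study <- function(study, idx) {
  out <- study
  out$sessions <- study$sessions[idx, , drop = FALSE]
  rownames(out$sessions) <- NULL
  out$connectomes <- study$connectomes[idx]
  out
}
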